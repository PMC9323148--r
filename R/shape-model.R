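#' Build an observation matrix from corresponded meshes
#'
#' Stacks vectorized corresponded meshes (xyz-interleaved) as the columns of
#' a 3p x n matrix, with per-column class labels, mirrored flags and the
#' original/mirror pairing.
#'
#' @param meshes list of corresponded [surface_mesh()]es (shared topology).
#' @param labels character vector of class labels (length n).
#' @param mirrored logical vector (length n), `TRUE` for mirrored twins.
#' @param mirror_pairs integer vector (length n): index of each column's
#'   mirror partner, `NA` when absent.
#' @return object of class `observation_matrix`: list with `X` (3p x n),
#'   `labels`, `mirrored`, `mirror_pairs`, `faces` (template topology).
#' @export
observation_matrix <- function(meshes, labels = NULL, mirrored = NULL,
                               mirror_pairs = NULL) {
  n <- length(meshes)
  if (n < 2L) stop("need at least two observations")
  p <- n_vertices(meshes[[1]])
  f <- meshes[[1]]$faces
  for (m in meshes) {
    if (n_vertices(m) != p || !identical(m$faces, f)) {
      stop("topology mismatch among corresponded meshes")
    }
  }
  X <- vapply(meshes, function(m) as_shape_vector(m$vertices), numeric(3L * p))
  if (!all(is.finite(X))) stop("non-finite coordinates in observations")
  if (is.null(labels)) labels <- rep(NA_character_, n)
  if (is.null(mirrored)) mirrored <- rep(FALSE, n)
  if (is.null(mirror_pairs)) mirror_pairs <- rep(NA_integer_, n)
  colnames(X) <- names(meshes)
  structure(list(X = X, labels = as.character(labels),
                 mirrored = as.logical(mirrored),
                 mirror_pairs = as.integer(mirror_pairs), faces = f),
            class = "observation_matrix")
}

#' Center observations (zero-mean data matrix)
#'
#' @param X 3p x n observation matrix.
#' @return list with `X_zm` (centered matrix) and `mean` (3p row-mean
#'   vector).
#' @export
center_observations <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least two observations")
  xbar <- rowMeans(X)
  list(X_zm = X - xbar, mean = xbar)
}

#' Weighted PCA shape model from centered observations (Gram-matrix route)
#'
#' Computes the weighted Gram matrix `G_W = X^T M3 X` (n x n), its symmetric
#' eigendecomposition `G_W = U_G Lambda_G U_G^T` with eigenvalues descending,
#' the principal components `V = X U_G Lambda_G^(-1/2)` (computed only for
#' eigenvalues above the rank cutoff), and the sample-covariance eigenvalues
#' `Lambda = Lambda_G / (n - 1)`. The columns of V are M3-orthonormal
#' (`V^T M3 V = I`). Compared with plain PCA, the area-weighted inner product
#' stops densely sampled regions (the face) from dominating the components.
#' As the data are centered, the smallest eigenvalue is (numerically) zero
#' and is dropped, so at most n - 1 components are returned.
#'
#' @param X_zm centered 3p x n matrix (see [center_observations()]).
#' @param M3 3p x 3p channel-replicated mass matrix (or a `mass_matrix`
#'   object, whose `M3` is used); identity weighting recovers ordinary PCA.
#' @param mean the mean shape to store in the model (3p vector).
#' @param rank_cutoff eigenvalues below `rank_cutoff * lambda_1` are treated
#'   as zero and dropped (default 1e-10).
#' @param faces template topology to store, optional.
#' @param labels training labels to store, optional.
#' @return object of class `shape_model`: list with `mean`, `V` (3p x m),
#'   `lambda` (m descending eigenvalues), `M3`, `faces`, `n_train`,
#'   `labels`.
#' @export
build_wpca_model <- function(X_zm, M3, mean = NULL, rank_cutoff = 1e-10,
                             faces = NULL, labels = NULL) {
  X_zm <- as.matrix(X_zm)
  n <- ncol(X_zm)
  if (n < 2L) stop("need at least two observations")
  if (inherits(M3, "mass_matrix")) M3 <- M3$M3
  if (nrow(M3) != nrow(X_zm) || ncol(M3) != nrow(X_zm)) {
    stop("M3 must be 3p x 3p for 3p = ", nrow(X_zm))
  }
  if (all(X_zm == 0)) stop("all-zero (constant) observations: no variation")
  MX <- as.matrix(M3 %*% X_zm)
  G <- crossprod(X_zm, MX)
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values > rank_cutoff * eg$values[1]
  U <- eg$vectors[, keep, drop = FALSE]
  lam_G <- eg$values[keep]
  V <- X_zm %*% sweep(U, 2, 1 / sqrt(lam_G), `*`)
  # deterministic sign convention: largest-magnitude entry positive
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  if (is.null(mean)) mean <- numeric(nrow(X_zm))
  structure(list(mean = as.numeric(mean), V = V, lambda = lam_G / (n - 1),
                 M3 = M3, faces = faces, n_train = n, labels = labels),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat("shape_model: p=", length(x$mean) / 3, " vertices, ", n_components(x),
      " components, n_train=", x$n_train, "\n", sep = "")
  invisible(x)
}

#' Number of retained components of a shape model
#' @param model a `shape_model`.
#' @return integer.
#' @export
n_components <- function(model) ncol(model$V)

#' Build a shape model from corresponded meshes (GPA + weighted PCA)
#'
#' Full pipeline step: rigid generalized Procrustes alignment, centering, and
#' the Gram-matrix weighted PCA. The mass matrix is computed on the template
#' topology at the aligned mean shape.
#'
#' @param obs an [observation_matrix()] (or list of corresponded meshes).
#' @param mass optional `mass_matrix`; computed from the mean shape on the
#'   template topology when omitted.
#' @param gpa run rigid GPA first (default `TRUE`).
#' @param ... passed to [build_wpca_model()].
#' @return a `shape_model` (with the aligned observations attached as
#'   attribute `aligned`).
#' @export
build_shape_model <- function(obs, mass = NULL, gpa = TRUE, ...) {
  if (!inherits(obs, "observation_matrix")) {
    obs <- observation_matrix(obs)
  }
  X <- obs$X
  if (gpa) {
    al <- generalized_procrustes_rigid(X)
    X <- al$X
  }
  cen <- center_observations(X)
  if (is.null(mass)) {
    mean_mesh <- surface_mesh(as_vertex_matrix(cen$mean), obs$faces,
                              validate = FALSE)
    mass <- compute_mass_matrix(mean_mesh)
  }
  model <- build_wpca_model(cen$X_zm, mass, mean = cen$mean,
                            faces = obs$faces, labels = obs$labels, ...)
  attr(model, "aligned") <- X
  model
}

#' Synthesize a shape from coefficients
#'
#' Evaluates `x = mean + V Lambda^(1/2) alpha`: coefficients are standardized
#' (unitless), each multiplying its component scaled by the standard
#' deviation `sqrt(lambda_k)`.
#'
#' @param model a `shape_model`.
#' @param alpha numeric coefficient vector, length <= number of components
#'   (shorter vectors are zero-padded).
#' @param as_mesh return a [surface_mesh()] on the template topology instead
#'   of a shape vector (requires `model$faces`).
#' @return 3p shape vector, or a `surface_mesh`.
#' @export
synthesize_shape <- function(model, alpha, as_mesh = FALSE) {
  m <- n_components(model)
  if (length(alpha) > m) {
    stop("alpha has ", length(alpha), " entries but the model has ", m,
         " components")
  }
  a <- numeric(m)
  a[seq_along(alpha)] <- alpha
  x <- model$mean + as.vector(model$V %*% (sqrt(model$lambda) * a))
  if (as_mesh) {
    if (is.null(model$faces)) stop("model stores no template topology")
    surface_mesh(as_vertex_matrix(x), model$faces, validate = FALSE)
  } else {
    x
  }
}

#' Project a shape into model coefficients
#'
#' The M3-weighted left inverse of [synthesize_shape()]:
#' `alpha = Lambda^(-1/2) V^T M3 (x - mean)`, using the mass-weighted inner
#' product under which V is orthonormal. The shape must be on the template
#' topology and GPA-aligned to the model frame (see [align_to_model()]).
#'
#' @param model a `shape_model`.
#' @param x 3p shape vector or corresponded [surface_mesh()].
#' @param k number of leading components to use (default: all).
#' @return coefficient vector of length `k`.
#' @export
project_shape <- function(model, x, k = n_components(model)) {
  if (inherits(x, "surface_mesh")) x <- as_shape_vector(x$vertices)
  if (length(x) != length(model$mean)) stop("shape size mismatch")
  if (k < 1L || k > n_components(model)) stop("k out of range")
  lam <- model$lambda[seq_len(k)]
  if (any(lam <= 0)) stop("zero eigenvalue in requested component range")
  b <- crossprod(model$V[, seq_len(k), drop = FALSE],
                 as.vector(model$M3 %*% (x - model$mean)))
  as.vector(b) / sqrt(lam)
}

#' Rigidly align a shape to a model's mean (projection pre-step)
#'
#' @param model a `shape_model`.
#' @param x 3p shape vector or corresponded [surface_mesh()].
#' @return aligned 3p shape vector.
#' @export
align_to_model <- function(model, x) {
  if (inherits(x, "surface_mesh")) x <- as_shape_vector(x$vertices)
  V <- as_vertex_matrix(x)
  as_shape_vector(apply_rigid(rigid_align(V, as_vertex_matrix(model$mean)), V))
}

#' Sample random instances from a shape model
#'
#' Coefficients drawn i.i.d. standard normal per component (the model
#' distribution); shapes synthesized with [synthesize_shape()].
#'
#' @param model a `shape_model`.
#' @param n number of instances.
#' @param seed integer seed (reproducible; caller RNG state untouched).
#' @param k number of leading components to sample (default: all).
#' @return list with `alpha` (k x n coefficient draws) and `shapes`
#'   (3p x n matrix of synthesized shape vectors).
#' @export
sample_instances <- function(model, n, seed = 1L, k = n_components(model)) {
  stopifnot(n >= 1)
  A <- with_seed(seed, matrix(stats::rnorm(k * n), k, n))
  S <- vapply(seq_len(n), function(j) synthesize_shape(model, A[, j]),
              numeric(length(model$mean)))
  list(alpha = A, shapes = S)
}

#' Build class-specific submodels and the cranium-only model
#'
#' One shape model per class (each from its class columns only, with its own
#' GPA) and one cranial model built on the cranial submesh coordinates of all
#' observations, with its own GPA and a mass matrix computed on the cranial
#' submesh. Mirrored twins carry their original's label and contribute to the
#' same submodel.
#'
#' @param obs an [observation_matrix()].
#' @param cranial_mask integer template vertex indices of the cranial region
#'   (optional; cranial model skipped when `NULL`).
#' @param ... passed to [build_shape_model()].
#' @return list with `submodels` (named list of `shape_model`s, one per
#'   class) and `cranial` (the cranium-only `shape_model`, or `NULL`).
#' @export
build_submodels <- function(obs, cranial_mask = NULL, ...) {
  stopifnot(inherits(obs, "observation_matrix"))
  classes <- unique(obs$labels)
  small <- classes[vapply(classes,
                          function(cl) sum(obs$labels == cl) < 2L, logical(1))]
  if (length(small) > 0L) {
    stop("class(es) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  }
  submodels <- lapply(classes, function(cl) {
    idx <- which(obs$labels == cl)
    sub <- structure(list(X = obs$X[, idx, drop = FALSE],
                          labels = obs$labels[idx],
                          mirrored = obs$mirrored[idx],
                          mirror_pairs = rep(NA_integer_, length(idx)),
                          faces = obs$faces),
                     class = "observation_matrix")
    build_shape_model(sub, ...)
  })
  names(submodels) <- classes
  cranial <- if (!is.null(cranial_mask)) {
    build_cranial_model(obs, cranial_mask, ...)
  }
  list(submodels = submodels, cranial = cranial)
}

#' Build the cranium-only model
#'
#' Restricts every observation to the cranial vertex mask (defined once on
#' the template and transferred through shared point identifiers), runs its
#' own GPA on the cranial coordinates and builds the weighted PCA model with
#' a mass matrix computed on the cranial submesh.
#'
#' @param obs an [observation_matrix()].
#' @param cranial_mask integer template vertex indices.
#' @param ... passed to [build_shape_model()].
#' @return a `shape_model` on the cranial submesh (with `index_map` element
#'   giving parent vertex indices).
#' @export
build_cranial_model <- function(obs, cranial_mask, ...) {
  stopifnot(inherits(obs, "observation_matrix"))
  tpl <- surface_mesh(as_vertex_matrix(obs$X[, 1]), obs$faces,
                      validate = FALSE)
  sub <- extract_submesh(tpl, cranial_mask)
  rows <- coordinate_rows(sub$index_map)
  cobs <- structure(list(X = obs$X[rows, , drop = FALSE], labels = obs$labels,
                         mirrored = obs$mirrored,
                         mirror_pairs = obs$mirror_pairs,
                         faces = sub$mesh$faces),
                    class = "observation_matrix")
  model <- build_shape_model(cobs, ...)
  model$index_map <- sub$index_map
  model
}

#' Save / load a shape model container
#'
#' Serializes the model (mean, components, eigenvalues, mass matrix,
#' topology, labels) with a provenance attribute, as an RDS file.
#'
#' @param model a `shape_model`.
#' @param path output path (conventionally `.rds`).
#' @return `path` invisibly / the restored `shape_model`.
#' @export
save_shape_model <- function(model, path) {
  attr(model, "provenance") <- paste0("craniomorph shape_model v1; saved ",
                                      format(Sys.time(), "%Y-%m-%d"))
  attr(model, "aligned") <- NULL
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_shape_model
#' @export
load_shape_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "shape_model")) stop("not a shape_model file: ", path)
  model
}
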