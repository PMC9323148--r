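#' Landmark error of a morphed template
#'
#' Mean Euclidean distance between the morphed template's landmark vertices
#' and the annotated target landmarks: a sparse point-to-point error on known
#' correspondences.
#'
#' @param morphed corresponded [surface_mesh()].
#' @param template_lm_indices named integer vector of template landmark
#'   vertex indices.
#' @param target_lms target [landmark_set()].
#' @return mean landmark error (mm).
#' @export
landmark_error <- function(morphed, template_lm_indices, target_lms) {
  L <- landmark_coords(target_lms, names = names(template_lm_indices))
  P <- morphed$vertices[template_lm_indices, , drop = FALSE]
  mean(sqrt(rowSums((P - L)^2)))
}

#' Vertex-to-nearest-neighbor distance
#'
#' Mean distance from each morphed vertex to the nearest point on the target
#' surface (exact point-to-triangle): how closely the template was morphed
#' onto the target, regardless of morphological correctness.
#'
#' @param morphed corresponded [surface_mesh()].
#' @param target target [surface_mesh()].
#' @return mean distance (mm).
#' @export
v2nn_distance <- function(morphed, target) {
  mean(closest_on_mesh(morphed$vertices, target)$distance)
}

#' Per-class surface normal deviation
#'
#' Correspondence-quality metric: after removing translation and rotation
#' within each class (rigid GPA), computes for every vertex the mean pairwise
#' angle between corresponding per-vertex normals across the class's morphs;
#' the class value is the average over vertices, and the cumulative value is
#' the sample-size-weighted average over classes. Evaluating per class avoids
#' penalizing genuine shape differences between pathologies.
#'
#' @param morphed_set list of corresponded [surface_mesh()]es.
#' @param labels class label per mesh.
#' @return list with `per_class` (named vector, degrees) and `cumulative`
#'   (scalar, degrees). Classes of size 1 are excluded with a warning.
#' @export
surface_normal_deviation_per_class <- function(morphed_set, labels) {
  stopifnot(length(morphed_set) == length(labels))
  classes <- unique(labels)
  res <- numeric(0)
  sizes <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) {
      warning("class '", cl, "' has a single morph; excluded")
      next
    }
    al <- generalized_procrustes_rigid(morphed_set[idx])
    f <- morphed_set[[idx[1]]]$faces
    normals <- lapply(seq_along(idx), function(j) {
      vertex_normals(surface_mesh(as_vertex_matrix(al$X[, j]), f,
                                  validate = FALSE))
    })
    k <- length(idx)
    pair_sum <- 0
    n_pairs <- 0L
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        ct <- pmin(pmax(rowSums(normals[[a]] * normals[[b]]), -1), 1)
        pair_sum <- pair_sum + acos(ct) * 180 / pi
        n_pairs <- n_pairs + 1L
      }
    }
    res[cl] <- mean(pair_sum / n_pairs)
    sizes[cl] <- length(idx)
  }
  if (length(res) == 0L) stop("no class with >= 2 morphs")
  list(per_class = res, cumulative = sum(res * sizes) / sum(sizes))
}

#' Model compactness
#'
#' Fraction of total variance captured by the first m components:
#' `sum(lambda[1:m]) / sum(lambda)`. Non-decreasing in m and 1 at full rank.
#'
#' @param model a `shape_model`.
#' @param m number of components (1..rank).
#' @return variance fraction in `[0, 1]`.
#' @export
compactness <- function(model, m) {
  r <- n_components(model)
  if (m < 1L || m > r) stop("m out of range [1, ", r, "]")
  sum(model$lambda[seq_len(m)]) / sum(model$lambda)
}

#' Model generalization (leave-one-out reconstruction error)
#'
#' For each observation: rebuild the model from the remaining columns
#' (GPA + weighted PCA), rigidly align the left-out shape to the fold mean,
#' project with m components, synthesize, and report the mean per-vertex
#' Euclidean error; the result averages over folds. Measures the model's
#' ability to represent unseen observations.
#'
#' @param obs an [observation_matrix()] (n >= 3).
#' @param m number of components; clamped (with a warning) to each fold's
#'   rank.
#' @param mass optional `mass_matrix` reused across folds (computed per fold
#'   from the fold mean when omitted).
#' @return list with `mean` (mm) and `per_fold` (n errors, mm).
#' @export
generalization <- function(obs, m, mass = NULL) {
  stopifnot(inherits(obs, "observation_matrix"))
  n <- ncol(obs$X)
  if (n < 3L) stop("need at least 3 observations for leave-one-out")
  errs <- vapply(seq_len(n), function(j) {
    sub <- structure(list(X = obs$X[, -j, drop = FALSE],
                          labels = obs$labels[-j],
                          mirrored = obs$mirrored[-j],
                          mirror_pairs = rep(NA_integer_, n - 1L),
                          faces = obs$faces),
                     class = "observation_matrix")
    fold_model <- build_shape_model(sub, mass = mass)
    mj <- m
    if (mj > n_components(fold_model)) {
      warning("m = ", m, " exceeds fold rank ", n_components(fold_model),
              "; clamped")
      mj <- n_components(fold_model)
    }
    x <- align_to_model(fold_model, obs$X[, j])
    alpha <- project_shape(fold_model, x, k = mj)
    rec <- synthesize_shape(fold_model, alpha)
    mean(sqrt(rowSums((as_vertex_matrix(x) - as_vertex_matrix(rec))^2)))
  }, numeric(1))
  list(mean = mean(errs), per_fold = errs)
}

#' Model specificity (synthetic-to-training distance)
#'
#' Draws Gaussian instances using the first m components and reports, for
#' each, the mean per-vertex distance to the nearest training shape
#' (corresponded topologies make per-vertex distance meaningful), averaged
#' over draws. Measures whether random model samples resemble the training
#' data.
#'
#' @param model a `shape_model`.
#' @param training 3p x n matrix of (aligned) training shape vectors.
#' @param n_samples number of Gaussian draws.
#' @param m number of leading components to sample.
#' @param seed integer seed.
#' @return list with `mean` (mm) and `per_sample` distances (mm).
#' @export
specificity <- function(model, training, n_samples = 100L,
                        m = n_components(model), seed = 1L) {
  stopifnot(n_samples >= 1)
  training <- as.matrix(training)
  sam <- sample_instances(model, n_samples, seed = seed, k = m)
  per <- vapply(seq_len(n_samples), function(j) {
    Vj <- as_vertex_matrix(sam$shapes[, j])
    min(vapply(seq_len(ncol(training)), function(i) {
      mean(sqrt(rowSums((Vj - as_vertex_matrix(training[, i]))^2)))
    }, numeric(1)))
  }, numeric(1))
  list(mean = mean(per), per_sample = per)
}

#' Model metric curves (compactness, generalization, specificity)
#'
#' Evaluates the three standard shape-model quality metrics for
#' m = 1..max_components.
#'
#' @param obs an [observation_matrix()].
#' @param max_components largest m (default: full rank of the full-data
#'   model).
#' @param n_samples Monte Carlo draws for specificity.
#' @param seed seed for specificity sampling.
#' @param metrics subset of `c("compactness", "generalization",
#'   "specificity")`.
#' @return data.frame with one row per m.
#' @export
model_metrics <- function(obs, max_components = NULL, n_samples = 100L,
                          seed = 1L,
                          metrics = c("compactness", "generalization",
                                      "specificity")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  model <- build_shape_model(obs)
  r <- n_components(model)
  if (is.null(max_components)) max_components <- r
  max_components <- min(max_components, r)
  ms <- seq_len(max_components)
  out <- data.frame(m = ms)
  if ("compactness" %in% metrics) {
    out$compactness <- vapply(ms, function(m) compactness(model, m),
                              numeric(1))
  }
  if ("generalization" %in% metrics) {
    out$generalization <- vapply(ms, function(m) generalization(obs, m)$mean,
                                 numeric(1))
  }
  if ("specificity" %in% metrics) {
    training <- attr(model, "aligned")
    out$specificity <- vapply(ms, function(m) {
      specificity(model, training, n_samples = n_samples, m = m,
                  seed = seed)$mean
    }, numeric(1))
  }
  out
}
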