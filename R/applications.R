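#' Per-class mean coefficient vectors
#'
#' Projects each class's (GPA-aligned) training shapes into the full model
#' and averages the coefficient vectors per class. These class means are the
#' attribute directions used by [remove_pathology()].
#'
#' @param model the full `shape_model`.
#' @param X 3p x n matrix of aligned training shape vectors (e.g.
#'   `attr(model, "aligned")`).
#' @param labels class label per column.
#' @param align rigidly re-align each shape to the model mean before
#'   projection (default `TRUE`).
#' @return matrix with one named row per class (class means in coefficient
#'   space).
#' @export
class_mean_coefficients <- function(model, X, labels, align = TRUE) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(labels))
  A <- t(vapply(seq_len(ncol(X)), function(j) {
    x <- if (align) align_to_model(model, X[, j]) else X[, j]
    project_shape(model, x)
  }, numeric(n_components(model))))
  cls <- unique(labels)
  out <- t(vapply(cls, function(cl) colMeans(A[labels == cl, , drop = FALSE]),
                  numeric(ncol(A))))
  rownames(out) <- cls
  out
}

#' Remove (or impose) a pathology by attribute regression
#'
#' Translates a subject's coefficient vector along the difference of class
#' means: `alpha' = alpha + alpha_mu_to - alpha_mu_from`. Moving a
#' scaphocephalic head toward the control mean removes the sagittal-fusion
#' shape while keeping the subject's identity; the operation is exactly
#' invertible (a translation in coefficient space).
#'
#' @param alpha subject coefficient vector (full-model frame).
#' @param from_class,to_class class names present in `class_means`.
#' @param class_means matrix of per-class mean coefficients
#'   (see [class_mean_coefficients()]).
#' @return edited coefficient vector.
#' @export
remove_pathology <- function(alpha, from_class, to_class, class_means) {
  for (cl in c(from_class, to_class)) {
    if (!cl %in% rownames(class_means)) stop("unknown class: ", cl)
  }
  m <- length(alpha)
  stopifnot(m <= ncol(class_means))
  alpha + class_means[to_class, seq_len(m)] - class_means[from_class, seq_len(m)]
}

#' Fixed-region flexibility modes (constrained generalized eigenvalue
#' problem)
#'
#' Finds coefficient-space directions that maximally displace the free
#' vertices while keeping a chosen vertex set (e.g. the cranium) nearly
#' fixed. With `S = V Lambda^(1/2)` (the coefficient-to-displacement map),
#' `A` the rows of S at free coordinates and `B` the rows at fixed
#' coordinates, modes solve `(A^T A) w = lambda (B^T B + eps I) w`; the
#' eigenvalue is the (regularized) free-to-fixed displacement-energy ratio
#' and modes are returned in descending order. A small Tikhonov floor `eps`
#' keeps the problem well-posed when `B^T B` is rank-deficient. Useful for
#' pathology-preserving data augmentation: sample faces/ears/necks while the
#' cranial shape stays put.
#'
#' @param model a `shape_model`.
#' @param fixed_vertex_ids integer vertex indices to hold fixed (nonempty,
#'   strict subset).
#' @param eps regularization; default `1e-8 * trace(B^T B) / m`.
#' @param n_modes number of modes to return (default: all).
#' @return object of class `flexibility_basis`: list with `modes` (m x
#'   n_modes coefficient directions, `(B^T B + eps I)`-orthonormal),
#'   `values` (descending generalized eigenvalues), `fixed_vertex_ids`.
#' @export
flexibility_modes <- function(model, fixed_vertex_ids, eps = NULL,
                              n_modes = NULL) {
  p <- length(model$mean) / 3L
  fixed_vertex_ids <- unique(as.integer(fixed_vertex_ids))
  if (length(fixed_vertex_ids) == 0L) stop("fixed vertex set is empty")
  if (length(fixed_vertex_ids) >= p) {
    stop("fixed vertex set must be a strict subset of the vertices")
  }
  m <- n_components(model)
  S <- model$V %*% diag(sqrt(model$lambda), m, m)
  fixed_rows <- coordinate_rows(fixed_vertex_ids)
  A <- S[-fixed_rows, , drop = FALSE]
  B <- S[fixed_rows, , drop = FALSE]
  AtA <- crossprod(A)
  BtB <- crossprod(B)
  if (is.null(eps)) eps <- 1e-8 * sum(diag(BtB)) / m
  if (eps <= 0) stop("eps must be positive")
  R <- chol(BtB + diag(eps, m))
  Ri <- backsolve(R, diag(m))
  K <- crossprod(Ri, AtA %*% Ri)
  K <- (K + t(K)) / 2
  ek <- eigen(K, symmetric = TRUE)
  W <- Ri %*% ek$vectors      # (B^T B + eps I)-orthonormal
  if (is.null(n_modes)) n_modes <- m
  n_modes <- min(n_modes, m)
  structure(list(modes = W[, seq_len(n_modes), drop = FALSE],
                 values = pmax(ek$values[seq_len(n_modes)], 0),
                 fixed_vertex_ids = fixed_vertex_ids),
            class = "flexibility_basis")
}

#' @export
print.flexibility_basis <- function(x, ...) {
  cat("flexibility_basis: ", ncol(x$modes), " modes, ",
      length(x$fixed_vertex_ids), " fixed vertices; leading ratio ",
      format(x$values[1], digits = 4), "\n", sep = "")
  invisible(x)
}

#' RMS displacement of a mode over fixed vs free vertices
#'
#' @param model the `shape_model` the basis was built from.
#' @param basis a `flexibility_basis`.
#' @param mode mode index.
#' @return list with `fixed`, `free` RMS displacements (mm) and their
#'   `ratio`.
#' @export
mode_displacement_ratio <- function(model, basis, mode = 1L) {
  m <- n_components(model)
  disp <- model$V %*% (sqrt(model$lambda) * basis$modes[, mode])
  fixed_rows <- coordinate_rows(basis$fixed_vertex_ids)
  rms <- function(v) sqrt(mean(v^2))
  fx <- rms(disp[fixed_rows])
  fr <- rms(disp[-fixed_rows])
  list(fixed = fx, free = fr, ratio = fx / fr)
}

#' Sample shapes with a region held fixed
#'
#' Gaussian draws along the top flexibility modes (each mode direction
#' normalized to unit coefficient norm) added to a base shape's
#' coefficients. The fixed-region displacement stays bounded as per the
#' basis construction.
#'
#' @param model a `shape_model`.
#' @param basis a `flexibility_basis` from the same model.
#' @param n number of draws (0 returns the base shape unchanged).
#' @param seed integer seed.
#' @param base_alpha base-shape coefficients (default the mean, all zero).
#' @param n_modes number of top modes to sample along (default 3).
#' @param sd standard deviation of the per-mode draws (in coefficient-norm
#'   units, default 1).
#' @return list with `alpha` (coefficient matrix, one column per draw; the
#'   base coefficients when n = 0) and `shapes` (3p x max(n,1) shape
#'   vectors).
#' @export
sample_constrained <- function(model, basis, n, seed = 1L, base_alpha = NULL,
                               n_modes = 3L, sd = 1) {
  m <- n_components(model)
  if (is.null(base_alpha)) base_alpha <- numeric(m)
  n_modes <- min(n_modes, ncol(basis$modes))
  W <- basis$modes[, seq_len(n_modes), drop = FALSE]
  W <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  if (n == 0L) {
    A <- matrix(base_alpha, m, 1L)
  } else {
    Z <- with_seed(seed, matrix(stats::rnorm(n_modes * n, sd = sd),
                                n_modes, n))
    A <- matrix(base_alpha, m, n) + W %*% Z
  }
  S <- vapply(seq_len(ncol(A)),
              function(j) synthesize_shape(model, A[, j]),
              numeric(length(model$mean)))
  list(alpha = A, shapes = S)
}
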