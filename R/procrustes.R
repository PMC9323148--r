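#' Landmark-based similarity alignment (Procrustes analysis)
#'
#' Closed-form orthogonal Procrustes with isotropic scaling: finds the
#' similarity transform (scale s > 0, rotation R with det +1, translation t)
#' minimizing the sum of squared distances between the transformed source
#' landmarks and the target landmarks. Used to pre-align the template to each
#' target scan before nonrigid morphing; it neither rescales nor changes the
#' target.
#'
#' @param source_lms,target_lms [landmark_set()]s sharing names (or plain
#'   n x 3 matrices in matched row order).
#' @return object of class `similarity_transform`: list with `scale`,
#'   `rotation` (3 x 3), `translation` (3-vector).
#' @export
procrustes_similarity <- function(source_lms, target_lms) {
  S <- if (inherits(source_lms, "landmark_set")) landmark_coords(source_lms)
       else as.matrix(source_lms)
  Tm <- if (inherits(target_lms, "landmark_set")) {
    landmark_coords(target_lms, names = rownames(S))
  } else as.matrix(target_lms)
  if (nrow(S) != nrow(Tm)) stop("landmark sets differ in size")
  if (nrow(S) < 3L) stop("need >= 3 landmarks for a similarity alignment")
  ms <- colMeans(S)
  mt <- colMeans(Tm)
  Sc <- sweep(S, 2, ms)
  Tc <- sweep(Tm, 2, mt)
  ssq <- sum(Sc^2)
  if (ssq < .Machine$double.eps) stop("degenerate (coincident) source landmarks")
  sv <- svd(crossprod(Sc, Tc))   # H = Sc^T Tc
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1)) {
    stop("collinear landmark configuration; rotation undetermined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- sum(sv$d * c(1, 1, d)) / ssq
  t_vec <- unname(mt - s * as.vector(R %*% ms))
  structure(list(scale = s, rotation = unname(R), translation = t_vec),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#'
#' @param transform a `similarity_transform`.
#' @param points n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sweep(points %*% t(transform$rotation) * transform$scale, 2,
        transform$translation, `+`)
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat("similarity_transform: scale=", format(x$scale, digits = 6),
      ", translation=(", paste(format(x$translation, digits = 4),
                               collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# optimal rigid (rotation + translation) alignment of X onto Y (Kabsch)
rigid_align <- function(X, Y) {
  mx <- colMeans(X)
  my <- colMeans(Y)
  H <- crossprod(sweep(X, 2, mx), sweep(Y, 2, my))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = my - as.vector(R %*% mx))
}

apply_rigid <- function(rt, X) {
  sweep(X %*% t(rt$rotation), 2, rt$translation, `+`)
}

#' Rigid generalized Procrustes analysis of corresponded shapes
#'
#' Iteratively aligns every shape to the evolving mean by optimal rotation
#' and translation (no scaling: scale is treated as an attribute of shape,
#' since craniosynostosis-related features depend on age and head size),
#' recomputing the mean until it stabilizes. The Euclidean distance is the
#' Procrustes metric. Removes the non-shape attributes translation and
#' rotation; centroid sizes are untouched.
#'
#' @param X 3p x n observation matrix (xyz-interleaved columns) or a list of
#'   corresponded [surface_mesh()]es sharing the template topology.
#' @param tol relative mean-shape change for convergence (default 1e-7).
#' @param max_iter maximum iterations (default 100).
#' @return list with `X` (aligned 3p x n matrix), `mean` (3p mean shape),
#'   `iterations`.
#' @export
generalized_procrustes_rigid <- function(X, tol = 1e-7, max_iter = 100L) {
  if (is.list(X) && !is.matrix(X)) {
    p0 <- n_vertices(X[[1]])
    f0 <- X[[1]]$faces
    for (m in X) {
      if (n_vertices(m) != p0 || !identical(m$faces, f0)) {
        stop("topology mismatch: all meshes must share the template topology")
      }
    }
    X <- vapply(X, function(m) as_shape_vector(m$vertices), numeric(3L * p0))
  }
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < 2L) stop("need at least two shapes")
  p <- nrow(X) / 3L
  shapes <- lapply(seq_len(n), function(j) as_vertex_matrix(X[, j]))
  # start by centering each shape
  shapes <- lapply(shapes, function(V) sweep(V, 2, colMeans(V)))
  mean_shape <- Reduce(`+`, shapes) / n
  it <- 0L
  repeat {
    it <- it + 1L
    shapes <- lapply(shapes, function(V) apply_rigid(rigid_align(V, mean_shape), V))
    new_mean <- Reduce(`+`, shapes) / n
    delta <- sqrt(sum((new_mean - mean_shape)^2)) /
      max(sqrt(sum(mean_shape^2)), .Machine$double.eps)
    mean_shape <- new_mean
    if (delta < tol || it >= max_iter) break
  }
  Xa <- vapply(shapes, as_shape_vector, numeric(3L * p))
  dimnames(Xa) <- dimnames(X)
  list(X = Xa, mean = as_shape_vector(mean_shape), iterations = it)
}
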