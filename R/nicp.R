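#' Configuration for optimal-step nonrigid ICP (affine per-vertex)
#'
#' The morph runs through a decreasing stiffness schedule. At each stiffness
#' level, nearest-point correspondences against the target surface are found,
#' implausible correspondences are pruned, and the sparse linear least-squares
#' system for all per-vertex 3 x 4 affine transforms is solved; this repeats
#' until the transform-change norm falls below the inner tolerance. High
#' stiffness recovers a near-global transform; low stiffness lets the
#' template creep into target detail.
#'
#' @param stiffness strictly decreasing positive stiffness schedule (default
#'   100 to 1 in 8 geometric steps).
#' @param landmark_weights nonnegative landmark-term weights, one per
#'   stiffness level (default decaying linearly 10 to 0: landmarks guide the
#'   early, stiff levels and release at the end).
#' @param gamma skew weight in the per-edge transform penalty
#'   `diag(1, 1, 1, gamma)` (weights the translational part of the
#'   transform difference against the linear part).
#' @param inner_tol_factor per-level convergence threshold on the Frobenius
#'   norm of the transform change, as a multiple of the vertex count p
#'   (threshold = `inner_tol_factor * p`).
#' @param max_inner maximum inner iterations per stiffness level.
#' @param prune_angle correspondences whose morphed-template vertex normal
#'   deviates from the target surface normal by more than this angle
#'   (degrees) get zero distance weight.
#' @param prune_dist_factor correspondences farther than this multiple of the
#'   target's median edge length get zero distance weight.
#' @return object of class `nicp_config`.
#' @export
nicp_config <- function(stiffness = exp(seq(log(100), log(1), length.out = 8)),
                        landmark_weights = seq(10, 0,
                                               length.out = length(stiffness)),
                        gamma = 1, inner_tol_factor = 1e-4, max_inner = 20L,
                        prune_angle = 90, prune_dist_factor = 10) {
  if (length(stiffness) == 0L) stop("stiffness schedule must be nonempty")
  if (any(stiffness <= 0)) stop("stiffness values must be positive")
  if (any(diff(stiffness) >= 0)) stop("stiffness must be strictly decreasing")
  if (length(landmark_weights) != length(stiffness)) {
    stop("landmark_weights must match the stiffness schedule length")
  }
  if (any(landmark_weights < 0)) stop("landmark weights must be >= 0")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(stiffness = stiffness, landmark_weights = landmark_weights,
                 gamma = gamma, inner_tol_factor = inner_tol_factor,
                 max_inner = as.integer(max_inner), prune_angle = prune_angle,
                 prune_dist_factor = prune_dist_factor),
            class = "nicp_config")
}

#' Read an N-ICP configuration from YAML
#'
#' YAML keys mirror the [nicp_config()] argument names.
#'
#' @param path YAML file.
#' @return an `nicp_config`.
#' @export
read_nicp_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(nicp_config, vals)
}

#' Morph a template mesh onto a target with optimal-step nonrigid ICP
#'
#' One affine 3 x 4 transform per template vertex, regularized by a stiffness
#' term penalizing transform differences across template edges, a distance
#' term pulling vertices to their closest points on the target surface
#' (point-to-triangle), and a landmark term tying annotated landmarks
#' together. All three terms are minimized simultaneously in one sparse
#' linear least-squares solve per iteration. The template should be
#' pre-aligned to the target (see [procrustes_similarity()] /
#' [morph_scan()]).
#'
#' @param template a [surface_mesh()] (the pre-aligned template).
#' @param target a [surface_mesh()] (the scan; never modified).
#' @param template_lms template-side landmarks: either a [landmark_set()] of
#'   positions on the template surface (each is embedded barycentrically in
#'   its containing face, so the landmark constraint moves with the morph) or
#'   a named integer vector of template vertex indices. `NULL` for
#'   landmark-free morphing.
#' @param target_lms [landmark_set()] with matching names (ignored when
#'   `template_lms` is `NULL`).
#' @param config an [nicp_config()].
#' @return object of class `morph_result`: list with `morphed` (template
#'   topology, target geometry), `transforms` (4p x 3 stacked affine
#'   transforms), `converged`, `trace` (per-level mean vertex-to-surface
#'   distance, mm).
#' @export
nicp_affine <- function(template, target, template_lms = NULL,
                        target_lms = NULL, config = nicp_config()) {
  p <- n_vertices(template)
  f <- template$faces
  edges <- mesh_edges(template)
  e_n <- nrow(edges)
  g <- c(1, 1, 1, config$gamma)

  # stiffness structure: for edge (i, j), rows penalize g_c * (X_i - X_j)
  col_of <- function(vid, c) 4L * (vid - 1L) + c
  bi <- rep(seq_len(4L * e_n), 2L)
  bj <- c(rep(4L * (edges[, 1] - 1L), times = 4L) + rep(1:4, each = e_n),
          rep(4L * (edges[, 2] - 1L), times = 4L) + rep(1:4, each = e_n))
  bx <- c(rep(g, each = e_n), rep(-g, each = e_n))
  # rows grouped by channel c within blocks; order of rows is irrelevant for BtB
  B_stiff <- Matrix::sparseMatrix(i = bi, j = bj, x = bx,
                                  dims = c(4L * e_n, 4L * p))
  BtB <- Matrix::crossprod(B_stiff)

  v0 <- template$vertices
  D <- Matrix::sparseMatrix(
    i = rep(seq_len(p), 4L),
    j = c(col_of(seq_len(p), 1L), col_of(seq_len(p), 2L),
          col_of(seq_len(p), 3L), col_of(seq_len(p), 4L)),
    x = c(v0[, 1], v0[, 2], v0[, 3], rep(1, p)),
    dims = c(p, 4L * p))

  use_lm <- !is.null(template_lms) && length(template_lms) > 0L
  if (use_lm) {
    if (inherits(template_lms, "landmark_set")) {
      emb <- embed_on_mesh(landmark_coords(template_lms), template)
      lm_names <- template_lms$name
      nl <- length(lm_names)
      DL <- Matrix::sparseMatrix(
        i = rep(seq_len(nl), 12L),
        j = as.vector(vapply(1:3, function(corner) {
          as.numeric(rep(4L * (emb$vertex[, corner] - 1L), times = 4L) +
                       rep(1:4, each = nl))
        }, numeric(4L * nl))),
        x = as.vector(vapply(1:3, function(corner) {
          w <- emb$bary[, corner]
          c(w * v0[emb$vertex[, corner], 1], w * v0[emb$vertex[, corner], 2],
            w * v0[emb$vertex[, corner], 3], w)
        }, numeric(4L * nl))),
        dims = c(nl, 4L * p))
    } else {
      lm_names <- names(template_lms)
      DL <- D[template_lms, , drop = FALSE]
    }
    UL <- landmark_coords(target_lms, names = lm_names)
    DLtDL <- Matrix::crossprod(DL)
    DLtUL <- Matrix::crossprod(DL, UL)
  }

  tv <- target$vertices
  med_edge <- stats::median(sqrt(rowSums(
    (tv[target$faces[, 1], , drop = FALSE] -
     tv[target$faces[, 2], , drop = FALSE])^2)))
  target_fn <- face_normals(target)
  cos_prune <- cos(config$prune_angle * pi / 180)

  X <- matrix(0, 4L * p, 3L)
  X[col_of(seq_len(p), 1L), 1] <- 1
  X[col_of(seq_len(p), 2L), 2] <- 1
  X[col_of(seq_len(p), 3L), 3] <- 1

  tol <- config$inner_tol_factor * p
  trace <- numeric(length(config$stiffness))
  converged <- TRUE
  for (lev in seq_along(config$stiffness)) {
    alpha <- config$stiffness[lev]
    beta <- config$landmark_weights[lev]
    level_ok <- FALSE
    for (it in seq_len(config$max_inner)) {
      cur <- as.matrix(D %*% X)
      cp <- closest_on_mesh(cur, target)
      w <- rep(1, p)
      w[cp$distance > config$prune_dist_factor * med_edge] <- 0
      vn <- vertex_normals(surface_mesh(cur, f, validate = FALSE))
      ndot <- rowSums(vn * target_fn[cp$face, , drop = FALSE])
      w[ndot < cos_prune] <- 0
      W2D <- D * w^2  # row scaling
      AtA <- alpha^2 * BtB + Matrix::crossprod(D, W2D)
      Atb <- Matrix::crossprod(W2D, cp$point)
      if (use_lm && beta > 0) {
        AtA <- AtA + beta^2 * DLtDL
        Atb <- Atb + beta^2 * DLtUL
      }
      Xnew <- tryCatch(as.matrix(Matrix::solve(AtA, Atb)),
                       error = function(e) {
                         stop("singular morphing system (disconnected ",
                              "template or all correspondences pruned): ",
                              conditionMessage(e))
                       })
      change <- sqrt(sum((Xnew - X)^2))
      X <- Xnew
      if (change < tol) { level_ok <- TRUE; break }
    }
    if (!level_ok) {
      warning("stiffness level ", lev, " did not converge in ",
              config$max_inner, " iterations")
      converged <- FALSE
    }
    cur <- as.matrix(D %*% X)
    trace[lev] <- mean(closest_on_mesh(cur, target)$distance)
  }
  morphed <- surface_mesh(as.matrix(D %*% X), f, validate = FALSE)
  structure(list(morphed = morphed, transforms = X, converged = converged,
                 trace = trace),
            class = "morph_result")
}

#' @export
print.morph_result <- function(x, ...) {
  cat("morph_result: ", n_vertices(x$morphed), " vertices, final mean ",
      "surface distance ", format(utils::tail(x$trace, 1), digits = 4),
      " mm", if (!x$converged) " (not fully converged)", "\n", sep = "")
  invisible(x)
}

#' Barycentric embedding of points on a mesh surface
#'
#' Projects points onto the mesh (point-to-triangle) and returns, for each,
#' the containing face's vertex indices and the barycentric coordinates of
#' the projection.
#'
#' @param points n x 3 matrix.
#' @param mesh a [surface_mesh()].
#' @return list with `vertex` (n x 3 vertex indices), `bary` (n x 3
#'   barycentric weights), `point` (n x 3 projected positions).
#' @export
embed_on_mesh <- function(points, mesh) {
  cp <- closest_on_mesh(points, mesh)
  f <- mesh$faces[cp$face, , drop = FALSE]
  A <- mesh$vertices[f[, 1], , drop = FALSE]
  e0 <- mesh$vertices[f[, 2], , drop = FALSE] - A
  e1 <- mesh$vertices[f[, 3], , drop = FALSE] - A
  e2 <- cp$point - A
  d00 <- rowSums(e0 * e0); d01 <- rowSums(e0 * e1); d11 <- rowSums(e1 * e1)
  d20 <- rowSums(e2 * e0); d21 <- rowSums(e2 * e1)
  den <- pmax(d00 * d11 - d01^2, .Machine$double.eps)
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  bary <- cbind(pmin(pmax(1 - v - w, 0), 1), pmin(pmax(v, 0), 1),
                pmin(pmax(w, 0), 1))
  bary <- bary / rowSums(bary)
  list(vertex = f, bary = bary, point = cp$point)
}

#' Morph the template onto a scan (alignment + nonrigid ICP)
#'
#' Convenience wrapper: similarity-aligns the template to the scan using the
#' shared landmark names, then runs [nicp_affine()] with the aligned template
#' landmarks embedded on the template surface.
#'
#' @param template list with a `scan` element (the template [head_scan()]),
#'   as returned by [generate_template()].
#' @param scan the target [head_scan()].
#' @param config an [nicp_config()].
#' @return a `morph_result` (see [nicp_affine()]).
#' @export
morph_scan <- function(template, scan, config = nicp_config()) {
  tr <- procrustes_similarity(template$scan$landmarks, scan$landmarks)
  pre <- surface_mesh(apply_transform(tr, template$scan$mesh$vertices),
                      template$scan$mesh$faces, validate = FALSE)
  pre_lms <- template$scan$landmarks
  lp <- apply_transform(tr, landmark_coords(pre_lms))
  pre_lms$x <- lp[, 1]; pre_lms$y <- lp[, 2]; pre_lms$z <- lp[, 3]
  nicp_affine(pre, scan$mesh, pre_lms, scan$landmarks, config)
}

#' Transfer a corresponded mesh onto the mirrored twin of its scan
#'
#' For a bilaterally symmetric template, the morph of the template onto the
#' mirrored scan is the mirror image of the morph onto the original scan with
#' vertex identities swapped left/right. This reflects the corresponded mesh
#' across the scan's midsagittal plane and permutes vertices by the
#' template's symmetry map, so each vertex id keeps its (laterality-swapped)
#' anatomical meaning without re-running the morph.
#'
#' @param morphed corresponded [surface_mesh()] (template topology).
#' @param symmetry_map template symmetry permutation
#'   (see [template_symmetry_map()]).
#' @param plane reflection plane `list(point, normal)`, typically the scan's
#'   [midsagittal_plane()].
#' @return corresponded `surface_mesh` of the mirrored scan.
#' @export
mirror_corresponded <- function(morphed, symmetry_map, plane) {
  v <- reflect_points(morphed$vertices, plane)[symmetry_map, , drop = FALSE]
  surface_mesh(v, morphed$faces, validate = FALSE)
}
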