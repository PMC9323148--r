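#' Subdivided icosahedron (unit icosphere)
#'
#' Genus-0 triangulation of the unit sphere by repeated edge-midpoint
#' subdivision of an icosahedron, vertices projected onto the sphere after
#' each level. The vertex set is exactly symmetric under x -> -x, which the
#' synthetic-head generator relies on for bilaterally symmetric head proxies.
#'
#' @param subdivisions number of subdivision levels (0 = icosahedron,
#'   12 vertices; each level roughly quadruples the face count: 2 -> 162,
#'   3 -> 642, 4 -> 2562 vertices).
#' @return a [surface_mesh()] with outward-facing (counterclockwise) winding.
#' @export
icosphere <- function(subdivisions = 3L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c(1,  t, 0), c(-1, -t,  0), c(1, -t,  0),
    c( 0, -1,  t), c(0,  1, t), c( 0, -1, -t), c(0,  1, -t),
    c( t,  0, -1), c(t,  0, 1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mid_env <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      id <- mid_env[[k]]
      if (is.null(id)) {
        m <- (v[a, ] + v[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        newv[[length(newv) + 1L]] <<- m
        id <- nv + length(newv)
        mid_env[[k]] <- id
      }
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  mesh <- surface_mesh(v, f, validate = FALSE)
  # enforce outward winding (convex shape: normal must align with radius)
  fn <- face_normals(mesh)
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  flip <- rowSums(fn * ctr) < 0
  if (any(flip)) f[flip, ] <- f[flip, c(1, 3, 2)]
  surface_mesh(v, f, validate = FALSE)
}

# evaluate code with a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# smooth angular window: 1 at the center direction, 0 beyond theta0 (radians)
angular_window <- function(u, center, theta0) {
  center <- center / sqrt(sum(center^2))
  ct <- pmin(pmax(u %*% center, -1), 1)
  theta <- acos(ct)
  w <- numeric(nrow(u))
  inside <- theta < theta0
  w[inside] <- cos(pi * theta[inside] / (2 * theta0))^2
  w
}

# unit landmark directions of the head proxy (sphere parameterization)
synthetic_landmark_dirs <- function() {
  d <- rbind(
    nasion            = c( 0.00, 1.00, 0.18),
    sellion           = c( 0.00, 1.00, 0.05),
    exocanthion_left  = c(-0.35, 1.00, 0.12),
    exocanthion_right = c( 0.35, 1.00, 0.12),
    tragus_left       = c(-1.00, 0.05, -0.05),
    tragus_right      = c( 1.00, 0.05, -0.05),
    euryon_left       = c(-1.00, 0.12, 0.25),
    euryon_right      = c( 1.00, 0.12, 0.25),
    opisthocranion    = c( 0.00, -1.00, 0.08),
    vertex_point      = c( 0.00, 0.02, 1.00))
  d / sqrt(rowSums(d^2))
}

# deterministic deformation map: unit directions -> deformed head surface.
# Applied identically to mesh vertices and landmark directions so landmarks
# ride every deformation field.
synthetic_head_map <- function(u, class, magnitude, size, face_amp, axes,
                               params) {
  P <- u %*% diag(axes)                       # base ellipsoid
  rhat <- P / sqrt(rowSums(P^2))
  # frontal face protrusion (nose/eye/mouth block, below the cranial vault)
  wf <- angular_window(u, c(0, 1, -0.25), 0.45)
  P <- P + face_amp * wf * rhat
  # individual facial detail: mirror-paired bumps at fixed sub-cranial
  # locations (nose, chin, cheeks, ears, neck), amplitudes per subject
  if (!is.null(params$face_detail) && any(params$face_detail != 0)) {
    a <- params$face_detail
    w <- a[1] * angular_window(u, c(0, 1, -0.32), 0.25) +
      a[2] * angular_window(u, c(0, 0.88, -0.55), 0.3) +
      a[3] * (angular_window(u, c(-0.45, 0.85, -0.35), 0.3) +
                angular_window(u, c(0.45, 0.85, -0.35), 0.3)) +
      a[4] * (angular_window(u, c(-1, 0.02, -0.12), 0.3) +
                angular_window(u, c(1, 0.02, -0.12), 0.3)) +
      a[5] * angular_window(u, c(0, -0.95, -0.4), 0.35)
    P <- P + w * rhat
  }
  if (class == "sagittal") {
    # growth along the fused sagittal suture: anteroposterior elongation with
    # compensatory lateral narrowing; length/width ratio scales by (1+m)
    P[, 1] <- P[, 1] / sqrt(1 + magnitude)
    P[, 2] <- P[, 2] * sqrt(1 + magnitude)
  } else if (class == "metopic") {
    # trigonocephaly: anterior wedge, forehead narrowed toward the midline
    wm <- angular_window(u, c(0, 0.85, 0.5), 0.75)
    P[, 1] <- P[, 1] * (1 - magnitude * wm)
  } else if (class == "coronal") {
    # unilateral coronal fusion: frontal flattening on one side with a
    # contralateral compensatory bulge, plus the restricted anteroposterior
    # growth perpendicular to the coronal suture (mild brachycephalic
    # shortening/widening), which unilateral cases share in attenuated form
    s <- params$side
    w1 <- angular_window(u, c(0.6 * s, 0.75, 0.35), 0.6)
    w2 <- angular_window(u, c(-0.6 * s, 0.75, 0.35), 0.6)
    P <- P + (-12 * magnitude * w1 + 8 * magnitude * w2) * rhat
    P[, 1] <- P[, 1] * sqrt(1 + 0.5 * magnitude)
    P[, 2] <- P[, 2] / sqrt(1 + 0.5 * magnitude)
  } else if (class == "control") {
    # mild symmetric idiosyncratic shape variation: mirrored bump pairs
    if (!is.null(params$bumps) && nrow(params$bumps) > 0L) {
      for (b in seq_len(nrow(params$bumps))) {
        ctr <- params$bumps[b, 1:3]
        amp <- params$bumps[b, 4]
        ctr_m <- ctr * c(-1, 1, 1)
        w <- angular_window(u, ctr, 0.8) + angular_window(u, ctr_m, 0.8)
        P <- P + amp * w * rhat
      }
    }
  }
  P * size
}

#' Generate one synthetic head scan
#'
#' Produces a class-specific head-shape proxy: a subdivided-icosahedron
#' ellipsoid with a frontal face protrusion, deformed by a smooth
#' class-specific displacement field, with the 10 schema landmarks placed by
#' the same analytic map (so landmarks ride the deformation), plus optional
#' additive Gaussian vertex noise. Deformity directions follow the clinical
#' growth patterns: sagittal fusion elongates the head anteroposteriorly and
#' narrows it laterally; metopic fusion produces a triangular forehead
#' (anterior wedge); unilateral coronal fusion flattens one frontal side with
#' a contralateral bulge; controls get small symmetric perturbations.
#'
#' @param class one of [scan_classes()].
#' @param magnitude deformity magnitude (dimensionless; 0 disables the class
#'   field, giving the symmetric base head).
#' @param size global scale factor emulating age-dependent head size.
#' @param noise standard deviation (mm) of i.i.d. Gaussian vertex noise.
#' @param seed integer seed; identical seeds give bit-identical scans.
#' @param subdivisions icosphere subdivision level (default 4, 2562 vertices).
#' @param face_amp face-protrusion amplitude (mm); varies across individuals
#'   in a cohort, providing facial variation independent of the cranium.
#' @param face_detail_sd standard deviation (mm) of the five mirror-paired
#'   facial-detail amplitudes (nose, chin, cheeks, ears, neck), drawn per
#'   subject. Individual facial variation independent of cranial shape; 0
#'   gives the neutral face.
#' @param axes ellipsoid half-axes (mm): lateral, anteroposterior, vertical.
#' @param id optional scan id.
#' @return a [head_scan()].
#' @export
generate_head <- function(class, magnitude = 0.3, size = 1, noise = 0.5,
                          seed = 1L, subdivisions = 4L, face_amp = 9,
                          face_detail_sd = 1.5, axes = c(55, 72, 65),
                          id = NULL) {
  class <- match.arg(class, scan_classes())
  base <- icosphere(subdivisions)
  u <- base$vertices  # unit directions
  with_seed(seed, {
    params <- list()
    # drawn first so that equal seeds give the same face across classes
    params$face_detail <- if (face_detail_sd > 0) {
      stats::rnorm(5, sd = face_detail_sd)
    } else {
      numeric(5)
    }
    if (class == "coronal") {
      params$side <- if (stats::runif(1) < 0.5) -1 else 1
    } else if (class == "control" && magnitude > 0) {
      nb <- 3L
      dirs <- matrix(stats::rnorm(3L * nb), nb, 3L)
      dirs[, 1] <- abs(dirs[, 1])  # mirrored partner added in the map
      dirs <- dirs / sqrt(rowSums(dirs^2))
      amps <- stats::runif(nb, -1, 1) * 5 * magnitude
      params$bumps <- cbind(dirs, amps)
    }
    P <- synthetic_head_map(u, class, magnitude, size, face_amp, axes, params)
    L <- synthetic_head_map(synthetic_landmark_dirs(), class, magnitude, size,
                            face_amp, axes, params)
    if (noise > 0) {
      P <- P + matrix(stats::rnorm(length(P), sd = noise), nrow(P), 3L)
    }
    mesh <- surface_mesh(P, base$faces, validate = FALSE)
    # annotate landmarks on the scanned surface, as an expert would
    Lm <- closest_on_mesh(L, mesh)$point
    rownames(Lm) <- rownames(L)
    age <- as.integer(round(60 + pmax(0, pmin(1, (size - 0.85) / 0.30)) * 480))
    head_scan(mesh, landmark_set(Lm), class, age_days = age, id = id)
  })
}

#' Generate the symmetric template head
#'
#' The undeformed, noise-free base head (control with magnitude 0), used as
#' the morphing template. Returns the template scan together with the
#' template-vertex index of each landmark (nearest vertex) and the exact
#' bilateral symmetry permutation of the template vertex set.
#'
#' @inheritParams generate_head
#' @return list with `scan` (a [head_scan()]), `landmark_indices` (named
#'   integer vector) and `symmetry_map` (integer permutation: vertex i maps to
#'   its mirror partner).
#' @export
generate_template <- function(subdivisions = 4L, face_amp = 9,
                              axes = c(55, 72, 65)) {
  scan <- generate_head("control", magnitude = 0, size = 1, noise = 0,
                        seed = 0L, subdivisions = subdivisions,
                        face_amp = face_amp, face_detail_sd = 0, axes = axes,
                        id = "template")
  lm_idx <- template_landmark_indices(scan$mesh, scan$landmarks)
  list(scan = scan, landmark_indices = lm_idx,
       symmetry_map = template_symmetry_map(scan$mesh))
}

#' Nearest template vertex for each landmark
#'
#' @param mesh template [surface_mesh()].
#' @param landmarks a [landmark_set()].
#' @return named integer vector of vertex indices.
#' @export
template_landmark_indices <- function(mesh, landmarks) {
  L <- landmark_coords(landmarks)
  idx <- vapply(seq_len(nrow(L)), function(i) {
    which.min(colSums((t(mesh$vertices) - L[i, ])^2))
  }, integer(1))
  stats::setNames(idx, rownames(L))
}

#' Bilateral symmetry permutation of a mirror-symmetric mesh
#'
#' For a mesh whose vertex set is (numerically) symmetric under reflection
#' across the plane x = 0, returns the permutation mapping each vertex to its
#' mirror partner. Used to transfer a morphed (corresponded) template onto the
#' mirrored twin of a scan without re-running the morph.
#'
#' @param mesh a [surface_mesh()].
#' @param tol maximum allowed match distance as a fraction of the mean edge
#'   length.
#' @return integer permutation vector (an involution).
#' @export
template_symmetry_map <- function(mesh, tol = 0.1) {
  v <- mesh$vertices
  vr <- v
  vr[, 1] <- -vr[, 1]
  p <- nrow(v)
  map <- integer(p)
  d2 <- numeric(p)
  # chunked nearest-neighbour search, exact
  chunk <- 512L
  for (s in seq(1L, p, by = chunk)) {
    e <- min(s + chunk - 1L, p)
    D <- outer(rowSums(vr[s:e, , drop = FALSE]^2), rowSums(v^2), `+`) -
      2 * vr[s:e, , drop = FALSE] %*% t(v)
    map[s:e] <- max.col(-D, ties.method = "first")
    d2[s:e] <- D[cbind(seq_len(e - s + 1L), map[s:e])]
  }
  el <- mean(sqrt(rowSums((v[mesh$faces[, 1], ] - v[mesh$faces[, 2], ])^2)))
  if (max(sqrt(pmax(d2, 0))) > tol * el || anyDuplicated(map)) {
    stop("mesh is not bilaterally symmetric: no exact vertex pairing found")
  }
  map
}

#' Generate a synthetic cohort of head scans
#'
#' Draws per-scan deformity magnitudes, sizes and face amplitudes from the
#' stated ranges (reproducibly per seed) and generates class-labelled scans.
#' Optionally writes a pipeline-ready layout: one PLY mesh and one landmark
#' CSV per scan plus a labels CSV.
#'
#' @param n_per_class scans per class (single number or vector named by
#'   class).
#' @param classes classes to generate (default all four).
#' @param magnitude_range uniform range of deformity magnitudes.
#' @param size_range uniform range of global size factors.
#' @param face_amp_range uniform range of face-protrusion amplitudes (mm).
#' @param face_detail_sd per-subject facial-detail amplitude sd (mm), see
#'   [generate_head()].
#' @param noise Gaussian vertex noise sd (mm).
#' @param seed cohort seed.
#' @param subdivisions icosphere subdivision level.
#' @param out_dir optional output directory for meshes/landmarks/labels.
#' @return list with `scans` (list of [head_scan()]) and `labels`
#'   (data.frame id, label, age_days, mirrored).
#' @export
generate_cohort <- function(n_per_class, classes = scan_classes(),
                            magnitude_range = c(0.2, 0.4),
                            size_range = c(0.85, 1.15),
                            face_amp_range = c(4, 14),
                            face_detail_sd = 1.5,
                            noise = 0.5, seed = 7L, subdivisions = 4L,
                            out_dir = NULL) {
  if (length(n_per_class) == 1L) {
    n_per_class <- stats::setNames(rep(n_per_class, length(classes)), classes)
  }
  draws <- with_seed(seed, {
    n_tot <- sum(n_per_class[classes])
    list(mag = stats::runif(n_tot, magnitude_range[1], magnitude_range[2]),
         size = stats::runif(n_tot, size_range[1], size_range[2]),
         famp = stats::runif(n_tot, face_amp_range[1], face_amp_range[2]),
         seeds = sample.int(2^30, n_tot))
  })
  scans <- list()
  i <- 0L
  for (cl in classes) {
    for (k in seq_len(n_per_class[[cl]])) {
      i <- i + 1L
      id <- sprintf("%s_%03d", cl, k)
      scans[[id]] <- generate_head(cl, magnitude = draws$mag[i],
                                   size = draws$size[i], noise = noise,
                                   seed = draws$seeds[i],
                                   subdivisions = subdivisions,
                                   face_amp = draws$famp[i],
                                   face_detail_sd = face_detail_sd, id = id)
    }
  }
  labels <- data.frame(
    id = names(scans),
    label = vapply(scans, `[[`, character(1), "label"),
    age_days = vapply(scans, `[[`, integer(1), "age_days"),
    mirrored = vapply(scans, `[[`, logical(1), "mirrored"),
    stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(scans)) {
      write_mesh(scans[[id]]$mesh, file.path(out_dir, paste0(id, ".ply")))
      write_landmarks(scans[[id]]$landmarks,
                      file.path(out_dir, paste0(id, "_landmarks.csv")))
    }
    utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
  }
  list(scans = scans, labels = labels)
}
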