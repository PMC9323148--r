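# shared fixtures, built in code and cached per test run

single_triangle <- function(side = 1) {
  surface_mesh(rbind(c(0, 0, 0), c(side, 0, 0),
                     c(side / 2, side * sqrt(3) / 2, 0)),
               rbind(c(1L, 2L, 3L)))
}

# planar n x n grid in the xy-plane, unit spacing, triangulated
grid_mesh <- function(n = 5) {
  xy <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  v <- cbind(xy$x, xy$y, 0)
  id <- function(i, j) (j - 1L) * n + i
  f <- do.call(rbind, lapply(seq_len(n - 1L), function(j) {
    do.call(rbind, lapply(seq_len(n - 1L), function(i) {
      rbind(c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
            c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
    }))
  }))
  surface_mesh(v, f)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_template <- function() cached("tpl2", generate_template(subdivisions = 2))

# 5 scans/class at low resolution; generated heads share the icosphere
# topology, so they are densely corresponded by construction
small_cohort_obs <- function() {
  cached("obs5", {
    cohort <- generate_cohort(5, noise = 0.5, seed = 13, subdivisions = 2)
    observation_matrix(lapply(cohort$scans, `[[`, "mesh"),
                       labels = cohort$labels$label)
  })
}

# independent R implementation of point-to-triangle distance (oracle for the
# compiled closest-point kernel): dense barycentric sampling of the triangle
oracle_point_tri_dist <- function(p, a, b, c, n = 200) {
  best <- Inf
  for (i in 0:n) {
    for (j in 0:(n - i)) {
      w <- c(i, j, n - i - j) / n
      q <- w[1] * a + w[2] * b + w[3] * c
      best <- min(best, sqrt(sum((p - q)^2)))
    }
  }
  best
}
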