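test_that("rigid GPA aligns rigidly-displaced copies of one shape", {
  mesh <- generate_head("metopic", 0.3, noise = 0, seed = 2,
                        subdivisions = 1)$mesh
  V <- mesh$vertices
  set.seed(8)
  shapes <- lapply(1:4, function(i) {
    A <- matrix(rnorm(9), 3)
    R0 <- qr.Q(qr(A))
    if (det(R0) < 0) R0[, 1] <- -R0[, 1]
    sweep(V %*% t(R0), 2, rnorm(3, sd = 30), `+`)
  })
  X <- vapply(shapes, as_shape_vector, numeric(3 * nrow(V)))
  al <- generalized_procrustes_rigid(X)
  # pairwise RMSD after alignment ~ 0
  for (i in 1:3) {
    for (j in (i + 1):4) {
      rmsd <- sqrt(mean((al$X[, i] - al$X[, j])^2))
      expect_lt(rmsd, 1e-6)
    }
  }
  # centroid size unchanged (rigid only, scale kept as a shape attribute)
  csize <- function(x) {
    Vm <- as_vertex_matrix(x)
    sqrt(sum(sweep(Vm, 2, colMeans(Vm))^2))
  }
  for (j in 1:4) expect_equal(csize(al$X[, j]), csize(X[, j]),
                              tolerance = 1e-9)
})

test_that("GPA of identical copies has zero post-alignment variance", {
  mesh <- icosphere(1)
  X <- vapply(1:3, function(i) as_shape_vector(mesh$vertices),
              numeric(3 * n_vertices(mesh)))
  al <- generalized_procrustes_rigid(X)
  expect_lt(max(abs(al$X - al$X[, 1])), 1e-10)
})

test_that("centering is idempotent with zero row means", {
  set.seed(4)
  X <- matrix(rnorm(60), 12, 5)
  cen <- center_observations(X)
  expect_equal(cen$mean, rowMeans(X))
  expect_lt(max(abs(rowMeans(cen$X_zm))), 1e-12)
  cen2 <- center_observations(cen$X_zm)
  expect_lt(max(abs(cen2$X_zm - cen$X_zm)), 1e-12)
  # two columns
  ab <- center_observations(cbind(1:3, 7:9))
  expect_equal(ab$mean, c(4, 5, 6))
  expect_equal(ab$X_zm[, 1], -ab$X_zm[, 2])
})

test_that("Gram-route WPCA matches the direct weighted covariance oracle", {
  set.seed(3)
  X <- matrix(rnorm(36 * 5), 36, 5)
  m3 <- runif(36, 0.2, 2)
  cen <- center_observations(X)
  mod <- build_wpca_model(cen$X_zm, Matrix::Diagonal(x = m3),
                          mean = cen$mean)
  # brute-force 36x36 oracle: eigenvalues of M^(1/2) S M^(1/2)
  S <- tcrossprod(cen$X_zm) / 4
  K <- diag(sqrt(m3)) %*% S %*% diag(sqrt(m3))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(mod$lambda, ev[seq_len(n_components(mod))], tolerance = 1e-8)
  # V is M3-orthonormal
  G <- as.matrix(Matrix::crossprod(mod$V, Matrix::Diagonal(x = m3) %*% mod$V))
  expect_lt(max(abs(G - diag(n_components(mod)))), 1e-6)
})

test_that("with identity weighting WPCA reduces to plain PCA up to sign", {
  set.seed(5)
  X <- matrix(rnorm(30 * 6), 30, 6)
  cen <- center_observations(X)
  mod <- build_wpca_model(cen$X_zm, Matrix::Diagonal(30), mean = cen$mean)
  eI <- eigen(tcrossprod(cen$X_zm) / 5, symmetric = TRUE)
  expect_equal(mod$lambda, eI$values[seq_len(n_components(mod))],
               tolerance = 1e-8)
  for (k in seq_len(n_components(mod))) {
    delta <- min(max(abs(mod$V[, k] - eI$vectors[, k])),
                 max(abs(mod$V[, k] + eI$vectors[, k])))
    expect_lt(delta, 1e-8)
  }
})

test_that("centered data drop the zero eigenvalue (m <= n-1)", {
  set.seed(6)
  X <- matrix(rnorm(24 * 5), 24, 5)
  cen <- center_observations(X)
  G <- crossprod(cen$X_zm)
  full_eigs <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_lte(full_eigs[5], 1e-10 * full_eigs[1])
  mod <- build_wpca_model(cen$X_zm, Matrix::Diagonal(24), mean = cen$mean)
  expect_equal(n_components(mod), 4)
})

test_that("synthesis and projection are mutually inverse", {
  obs <- small_cohort_obs()
  model <- build_shape_model(obs)
  m <- n_components(model)
  # alpha = 0 -> mean exactly
  expect_equal(synthesize_shape(model, numeric(0)), model$mean)
  # left inverse on random coefficients
  set.seed(10)
  a <- rnorm(m)
  expect_equal(project_shape(model, synthesize_shape(model, a)), a,
               tolerance = 1e-6)
  # training round trip (full rank): aligned column reconstructs
  X <- attr(model, "aligned")
  x <- X[, 3]
  rec <- synthesize_shape(model, project_shape(model, x))
  expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-6)
  # linearity
  a1 <- rnorm(m); a2 <- rnorm(m)
  lhs <- synthesize_shape(model, a1 + a2) - model$mean
  rhs <- (synthesize_shape(model, a1) - model$mean) +
    (synthesize_shape(model, a2) - model$mean)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  # project(mean) = 0
  expect_lt(max(abs(project_shape(model, model$mean))), 1e-9)
  # alpha longer than m errors
  expect_error(synthesize_shape(model, numeric(m + 1)), "components")
})

test_that("truncated projection is the optimal rank-k reconstruction", {
  set.seed(12)
  X <- matrix(rnorm(18 * 6), 18, 6)
  m3 <- runif(18, 0.5, 1.5)
  cen <- center_observations(X)
  mod <- build_wpca_model(cen$X_zm, Matrix::Diagonal(x = m3),
                          mean = cen$mean)
  x <- cen$mean + cen$X_zm[, 2]
  k <- 2
  a <- project_shape(mod, x, k = k)
  err_m3 <- function(coef) {
    r <- x - synthesize_shape(mod, c(coef, rep(0, n_components(mod) - k)))
    sum(m3 * r^2)
  }
  base <- err_m3(a)
  # brute-force perturbation search cannot beat the projection
  for (i in 1:40) {
    cand <- a + rnorm(k, sd = 0.3)
    expect_gte(err_m3(cand), base - 1e-10)
  }
  # and numerical optimization lands on the projection
  opt <- stats::optim(rep(0, k), err_m3, method = "BFGS")
  expect_equal(opt$par, a, tolerance = 1e-4)
})

test_that("Gaussian sampling is reproducible and self-consistent", {
  obs <- small_cohort_obs()
  model <- build_shape_model(obs)
  s1 <- sample_instances(model, 5, seed = 77)
  s2 <- sample_instances(model, 5, seed = 77)
  expect_identical(s1$shapes, s2$shapes)
  expect_false(identical(s1$shapes,
                         sample_instances(model, 5, seed = 78)$shapes))
  # law of large numbers on the coefficient draws
  big <- sample_instances(model, 10000, seed = 1, k = 2)
  se <- 1 / sqrt(10000)
  expect_lt(max(abs(rowMeans(big$alpha))), 3 * se)
  # projecting samples back recovers ~unit variance per component
  back <- vapply(seq_len(200), function(j) {
    project_shape(model, big$shapes[, j])[1:2]
  }, numeric(2))
  expect_equal(unname(apply(back, 1, stats::var)), c(1, 1), tolerance = 0.35)
})

test_that("submodels and the cranial model partition the training data", {
  obs <- small_cohort_obs()
  # all-one-class: submodel equals full model
  one <- structure(list(X = obs$X[, 1:5], labels = rep("control", 5),
                        mirrored = rep(FALSE, 5),
                        mirror_pairs = rep(NA_integer_, 5),
                        faces = obs$faces),
                   class = "observation_matrix")
  sm <- build_submodels(one)
  full <- build_shape_model(one)
  expect_equal(sm$submodels$control$lambda, full$lambda, tolerance = 1e-9)
  expect_equal(sm$submodels$control$mean, full$mean, tolerance = 1e-9)
  # per-class means match the class means
  sm4 <- build_submodels(obs)
  expect_named(sm4$submodels,
               unique(obs$labels), ignore.order = TRUE)
  for (cl in unique(obs$labels)) {
    idx <- which(obs$labels == cl)
    al <- generalized_procrustes_rigid(obs$X[, idx])
    expect_equal(sm4$submodels[[cl]]$mean, al$mean, tolerance = 1e-6)
  }
  # class with < 2 members errors naming the class
  bad <- structure(list(X = obs$X[, 1:6],
                        labels = c(rep("control", 5), "sagittal"),
                        mirrored = rep(FALSE, 6),
                        mirror_pairs = rep(NA_integer_, 6),
                        faces = obs$faces),
                   class = "observation_matrix")
  expect_error(build_submodels(bad), "sagittal")
  # cranial model dimension bookkeeping
  tpl <- small_template()
  mask <- default_cranial_mask(tpl)
  cm <- build_cranial_model(obs, mask)
  expect_equal(length(cm$mean), 3 * length(mask))
  expect_identical(cm$index_map, sort(unique(as.integer(mask))))
})

test_that("eigenvalues conserve the weighted training variance", {
  obs <- small_cohort_obs()
  model <- build_shape_model(obs)
  X <- attr(model, "aligned")
  cen <- center_observations(X)
  total <- sum(vapply(seq_len(ncol(X)), function(j) {
    as.numeric(crossprod(cen$X_zm[, j], as.vector(model$M3 %*% cen$X_zm[, j])))
  }, numeric(1))) / (ncol(X) - 1)
  expect_equal(sum(model$lambda), total, tolerance = 1e-8)
})

test_that("model container round trips through disk", {
  obs <- small_cohort_obs()
  model <- build_shape_model(obs)
  path <- withr::local_tempfile(fileext = ".rds")
  save_shape_model(model, path)
  back <- load_shape_model(path)
  expect_equal(back$mean, model$mean)
  expect_equal(back$lambda, model$lambda)
  expect_equal(as.matrix(back$V), as.matrix(model$V))
  expect_match(attr(back, "provenance"), "shape_model v1")
})
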