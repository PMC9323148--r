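make_mirrored_labels <- function(n_per_class, classes = scan_classes()) {
  n <- n_per_class * length(classes)
  labels <- rep(classes, each = n_per_class)
  list(labels = c(labels, labels),
       mirrored = rep(c(FALSE, TRUE), each = n),
       mirror_pairs = c(seq_len(n) + n, seq_len(n)))
}

test_that("CV plans are stratified, disjoint and mirror-leakage-free", {
  set.seed(1)
  for (trial in 1:5) {
    npc <- sample(10:17, 1)
    d <- make_mirrored_labels(npc)
    plan <- make_cv_plan(d$labels, d$mirrored, d$mirror_pairs,
                         n_folds = 10, seed = trial)
    expect_true(validate_cv_plan(plan, d$mirrored, d$mirror_pairs))
    tests <- lapply(plan$folds, `[[`, "test")
    expect_setequal(unlist(tests), which(!d$mirrored))
    expect_equal(anyDuplicated(unlist(tests)), 0)
    # stratification: per-class test counts differ by at most 1 across folds
    for (cl in scan_classes()) {
      counts <- vapply(tests, function(t) sum(d$labels[t] == cl), numeric(1))
      expect_lte(diff(range(counts)), 1)
    }
    # mirrors of training originals are in training, test mirrors are not
    for (f in plan$folds) {
      expect_length(intersect(d$mirror_pairs[f$test], f$train), 0)
      train_orig <- f$train[!d$mirrored[f$train]]
      expect_true(all(d$mirror_pairs[train_orig] %in% f$train))
    }
  }
})

test_that("balanced 40-sample cohorts give one test sample per class per fold", {
  d <- make_mirrored_labels(10)
  plan <- make_cv_plan(d$labels, d$mirrored, d$mirror_pairs, n_folds = 10,
                       seed = 0)
  for (f in plan$folds) {
    expect_equal(sort(d$labels[f$test]), sort(scan_classes()))
  }
  # deterministic per seed
  plan2 <- make_cv_plan(d$labels, d$mirrored, d$mirror_pairs, n_folds = 10,
                        seed = 0)
  expect_identical(lapply(plan$folds, `[[`, "test"),
                   lapply(plan2$folds, `[[`, "test"))
})

separable_features <- function(n_per_class = 12, k = 3, gap = 20, seed = 5) {
  classes <- scan_classes()
  n <- n_per_class * length(classes)
  centers <- diag(length(classes)) * gap
  with_seed(seed, {
    A <- do.call(rbind, lapply(seq_along(classes), function(i) {
      matrix(rnorm(n_per_class * k), n_per_class, k) +
        matrix(centers[i, seq_len(k)], n_per_class, k, byrow = TRUE)
    }))
    A
  })
}

test_that("all five classifiers separate well-separated Gaussian blobs", {
  A <- separable_features(k = 3)
  labels <- rep(scan_classes(), each = 12)
  train <- seq_len(nrow(A)) %% 2 == 0
  for (clf in c("svm", "lda", "nb", "knn", "bdt")) {
    pred <- train_predict(clf, A[train, ], labels[train], A[!train, ])
    expect_equal(mean(pred == labels[!train]), 1.0,
                 info = clf)
  }
  expect_error(train_predict("mlp", A, labels, A), "arg")
})

test_that("LDA places the 1-D two-class boundary at the midpoint of means", {
  set.seed(7)
  x <- c(rnorm(60, -2, 1), rnorm(60, 4, 1))
  y <- rep(c("a", "b"), each = 60)
  mid <- (mean(x[1:60]) + mean(x[61:120])) / 2
  eps <- 1e-4
  probe <- matrix(c(mid - eps, mid + eps), ncol = 1)
  pred <- train_predict("lda", matrix(x, ncol = 1), y, probe)
  expect_equal(pred, c("a", "b"))
  # boundary localized at the midpoint within 1e-6: bisect
  lo <- mid - 1; hi <- mid + 1
  for (i in 1:40) {
    cand <- (lo + hi) / 2
    p <- train_predict("lda", matrix(x, ncol = 1), y,
                       matrix(cand, ncol = 1))
    if (p == "a") lo <- cand else hi <- cand
  }
  expect_equal((lo + hi) / 2, mid, tolerance = 1e-6)
})

test_that("kNN breaks 2-2-1 ties by the nearest neighbour among tied classes", {
  # query at origin; class a at distances 2, 3; class b at 1.5, 3.5 (tied
  # 2-2 vote); class c single at 1.0 (nearest overall but minority)
  train <- matrix(c(2, 3, 1.5, 3.5, 1), ncol = 1)
  y <- c("a", "a", "b", "b", "c")
  pred <- train_predict("knn", train, y, matrix(0, ncol = 1))
  # tie between a and b; nearest among tied is b (1.5)
  expect_equal(pred, "b")
  # flip distances: now a (1.2) is nearest among tied
  train2 <- matrix(c(1.2, 3, 1.5, 3.5, 1), ncol = 1)
  expect_equal(train_predict("knn", train2, y, matrix(0, ncol = 1)), "a")
  # mixed batch: tied and untied queries both yield class labels
  batch <- matrix(c(0, 3.4), ncol = 1)
  pred <- train_predict("knn", train, y, batch)
  expect_true(all(pred %in% y))
  expect_equal(pred[1], "b")
})

test_that("component sweep finds signal in the first component", {
  # class signal entirely in feature 1; features 2..5 pure noise
  d <- make_mirrored_labels(10)
  n <- length(d$labels)
  sig <- c(control = 0, coronal = 30, sagittal = 60, metopic = 90)
  A <- with_seed(3, cbind(sig[d$labels] + rnorm(n),
                          matrix(rnorm(n * 4), n, 4)))
  feats <- structure(list(features = unname(A), labels = d$labels,
                          mirrored = d$mirrored,
                          mirror_pairs = d$mirror_pairs),
                     class = "feature_table")
  plan <- make_cv_plan(d$labels, d$mirrored, d$mirror_pairs, seed = 1)
  sw <- sweep_components(feats, plan, "lda", k_max = 5)
  expect_equal(sw$chosen_k, 1)
  expect_equal(sw$accuracy[1], 1.0)
  # noise components never improve on the perfect first component
  expect_true(all(sw$accuracy <= sw$accuracy[1] + 1e-12))
  # reproducible
  sw2 <- sweep_components(feats, plan, "lda", k_max = 5)
  expect_identical(sw$accuracy, sw2$accuracy)
})

test_that("classification report reproduces the published worked example", {
  C <- matrix(c(178, 0, 0, 0,
                5, 17, 0, 0,
                0, 0, 56, 0,
                3, 0, 0, 108),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("Con", "Cor", "Met", "Sag"),
                              c("Con", "Cor", "Met", "Sag")))
  rep <- compute_report(C)
  expect_equal(round(rep$accuracy, 3), 0.978)
  expect_equal(round(rep$g_mean, 3), 0.931)
  expect_equal(round(unname(rep$sensitivity), 3), c(1, 0.773, 1, 0.973))
  expect_equal(round(unname(rep$specificity), 3), c(0.958, 1, 1, 1))
})

test_that("classification report handles perfect and degenerate matrices", {
  D <- diag(c(5, 8, 2, 4))
  rep <- compute_report(D)
  expect_equal(unname(rep$sensitivity), rep(1, 4))
  expect_equal(unname(rep$specificity), rep(1, 4))
  expect_equal(rep$g_mean, 1)
  expect_equal(rep$accuracy, 1)

  C2 <- matrix(c(1, 1, 1, 1), 2)
  rep2 <- compute_report(C2)
  expect_equal(rep2$accuracy, 0.5)
  expect_equal(unname(rep2$sensitivity), c(0.5, 0.5))
  expect_equal(rep2$g_mean, 0.5)

  expect_warning(compute_report(matrix(c(2, 1, 0, 0), 2, byrow = TRUE)),
                 "undefined")
  expect_error(compute_report(matrix(1:6, 2)), "square")
  expect_error(compute_report(matrix(c(1, -1, 0, 1), 2)), "nonnegative")
})
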