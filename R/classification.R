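#' Shape-coefficient feature table for classification
#'
#' Projects every observation into the (cranial) shape model and keeps the
#' first k standardized coefficients as classifier features. No further
#' standardization is applied: the coefficients' sqrt(lambda) scaling is the
#' feature scale.
#'
#' @param model the (cranial) `shape_model`.
#' @param obs an [observation_matrix()] on the model's topology (the cranial
#'   coordinates when the model is cranial).
#' @param k number of leading coefficients.
#' @param align rigidly align each observation to the model mean before
#'   projection (default `TRUE`).
#' @return object of class `feature_table`: list with `features` (n x k
#'   matrix), `labels`, `mirrored`, `mirror_pairs`.
#' @export
feature_table <- function(model, obs, k = n_components(model), align = TRUE) {
  stopifnot(inherits(obs, "observation_matrix"))
  if (k > n_components(model)) stop("k exceeds the model rank")
  n <- ncol(obs$X)
  A <- vapply(seq_len(n), function(j) {
    x <- if (align) align_to_model(model, obs$X[, j]) else obs$X[, j]
    project_shape(model, x, k = k)
  }, numeric(k))
  A <- matrix(A, nrow = k)  # vapply drops to a vector when k = 1
  A <- t(A)
  if (!all(is.finite(A))) stop("non-finite feature values")
  rownames(A) <- colnames(obs$X)
  structure(list(features = A, labels = obs$labels, mirrored = obs$mirrored,
                 mirror_pairs = obs$mirror_pairs),
            class = "feature_table")
}

#' Mirror-aware stratified k-fold cross-validation plan
#'
#' Stratified folds are formed on the unmirrored samples only; each fold's
#' test set contains only original scans, while its training set contains the
#' remaining originals plus the mirrored twins of those training originals.
#' A test sample's mirror twin is therefore never in the training set (no
#' cross-over leakage), yet training still benefits from the doubled,
#' symmetry-balanced sample.
#'
#' @param labels class label per observation (originals and mirrors).
#' @param mirrored logical per observation.
#' @param mirror_pairs integer per observation: index of the mirror partner
#'   (`NA` if none).
#' @param n_folds number of folds (default 10). Classes smaller than
#'   `n_folds` simply appear in fewer folds.
#' @param seed fold-assignment seed (default 0).
#' @return object of class `cv_plan`: list of folds, each with `test`
#'   (original observation indices) and `train` (originals + their mirrors).
#' @export
make_cv_plan <- function(labels, mirrored, mirror_pairs, n_folds = 10L,
                         seed = 0L) {
  n <- length(labels)
  stopifnot(length(mirrored) == n, length(mirror_pairs) == n)
  orig <- which(!mirrored)
  if (length(unique(labels[orig])) < 2L) {
    stop("need at least two classes for cross-validation")
  }
  fold_of <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels[orig])) {
      ids <- orig[labels[orig] == cl]
      ids <- ids[sample.int(length(ids))]
      # deal round-robin: per-class fold counts differ by at most one
      fold_of[ids] <- ((seq_along(ids) - 1L) %% n_folds) + 1L
    }
  })
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- orig[fold_of[orig] == f]
    train_orig <- setdiff(orig, test)
    train_mirror <- mirror_pairs[train_orig]
    train_mirror <- train_mirror[!is.na(train_mirror)]
    list(test = test, train = c(train_orig, train_mirror))
  })
  folds <- folds[vapply(folds, function(f) length(f$test) > 0L, logical(1))]
  plan <- structure(list(folds = folds, n = n, orig = orig),
                    class = "cv_plan")
  validate_cv_plan(plan, mirrored, mirror_pairs)
  plan
}

#' Assert the no-leakage invariants of a CV plan
#'
#' Checks that the test sets partition the unmirrored observations, that no
#' test observation's mirror twin is in that fold's training set, and that no
#' test observation is in its own training set. Called on every plan
#' construction and by the CV driver.
#'
#' @param plan a `cv_plan`.
#' @param mirrored,mirror_pairs as in [make_cv_plan()].
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_cv_plan <- function(plan, mirrored, mirror_pairs) {
  all_test <- unlist(lapply(plan$folds, `[[`, "test"))
  if (anyDuplicated(all_test)) stop("CV leakage: overlapping test sets")
  if (!setequal(all_test, plan$orig)) {
    stop("CV leakage: test sets do not partition the unmirrored samples")
  }
  for (f in plan$folds) {
    if (length(intersect(f$test, f$train)) > 0L) {
      stop("CV leakage: test sample in its own training set")
    }
    twins <- mirror_pairs[f$test]
    twins <- twins[!is.na(twins)]
    if (length(intersect(twins, f$train)) > 0L) {
      stop("CV leakage: mirror twin of a test sample in the training set")
    }
  }
  invisible(TRUE)
}

# k-nearest-neighbour with the nearest-among-tied-classes tie-break
knn5_predict <- function(train_x, train_y, test_x, k = 5L) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  k <- min(k, nrow(train_x))
  apply(test_x, 1L, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    ord <- order(d)
    nn <- ord[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) {
      top
    } else {
      # tie: the class of the single nearest neighbour among the tied classes
      as.character(train_y[nn][train_y[nn] %in% top][1L])
    }
  })
}

#' Train a classifier and predict test labels
#'
#' The five supported classifiers and their settings: `svm` — RBF-kernel
#' support vector machine with one-versus-one multiclass (6 binary
#' classifiers for 4 classes); `lda` — Gaussian linear discriminant analysis
#' with a shared covariance matrix and class priors (Mahalanobis rule);
#' `nb` — Gaussian naive Bayes; `knn` — 5 nearest neighbours in Euclidean
#' space, ties broken by the nearest neighbour among the tied classes;
#' `bdt` — binary decision tree with default settings.
#'
#' @param classifier one of `"svm"`, `"lda"`, `"nb"`, `"knn"`, `"bdt"`.
#' @param train_x n x k numeric feature matrix.
#' @param train_y factor/character labels.
#' @param test_x m x k feature matrix.
#' @return character vector of m predicted labels.
#' @export
train_predict <- function(classifier, train_x, train_y, test_x) {
  classifier <- match.arg(classifier, c("svm", "lda", "nb", "knn", "bdt"))
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0L) stop("empty training set")
  train_y <- factor(train_y)
  colnames(train_x) <- colnames(test_x) <- paste0("c", seq_len(ncol(train_x)))
  pred <- switch(classifier,
    svm = {
      fit <- e1071::svm(train_x, train_y, kernel = "radial", scale = FALSE)
      stats::predict(fit, test_x)
    },
    lda = {
      fit <- MASS::lda(train_x, grouping = train_y)
      stats::predict(fit, test_x)$class
    },
    nb = {
      fit <- e1071::naiveBayes(train_x, train_y)
      stats::predict(fit, test_x)
    },
    knn = knn5_predict(train_x, train_y, test_x, k = 5L),
    bdt = {
      df <- data.frame(train_x)
      df$.label <- train_y
      # grow the tree unconstrained (the default of the usual
      # machine-learning decision-tree implementations); rpart's own
      # defaults would refuse to split small nodes
      fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 2,
                                                         minbucket = 1,
                                                         cp = 0))
      stats::predict(fit, data.frame(test_x), type = "class")
    })
  as.character(pred)
}

#' Run cross-validated classification and pool the confusion matrix
#'
#' Each original sample is tested exactly once across the folds, so the
#' pooled confusion matrix (true class x predicted class) summarizes the
#' whole plan.
#'
#' @param features a [feature_table()].
#' @param plan a `cv_plan` (validated against the feature table's mirror
#'   structure on every call).
#' @param classifier classifier name (see [train_predict()]).
#' @param k number of leading feature columns to use (default all).
#' @return list with `confusion` (square counts matrix over
#'   [scan_classes()] present), `accuracy`, `predictions`.
#' @export
cross_validate <- function(features, plan, classifier, k = NULL) {
  stopifnot(inherits(features, "feature_table"))
  validate_cv_plan(plan, features$mirrored, features$mirror_pairs)
  A <- features$features
  if (!is.null(k)) A <- A[, seq_len(k), drop = FALSE]
  labels <- features$labels
  pred <- rep(NA_character_, length(labels))
  for (f in plan$folds) {
    pred[f$test] <- train_predict(classifier, A[f$train, , drop = FALSE],
                                  labels[f$train], A[f$test, , drop = FALSE])
  }
  test_ids <- unlist(lapply(plan$folds, `[[`, "test"))
  lv <- intersect(scan_classes(), unique(labels))
  if (length(lv) == 0L) lv <- sort(unique(labels))
  C <- table(factor(labels[test_ids], levels = lv),
             factor(pred[test_ids], levels = lv))
  C <- unclass(as.matrix(C))
  names(dimnames(C)) <- c("true", "predicted")
  list(confusion = C, accuracy = sum(diag(C)) / sum(C), predictions = pred)
}

#' Sweep the number of principal components
#'
#' Runs the full cross-validation for k = 1..k_max leading coefficients and
#' records the pooled accuracy; the chosen k is the accuracy argmax (smallest
#' k on ties). The leading components carry the overall shape signal while
#' trailing components are mostly noise, so accuracy typically rises and then
#' flattens or decays.
#'
#' @param features a [feature_table()] with at least `k_max` columns.
#' @param plan a `cv_plan`.
#' @param classifier classifier name.
#' @param k_max largest number of components (default
#'   `min(100, ncol(features))`).
#' @return list with `accuracy` (length-k_max vector), `chosen_k`, and
#'   `best` (the CV result at `chosen_k`).
#' @export
sweep_components <- function(features, plan, classifier, k_max = NULL) {
  p_avail <- ncol(features$features)
  if (is.null(k_max)) k_max <- min(100L, p_avail)
  if (k_max > p_avail) stop("k_max exceeds available components")
  acc <- vapply(seq_len(k_max), function(k) {
    cross_validate(features, plan, classifier, k = k)$accuracy
  }, numeric(1))
  chosen <- which.max(acc)  # first maximum = smallest k on ties
  list(accuracy = acc, chosen_k = chosen,
       best = cross_validate(features, plan, classifier, k = chosen))
}

#' Classification report from a confusion matrix
#'
#' Per-class sensitivity (recall) and one-versus-rest specificity, their
#' geometric-mean summary (g-mean over the per-class sensitivities, robust
#' under class imbalance) and overall accuracy.
#'
#' @param C square confusion matrix of nonnegative integer counts, rows =
#'   true classes, columns = predicted classes.
#' @param classifier,components optional metadata recorded in the report.
#' @return object of class `classification_report`: list with `confusion`,
#'   `sensitivity`, `specificity` (named per-class vectors), `g_mean`,
#'   `accuracy`, `classifier`, `components`. An empty true-class row yields
#'   `NaN` sensitivity with a warning.
#' @export
compute_report <- function(C, classifier = NULL, components = NULL) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("confusion matrix must be square")
  if (any(C < 0) || any(C != round(C))) {
    stop("confusion matrix must hold nonnegative integer counts")
  }
  total <- sum(C)
  cls <- rownames(C)
  if (is.null(cls)) cls <- paste0("class", seq_len(nrow(C)))
  rs <- rowSums(C)
  if (any(rs == 0)) {
    warning("empty true-class row(s): sensitivity undefined for ",
            paste(cls[rs == 0], collapse = ", "))
  }
  sens <- diag(C) / rs
  spec <- vapply(seq_len(nrow(C)), function(i) {
    tn <- sum(C[-i, -i])
    fp <- sum(C[-i, i])
    tn / (tn + fp)
  }, numeric(1))
  names(sens) <- names(spec) <- cls
  structure(list(confusion = C, sensitivity = sens, specificity = spec,
                 g_mean = exp(mean(log(sens))),
                 accuracy = sum(diag(C)) / total,
                 classifier = classifier, components = components),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 3, ...) {
  cat("Classification report",
      if (!is.null(x$classifier)) paste0(" (", x$classifier,
        if (!is.null(x$components)) paste0(", ", x$components, " components"),
        ")"), "\n", sep = "")
  print(x$confusion)
  df <- data.frame(sensitivity = round(x$sensitivity, digits),
                   specificity = round(x$specificity, digits))
  print(df)
  cat("g-mean:         ", round(x$g_mean, digits), "\n")
  cat("total accuracy: ", round(x$accuracy, digits), "\n")
  invisible(x)
}
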