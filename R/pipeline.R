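#' Establish dense correspondence for a cohort
#'
#' Morphs the template onto every scan ([morph_scan()]) and, when
#' `mirror = TRUE`, adds the mirrored twin of each corresponded mesh
#' (reflection across the scan's midsagittal plane composed with the
#' template's bilateral symmetry permutation), doubling the sample while
#' keeping the original/mirror pairing for leakage-free cross-validation.
#'
#' @param template template list from [generate_template()] (elements `scan`,
#'   `landmark_indices`, `symmetry_map`).
#' @param scans list of [head_scan()]s.
#' @param config an [nicp_config()].
#' @param mirror add mirrored twins (default `TRUE`).
#' @param progress print one line per scan.
#' @return an [observation_matrix()]; column order is all originals then all
#'   mirrors. Morph convergence flags and final surface distances are
#'   attached as attributes `converged` and `v2nn`.
#' @export
correspond_cohort <- function(template, scans, config = nicp_config(),
                              mirror = TRUE, progress = FALSE) {
  n <- length(scans)
  morphed <- vector("list", n)
  conv <- logical(n)
  v2nn <- numeric(n)
  for (i in seq_len(n)) {
    mr <- morph_scan(template, scans[[i]], config)
    morphed[[i]] <- mr$morphed
    conv[i] <- mr$converged
    v2nn[i] <- utils::tail(mr$trace, 1)
    if (progress) {
      message(sprintf("[%d/%d] %s: v2nn %.4f mm", i, n,
                      if (is.null(scans[[i]]$id)) "scan" else scans[[i]]$id,
                      v2nn[i]))
    }
  }
  labels <- vapply(scans, `[[`, character(1), "label")
  ids <- names(scans)
  if (is.null(ids)) ids <- sprintf("scan_%03d", seq_len(n))
  if (mirror) {
    mirrors <- lapply(seq_len(n), function(i) {
      plane <- midsagittal_plane(scans[[i]]$landmarks)
      mirror_corresponded(morphed[[i]], template$symmetry_map, plane)
    })
    meshes <- c(morphed, mirrors)
    names(meshes) <- c(ids, paste0(ids, "_m"))
    obs <- observation_matrix(
      meshes, labels = c(labels, labels),
      mirrored = rep(c(FALSE, TRUE), each = n),
      mirror_pairs = c(seq_len(n) + n, seq_len(n)))
  } else {
    names(morphed) <- ids
    obs <- observation_matrix(morphed, labels = labels)
  }
  attr(obs, "converged") <- conv
  attr(obs, "v2nn") <- v2nn
  obs
}

#' Default cranial vertex mask for a template head
#'
#' Template vertices above the euryon level (the widest part of the cranial
#' vault), excluding the face block. Defined once on the template and
#' transferred to all corresponded meshes through shared point identifiers.
#'
#' @param template template list from [generate_template()] (or a
#'   [head_scan()]).
#' @return integer vector of template vertex indices.
#' @export
default_cranial_mask <- function(template) {
  scan <- if (!is.null(template$scan)) template$scan else template
  L <- landmark_coords(scan$landmarks, c("euryon_left", "euryon_right"))
  z0 <- mean(L[, 3])
  which(scan$mesh$vertices[, 3] > z0)
}

#' Cross-validated craniosynostosis classification from a corresponded cohort
#'
#' The classification half of the pipeline: cranial model (GPA + weighted PCA
#' on the cranial submesh), coefficient features, mirror-aware stratified
#' k-fold cross-validation, and the pooled classification report.
#'
#' @param obs an [observation_matrix()] from [correspond_cohort()].
#' @param cranial_mask template vertex indices of the cranial region.
#' @param classifier classifier name (see [train_predict()]).
#' @param k number of leading cranial coefficients (`NULL` sweeps 1..k_max
#'   and picks the accuracy argmax).
#' @param k_max sweep upper bound when `k` is `NULL`.
#' @param n_folds folds (default 10).
#' @param seed fold-assignment seed (default 0).
#' @return list with `report` (a [compute_report()] result), `cv` (pooled CV
#'   result), `model` (cranial `shape_model`), `features`, `plan`, and
#'   `sweep` (accuracy-vs-k curve when swept).
#' @export
classify_cohort <- function(obs, cranial_mask, classifier = "lda", k = 10L,
                            k_max = NULL, n_folds = 10L, seed = 0L) {
  model <- build_cranial_model(obs, cranial_mask)
  rows <- coordinate_rows(model$index_map)
  cobs <- structure(list(X = obs$X[rows, , drop = FALSE], labels = obs$labels,
                         mirrored = obs$mirrored,
                         mirror_pairs = obs$mirror_pairs,
                         faces = model$faces),
                    class = "observation_matrix")
  k_feat <- if (is.null(k)) {
    min(if (is.null(k_max)) 100L else k_max, n_components(model))
  } else {
    min(k, n_components(model))
  }
  feats <- feature_table(model, cobs, k = k_feat)
  plan <- make_cv_plan(obs$labels, obs$mirrored, obs$mirror_pairs,
                       n_folds = n_folds, seed = seed)
  sweep_res <- NULL
  if (is.null(k)) {
    sweep_res <- sweep_components(feats, plan, classifier, k_max = k_feat)
    cv <- sweep_res$best
    k_used <- sweep_res$chosen_k
  } else {
    cv <- cross_validate(feats, plan, classifier)
    k_used <- k_feat
  }
  list(report = compute_report(cv$confusion, classifier = classifier,
                               components = k_used),
       cv = cv, model = model, features = feats, plan = plan,
       sweep = sweep_res)
}
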