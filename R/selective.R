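# Percentile-thresholded selective evaluation: confidence distributions,
# strict-exceedance subsets C_t, ROC/PR metrics and the threshold ->
# performance curve.

#' Empirical percentile thresholds of a confidence distribution
#'
#' Thresholds are the empirical quantiles (linear interpolation between
#' order statistics, R's type-7 convention) of the scores; percentile 0 is
#' mapped to `-Inf` so that every sample passes the strict-exceedance rule.
#'
#' @param scores Numeric vector of confidence scores.
#' @param percentiles Percentiles in `[0, 100)`.
#' @return Named numeric vector of thresholds.
#' @export
percentile_thresholds <- function(scores, percentiles = c(0, 25, 50, 70)) {
  if (length(scores) == 0L) stopf("empty confidence distribution")
  if (any(percentiles < 0 | percentiles >= 100))
    stopf("percentiles must lie in [0, 100)")
  th <- vapply(percentiles, function(p) {
    if (p == 0) -Inf
    else stats::quantile(scores, p / 100, type = 7, names = FALSE)
  }, numeric(1))
  names(th) <- as.character(percentiles)
  th
}

#' Strict-exceedance confidence subset C_t
#'
#' `C_t = {x : c(x) > t}`: the samples whose confidence strictly exceeds
#' the threshold. With tied scores this can be empty at any nonzero
#' percentile, which is reported as unavailable rather than an error.
#'
#' @param ids Sample identifiers (parallel to `scores`).
#' @param scores Confidence scores.
#' @param threshold Threshold t.
#' @return List of class `thresholded_subset` with `threshold`, `members`
#'   (ids), `index` (positions), `fraction_considered` (percent) and
#'   `available`.
#' @export
filter_subset <- function(ids, scores, threshold) {
  if (length(ids) != length(scores)) stopf("ids/scores length mismatch")
  keep <- which(scores > threshold)
  structure(list(threshold = threshold, members = ids[keep], index = keep,
                 fraction_considered = 100 * length(keep) / length(ids),
                 available = length(keep) > 0L),
            class = "thresholded_subset")
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Ties in the scores receive half credit (mean ranks), which makes this
#' identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param labels 0/1 vector.
#' @param scores Predicted scores for class 1.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_rank <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise interpolation: `AP = sum_k (R_k - R_{k-1}) P_k` over
#' descending unique score thresholds.
#'
#' @param labels 0/1 vector.
#' @param scores Predicted scores for class 1.
#' @return AP in `[0, 1]`, or `NA` if no positives are present.
#' @export
average_precision <- function(labels, scores) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L)
  if (npos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics on a confidence subset
#'
#' AUC and AP are reported as `NA` ("unavailable") when the subset contains
#' a single class; accuracy is always computed via the strict
#' `delta > 0.5` rule.
#'
#' @param subset A [filter_subset()] result (or `NULL` for all samples).
#' @param deltas Class-1 probabilities for all samples.
#' @param labels 0/1 labels for all samples.
#' @return List with `auc`, `ap`, `accuracy`, `n`.
#' @export
metrics_on_subset <- function(subset, deltas, labels) {
  idx <- if (is.null(subset)) seq_along(deltas) else subset$index
  if (length(idx) == 0L)
    return(list(auc = NA_real_, ap = NA_real_, accuracy = NA_real_, n = 0L))
  d <- deltas[idx]; y <- as.integer(labels[idx])
  list(auc = auc_rank(y, d),
       ap = average_precision(y, d),
       accuracy = mean(predict_class(d) == y),
       n = length(idx))
}

#' Confidence-performance curve over percentile thresholds
#'
#' For each percentile, thresholds the confidence distribution, forms the
#' strict-exceedance subset and evaluates AUC, average precision and
#' accuracy on it. Empty subsets (possible under ties) are flagged
#' unavailable, mirroring report tables where such splits appear as "-".
#'
#' @param ids Sample identifiers.
#' @param scores Confidence scores (one per sample).
#' @param deltas Class-1 probabilities.
#' @param labels 0/1 labels.
#' @param percentiles Percentiles in `[0, 100)`.
#' @return A `metric_curve` data.frame with one row per percentile:
#'   `percentile`, `threshold`, `fraction_considered`, `n`, `auc`, `ap`,
#'   `accuracy`, `available`.
#' @export
confidence_curve <- function(ids, scores, deltas, labels,
                             percentiles = c(0, 25, 50, 70)) {
  th <- percentile_thresholds(scores, percentiles)
  rows <- lapply(seq_along(percentiles), function(i) {
    ss <- filter_subset(ids, scores, th[i])
    m <- metrics_on_subset(ss, deltas, labels)
    data.frame(percentile = percentiles[i], threshold = th[i],
               fraction_considered = ss$fraction_considered,
               n = m$n, auc = m$auc, ap = m$ap, accuracy = m$accuracy,
               available = ss$available)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_curve", "data.frame")
  out
}

#' Surrogate-metric subgroup analysis for a percentage-annotated cohort
#'
#' Scores every sample with the percentage surrogate confidence, builds the
#' percentile-thresholded performance curve, and reports the composition of
#' each subgroup (how many completely unmethylated samples at 0% versus
#' methylated samples it retains) so qualitative statements about which
#' patients each split isolates can be inspected directly.
#'
#' @param ids Sample identifiers.
#' @param pct Methylation percentages.
#' @param deltas Class-1 probabilities.
#' @param labels 0/1 labels.
#' @param params A [surrogate_params()].
#' @param percentiles Percentiles in `[0, 100)`.
#' @return List with `curve` (a `metric_curve`) and `composition`
#'   (data.frame: percentile, n, n_unmethylated_zero, n_methylated).
#' @export
surrogate_subgroups <- function(ids, pct, deltas, labels,
                                params = surrogate_params(),
                                percentiles = c(0, 25, 50, 70)) {
  conf <- surrogate_confidence(pct, params)
  curve <- confidence_curve(ids, conf, deltas, labels, percentiles)
  th <- percentile_thresholds(conf, percentiles)
  comp <- do.call(rbind, lapply(seq_along(percentiles), function(i) {
    ss <- filter_subset(ids, conf, th[i])
    data.frame(percentile = percentiles[i], n = length(ss$index),
               n_unmethylated_zero = sum(pct[ss$index] == 0),
               n_methylated = sum(labels[ss$index] == 1L))
  }))
  list(curve = curve, composition = comp, confidence = conf)
}

#' Empirical ROC and PR point sets
#'
#' @param deltas Class-1 probabilities.
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`), `pr`
#'   (data.frame `threshold`, `recall`, `precision`), and `auc` (trapezoid
#'   over the ROC, identical to [auc_rank()] within numerical precision).
#' @export
roc_pr_curves <- function(deltas, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes required for ROC/PR curves")
  ord <- order(deltas, decreasing = TRUE)
  y <- labels[ord]; s <- deltas[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  pr <- data.frame(threshold = thr, recall = tp / n1,
                   precision = tp / (tp + fp))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, pr = pr, auc = auc)
}

#' Permutation test for a selective-evaluation accuracy gain
#'
#' Tests whether restricting evaluation to the most confident samples
#' improves accuracy beyond chance: the observed accuracy on the
#' top-percentile subset is compared with its permutation null obtained by
#' shuffling the confidence scores across samples.
#'
#' @param scores Confidence scores.
#' @param deltas Class-1 probabilities.
#' @param labels 0/1 labels.
#' @param percentile Percentile defining the retained subset.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutations.
#' @return List with `gain` (subset accuracy minus overall accuracy),
#'   `p_value` and `available`.
#' @export
selective_gain_test <- function(scores, deltas, labels, percentile = 70,
                                n_perm = 500L, seed = 1L) {
  ids <- seq_along(scores)
  th <- percentile_thresholds(scores, c(0, percentile))[2]
  ss <- filter_subset(ids, scores, th)
  if (!ss$available)
    return(list(gain = NA_real_, p_value = NA_real_, available = FALSE))
  acc_all <- mean(predict_class(deltas) == labels)
  gain <- mean(predict_class(deltas[ss$index]) == labels[ss$index]) - acc_all
  k <- length(ss$index)
  null_gain <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    idx <- sample(ids, k)
    mean(predict_class(deltas[idx]) == labels[idx]) - acc_all
  }, numeric(1)))
  list(gain = gain,
       p_value = (1 + sum(null_gain >= gain)) / (1 + n_perm),
       available = TRUE)
}

#' Write a selective-evaluation report
#'
#' Emits the curve as CSV and JSON; unavailable splits carry `"-"` in the
#' CSV metric columns.
#'
#' @param curves Named list of `metric_curve` objects (one per confidence
#'   metric).
#' @param dir Output directory.
#' @return Invisibly, the combined data.frame.
#' @export
write_selective_report <- function(curves, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  combined <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- as.data.frame(curves[[nm]])
    cbind(method = nm, cv)
  }))
  pretty <- combined
  for (col in c("auc", "ap", "accuracy")) {
    v <- ifelse(pretty$available & is.finite(pretty[[col]]),
                sprintf("%.3f", pretty[[col]]), "-")
    pretty[[col]] <- v
  }
  utils::write.csv(pretty, file.path(dir, "selective_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(combined, file.path(dir, "selective_report.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  invisible(combined)
}
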