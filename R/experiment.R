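# End-to-end orchestration: generate -> preprocess -> split -> train ->
# score -> selective evaluation, with seeded reproducibility and a run
# directory of plain-text artifacts.

#' Experiment configuration
#'
#' Bundles the per-stage configurations. Split fractions are patient-level
#' and stratified by label; confidence thresholds are always computed on
#' validation scores only.
#'
#' @param cohort A [cohort_config()].
#' @param preprocess A [preprocess_spec()].
#' @param model A [model_config()].
#' @param train List of training options: `epochs`, `batch_size`, `lr`,
#'   `lambda_weight`, `augment` (an [augment_config()] or `NULL`).
#' @param metrics Confidence metrics to score on the validation set
#'   (subset of `c("msp", "odin", "branch", "abc", "oracle")`; `"oracle"`
#'   is the margin `|delta - 0.5|`, the best achievable confidence given
#'   the model's own probabilities).
#' @param confidence List of metric parameter objects: `odin`, `abc`,
#'   `surrogate`.
#' @param percentiles Evaluation percentiles.
#' @param train_frac Fraction of patients assigned to training.
#' @param seed Master seed for the run.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_preset("private_like"),
                              preprocess = preprocess_spec(
                                "roi", target_shape = c(16L, 16L, 8L)),
                              model = model_config(),
                              train = list(epochs = 30L, batch_size = 8L,
                                           lr = 1e-3, lambda_weight = 0.1,
                                           augment = NULL),
                              metrics = c("msp", "odin", "oracle"),
                              confidence = list(odin = odin_params(),
                                                abc = abc_params(),
                                                surrogate = surrogate_params()),
                              percentiles = c(0, 25, 50, 70),
                              train_frac = 0.7,
                              seed = 1L) {
  if (train_frac <= 0 || train_frac > 1) stopf("train_frac must lie in (0, 1]")
  mods_needed <- if (model$fusion %in% c("early"))
    model$in_channels else length(cohort$modalities)
  if (model$fusion == "early" && model$in_channels != length(cohort$modalities))
    stopf("early fusion in_channels (%d) must equal number of modalities (%d)",
          model$in_channels, length(cohort$modalities))
  structure(list(cohort = cohort, preprocess = preprocess, model = model,
                 train = train, metrics = metrics, confidence = confidence,
                 percentiles = percentiles, train_frac = train_frac,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Stratified patient-level train/validation split
#'
#' Patients are split at the patient level (no sample ever appears in both
#' sets) with per-class proportions within one patient of the requested
#' fraction.
#'
#' @param labels 0/1 vector, one entry per patient.
#' @param train_frac Fraction assigned to training.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
split_cohort <- function(labels, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac > 1) stopf("train_frac must lie in (0, 1]")
  labels <- as.integer(labels)
  tr <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      k <- round(length(idx) * train_frac)
      tr <- c(tr, sample(idx, k))
    }
  })
  val <- setdiff(seq_along(labels), tr)
  if (length(val) > 0L) {
    for (cl in unique(labels))
      if (!any(labels[val] == cl))
        warning(sprintf("class %d absent from validation split", cl))
  } else {
    warning("validation split is empty")
  }
  list(train = sort(tr), val = val)
}

#' Run a full experiment
#'
#' Generates the synthetic cohort, preprocesses every patient, trains the
#' configured fusion classifier on the stratified training split, scores
#' the validation patients with the configured confidence metrics, and
#' builds one percentile-thresholded performance curve per metric (plus the
#' surrogate-percentage subgroup analysis when exact percentages are
#' available). Identical config and seed give an identical summary.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional run directory; when given, the manifest,
#'   training history, confidence table, selective report and a summary
#'   JSON are written there. A failed stage leaves a
#'   `FAILED_<stage>` marker file.
#' @param verbose Print stage progress.
#' @return List with `summary` (val AUC/accuracy, curve points), `curves`,
#'   `scores` (confidence table), `model`, `split`, `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stage <- "generate"
  mark_fail <- function(e) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(conditionMessage(e), file.path(out_dir,
                                                paste0("FAILED_", stage)))
    }
    stop(e)
  }
  if (!is.null(out_dir) && dir.exists(out_dir))
    unlink(list.files(out_dir, pattern = "^FAILED_", full.names = TRUE))
  tryCatch({
    say <- function(...) if (verbose) message(sprintf(...))
    say("stage: generate")
    cohort <- generate_cohort(config$cohort)
    labels <- cohort$manifest$label
    pct <- vapply(cohort$records, function(r) r$methylation_pct, numeric(1))

    stage <- "preprocess"
    say("stage: preprocess")
    prepped <- lapply(cohort$records, preprocess_record,
                      spec = config$preprocess)
    dataset <- lapply(prepped, function(p) p$volumes)

    stage <- "split"
    split <- split_cohort(labels, config$train_frac, seed = config$seed + 17L)

    stage <- "train"
    say("stage: train (%d train / %d val patients)",
        length(split$train), length(split$val))
    model <- train_classifier(dataset[split$train], labels[split$train],
                              config$model, config$preprocess$target_shape,
                              epochs = config$train$epochs %||% 30L,
                              batch_size = config$train$batch_size %||% 8L,
                              lr = config$train$lr %||% 1e-3,
                              lambda_weight = config$train$lambda_weight %||% 0.1,
                              val_dataset = dataset[split$val],
                              val_labels = labels[split$val],
                              augment = config$train$augment,
                              seed = config$seed + 29L,
                              verbose = verbose)

    stage <- "score"
    say("stage: score")
    val_ids <- cohort$manifest$patient_id[split$val]
    val_labels <- labels[split$val]
    val_pct <- pct[split$val]
    deltas <- predict_delta(model, dataset[split$val])
    base_metrics <- setdiff(config$metrics, "oracle")
    scores <- if (length(base_metrics) > 0L)
      score_confidence(model, dataset[split$val], ids = val_ids,
                       labels = val_labels, pct = val_pct,
                       metrics = base_metrics,
                       odin = config$confidence$odin,
                       abc = config$confidence$abc,
                       surrogate = config$confidence$surrogate)
    else NULL
    if ("oracle" %in% config$metrics) {
      oracle <- data.frame(patient_id = val_ids, metric = "oracle",
                           score = abs(deltas - 0.5), delta = deltas,
                           label = val_labels, pct = val_pct,
                           stringsAsFactors = FALSE)
      scores <- rbind(scores, oracle)
    }

    stage <- "evaluate"
    say("stage: evaluate")
    curves <- list()
    for (m in unique(scores$metric)) {
      sm <- scores[scores$metric == m, ]
      curves[[m]] <- confidence_curve(sm$patient_id, sm$score, sm$delta,
                                      sm$label, config$percentiles)
    }
    subgroups <- NULL
    if (!config$cohort$percentages_hidden && all(is.finite(val_pct)))
      subgroups <- surrogate_subgroups(val_ids, val_pct, deltas, val_labels,
                                       config$confidence$surrogate,
                                       config$percentiles)

    m_all <- metrics_on_subset(NULL, deltas, val_labels)
    summary <- list(
      n_patients = length(labels),
      n_train = length(split$train), n_val = length(split$val),
      signal_strength = config$cohort$signal_strength,
      val_auc = m_all$auc, val_ap = m_all$ap, val_accuracy = m_all$accuracy,
      curves = lapply(curves, function(cv) as.data.frame(cv)),
      seed = config$seed)

    stage <- "report"
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                       row.names = FALSE)
      hist <- model$history
      if (!is.null(hist))
        utils::write.csv(hist, file.path(out_dir, "history.csv"),
                         row.names = FALSE)
      utils::write.csv(scores, file.path(out_dir, "confidence.csv"),
                       row.names = FALSE)
      write_selective_report(curves, out_dir)
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows",
                           na = "null")
    }
    list(summary = summary, curves = curves, subgroups = subgroups,
         scores = scores, deltas = deltas, model = model, split = split,
         manifest = cohort$manifest)
  }, error = mark_fail)
}
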