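#' Cohort generator configuration
#'
#' Describes a synthetic multimodal MRI cohort: how many patients carry a
#' methylation percentage of exactly 0, how many carry a percentage drawn
#' from a moment-calibrated truncated-normal law, the binarisation threshold,
#' and how strongly tumour appearance encodes the binary label.
#'
#' @param n_unmethylated_zero Number of patients with percentage exactly 0.
#' @param n_methylated Number of patients with percentage drawn in
#'   `[pct_min, pct_max]`.
#' @param pct_mean,pct_sd Target mean and standard deviation (percent) of the
#'   methylated group's truncated-normal law.
#' @param pct_min,pct_max Range bounds (percent) of the methylated group.
#' @param label_threshold Percent threshold; a patient is labelled 1 iff its
#'   percentage strictly exceeds this value.
#' @param signal_strength Real in `[0, 1]`. 0 means tumour appearance is
#'   statistically independent of the label; 1 means rim contrast and
#'   necrotic-core fraction differ maximally between labels.
#' @param modalities Character subset of `c("T1w","T1wCE","T2w","FLAIR")`.
#' @param volume_shape Integer triple, voxel dimensions of each volume.
#' @param percentages_hidden If `TRUE` the cohort manifest reports only the
#'   binary label (percentages set to `NA`), emulating challenge-style data
#'   where only the binarised status is released.
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_unmethylated_zero = 40L,
                          n_methylated = 58L,
                          pct_mean = 41.3,
                          pct_sd = 21.04,
                          pct_min = 8.4,
                          pct_max = 85.4,
                          label_threshold = 10,
                          signal_strength = 0,
                          modalities = c("FLAIR", "T1wCE"),
                          volume_shape = c(64L, 64L, 32L),
                          percentages_hidden = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_unmethylated_zero = as.integer(n_unmethylated_zero),
    n_methylated = as.integer(n_methylated),
    pct_mean = pct_mean, pct_sd = pct_sd,
    pct_min = pct_min, pct_max = pct_max,
    label_threshold = label_threshold,
    signal_strength = signal_strength,
    modalities = modalities,
    volume_shape = as.integer(volume_shape),
    percentages_hidden = isTRUE(percentages_hidden),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_unmethylated_zero < 0L || cfg$n_methylated < 0L)
    stopf("patient counts must be non-negative")
  if (cfg$n_methylated > 0L) {
    if (!(cfg$pct_min > 0)) stopf("pct_min must be > 0")
    if (cfg$pct_max <= cfg$pct_min) stopf("pct_max must exceed pct_min")
    if (cfg$pct_max > 100) stopf("pct_max must be <= 100")
  }
  if (cfg$signal_strength < 0 || cfg$signal_strength > 1)
    stopf("signal_strength must lie in [0, 1]")
  known <- c("T1w", "T1wCE", "T2w", "FLAIR")
  if (length(cfg$modalities) < 1L || !all(cfg$modalities %in% known))
    stopf("modalities must be a non-empty subset of {%s}",
          paste(known, collapse = ", "))
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 1L))
    stopf("volume_shape must be a positive integer triple")
  invisible(cfg)
}

#' Preset cohort configurations
#'
#' `cohort_preset("private_like")` emulates a 98-patient cohort with exact
#' pyrosequencing percentages: 40 patients at exactly 0% and 58 with
#' percentages in `[8.4, 85.4]` whose truncated-normal law is calibrated to
#' mean 41.3 and standard deviation 21.04. `cohort_preset("rsna_like")`
#' emulates a challenge-style training set with 300 methylated and 274
#' unmethylated patients and hidden percentages (binary labels only), with
#' all four structural modalities.
#'
#' @param name `"private_like"` or `"rsna_like"`.
#' @param ... Overrides passed to [cohort_config()] (e.g. `signal_strength`,
#'   `volume_shape`, `seed`).
#' @return A `cohort_config`.
#' @export
cohort_preset <- function(name = c("private_like", "rsna_like"), ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    private_like = list(
      n_unmethylated_zero = 40L, n_methylated = 58L,
      pct_mean = 41.3, pct_sd = 21.04, pct_min = 8.4, pct_max = 85.4,
      modalities = c("FLAIR", "T1wCE"), percentages_hidden = FALSE
    ),
    rsna_like = list(
      # percentages are hidden for this preset (only binary labels are
      # released); the methylated group is drawn strictly above the 10%
      # threshold so the labels are exactly 300 methylated / 274
      # unmethylated, and its hidden law uses loosely private-cohort-like
      # moments that are comfortably attainable on the narrowed range
      n_unmethylated_zero = 274L, n_methylated = 300L,
      pct_mean = 42, pct_sd = 18, pct_min = 10.5, pct_max = 85.4,
      modalities = c("T1w", "T1wCE", "T2w", "FLAIR"),
      percentages_hidden = TRUE
    )
  )
  base[names(over)] <- over
  do.call(cohort_config, base)
}

# Mean and sd of a normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  if (Z <= 0) return(c(NaN, NaN))
  dm <- (dnorm(al) - dnorm(be)) / Z
  m <- mu + sigma * dm
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z - dm^2)
  c(m, sqrt(v))
}

#' Calibrate a truncated-normal law to target moments
#'
#' Finds underlying normal parameters `(mu, sigma)` such that the normal
#' truncated to `[a, b]` has the requested mean and standard deviation.
#' Used to make the methylated group's percentage law reproduce all four
#' printed statistics (range, mean, sd) simultaneously.
#'
#' @param mean,sd Target moments of the truncated law.
#' @param a,b Truncation bounds.
#' @param tol Maximum tolerated residual on the matched moments.
#' @return List with `mu`, `sigma` and the achieved `moments`.
#' @export
calibrate_truncnorm <- function(mean, sd, a, b, tol = 1e-6) {
  if (sd <= 0) stopf("target sd must be positive")
  if (mean <= a || mean >= b)
    stopf("truncated-normal calibration failure: target mean %.3f outside (%g, %g)",
          mean, a, b)
  obj <- function(p) {
    mm <- suppressWarnings(truncnorm_moments(p[1], exp(p[2]), a, b))
    if (any(!is.finite(mm))) return(1e10)
    sum(((mm - c(mean, sd)) / c(max(abs(mean), 1), sd))^2)
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 10000))
  mu <- fit$par[1]; sigma <- exp(fit$par[2])
  mm <- truncnorm_moments(mu, sigma, a, b)
  if (any(!is.finite(mm)) || max(abs(mm - c(mean, sd))) > tol)
    stopf(paste0("truncated-normal calibration failure: targets mean=%g sd=%g ",
                 "unattainable on [%g, %g] (achieved %g, %g)"),
          mean, sd, a, b, mm[1], mm[2])
  list(mu = mu, sigma = sigma, moments = mm)
}

# Inverse-CDF sampler for the calibrated truncated normal; deterministic
# given the RNG state.
rtruncnorm_cal <- function(n, cal, a, b) {
  pa <- pnorm((a - cal$mu) / cal$sigma)
  pb <- pnorm((b - cal$mu) / cal$sigma)
  u <- runif(n)
  cal$mu + cal$sigma * qnorm(pa + u * (pb - pa))
}

#' Sample methylation percentages for a cohort
#'
#' Returns `n_unmethylated_zero` exact zeros followed by `n_methylated`
#' draws from the truncated-normal law on `[pct_min, pct_max]` whose
#' underlying parameters are calibrated so the truncated population mean and
#' sd equal `pct_mean` and `pct_sd`.
#'
#' @param config A [cohort_config()].
#' @return Numeric vector of percentages in `[0, 100]`, zeros first.
#' @export
sample_percentages <- function(config) {
  validate_cohort_config(config)
  zeros <- rep(0, config$n_unmethylated_zero)
  if (config$n_methylated == 0L) return(zeros)
  cal <- calibrate_truncnorm(config$pct_mean, config$pct_sd,
                             config$pct_min, config$pct_max)
  meth <- with_seed(config$seed,
                    rtruncnorm_cal(config$n_methylated, cal,
                                   config$pct_min, config$pct_max))
  c(zeros, meth)
}

#' Binarise a methylation percentage
#'
#' A patient is methylated (1) iff the percentage strictly exceeds the
#' threshold; a percentage exactly at the threshold is unmethylated (0).
#'
#' @param pct Percentage(s) in `[0, 100]`.
#' @param threshold Threshold in percent (default 10).
#' @return Integer vector of 0/1 labels.
#' @export
label_from_percentage <- function(pct, threshold = 10) {
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stopf("methylation percentage must lie in [0, 100]")
  as.integer(pct > threshold)
}

# Smooth low-frequency texture field: a small sum of random-phase cosines.
texture_field <- function(dims, n_waves = 4L, amp = 0.08) {
  g <- voxel_grid(dims)
  f <- numeric(prod(dims))
  for (i in seq_len(n_waves)) {
    k <- runif(3, 0.5, 2.0) * 2 * pi / dims
    ph <- runif(3, 0, 2 * pi)
    f <- f + runif(1, 0.3, 1) * cos(k[1] * g$x + ph[1]) *
      cos(k[2] * g$y + ph[2]) * cos(k[3] * g$z + ph[3])
  }
  array(amp * f / n_waves, dim = dims)
}

#' Generate a single tumour phantom
#'
#' Builds one synthetic patient: per-modality volumes containing a
#' brain-like noisy background and a tumour made of three nested ellipsoid
#' shells following the BraTS label convention — necrotic core (label 1),
#' enhancing rim (label 4) and surrounding edema (label 2) — plus the shared
#' segmentation mask.
#'
#' All random draws (geometry, texture, noise) are label-independent; the
#' label enters only through deterministic modulations scaled by
#' `signal_strength`: at strength `s`, unmethylated (label 0) tumours get a
#' brighter contrast-enhancing rim (the classic ring-enhancement association)
#' and a larger necrotic-core fraction, both increasing linearly in
#' `s * (1 - label)`. At `s = 0` the appearance distribution is identical
#' for both labels, so no classifier can beat chance.
#'
#' @param pct Methylation percentage of the patient.
#' @param label Binary label (0/1), consistent with `pct` and the threshold.
#' @param config A [cohort_config()].
#' @param rng_state Integer seed for this phantom.
#' @param patient_id Optional identifier string.
#' @return An object of class `patient_record` with elements `patient_id`,
#'   `volumes` (named list of 3D arrays), `mask` (3D integer array with
#'   values in \{0, 1, 2, 4\}), `methylation_pct` and `label`.
#' @export
generate_phantom <- function(pct, label, config, rng_state,
                             patient_id = "P000") {
  dims <- config$volume_shape
  if (any(dims < c(16L, 16L, 8L)))
    stopf("volume_shape must be at least (16, 16, 8)")
  s <- config$signal_strength

  with_seed(rng_state, {
    g <- voxel_grid(dims)
    ctr <- dims / 2
    brain_ax <- dims * 0.46
    rho_brain <- sqrt(((g$x - ctr[1]) / brain_ax[1])^2 +
                      ((g$y - ctr[2]) / brain_ax[2])^2 +
                      ((g$z - ctr[3]) / brain_ax[3])^2)
    brain <- rho_brain <= 1

    # tumour geometry: centre well inside the brain, random semi-axes
    t_ctr <- ctr + (dims * 0.10) * runif(3, -1, 1)
    t_ax <- pmax(dims * runif(3, 0.13, 0.20), 2)
    if (any(t_ctr - t_ax < 1) || any(t_ctr + t_ax > dims))
      stopf("tumour does not fit inside the volume")
    rho <- sqrt(((g$x - t_ctr[1]) / t_ax[1])^2 +
                ((g$y - t_ctr[2]) / t_ax[2])^2 +
                ((g$z - t_ctr[3]) / t_ax[3])^2)

    # necrotic-core fraction grows for unmethylated tumours as signal rises
    f_core_base <- runif(1, 0.30, 0.40)
    f_core <- min(f_core_base + 0.18 * s * (1 - label), 0.62)
    f_rim <- f_core + 0.22
    # edema occupies f_rim < rho <= 1
    mask <- integer(prod(dims))
    mask[rho <= 1 & rho > f_rim] <- 2L
    mask[rho <= f_rim & rho > f_core] <- 4L
    mask[rho <= f_core] <- 1L
    mask <- array(mask, dim = dims)

    # rim ring-enhancement contrast, stronger for unmethylated tumours
    rim_contrast <- 0.55 * (1 + 1.0 * s * (1 - label))
    tex <- texture_field(dims)
    noise1 <- array(rnorm(prod(dims), sd = 0.05), dim = dims)
    noise2 <- array(rnorm(prod(dims), sd = 0.05), dim = dims)

    # per-modality appearance multipliers (background, core, rim, edema)
    profiles <- list(
      T1w   = c(bg = 0.60, core = 0.45, rim = 0.15, ed = -0.05),
      T1wCE = c(bg = 0.60, core = 0.25, rim = 1.00, ed = 0.05),
      T2w   = c(bg = 0.55, core = 0.85, rim = 0.25, ed = 0.45),
      FLAIR = c(bg = 0.55, core = 0.55, rim = 0.30, ed = 0.80)
    )

    # smooth radial weights so shell edges are not hard steps
    ramp <- function(x, w = 0.08) pmin(pmax(x / w, 0), 1)
    w_core <- 1 - ramp(rho - f_core)
    w_rim <- (1 - ramp(rho - f_rim)) * ramp(rho - f_core)
    w_ed <- (1 - ramp(rho - 1)) * ramp(rho - f_rim)

    volumes <- lapply(config$modalities, function(m) {
      p <- profiles[[m]]
      v <- numeric(prod(dims))
      v[brain] <- p[["bg"]]
      v <- v + as.vector(tex) * brain
      v <- v + w_core * (p[["core"]] - p[["bg"]]) * 0.9
      rim_gain <- if (m == "T1wCE") rim_contrast else 0.3 * rim_contrast
      v <- v + w_rim * (p[["rim"]] - p[["bg"]] + rim_gain) * 0.9
      v <- v + w_ed * (p[["ed"]] - p[["bg"]]) * 0.6
      v <- v * brain
      # Rician-like magnitude noise inside the head, zero background outside
      v <- sqrt(pmax(v + as.vector(noise1), 0)^2 + (0.4 * as.vector(noise2))^2)
      v <- v * brain
      array(v, dim = dims)
    })
    names(volumes) <- config$modalities

    rec <- list(patient_id = patient_id, volumes = volumes, mask = mask,
                methylation_pct = pct, label = as.integer(label))
    class(rec) <- "patient_record"
    rec
  })
}

#' Generate a full synthetic cohort
#'
#' Samples methylation percentages via [sample_percentages()], derives the
#' binary labels with the strict threshold rule, and (optionally) builds the
#' per-patient phantom volumes. Identical `config` (including `seed`) gives
#' a bit-identical cohort.
#'
#' @param config A [cohort_config()].
#' @param volumes If `FALSE`, skip volume synthesis and return only the
#'   statistical skeleton (percentages, labels, manifest); useful when only
#'   the cohort's label structure is needed.
#' @return List with `records` (list of `patient_record`, or of
#'   volume-free stubs when `volumes = FALSE`), `manifest` (data.frame with
#'   `patient_id`, `methylation_pct`, `label`) and `config`.
#' @export
generate_cohort <- function(config, volumes = TRUE) {
  validate_cohort_config(config)
  pct <- sample_percentages(config)
  n <- length(pct)
  labels <- label_from_percentage(pct, config$label_threshold)
  ids <- sprintf("P%03d", seq_len(n))
  seeds <- derive_seeds(config$seed + 1L, n)

  records <- vector("list", n)
  for (i in seq_len(n)) {
    if (volumes) {
      records[[i]] <- generate_phantom(pct[i], labels[i], config, seeds[i],
                                       patient_id = ids[i])
    } else {
      rec <- list(patient_id = ids[i], volumes = NULL, mask = NULL,
                  methylation_pct = pct[i], label = labels[i])
      class(rec) <- "patient_record"
      records[[i]] <- rec
    }
  }
  manifest <- data.frame(
    patient_id = ids,
    methylation_pct = if (config$percentages_hidden) NA_real_ else pct,
    label = labels,
    stringsAsFactors = FALSE
  )
  list(records = records, manifest = manifest, config = config)
}

#' Write a cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' One `.nii.gz` file per modality per patient, one `<id>_mask.nii.gz`
#' segmentation per patient, and `manifest.csv` listing per-patient
#' percentage (NA when hidden), label and file paths.
#'
#' @param cohort Result of [generate_cohort()] (with volumes).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame with path columns added.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mods <- cohort$config$modalities
  man <- cohort$manifest
  for (m in mods) man[[paste0("path_", m)]] <- NA_character_
  man$path_mask <- NA_character_
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    if (is.null(rec$volumes))
      stopf("cohort was generated without volumes; nothing to write")
    for (m in mods) {
      p <- file.path(dir, sprintf("%s_%s.nii.gz", rec$patient_id, m))
      RNifti::writeNifti(RNifti::asNifti(rec$volumes[[m]]), p)
      man[[paste0("path_", m)]][i] <- p
    }
    pm <- file.path(dir, sprintf("%s_mask.nii.gz", rec$patient_id))
    RNifti::writeNifti(RNifti::asNifti(rec$mask), pm)
    man$path_mask[i] <- pm
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the NIfTI files.
#' @return List with `records` and `manifest` mirroring [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  mods <- sub("^path_", "", grep("^path_(?!mask)", names(man),
                                 value = TRUE, perl = TRUE))
  records <- lapply(seq_len(nrow(man)), function(i) {
    vols <- lapply(mods, function(m) {
      v <- RNifti::readNifti(man[[paste0("path_", m)]][i])
      array(as.numeric(v), dim = dim(v))
    })
    names(vols) <- mods
    mk <- RNifti::readNifti(man$path_mask[i])
    rec <- list(patient_id = man$patient_id[i], volumes = vols,
                mask = array(as.integer(round(as.numeric(mk))), dim = dim(mk)),
                methylation_pct = man$methylation_pct[i],
                label = as.integer(man$label[i]))
    class(rec) <- "patient_record"
    rec
  })
  list(records = records, manifest = man)
}
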