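test_that("percentage sampler reproduces the private-cohort structure", {
  cfg <- cohort_preset("private_like", seed = 11)
  p <- sample_percentages(cfg)
  expect_length(p, 98)
  expect_identical(sum(p == 0), 40L)
  meth <- p[p > 0]
  expect_length(meth, 58)
  expect_true(all(meth >= 8.4 & meth <= 85.4))
  # deterministic given seed
  expect_identical(p, sample_percentages(cfg))
  expect_false(identical(p, sample_percentages(cohort_preset("private_like",
                                                             seed = 12))))
})

test_that("degenerate config returns only the exact zeros", {
  cfg <- cohort_config(n_unmethylated_zero = 5L, n_methylated = 0L)
  expect_identical(sample_percentages(cfg), rep(0, 5))
})

test_that("truncated-normal calibration matches the analytic moments", {
  cal <- calibrate_truncnorm(41.3, 21.04, 8.4, 85.4)
  mm <- selectmri:::truncnorm_moments(cal$mu, cal$sigma, 8.4, 85.4)
  expect_equal(mm[1], 41.3, tolerance = 1e-6)
  expect_equal(mm[2], 21.04, tolerance = 1e-6)
})

test_that("infeasible moment targets raise an explicit calibration failure", {
  # a truncated normal on [8.4, 85.4] cannot reach sd 35 (uniform limit ~22.2)
  expect_error(calibrate_truncnorm(41.3, 35, 8.4, 85.4),
               "calibration failure")
  expect_error(calibrate_truncnorm(5, 10, 8.4, 85.4), "calibration failure")
})

test_that("sampled methylated moments converge to the calibrated targets", {
  # Monte-Carlo check against the analytic truncated-normal oracle
  means <- sds <- numeric(30)
  for (i in seq_len(30)) {
    cfg <- cohort_preset("private_like", seed = 1000L + i)
    p <- sample_percentages(cfg)
    means[i] <- mean(p[p > 0]); sds[i] <- sd(p[p > 0])
  }
  expect_lt(abs(mean(means) - 41.3), 1.5)
  expect_lt(abs(mean(sds) - 21.04), 2.0)
})

test_that("binarisation threshold is strict", {
  expect_identical(label_from_percentage(10.1, 10), 1L)
  expect_identical(label_from_percentage(10.0, 10), 0L)
  expect_identical(label_from_percentage(0, 10), 0L)
  expect_identical(label_from_percentage(c(9.9, 10, 10.0001), 10),
                   c(0L, 0L, 1L))
  expect_error(label_from_percentage(-1), "\\[0, 100\\]")
  expect_error(label_from_percentage(101), "\\[0, 100\\]")
})

test_that("phantom masks use the BraTS label convention", {
  cfg <- small_cohort()
  rec <- generate_phantom(50, 1, cfg, 7, "P001")
  expect_true(all(as.vector(rec$mask) %in% c(0L, 1L, 2L, 4L)))
  expect_true(all(c(1L, 2L, 4L) %in% rec$mask))   # all three shells present
  expect_identical(dim(rec$mask), dim(rec$volumes$FLAIR))
  expect_identical(sort(names(rec$volumes)), c("FLAIR", "T1wCE"))
})

test_that("at zero signal the phantom is voxel-identical across labels", {
  cfg <- small_cohort(signal = 0)
  r0 <- generate_phantom(0, 0, cfg, 99)
  r1 <- generate_phantom(50, 1, cfg, 99)
  expect_identical(r0$volumes, r1$volumes)
  expect_identical(r0$mask, r1$mask)
})

test_that("at full signal unmethylated tumours have the brighter rim", {
  cfg <- small_cohort(signal = 1)
  rim_contrast <- function(rec) {
    v <- rec$volumes$T1wCE
    mean(v[rec$mask == 4L]) / mean(v[rec$mask == 0L & v > 0])
  }
  c0 <- c1 <- numeric(50)
  for (i in seq_len(50)) {
    c0[i] <- rim_contrast(generate_phantom(0, 0, cfg, 2000L + i))
    c1[i] <- rim_contrast(generate_phantom(50, 1, cfg, 2000L + i))
  }
  expect_gt(mean(c0), mean(c1))
})

test_that("phantom errors when the volume cannot hold a tumour", {
  cfg <- small_cohort()
  cfg$volume_shape <- c(8L, 8L, 4L)
  expect_error(generate_phantom(0, 0, cfg, 1), "at least")
})

test_that("cohort presets deliver the documented label composition", {
  rsna <- generate_cohort(cohort_preset("rsna_like", seed = 3),
                          volumes = FALSE)
  expect_identical(sum(rsna$manifest$label == 1L), 300L)
  expect_identical(sum(rsna$manifest$label == 0L), 274L)
  expect_true(all(is.na(rsna$manifest$methylation_pct)))

  priv <- generate_cohort(cohort_preset("private_like", seed = 3),
                          volumes = FALSE)
  expect_identical(nrow(priv$manifest), 98L)
  expect_identical(sum(priv$manifest$methylation_pct == 0), 40L)
})

test_that("cohort generation is reproducible and label-consistent", {
  cfg <- small_cohort(n0 = 4, n1 = 4, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$records, b$records)     # bit-identical volumes
  for (r in a$records)
    expect_identical(r$label,
                     label_from_percentage(r$methylation_pct,
                                           cfg$label_threshold))
})

test_that("zero-signal phantom summaries are exchangeable across labels", {
  cfg <- small_cohort(signal = 0)
  stat <- function(rec) mean(rec$volumes$T1wCE[rec$mask == 4L])
  s0 <- vapply(1:25, function(i) stat(generate_phantom(0, 0, cfg, 500L + i)),
               numeric(1))
  s1 <- vapply(1:25, function(i) stat(generate_phantom(50, 1, cfg, 700L + i)),
               numeric(1))
  expect_gt(t.test(s0, s1)$p.value, 0.005)
})

test_that("cohorts round-trip through NIfTI files", {
  cfg <- small_cohort(n0 = 2, n1 = 1, seed = 13)
  cohort <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(length(back$records), 3L)
  expect_equal(back$records[[1]]$volumes$FLAIR,
               cohort$records[[1]]$volumes$FLAIR, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(array(back$records[[2]]$mask, dim = dim(back$records[[2]]$mask)),
                   cohort$records[[2]]$mask)
  unlink(dir, recursive = TRUE)
})
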