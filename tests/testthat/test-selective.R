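test_that("percentile thresholds give the canonical tie-free fractions", {
  D <- as.numeric(1:100)
  th <- percentile_thresholds(D, c(0, 25, 50, 70))
  fr <- vapply(th, function(t) 100 * mean(D > t), numeric(1))
  expect_equal(unname(fr), c(100, 75, 50, 30))
  # and on another tie-free size
  set.seed(1)
  D2 <- rnorm(200)
  fr2 <- vapply(percentile_thresholds(D2, c(0, 25, 50, 70)),
                function(t) 100 * mean(D2 > t), numeric(1))
  expect_equal(unname(fr2), c(100, 75, 50, 30))
})

test_that("fully tied scores make all non-zero percentiles unavailable", {
  D <- rep(3.3, 50)
  ids <- seq_along(D)
  th <- percentile_thresholds(D, c(0, 25, 50, 70))
  s0 <- filter_subset(ids, D, th[1])
  expect_true(s0$available)
  expect_equal(s0$fraction_considered, 100)
  for (k in 2:4) {
    sk <- filter_subset(ids, D, th[k])
    expect_false(sk$available)
    expect_identical(length(sk$index), 0L)
  }
})

test_that("subset membership follows strict exceedance", {
  D <- c(1, 2, 3, 4); ids <- letters[1:4]
  expect_identical(filter_subset(ids, D, 0.5)$members, ids)
  expect_identical(filter_subset(ids, D, 4)$members, character(0))
  s <- filter_subset(ids, D, 2)
  expect_identical(s$members, c("c", "d"))
  expect_equal(s$fraction_considered, 50)
})

test_that("ties shrink fractions at or below the nominal tie-free value", {
  set.seed(7)
  D <- sample(1:10, 120, replace = TRUE)   # heavy ties
  for (p in c(25, 50, 70)) {
    t <- percentile_thresholds(D, p)
    expect_lte(filter_subset(seq_along(D), D, t)$fraction_considered, 100 - p)
  }
})

test_that("rank AUC equals the all-pairs concordance oracle", {
  concordance_oracle <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  set.seed(11)
  for (rep in 1:4) {
    n <- 150
    y <- rbinom(n, 1, 0.4)
    s <- round(runif(n), 2)      # introduces ties
    expect_lt(abs(auc_rank(y, s) - concordance_oracle(y, s)), 1e-9)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rbinom(80, 1, 0.5)
  s <- rnorm(80) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_lt(abs(auc_rank(y, s) - ref), 1e-9)
})

test_that("average precision matches the per-positive oracle on tie-free data", {
  set.seed(13)
  n <- 100
  y <- rbinom(n, 1, 0.35)
  s <- rnorm(n)                  # tie-free almost surely
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]
  prec_at <- cumsum(ys) / seq_len(n)
  oracle <- sum(prec_at[ys == 1]) / sum(ys)
  expect_lt(abs(average_precision(y, s) - oracle), 1e-9)
})

test_that("subset metrics handle separable, random and one-class cases", {
  y <- c(rep(0, 5), rep(1, 5))
  d <- c(seq(0.1, 0.3, length.out = 5), seq(0.7, 0.9, length.out = 5))
  m <- metrics_on_subset(NULL, d, y)
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(metrics_on_subset(NULL, c(0.6, 0.4), c(1, 0))$accuracy, 1)
  # label-independent deltas hover at chance
  set.seed(14)
  y2 <- rbinom(2000, 1, 0.5); d2 <- runif(2000)
  expect_true(abs(metrics_on_subset(NULL, d2, y2)$auc - 0.5) < 0.05)
  # one-class subsets: AUC/AP unavailable, accuracy still defined
  m1 <- metrics_on_subset(NULL, c(0.6, 0.7), c(1, 1))
  expect_true(is.na(m1$auc))
  expect_equal(m1$accuracy, 1)
})

test_that("ROC/PR curves have the standard geometry and consistent areas", {
  y <- c(0, 0, 1, 1); d <- c(0.1, 0.2, 0.8, 0.9)
  rp <- roc_pr_curves(d, y)
  expect_true(any(rp$roc$fpr == 0 & rp$roc$tpr == 1))
  expect_equal(rp$auc, 1)
  # reversed ranking is the mirror image
  rp_rev <- roc_pr_curves(1 - d, y)
  expect_equal(rp_rev$auc, 1 - rp$auc)
  # trapezoid area equals rank AUC under ties
  set.seed(15)
  y3 <- rbinom(300, 1, 0.4); d3 <- round(runif(300), 2)
  expect_lt(abs(roc_pr_curves(d3, y3)$auc - auc_rank(y3, d3)), 1e-9)
  # random ranking: PR precision converges to prevalence
  set.seed(16)
  y4 <- rbinom(4000, 1, 0.3); d4 <- runif(4000)
  rp4 <- roc_pr_curves(d4, y4)
  expect_lt(abs(utils::tail(rp4$pr$precision, 1) - mean(y4)), 0.02)
  expect_lt(abs(average_precision(y4, d4) - mean(y4)), 0.05)
  expect_error(roc_pr_curves(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("an oracle confidence yields a monotone accuracy curve", {
  # construction: deltas correct in proportion to their margin
  set.seed(17)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  margin <- runif(n, 0, 0.5)
  correct <- rbinom(n, 1, 0.5 + margin) == 1
  d <- ifelse(correct == (y == 1), 0.5 + margin, 0.5 - margin)
  conf <- abs(d - 0.5)
  cv <- confidence_curve(seq_len(n), conf, d, y, c(0, 25, 50, 70))
  expect_true(all(diff(cv$accuracy) >= -1e-12))
  expect_true(all(cv$available))
  expect_equal(cv$fraction_considered, c(100, 75, 50, 30), tolerance = 1)
})

test_that("constant confidence leaves only the zero percentile available", {
  set.seed(18)
  n <- 60
  y <- rbinom(n, 1, 0.5); d <- runif(n)
  cv <- confidence_curve(seq_len(n), rep(1, n), d, y, c(0, 25, 50, 70))
  expect_identical(cv$available, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("random confidence gives a flat curve within noise", {
  set.seed(19)
  n <- 2000
  y <- rbinom(n, 1, 0.5); d <- runif(n); conf <- runif(n)
  cv <- confidence_curve(seq_len(n), conf, d, y, c(0, 25, 50, 70))
  expect_lt(max(cv$accuracy) - min(cv$accuracy), 0.08)
  gt <- selective_gain_test(conf, d, y, percentile = 70, n_perm = 300,
                            seed = 4)
  expect_gt(gt$p_value, 0.01)
})

test_that("surrogate subgroups expose the percentage tie structure", {
  # all-zero percentages: one tie group, only percentile 0 available
  n0 <- 30
  d0 <- runif(n0)
  sg0 <- surrogate_subgroups(seq_len(n0), rep(0, n0), d0, rep(0L, n0))
  expect_identical(sg0$curve$available, c(TRUE, FALSE, FALSE, FALSE))

  # private-like percentages: zeros all map to confidence exactly 10
  cfg <- cohort_preset("private_like", seed = 2)
  pct <- sample_percentages(cfg)
  y <- label_from_percentage(pct)
  set.seed(20)
  d <- runif(98)
  sg <- surrogate_subgroups(seq_len(98), pct, d, y)
  expect_equal(sg$curve$fraction_considered[1], 100)
  expect_true(all(sg$confidence[pct == 0] == 10))
  expect_identical(sg$composition$n[1], 98L)
  expect_identical(sg$composition$n_unmethylated_zero[1], 40L)
})

test_that("report writer renders unavailable splits as dashes", {
  set.seed(21)
  n <- 40
  y <- rbinom(n, 1, 0.5); d <- runif(n)
  curves <- list(msp = confidence_curve(seq_len(n), rep(0.5, n), d, y),
                 oracle = confidence_curve(seq_len(n), abs(d - 0.5), d, y))
  dir <- file.path(tempdir(), "report_test")
  out <- write_selective_report(curves, dir)
  csv <- utils::read.csv(file.path(dir, "selective_report.csv"))
  expect_true(all(csv$auc[csv$method == "msp"][2:4] == "-"))
  expect_true(file.exists(file.path(dir, "selective_report.json")))
  unlink(dir, recursive = TRUE)
})
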