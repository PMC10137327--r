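test_that("maximum softmax probability folds the two-class symmetry", {
  expect_equal(msp_confidence(0.5), 0.5)
  expect_equal(msp_confidence(0.9), 0.9)
  expect_equal(msp_confidence(0.1), 0.9)
  expect_error(msp_confidence(1.2), "\\[0, 1\\]")
})

test_that("perturbation score reduces to the softmax baseline at eps=0, T=1", {
  m <- tiny_test_net()
  for (i in 1:20) {
    x <- random_input(c(8, 8, 4), seed = 100 + i)
    expect_equal(odin_confidence(m, x, odin_params(temperature = 1,
                                                   epsilon = 0)),
                 msp_confidence(forward(m, x)$delta), tolerance = 1e-12)
  }
})

test_that("large temperatures drive the score to one half", {
  m <- tiny_test_net()
  x <- random_input(c(8, 8, 4), seed = 3)
  s <- odin_confidence(m, x, odin_params(temperature = 1e8, epsilon = 0))
  expect_lt(abs(s - 0.5), 1e-6)
})

test_that("the signed-gradient step increases the predicted-class score", {
  # linear toy model: the step provably increases log S_yhat
  set.seed(4)
  w <- array(rnorm(24), dim = c(4, 3, 2))
  m <- toy_linear_model(w, b = 0.3)
  x <- array(rnorm(24), dim = c(4, 3, 2))
  base <- max(selectmri:::model_probs_T(m, x, 2))
  pert <- odin_confidence(m, x, odin_params(temperature = 2, epsilon = 0.05))
  expect_gte(pert, base)
  expect_gt(pert, 0.5 - 1e-12)
})

test_that("branch adjustment interpolates between output and truth", {
  p <- c(0.6, 0.4); y <- c(1, 0)
  expect_equal(branch_adjust(p, 1, y), p)
  expect_equal(branch_adjust(p, 0, y), y)
  expect_equal(branch_adjust(p, 0.5, y), c(0.8, 0.2))
  expect_equal(sum(branch_adjust(p, 0.37, y)), 1)
})

test_that("branch loss reduces to cross-entropy at full confidence", {
  set.seed(5)
  for (i in 1:100) {
    p2 <- runif(1, 0.01, 0.99)
    p <- c(1 - p2, p2)
    y <- if (runif(1) > 0.5) c(1, 0) else c(0, 1)
    expect_equal(branch_loss(p, 1, y), -sum(log(p) * y), tolerance = 1e-12)
  }
  expect_equal(branch_loss(c(1, 0), 1, c(1, 0)), 0)
})

test_that("vanishing confidence makes the branch loss blow up", {
  p <- c(0.6, 0.4); y <- c(1, 0)
  l1 <- branch_loss(p, 0.5, y)
  l2 <- branch_loss(p, 1e-4, y)
  l3 <- branch_loss(p, 1e-12, y)
  expect_gt(l2, l1)
  expect_gt(l3, l2)
  expect_gt(branch_loss(p, 1e-300, y), 60)
  expect_message(branch_loss(p, 0, y), "clamped")
})

test_that("integrated gradients satisfy completeness on a smooth toy model", {
  # quadratic logit: z2 = a.x + q.x^2, analytic gradients
  set.seed(6)
  n <- 24
  a <- rnorm(n, sd = 0.4); q <- rnorm(n, sd = 0.2)
  m <- fn_model(
    logits_fn = function(x) c(0, sum(a * x + q * x^2)),
    logit_grad_fn = function(x) list(array(0, dim = dim(x)),
                                     array(a + 2 * q * as.vector(x),
                                           dim = dim(x))))
  x <- array(rnorm(n), dim = c(4, 3, 2))
  b <- array(0, dim = dim(x))
  ig <- integrated_gradients(m, x, b, ig_steps = 64, class = 1)
  F_ <- function(xx) forward(m, xx)$probs[2]
  expect_lt(abs(sum(ig) - (F_(x) - F_(b))), 1e-3)
  # against a much finer path integral the Riemann sum converges
  ig_fine <- integrated_gradients(m, x, b, ig_steps = 2048, class = 1)
  expect_lt(abs(sum(ig_fine) - (F_(x) - F_(b))), 1e-7)
  expect_lt(max(abs(ig - ig_fine)), 1e-4)
})

test_that("a constant classifier has attribution resilience exactly one", {
  shape <- c(12L, 12L, 4L)
  m <- toy_constant_model(shape = shape)
  x <- array(runif(prod(shape)), dim = shape)
  for (s in 1:3) {
    expect_identical(abc_confidence(m, x,
                                    abc_params(ig_steps = 4,
                                               n_perturbations = 8,
                                               seed = s)), 1)
  }
})

test_that("universally flipping perturbations give resilience zero", {
  shape <- c(12L, 12L, 4L)
  n <- prod(shape)
  k <- 10
  m <- fn_model(
    logits_fn = function(x) c(0, k * (sum(x) - n + 0.5)),
    logit_grad_fn = function(x) list(array(0, dim = shape),
                                     array(k, dim = shape)))
  x <- array(1, dim = shape)
  # switch budget forces every patch to baseline, which flips the class
  score <- abc_confidence(m, x, abc_params(ig_steps = 4, n_perturbations = 6,
                                           switch_budget = 5, seed = 2))
  expect_identical(score, 0)
})

test_that("attribution resilience works through the conv net", {
  m <- tiny_test_net(shape = c(8L, 8L, 4L))
  x <- random_input(c(8, 8, 4), seed = 12)
  s <- abc_confidence(m, x, abc_params(ig_steps = 4, n_perturbations = 6,
                                       patch_shape = c(4, 4, 2), seed = 3))
  expect_true(s >= 0 && s <= 1)
})

test_that("surrogate metric matches a brute-force branch-by-branch oracle", {
  params <- surrogate_params()
  oracle <- function(x) {
    # independent scalar evaluation of the two-branch definition
    if (x > 10) x - 10 else (10 - x) * exp(x / 5.5)
  }
  grid <- seq(0, 100, length.out = 10000)
  expect_lt(max(abs(surrogate_confidence(grid, params) -
                      vapply(grid, oracle, numeric(1)))), 1e-9)
})

test_that("surrogate metric vanishes only at the threshold and rises above it", {
  expect_equal(surrogate_confidence(10), 0)
  expect_equal(surrogate_confidence(85.4), 75.4)
  expect_equal(surrogate_confidence(0), 10)
  eps <- 1e-7
  expect_lt(abs(surrogate_confidence(10 - eps) - surrogate_confidence(10 + eps)),
            1e-5)
  up <- seq(10, 100, length.out = 2000)
  expect_true(all(diff(surrogate_confidence(up)) > 0))
  low <- seq(0, 10, by = 1e-4)
  vals <- surrogate_confidence(low)
  expect_true(all(vals[low < 10] > 0))
  expect_equal(low[which.max(vals)], 4.5, tolerance = 1e-3)
})

test_that("confidence scoring assembles a tidy per-sample table", {
  m <- tiny_test_net()
  samples <- lapply(1:4, function(i) random_input(c(8, 8, 4), seed = i))
  tab <- score_confidence(m, samples, labels = c(0, 1, 0, 1),
                          pct = c(0, 50, 5, 80),
                          metrics = c("msp", "surrogate"))
  expect_identical(nrow(tab), 8L)
  expect_identical(sort(unique(tab$metric)), c("msp", "surrogate"))
  expect_true(all(tab$score[tab$metric == "msp"] >= 0.5))
  expect_equal(tab$score[tab$metric == "surrogate"],
               surrogate_confidence(c(0, 50, 5, 80)))
})
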