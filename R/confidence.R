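# Per-prediction confidence scores: maximum softmax probability, the
# temperature-scaled input-perturbation score, the trained confidence
# branch, the attribution-resilience (integrated-gradients) score, and the
# methylation-percentage surrogate metric.

#' Parameter containers for the confidence metrics
#'
#' @param temperature Softmax temperature T > 0.
#' @param epsilon Input perturbation magnitude (normalized-intensity
#'   units), >= 0.
#' @return A parameter list of the corresponding class.
#' @export
odin_params <- function(temperature = 1000, epsilon = 0.001) {
  if (temperature <= 0) stopf("temperature must be > 0")
  if (epsilon < 0) stopf("epsilon must be >= 0")
  structure(list(temperature = temperature, epsilon = epsilon),
            class = "odin_params")
}

#' @rdname odin_params
#' @param lambda_weight Confidence-penalty weight lambda > 0.
#' @export
branch_params <- function(lambda_weight = 0.1) {
  if (lambda_weight <= 0) stopf("lambda_weight must be > 0")
  structure(list(lambda_weight = lambda_weight), class = "branch_params")
}

#' @rdname odin_params
#' @param ig_steps Number of Riemann steps for the integrated-gradients
#'   path (midpoint rule), >= 2.
#' @param patch_shape Voxel triple over which attributions are pooled into
#'   switch probabilities (default 6 x 6 x 2).
#' @param n_perturbations Number S of perturbed inputs drawn per sample.
#' @param baseline `"zeros"` or `"blur"` (Gaussian-blurred input).
#' @param switch_budget Expected fraction of patches switched to baseline
#'   when attributions are uniform.
#' @param seed Seed for the perturbation draws.
#' @export
abc_params <- function(ig_steps = 16L, patch_shape = c(6L, 6L, 2L),
                       n_perturbations = 30L,
                       baseline = c("zeros", "blur"),
                       switch_budget = 0.2, seed = 1L) {
  if (ig_steps < 2L) stopf("ig_steps must be >= 2")
  if (n_perturbations < 1L) stopf("n_perturbations must be >= 1")
  structure(list(ig_steps = as.integer(ig_steps),
                 patch_shape = as.integer(patch_shape),
                 n_perturbations = as.integer(n_perturbations),
                 baseline = match.arg(baseline),
                 switch_budget = switch_budget, seed = as.integer(seed)),
            class = "abc_params")
}

#' @rdname odin_params
#' @param kappa Decision-frontier percentage (the binarisation threshold),
#'   in (0, 100).
#' @param alpha Exponential growth scale of the sub-threshold branch, > 0.
#' @export
surrogate_params <- function(kappa = 10, alpha = 5.5) {
  if (kappa <= 0 || kappa >= 100) stopf("kappa must lie in (0, 100)")
  if (alpha <= 0) stopf("alpha must be > 0")
  structure(list(kappa = kappa, alpha = alpha), class = "surrogate_params")
}

#' Maximum softmax probability confidence
#'
#' For a two-class problem the maximum softmax probability is
#' `max(delta, 1 - delta)`, which lies in `[0.5, 1]`.
#'
#' @param delta Probability (vector) of class 1.
#' @return Confidence score(s) in `[0.5, 1]`.
#' @export
msp_confidence <- function(delta) {
  if (any(delta < 0 | delta > 1)) stopf("delta must lie in [0, 1]")
  pmax(delta, 1 - delta)
}

#' A differentiable model defined by closures
#'
#' Wraps an arbitrary two-class model given by a logit function and the
#' analytic gradients of the logits, exposing the same interface as the
#' package's convolutional models. Used for toy differentiable models in
#' oracle tests and for any externally defined classifier.
#'
#' @param logits_fn Function mapping an input array/matrix to a length-2
#'   logit vector.
#' @param logit_grad_fn Function mapping an input to a list of two arrays:
#'   the gradient of each logit with respect to the input. `NULL` makes the
#'   model non-differentiable (gradient-based scores will refuse it).
#' @return Object of class `fn_model`.
#' @export
fn_model <- function(logits_fn, logit_grad_fn = NULL) {
  structure(list(logits_fn = logits_fn, logit_grad_fn = logit_grad_fn),
            class = "fn_model")
}

#' @export
forward.fn_model <- function(model, input, ...) {
  z <- model$logits_fn(input)
  p <- as.vector(softmax_rows(matrix(z, 1, 2)))
  structure(list(delta = p[2], confidence = NULL, logits = z, probs = p),
            class = "model_output")
}

# Gradient interface shared by conv3d_net and fn_model. The default method
# in net.R handles conv3d_net; this one chains analytic logit gradients.
input_gradient_fn_model <- function(model, input, class = NULL,
                                    temperature = 1, type = "logprob") {
  if (is.null(model$logit_grad_fn))
    stopf("model is not differentiable with respect to its input")
  z <- model$logits_fn(input)
  probs <- as.vector(softmax_rows(matrix(z, 1, 2)))
  pT <- as.vector(softmax_rows(matrix(z / temperature, 1, 2)))
  y <- if (is.null(class)) which.max(probs) else as.integer(class) + 1L
  gz <- model$logit_grad_fn(input)
  if (type == "logprob") {
    grad <- (gz[[y]] - pT[1] * gz[[1]] - pT[2] * gz[[2]]) / temperature
  } else {
    grad <- probs[y] * ((if (y == 1) gz[[1]] else gz[[2]]) -
                          probs[1] * gz[[1]] - probs[2] * gz[[2]])
  }
  list(grad = grad, probs_T = pT, probs = probs, delta = probs[2],
       class = y - 1L)
}

model_gradient <- function(model, input, class = NULL, temperature = 1,
                           type = "logprob") {
  if (inherits(model, "fn_model"))
    input_gradient_fn_model(model, input, class, temperature, type)
  else if (inherits(model, "conv3d_net"))
    input_gradient(model, input, class, temperature, type)
  else stopf("model is not differentiable with respect to its input")
}

model_probs_T <- function(model, input, temperature) {
  out <- forward(model, input)
  if (is.null(out$logits))
    stopf("model does not expose logits; temperature scaling unsupported")
  as.vector(softmax_rows(matrix(out$logits / temperature, 1, 2)))
}

#' Temperature-scaled input-perturbation confidence (ODIN-style)
#'
#' The input is nudged toward the predicted class by a signed-gradient
#' step, `x_tilde = x - epsilon * sign(-grad_x log S_yhat(x; T))`, and the
#' confidence is the maximum temperature-scaled class probability at the
#' perturbed input. With `epsilon = 0` and `T = 1` this reduces exactly to
#' [msp_confidence()].
#'
#' @param model A differentiable model (`conv3d_net` or [fn_model()]).
#' @param input Model input.
#' @param params An [odin_params()].
#' @return Confidence score in `[0.5, 1]` for two classes.
#' @export
odin_confidence <- function(model, input, params = odin_params()) {
  if (is.list(input) && !is.data.frame(input) &&
      inherits(model, "conv3d_net")) input <- fuse_early(input)
  g <- model_gradient(model, input, class = NULL,
                      temperature = params$temperature, type = "logprob")
  if (params$epsilon == 0) return(max(g$probs_T))
  # x - eps * sign(-grad) = x + eps * sign(grad)
  pert <- input + params$epsilon * sign(array(g$grad, dim = dim(input) %||%
                                                length(g$grad)))
  max(model_probs_T(model, pert, params$temperature))
}

#' Confidence-branch probability adjustment
#'
#' `p_adj = c * p + (1 - c) * y`: the classifier's probability vector is
#' pulled toward the one-hot ground truth in proportion to the model's own
#' lack of confidence.
#'
#' @param p Probability vector (or matrix, one row per sample).
#' @param confidence Confidence scalar(s) in `[0, 1]`.
#' @param y One-hot ground-truth vector (or matrix).
#' @return Adjusted probabilities, same shape as `p`.
#' @export
branch_adjust <- function(p, confidence, y) {
  if (any(confidence < 0 | confidence > 1))
    stopf("confidence must lie in [0, 1]")
  confidence * p + (1 - confidence) * y
}

#' Confidence-branch training loss for one sample
#'
#' Cross-entropy of the adjusted probabilities against the one-hot truth
#' plus the confidence penalty `-lambda * log(c)`. At `c = 1` this is the
#' ordinary cross-entropy of `p` against `y`.
#'
#' @param p Probability vector over classes.
#' @param confidence Confidence scalar in `(0, 1]`; an exact 0 is clamped
#'   to `1e-12` with a message.
#' @param y One-hot ground-truth vector.
#' @param params A [branch_params()].
#' @return Scalar loss.
#' @export
branch_loss <- function(p, confidence, y, params = branch_params()) {
  if (confidence <= 0) {
    message("confidence clamped away from 0 in branch_loss")
    confidence <- 1e-12
  }
  padj <- branch_adjust(p, confidence, y)
  -sum(log(pmax(padj, 1e-300)) * y) - params$lambda_weight * log(confidence)
}

# Patch index per voxel for a given volume shape and patch shape.
patch_index <- function(dims, patch_shape) {
  g <- voxel_grid(dims)
  np <- ceiling(dims / patch_shape)
  px <- (g$x - 1L) %/% patch_shape[1]
  py <- (g$y - 1L) %/% patch_shape[2]
  pz <- (g$z - 1L) %/% patch_shape[3]
  id <- (pz * np[2] + py) * np[1] + px + 1L
  list(id = id, n = prod(np))
}

#' Integrated gradients of the predicted-class probability
#'
#' Midpoint-rule Riemann approximation of the path integral from the
#' baseline to the input; the attribution sum converges to
#' `S_y(x) - S_y(baseline)` as `ig_steps` grows (completeness).
#'
#' @param model A differentiable model.
#' @param input Model input (array).
#' @param baseline Baseline array, same shape.
#' @param ig_steps Number of steps.
#' @param class Class whose probability is attributed; `NULL` for the
#'   predicted class.
#' @return Array of integrated gradients, same shape as `input`.
#' @export
integrated_gradients <- function(model, input, baseline, ig_steps = 16L,
                                 class = NULL) {
  if (is.null(class))
    class <- which.max(forward(model, input)$probs) - 1L
  acc <- 0
  for (k in seq_len(ig_steps)) {
    xk <- baseline + (k - 0.5) / ig_steps * (input - baseline)
    g <- model_gradient(model, xk, class = class, type = "prob")
    acc <- acc + array(g$grad, dim = dim(input))
  }
  (input - baseline) * acc / ig_steps
}

#' Attribution-resilience confidence (ABC-style)
#'
#' Integrated-gradient attributions (divided by the feature value, guarded
#' near zero) are pooled into per-patch switch probabilities; `S` perturbed
#' inputs are drawn by switching whole patches to the baseline with those
#' probabilities, and the confidence is the fraction of perturbed inputs on
#' which the predicted class is unchanged.
#'
#' Patch pooling: mean absolute attribution per patch, rescaled to sum to 1
#' across patches, then scaled so the expected fraction of switched patches
#' equals `switch_budget` when attributions are uniform (probabilities are
#' capped at 1). All-zero attributions fall back to uniform switch
#' probabilities (with a message).
#'
#' @param model A differentiable model.
#' @param input Model input: 3D array, or 4D `(x, y, z, channel)` array.
#' @param params An [abc_params()].
#' @return Confidence score in `[0, 1]`.
#' @export
abc_confidence <- function(model, input, params = abc_params()) {
  if (is.list(input) && !is.data.frame(input) &&
      inherits(model, "conv3d_net")) input <- fuse_early(input)
  dims_full <- dim(input)
  vol_dims <- if (length(dims_full) == 4L) dims_full[1:3] else dims_full
  baseline <- switch(params$baseline,
    zeros = array(0, dim = dims_full),
    blur = {
      if (length(dims_full) == 4L) {
        b <- input
        for (ch in seq_len(dims_full[4]))
          b[, , , ch] <- gaussian_blur3d(input[, , , ch], sigma = 2)
        b
      } else gaussian_blur3d(input, sigma = 2)
    })
  orig <- forward(model, input)
  orig_class <- predict_class(orig$delta)

  ig <- integrated_gradients(model, input, baseline, params$ig_steps,
                             class = orig_class)
  feat <- input
  attr_ <- ifelse(abs(feat) < 1e-6, 0, ig / feat)

  pi_ <- patch_index(vol_dims, params$patch_shape)
  attr_vec <- if (length(dims_full) == 4L)
    rowMeans(matrix(abs(attr_), prod(vol_dims), dims_full[4]))
  else as.vector(abs(attr_))
  patch_mean <- as.vector(rowsum(attr_vec, pi_$id, reorder = TRUE)) /
    tabulate(pi_$id, pi_$n)
  tot <- sum(patch_mean)
  if (tot <= 0) {
    message("all-zero attributions: using uniform switch probabilities")
    share <- rep(1 / pi_$n, pi_$n)
  } else {
    share <- patch_mean / tot
  }
  switch_prob <- pmin(1, params$switch_budget * pi_$n * share)

  same <- with_seed(params$seed, {
    vapply(seq_len(params$n_perturbations), function(s) {
      sw <- runif(pi_$n) < switch_prob
      if (!any(sw)) return(orig_class)
      vox <- sw[pi_$id]
      xp <- input
      if (length(dims_full) == 4L) {
        for (ch in seq_len(dims_full[4])) {
          slab <- xp[, , , ch]; bl <- baseline[, , , ch]
          slab[vox] <- bl[vox]
          xp[, , , ch] <- slab
        }
      } else {
        xp[vox] <- baseline[vox]
      }
      predict_class(forward(model, xp)$delta)
    }, integer(1))
  })
  mean(same == orig_class)
}

#' Methylation-percentage surrogate confidence
#'
#' Maps an exact methylation percentage to a distance-from-decision-
#' frontier confidence: `x - kappa` above the threshold, and
#' `(kappa - x) * exp(x / alpha)` below it. The metric is continuous on
#' `[0, 100]`, vanishes exactly at `x = kappa`, increases strictly above
#' the threshold, and has an interior maximum of the lower branch at
#' `x = kappa - alpha`.
#'
#' @param pct Methylation percentage(s) in `[0, 100]`.
#' @param params A [surrogate_params()] (defaults kappa = 10, alpha = 5.5).
#' @return Non-negative confidence score(s).
#' @export
surrogate_confidence <- function(pct, params = surrogate_params()) {
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stopf("percentage must lie in [0, 100]")
  ifelse(pct > params$kappa,
         pct - params$kappa,
         (params$kappa - pct) * exp(pct / params$alpha))
}

#' Score a set of samples with the requested confidence metrics
#'
#' @param model A trained model.
#' @param samples List of model inputs.
#' @param ids Sample identifiers.
#' @param labels Optional 0/1 labels.
#' @param pct Optional methylation percentages (enables the surrogate
#'   metric).
#' @param metrics Character subset of
#'   `c("msp", "odin", "branch", "abc", "surrogate")`.
#' @param odin,abc,surrogate Parameter objects for the respective metrics.
#' @return Long data.frame with columns `patient_id`, `metric`, `score`,
#'   `delta`, `label`, `pct`.
#' @export
score_confidence <- function(model, samples, ids = NULL, labels = NULL,
                             pct = NULL,
                             metrics = c("msp", "odin"),
                             odin = odin_params(), abc = abc_params(),
                             surrogate = surrogate_params()) {
  n <- length(samples)
  ids <- ids %||% sprintf("S%03d", seq_len(n))
  deltas <- numeric(n); confs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    out <- forward(model, samples[[i]])
    deltas[i] <- out$delta
    if (!is.null(out$confidence)) confs[i] <- out$confidence
  }
  rows <- list()
  for (m in metrics) {
    score <- switch(m,
      msp = msp_confidence(deltas),
      odin = vapply(samples, function(s)
        odin_confidence(model, s, odin), numeric(1)),
      branch = {
        if (all(is.na(confs)))
          stopf("model has no confidence branch; cannot score 'branch'")
        confs
      },
      abc = vapply(seq_len(n), function(i) {
        p <- abc; p$seed <- abc$seed + i
        abc_confidence(model, samples[[i]], p)
      }, numeric(1)),
      surrogate = {
        if (is.null(pct)) stopf("surrogate metric requires percentages")
        surrogate_confidence(pct, surrogate)
      },
      stopf("unknown metric '%s'", m))
    rows[[m]] <- data.frame(patient_id = ids, metric = m, score = score,
                            delta = deltas,
                            label = labels %||% NA_integer_,
                            pct = pct %||% NA_real_,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
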