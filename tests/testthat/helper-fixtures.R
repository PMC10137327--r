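# Shared fixtures: small cohort configurations and toy differentiable
# models used by the confidence-metric oracle tests.

small_cohort <- function(n0 = 6L, n1 = 6L, signal = 1, seed = 1L,
                         shape = c(16L, 16L, 8L)) {
  cohort_config(n_unmethylated_zero = n0, n_methylated = n1,
                signal_strength = signal, volume_shape = shape,
                modalities = c("FLAIR", "T1wCE"), seed = seed)
}

# Linear two-class model on an arbitrary array input: logits (0, w.x + b).
toy_linear_model <- function(w, b = 0) {
  fn_model(
    logits_fn = function(x) c(0, sum(w * x) + b),
    logit_grad_fn = function(x) list(array(0, dim = dim(w) %||% length(w)), w)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Constant-output model: prediction never changes, gradients vanish.
toy_constant_model <- function(logits = c(0.2, 1.1), shape) {
  fn_model(
    logits_fn = function(x) logits,
    logit_grad_fn = function(x) list(array(0, dim = shape),
                                     array(0, dim = shape))
  )
}

# A small untrained conv net shared across confidence tests.
tiny_test_net <- function(shape = c(8L, 8L, 4L), channels = 2L, seed = 3L,
                          confidence_head = FALSE) {
  cfg <- model_config("tiny", in_channels = channels, fusion = "early",
                      confidence_head = confidence_head, seed = seed)
  build_model(cfg, shape)
}

random_input <- function(shape, channels = 2L, seed = 1L) {
  set.seed(seed)
  array(rnorm(prod(shape) * channels), dim = c(shape, channels))
}
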