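# Modality fusion strategies: at the input (early), at the embedding level
# (multi-head attention followed by probabilistic modality docking), or at
# the decision level (late).

# Fixed canonical channel order so early fusion is independent of the order
# in which the caller's list happens to be named.
canonical_modalities <- function(names) sort(names)

#' Early fusion: stack modality volumes into one multi-channel volume
#'
#' Modalities are stacked along a trailing channel axis in a fixed
#' name-sorted order, so a permuted input list yields an identical output.
#'
#' @param volumes Named list of 3D arrays sharing one shape.
#' @return 4D array `(x, y, z, channel)` with a `modalities` attribute.
#' @export
fuse_early <- function(volumes) {
  if (length(volumes) < 1L) stopf("fusion error: no modalities supplied")
  ord <- canonical_modalities(names(volumes))
  d <- dim(volumes[[1]])
  for (v in volumes) {
    check_volume(v)
    if (!all(dim(v) == d)) stopf("fusion error: modality shape mismatch")
  }
  out <- array(0, dim = c(d, length(volumes)))
  for (i in seq_along(ord)) out[, , , i] <- volumes[[ord[i]]]
  attr(out, "modalities") <- ord
  out
}

#' Multi-head attention parameters for intermediate fusion
#'
#' Query and key projections per head; values are taken as the embeddings
#' themselves (identity value projection), so the attention layer produces
#' row-stochastic re-weightings of the modality embeddings and the
#' subsequent docking step remains a convex combination.
#'
#' @param embedding_dim Embedding width d.
#' @param heads Number of heads (must divide d).
#' @param seed Integer seed for initialisation.
#' @return List of per-head `Wq`, `Wk` matrices (d x d/heads).
#' @export
attention_params <- function(embedding_dim, heads, seed = 1L) {
  if (embedding_dim %% heads != 0L)
    stopf("attention heads must divide embedding_dim")
  dh <- embedding_dim %/% heads
  with_seed(seed, lapply(seq_len(heads), function(h)
    list(Wq = matrix(rnorm(embedding_dim * dh, sd = sqrt(1 / embedding_dim)),
                     embedding_dim, dh),
         Wk = matrix(rnorm(embedding_dim * dh, sd = sqrt(1 / embedding_dim)),
                     embedding_dim, dh))))
}

#' Intermediate fusion: attention over modality embeddings, then docking
#'
#' A layer of multi-head self-attention is applied across the sequence of
#' modality embeddings (values are the embeddings themselves, so each
#' post-attention embedding is a convex combination of the inputs). The
#' docking step then combines the post-attention embeddings into a single
#' vector: in `"inference"` mode the expectation under the per-modality
#' docking probabilities; in `"sample"` mode one modality is drawn per
#' embedding coordinate with those probabilities.
#'
#' @param embeddings Matrix (modalities x d) or list of equal-length
#'   numeric vectors.
#' @param config A [model_config()] (supplies heads and, if `attn` is
#'   `NULL`, the seed for the attention parameters).
#' @param attn Attention parameters from [attention_params()]; `NULL` means
#'   seeded defaults.
#' @param docking_probs Per-modality probabilities summing to 1; `NULL`
#'   means uniform.
#' @param mode `"inference"` (expectation) or `"sample"`.
#' @param detail If `TRUE`, return intermediate quantities (for training
#'   and diagnostics) instead of just the fused vector.
#' @return Fused embedding vector, or a detail list with `fused`, `Z`
#'   (post-attention embeddings), `A` (per-head attention matrices), and in
#'   sample mode `selected` (the modality index chosen per coordinate).
#' @export
fuse_intermediate <- function(embeddings, config, attn = NULL,
                              docking_probs = NULL,
                              mode = c("inference", "sample"),
                              detail = FALSE) {
  mode <- match.arg(mode)
  E <- if (is.list(embeddings)) do.call(rbind, embeddings) else embeddings
  if (!is.matrix(E)) E <- matrix(E, nrow = 1)
  M <- nrow(E); d <- ncol(E)
  if (M == 1L) {
    warning("single modality: intermediate fusion is a pass-through")
    out <- as.vector(E[1, ])
    if (!detail) return(out)
    return(list(fused = out, Z = E, A = list(), E = E,
                p = 1, selected = rep(1L, d)))
  }
  p <- docking_probs %||% rep(1 / M, M)
  if (length(p) != M || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stopf("docking probabilities must be a length-%d simplex vector", M)
  attn <- attn %||% attention_params(d, config$attention_heads,
                                     seed = config$seed + 1L)
  H <- length(attn)
  A <- vector("list", H)
  QK <- vector("list", H)
  Z <- matrix(0, M, d)
  for (h in seq_len(H)) {
    Q <- E %*% attn[[h]]$Wq
    K <- E %*% attn[[h]]$Wk
    S <- Q %*% t(K) / sqrt(ncol(Q))
    A[[h]] <- softmax_rows(S)
    QK[[h]] <- list(Q = Q, K = K)
    Z <- Z + A[[h]] %*% E / H
  }
  if (mode == "inference") {
    fused <- as.vector(t(Z) %*% p)
    selected <- NULL
  } else {
    selected <- sample.int(M, d, replace = TRUE, prob = p)
    fused <- Z[cbind(selected, seq_len(d))]
  }
  if (!detail) return(fused)
  list(fused = fused, Z = Z, A = A, QK = QK, E = E, p = p,
       selected = selected, mode = mode)
}

# Backward pass of expectation-mode intermediate fusion for one sample.
# `fu` is the detail list from fuse_intermediate(); dfused is the gradient
# at the fused vector. Returns dE (M x d) and per-head dWq/dWk.
fuse_intermediate_bwd <- function(fu, dfused, attn, config) {
  E <- fu$E; M <- nrow(E); d <- ncol(E); H <- length(attn)
  p <- fu$p
  # dZ from docking
  if (!is.null(fu$selected)) {
    dZ <- matrix(0, M, d)
    dZ[cbind(fu$selected, seq_len(d))] <- dfused
  } else {
    dZ <- p %o% dfused
  }
  dE <- matrix(0, M, d)
  dattn <- vector("list", H)
  for (h in seq_len(H)) {
    Ah <- fu$A[[h]]
    Q <- fu$QK[[h]]$Q; K <- fu$QK[[h]]$K
    dAh <- (dZ %*% t(E)) / H
    dE <- dE + t(Ah) %*% dZ / H
    # softmax rows backward
    dS <- Ah * (dAh - rowSums(dAh * Ah))
    scale <- 1 / sqrt(ncol(Q))
    dQ <- dS %*% K * scale
    dK <- t(dS) %*% Q * scale
    dattn[[h]] <- list(Wq = t(E) %*% dQ, Wk = t(E) %*% dK)
    dE <- dE + dQ %*% t(attn[[h]]$Wq) + dK %*% t(attn[[h]]$Wk)
  }
  list(dE = dE, dattn = dattn)
}

#' Late fusion: average per-model class probabilities
#'
#' @param deltas Numeric vector of per-modality predicted probabilities of
#'   class 1, each in `[0, 1]`.
#' @return Their unweighted mean (or majority vote when `vote = TRUE`).
#' @param vote Use a majority vote over the thresholded per-model classes
#'   instead of the mean probability.
#' @export
fuse_late <- function(deltas, vote = FALSE) {
  if (length(deltas) == 0L) stopf("fusion error: no predictions to fuse")
  if (any(deltas < 0 | deltas > 1)) stopf("deltas must lie in [0, 1]")
  if (vote) return(as.numeric(mean(predict_class(deltas)) > 0.5))
  mean(deltas)
}

#' Threshold a class probability into a class
#'
#' The predicted class is 1 iff `delta` strictly exceeds 0.5; a tie at
#' exactly 0.5 is assigned to class 0.
#'
#' @param delta Probability (or vector of probabilities) of class 1.
#' @return Integer 0/1 vector.
#' @export
predict_class <- function(delta) {
  if (any(delta < 0 | delta > 1)) stopf("delta must lie in [0, 1]")
  as.integer(delta > 0.5)
}
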