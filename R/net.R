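# 3D convolutional network engine.
#
# Feature maps live as dense matrices of shape (batch * n_voxels) x channels;
# a 3x3x3 "same" convolution is a sum of 27 shifted-index matrix products
# against a zero-padded row. This keeps everything in BLAS calls, and makes
# the exact gradient with respect to the input available for free, which the
# perturbation- and attribution-based confidence scores require.

conv_offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))

# Index maps for one resolution and batch size. Out-of-volume neighbours
# point at a dedicated zero row (B * nvox + 1).
make_geom <- function(dims, B) {
  nvox <- prod(dims)
  g <- voxel_grid(dims)
  zero_row <- B * nvox + 1L
  idx <- vector("list", 27L)
  for (k in 1:27) {
    xs <- g$x + conv_offsets[k, 1]
    ys <- g$y + conv_offsets[k, 2]
    zs <- g$z + conv_offsets[k, 3]
    ok <- xs >= 1 & xs <= dims[1] & ys >= 1 & ys <= dims[2] &
      zs >= 1 & zs <= dims[3]
    base <- ifelse(ok, ((zs - 1L) * dims[2] + (ys - 1L)) * dims[1] + xs, NA)
    full <- integer(B * nvox)
    for (b in seq_len(B)) {
      seg <- base + (b - 1L) * nvox
      seg[is.na(base)] <- zero_row
      full[((b - 1L) * nvox + 1L):(b * nvox)] <- seg
    }
    idx[[k]] <- full
  }
  # 2x mean-pool grouping (requires even dims)
  pool <- NULL
  if (all(dims %% 2L == 0L)) {
    pd <- dims %/% 2L
    ox <- (g$x + 1L) %/% 2L; oy <- (g$y + 1L) %/% 2L; oz <- (g$z + 1L) %/% 2L
    pg1 <- ((oz - 1L) * pd[2] + (oy - 1L)) * pd[1] + ox
    npool <- prod(pd)
    pg <- integer(B * nvox)
    for (b in seq_len(B))
      pg[((b - 1L) * nvox + 1L):(b * nvox)] <- pg1 + (b - 1L) * npool
    pool <- list(group = pg, out_dims = pd, n_out = B * npool)
  }
  list(dims = dims, B = B, nvox = nvox, idx = idx, zero_row = zero_row,
       pool = pool, gap_group = rep(seq_len(B), each = nvox))
}

pad_zero_row <- function(X) rbind(X, 0)

conv_fwd <- function(X, W, b, geom) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  Xz <- pad_zero_row(X)
  Y <- matrix(rep(b, each = nrow(X)), nrow(X), cout)
  for (k in 1:27)
    Y <- Y + Xz[geom$idx[[k]], , drop = FALSE] %*% matrix(W[k, , ], cin, cout)
  Y
}

# Gradients of a conv layer. Returns input grad and, when X is supplied,
# parameter grads.
conv_bwd <- function(dY, X, W, geom, want_params = TRUE) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  dYz <- pad_zero_row(dY)
  dX <- matrix(0, nrow(dY), cin)
  for (k in 1:27) {
    Wk <- matrix(W[k, , ], cin, cout)
    dX <- dX + dYz[geom$idx[[28L - k]], , drop = FALSE] %*% t(Wk)
  }
  out <- list(dX = dX)
  if (want_params) {
    dW <- array(0, dim = dim(W))
    Xz <- pad_zero_row(X)
    for (k in 1:27)
      dW[k, , ] <- crossprod(Xz[geom$idx[[k]], , drop = FALSE], dY)
    out$dW <- dW
    out$db <- colSums(dY)
  }
  out
}

pool_fwd <- function(X, geom) {
  out <- rowsum(X, geom$pool$group, reorder = TRUE) / 8
  dimnames(out) <- NULL
  out
}
pool_bwd <- function(dY, geom) {
  dY[geom$pool$group, , drop = FALSE] / 8
}

relu <- function(x) x * (x > 0)

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Classifier configuration
#'
#' @param encoder_depth `"tiny"` (three residual stages, CPU-friendly) or
#'   `"deep"` (wider/deeper residual encoder in the ResNet10-3D spirit).
#' @param in_channels Number of input channels: the number of modalities
#'   under early fusion, 1 otherwise.
#' @param fusion One of `"none"`, `"early"`, `"intermediate"`, `"late"`.
#' @param attention_heads Number of attention heads for intermediate fusion;
#'   must divide `embedding_dim`.
#' @param embedding_dim Encoder embedding width. `NULL` means the encoder's
#'   native width (16 for tiny, 64 for deep).
#' @param confidence_head Attach the trained confidence branch (a sigmoid
#'   head on the penultimate embedding).
#' @param seed Seed for weight initialisation.
#' @return An object of class `model_config`.
#' @export
model_config <- function(encoder_depth = c("tiny", "deep"),
                         in_channels = 2L,
                         fusion = c("early", "none", "intermediate", "late"),
                         attention_heads = 2L,
                         embedding_dim = NULL,
                         confidence_head = FALSE,
                         seed = 1L) {
  encoder_depth <- match.arg(encoder_depth)
  fusion <- match.arg(fusion)
  native <- if (encoder_depth == "tiny") 16L else 64L
  embedding_dim <- as.integer(embedding_dim %||% native)
  if (embedding_dim %% attention_heads != 0L)
    stopf("attention_heads must divide embedding_dim")
  if (in_channels < 1L) stopf("in_channels must be >= 1")
  structure(list(encoder_depth = encoder_depth,
                 in_channels = as.integer(in_channels),
                 fusion = fusion,
                 attention_heads = as.integer(attention_heads),
                 embedding_dim = embedding_dim,
                 confidence_head = isTRUE(confidence_head),
                 seed = as.integer(seed)),
            class = "model_config")
}

encoder_plan <- function(config) {
  if (config$encoder_depth == "tiny") {
    list(stem = 8L,
         stages = list(list(ch = 8L, pool = TRUE),
                       list(ch = 16L, pool = TRUE),
                       list(ch = config$embedding_dim, pool = FALSE)))
  } else {
    list(stem = 16L,
         stages = list(list(ch = 16L, pool = TRUE),
                       list(ch = 32L, pool = TRUE),
                       list(ch = 64L, pool = TRUE),
                       list(ch = config$embedding_dim, pool = FALSE)))
  }
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))), dim = c(k, cin, cout))
}

#' Build a 3D residual convolutional classifier
#'
#' The encoder is a stack of residual stages (3x3x3 convolutions with
#' identity skips and 2x mean-pool downsampling) followed by global average
#' pooling into an embedding; the head is a 2-way linear classifier with
#' softmax output and, optionally, a sigmoid confidence branch. Weight
#' initialisation is fully determined by `config$seed`.
#'
#' @param config A [model_config()].
#' @param input_shape Integer triple; each axis must be divisible by 4 so
#'   two pooling stages apply cleanly (deep encoder: divisible by 8).
#' @return An object of class `conv3d_net`.
#' @export
build_model <- function(config, input_shape) {
  input_shape <- as.integer(input_shape)
  plan <- encoder_plan(config)
  n_pools <- sum(vapply(plan$stages, function(s) s$pool, logical(1)))
  if (any(input_shape %% (2L^n_pools) != 0L))
    stopf("input_shape must be divisible by %d on every axis", 2L^n_pools)
  enc_in <- if (config$fusion %in% c("early")) config$in_channels else 1L
  if (config$fusion %in% c("none")) enc_in <- config$in_channels

  params <- with_seed(config$seed, {
    p <- list(stem = list(W = he_init(27L, enc_in, plan$stem),
                          b = numeric(plan$stem)))
    prev <- plan$stem
    p$stages <- lapply(plan$stages, function(sg) {
      st <- list(up = NULL)
      if (sg$ch != prev)
        st$up <- list(W = he_init(27L, prev, sg$ch), b = numeric(sg$ch))
      st$c1 <- list(W = he_init(27L, sg$ch, sg$ch), b = numeric(sg$ch))
      st$c2 <- list(W = he_init(27L, sg$ch, sg$ch), b = numeric(sg$ch))
      prev <<- sg$ch
      st
    })
    d <- config$embedding_dim
    p$head <- list(W = matrix(rnorm(d * 2, sd = sqrt(1 / d)), d, 2),
                   b = numeric(2))
    if (config$confidence_head)
      p$conf <- list(W = matrix(rnorm(d, sd = sqrt(1 / d)), d, 1), b = 0)
    if (config$fusion == "intermediate")
      p$attn <- attention_params(d, config$attention_heads,
                                 seed = config$seed + 1L)
    p
  })

  model <- list(config = config, input_shape = input_shape, params = params,
                plan = plan, geom_cache = new.env(parent = emptyenv()))
  class(model) <- "conv3d_net"
  model
}

model_geom <- function(model, dims, B) {
  key <- paste(c(dims, B), collapse = "x")
  cache <- model$geom_cache
  if (is.null(cache[[key]])) cache[[key]] <- make_geom(dims, B)
  cache[[key]]
}

# Encoder forward. X: (B*nvox) x C matrix. Returns embedding (B x d) and a
# cache for the backward pass.
encoder_fwd <- function(model, X, B) {
  dims <- model$input_shape
  geom <- model_geom(model, dims, B)
  p <- model$params
  cache <- list(geoms = list(), acts = list())

  Zs <- conv_fwd(X, p$stem$W, p$stem$b, geom)
  A <- relu(Zs)
  cache$X <- X; cache$Zs <- Zs; cache$geom_stem <- geom
  for (i in seq_along(p$stages)) {
    st <- p$stages[[i]]
    sc <- list(geom = geom)
    if (!is.null(st$up)) {
      sc$Ain <- A
      sc$Zu <- conv_fwd(A, st$up$W, st$up$b, geom)
      A <- relu(sc$Zu)
    }
    sc$Au <- A
    sc$Z1 <- conv_fwd(A, st$c1$W, st$c1$b, geom)
    sc$R1 <- relu(sc$Z1)
    sc$Z2 <- conv_fwd(sc$R1, st$c2$W, st$c2$b, geom)
    sc$S <- sc$Au + sc$Z2
    A <- relu(sc$S)
    if (model$plan$stages[[i]]$pool) {
      sc$Apre_pool <- A
      A <- pool_fwd(A, geom)
      geom <- model_geom(model, geom$pool$out_dims, B)
    }
    cache$acts[[i]] <- sc
  }
  nlast <- geom$nvox
  E <- rowsum(A, geom$gap_group, reorder = TRUE) / nlast
  dimnames(E) <- NULL
  cache$geom_last <- geom
  cache$A_last <- A
  list(E = E, cache = cache)
}

# Encoder backward: propagate dE (B x d) to input gradient and (optionally)
# parameter gradients.
encoder_bwd <- function(model, cache, dE, want_params = TRUE,
                        want_input = TRUE) {
  p <- model$params
  geom <- cache$geom_last
  grads <- if (want_params) list(stages = vector("list", length(p$stages)))
           else NULL
  dA <- dE[geom$gap_group, , drop = FALSE] / geom$nvox
  for (i in rev(seq_along(p$stages))) {
    sc <- cache$acts[[i]]
    st <- p$stages[[i]]
    if (model$plan$stages[[i]]$pool) {
      dA <- pool_bwd(dA, sc$geom)
      dA <- dA * (sc$Apre_pool > 0)
    } else {
      dA <- dA * (relu(sc$S) > 0)
    }
    # dA is now gradient at S = Au + Z2
    g2 <- conv_bwd(dA, sc$R1, st$c2$W, sc$geom, want_params)
    dR1 <- g2$dX * (sc$Z1 > 0)
    g1 <- conv_bwd(dR1, sc$Au, st$c1$W, sc$geom, want_params)
    dAu <- dA + g1$dX
    gu <- NULL
    if (!is.null(st$up)) {
      dZu <- dAu * (sc$Zu > 0)
      gu <- conv_bwd(dZu, sc$Ain, st$up$W, sc$geom, want_params)
      dA <- gu$dX
    } else {
      dA <- dAu
    }
    if (want_params) {
      grads$stages[[i]] <- list(
        up = if (!is.null(gu)) list(W = gu$dW, b = gu$db) else NULL,
        c1 = list(W = g1$dW, b = g1$db),
        c2 = list(W = g2$dW, b = g2$db))
    }
  }
  dZs <- dA * (cache$Zs > 0)
  gs <- conv_bwd(dZs, cache$X, p$stem$W, cache$geom_stem,
                 want_params)
  if (want_params) grads$stem <- list(W = gs$dW, b = gs$db)
  list(dX = if (want_input) gs$dX else NULL, grads = grads)
}

head_fwd <- function(model, E) {
  p <- model$params
  logits <- E %*% p$head$W + matrix(p$head$b, nrow(E), 2, byrow = TRUE)
  probs <- softmax_rows(logits)
  conf <- NULL
  if (!is.null(p$conf)) {
    u <- as.vector(E %*% p$conf$W + p$conf$b)
    conf <- 1 / (1 + exp(-u))
  }
  list(logits = logits, probs = probs, conf = conf)
}

# Full forward on a batch matrix. For intermediate fusion X must be the
# (B*nvox) x M matrix of modality channels; each modality column is encoded
# separately through the shared encoder, then fused.
net_fwd_batch <- function(model, X, B, keep_cache = FALSE) {
  if (model$config$fusion == "intermediate") {
    M <- ncol(X)
    embs <- vector("list", M)
    caches <- vector("list", M)
    for (m in seq_len(M)) {
      fw <- encoder_fwd(model, X[, m, drop = FALSE], B)
      embs[[m]] <- fw$E
      caches[[m]] <- fw$cache
    }
    d <- model$config$embedding_dim
    E <- matrix(0, B, d)
    att <- vector("list", B)
    for (b in seq_len(B)) {
      Eb <- do.call(rbind, lapply(embs, function(e) e[b, ]))
      fu <- fuse_intermediate(Eb, model$config, attn = model$params$attn,
                              mode = "inference", detail = TRUE)
      E[b, ] <- fu$fused
      att[[b]] <- fu
    }
    hd <- head_fwd(model, E)
    out <- c(hd, list(E = E))
    if (keep_cache)
      out$cache <- list(type = "intermediate", embs = embs, caches = caches,
                        att = att, E = E)
    return(out)
  }
  fw <- encoder_fwd(model, X, B)
  hd <- head_fwd(model, fw$E)
  out <- c(hd, list(E = fw$E))
  if (keep_cache) out$cache <- c(fw$cache, list(type = "plain", E = fw$E))
  out
}

# Canonical input: a 4D array (x, y, z, channel) or a (nvox x C) matrix.
as_input_matrix <- function(x, input_shape = NULL) {
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 4L)
    return(matrix(x, prod(dim(x)[1:3]), dim(x)[4]))
  if (is.array(x) && length(dim(x)) == 3L)
    return(matrix(x, prod(dim(x)), 1L))
  stopf("model input must be a 3D/4D array or a voxel-by-channel matrix")
}

#' Run a classifier on one sample
#'
#' @param model A trained (or freshly built) model.
#' @param input A 4D array `(x, y, z, channel)`, a 3D array for
#'   single-channel models, or a named list of modality volumes (fused
#'   according to the model's fusion setting).
#' @param ... Unused.
#' @return A `model_output` list: `delta` (probability of class 1),
#'   `confidence` (trained branch output or `NULL`), `logits`, `probs`.
#' @export
forward <- function(model, input, ...) UseMethod("forward")

#' @export
forward.conv3d_net <- function(model, input, ...) {
  if (is.list(input) && !is.data.frame(input)) input <- fuse_early(input)
  X <- as_input_matrix(input, model$input_shape)
  if (nrow(X) != prod(model$input_shape))
    stopf("input voxel count %d does not match model input shape", nrow(X))
  out <- net_fwd_batch(model, X, 1L)
  structure(list(delta = out$probs[1, 2],
                 confidence = if (!is.null(out$conf)) out$conf[1] else NULL,
                 logits = out$logits[1, ], probs = out$probs[1, ]),
            class = "model_output")
}

#' Batched class-1 probabilities for a list of samples
#'
#' @param model A `conv3d_net` or `late_ensemble`.
#' @param samples List of model inputs (see [forward()]).
#' @return Numeric vector of `delta` values.
#' @export
predict_delta <- function(model, samples) {
  vapply(samples, function(s) forward(model, s)$delta, numeric(1))
}

#' Gradient of the model output with respect to the input
#'
#' Computes either the gradient of `log S_y(x; T)` (temperature-scaled
#' log-probability of class `class`, as used by the perturbation confidence
#' score) or of the plain softmax probability `S_y(x)` (as used by
#' integrated gradients).
#'
#' @param model A `conv3d_net`.
#' @param input Model input (see [forward()]).
#' @param class Class index (0 or 1); `NULL` means the predicted class.
#' @param temperature Softmax temperature T > 0.
#' @param type `"logprob"` or `"prob"`.
#' @return List with `grad` (matrix, voxels by channels), `probs_T`
#'   (temperature-scaled probabilities), `probs`, `delta`.
#' @export
input_gradient <- function(model, input, class = NULL, temperature = 1,
                           type = c("logprob", "prob")) {
  type <- match.arg(type)
  if (temperature <= 0) stopf("temperature must be positive")
  if (is.list(input) && !is.data.frame(input)) input <- fuse_early(input)
  X <- as_input_matrix(input, model$input_shape)
  out <- net_fwd_batch(model, X, 1L, keep_cache = TRUE)
  probs <- out$probs[1, ]
  pT <- softmax_rows(out$logits / temperature)[1, ]
  y <- if (is.null(class)) which.max(probs) else as.integer(class) + 1L
  # d objective / d logits
  if (type == "logprob") {
    dlogits <- -pT / temperature
    dlogits[y] <- dlogits[y] + 1 / temperature
  } else {
    dlogits <- -probs[y] * probs
    dlogits[y] <- dlogits[y] + probs[y]
  }
  dlog <- matrix(dlogits, 1, 2)
  dE <- dlog %*% t(model$params$head$W)
  if (model$config$fusion == "intermediate") {
    grad <- input_gradient_intermediate(model, out$cache, dE)
  } else {
    bw <- encoder_bwd(model, out$cache, dE, want_params = FALSE,
                      want_input = TRUE)
    grad <- bw$dX
  }
  list(grad = grad, probs_T = pT, probs = probs, delta = probs[2],
       class = y - 1L)
}

# Input gradient through attention + expectation docking for a single
# sample (B = 1).
input_gradient_intermediate <- function(model, cache, dE) {
  M <- length(cache$embs)
  fu <- cache$att[[1]]
  dEmb <- fuse_intermediate_bwd(fu, as.vector(dE), model$params$attn,
                                model$config)$dE
  grads <- vector("list", M)
  for (m in seq_len(M)) {
    bw <- encoder_bwd(model, cache$caches[[m]],
                      matrix(dEmb[m, ], 1), want_params = FALSE,
                      want_input = TRUE)
    grads[[m]] <- bw$dX
  }
  do.call(cbind, grads)
}

#' Number of trainable parameters
#' @param model A `conv3d_net`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  s <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else s <<- s + length(x)
    invisible(NULL)
  }
  walk(model$params)
  s
}
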