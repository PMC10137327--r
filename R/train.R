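# Training: Adam over the parameter tree, standard cross-entropy or the
# confidence-branch loss (adjusted probabilities plus a -lambda*log(c)
# penalty with a budget heuristic on lambda).

# Apply f leaf-wise across parallel parameter trees (lists of lists of
# numeric arrays); NULL leaves (absent optional blocks) are preserved.
tree_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      if (is.null(a[[i]])) { out[i] <- list(NULL); next }
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

adam_step <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  params <- tree_map(function(p, m, v)
    p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

# Loss value and gradient at the logits (and confidence unit) for a batch.
# y is an integer 0/1 vector.
loss_grads <- function(logits, probs, conf, y, lambda_weight) {
  B <- nrow(probs)
  ti <- cbind(seq_len(B), y + 1L)
  if (is.null(conf)) {
    loss <- -mean(log(pmax(probs[ti], 1e-12)))
    Y <- matrix(0, B, 2); Y[ti] <- 1
    return(list(loss = loss, dlogits = (probs - Y) / B, du = NULL))
  }
  c_ <- pmin(pmax(conf, 1e-6), 1 - 1e-6)
  pt <- probs[ti]
  ppt <- c_ * pt + (1 - c_)                     # adjusted prob of true class
  loss <- mean(-log(ppt)) + lambda_weight * mean(-log(c_))
  # d(-log ppt)/dz_j = -(c pt / ppt) (delta_tj - p_j)
  Y <- matrix(0, B, 2); Y[ti] <- 1
  dlogits <- -(c_ * pt / ppt) * (Y - probs) / B
  dc <- -(pt - 1) / ppt - lambda_weight / c_
  du <- dc * c_ * (1 - c_) / B
  list(loss = loss, dlogits = dlogits, du = du)
}

# Assemble the full gradient tree (encoder + head [+ conf, attn]) for one
# batch with cached forward state.
batch_grads <- function(model, fw, y, lambda_weight) {
  lg <- loss_grads(fw$logits, fw$probs, fw$conf, y, lambda_weight)
  E <- fw$E
  p <- model$params
  dW_head <- crossprod(E, lg$dlogits)
  db_head <- colSums(lg$dlogits)
  dE <- lg$dlogits %*% t(p$head$W)
  grads <- list(head = list(W = dW_head, b = db_head))
  if (!is.null(lg$du)) {
    grads$conf <- list(W = crossprod(E, matrix(lg$du)), b = sum(lg$du))
    dE <- dE + lg$du %o% as.vector(p$conf$W)
  }
  cache <- fw$cache
  if (cache$type == "intermediate") {
    B <- nrow(E); M <- length(cache$embs)
    dEmb <- lapply(seq_len(M), function(m) matrix(0, B, ncol(E)))
    H <- length(p$attn)
    dattn_acc <- lapply(seq_len(H), function(h)
      list(Wq = 0 * p$attn[[h]]$Wq, Wk = 0 * p$attn[[h]]$Wk))
    for (b in seq_len(B)) {
      bw <- fuse_intermediate_bwd(cache$att[[b]], dE[b, ], p$attn,
                                  model$config)
      for (m in seq_len(M)) dEmb[[m]][b, ] <- bw$dE[m, ]
      for (h in seq_len(H)) {
        dattn_acc[[h]]$Wq <- dattn_acc[[h]]$Wq + bw$dattn[[h]]$Wq
        dattn_acc[[h]]$Wk <- dattn_acc[[h]]$Wk + bw$dattn[[h]]$Wk
      }
    }
    enc <- NULL
    for (m in seq_len(M)) {
      bwm <- encoder_bwd(model, cache$caches[[m]], dEmb[[m]],
                         want_params = TRUE, want_input = FALSE)
      enc <- if (is.null(enc)) bwm$grads
             else tree_map(`+`, enc, bwm$grads)
    }
    grads$stem <- enc$stem
    grads$stages <- enc$stages
    grads$attn <- dattn_acc
  } else {
    bw <- encoder_bwd(model, cache, dE, want_params = TRUE,
                      want_input = FALSE)
    grads$stem <- bw$grads$stem
    grads$stages <- bw$grads$stages
  }
  # order gradient tree like the parameter tree
  grads <- grads[names(p)[names(p) %in% names(grads)]]
  list(grads = grads, loss = lg$loss)
}

sample_to_matrix <- function(sample, model_cfg, modality = NULL) {
  if (is.list(sample) && !is.data.frame(sample)) {
    if (!is.null(modality)) return(as_input_matrix(sample[[modality]]))
    return(as_input_matrix(fuse_early(sample)))
  }
  as_input_matrix(sample)
}

eval_deltas_net <- function(model, Xs, chunk = 16L) {
  n <- length(Xs)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    X <- do.call(rbind, Xs[i:j])
    fw <- net_fwd_batch(model, X, j - i + 1L)
    out[i:j] <- fw$probs[, 2]
    i <- j + 1L
  }
  out
}

#' Train a fusion classifier on a prepared dataset
#'
#' Trains the 3D residual classifier with Adam on softmax cross-entropy
#' (or, with `confidence_head = TRUE` in the config, on the adjusted-
#' probability loss with confidence penalty `-lambda * log(c)` and a budget
#' heuristic that nudges `lambda` so the mean confidence penalty tracks
#' `conf_budget`). `fusion = "late"` trains one unimodal model per modality
#' and returns an averaging ensemble.
#'
#' @param dataset List of samples; each sample is a named list of
#'   preprocessed modality volumes (3D arrays of the same shape).
#' @param labels Integer 0/1 vector, one per sample.
#' @param config A [model_config()].
#' @param input_shape Voxel triple of the preprocessed volumes.
#' @param epochs,batch_size,lr Optimisation schedule.
#' @param lambda_weight Initial confidence-penalty weight (confidence head
#'   only).
#' @param conf_budget Target mean value of `-log(c)` for the lambda budget
#'   heuristic.
#' @param val_dataset,val_labels Optional held-out set evaluated each epoch.
#' @param augment Optional [augment_config()]; when supplied, each training
#'   sample is re-augmented every epoch with a seed derived from the run
#'   seed.
#' @param seed Seed controlling batching order, augmentation and weight
#'   initialisation override (`NULL` keeps `config$seed`).
#' @param verbose Print one line per epoch.
#' @return The trained model (`conv3d_net` or `late_ensemble`) with a
#'   `history` data.frame attached (epoch, loss, val_auc, val_acc, lambda).
#' @export
train_classifier <- function(dataset, labels, config, input_shape,
                             epochs = 30L, batch_size = 8L, lr = 1e-3,
                             lambda_weight = 0.1, conf_budget = 0.3,
                             val_dataset = NULL, val_labels = NULL,
                             augment = NULL, seed = NULL, verbose = FALSE) {
  labels <- as.integer(labels)
  if (length(dataset) != length(labels)) stopf("dataset/labels length mismatch")
  seed <- as.integer(seed %||% config$seed)

  if (config$fusion == "late") {
    mods <- canonical_modalities(names(dataset[[1]]))
    models <- list()
    for (m in mods) {
      cfg_m <- config
      cfg_m$fusion <- "none"
      cfg_m$in_channels <- 1L
      sub <- lapply(dataset, function(s) s[m])
      sub_val <- if (!is.null(val_dataset))
        lapply(val_dataset, function(s) s[m]) else NULL
      models[[m]] <- train_classifier(sub, labels, cfg_m, input_shape,
                                      epochs = epochs, batch_size = batch_size,
                                      lr = lr, lambda_weight = lambda_weight,
                                      conf_budget = conf_budget,
                                      val_dataset = sub_val,
                                      val_labels = val_labels,
                                      augment = augment,
                                      seed = seed + match(m, mods),
                                      verbose = verbose)
      models[[m]]$modality <- m
    }
    ens <- structure(list(models = models, modalities = mods,
                          config = config), class = "late_ensemble")
    if (!is.null(val_dataset)) {
      dv <- predict_delta(ens, val_dataset)
      ens$history <- data.frame(epoch = epochs,
                                loss = NA_real_,
                                val_auc = auc_rank(val_labels, dv),
                                val_acc = mean(predict_class(dv) == val_labels),
                                lambda = NA_real_)
    }
    return(ens)
  }

  model <- build_model(config, input_shape)
  Xs <- lapply(dataset, sample_to_matrix, model_cfg = config)
  Xv <- if (!is.null(val_dataset))
    lapply(val_dataset, sample_to_matrix, model_cfg = config) else NULL

  state <- list(m = tree_map(function(x) 0 * x, model$params),
                v = tree_map(function(x) 0 * x, model$params))
  lam <- lambda_weight
  hist <- list()
  t_glob <- 0L
  n <- length(Xs)
  ep_seeds <- derive_seeds(seed, epochs)

  for (ep in seq_len(epochs)) {
    Xep <- Xs
    if (!is.null(augment)) {
      aug_seeds <- derive_seeds(ep_seeds[ep] + 1L, n)
      Xep <- lapply(seq_len(n), function(i) {
        av <- augment_volumes(dataset[[i]], aug_seeds[i], augment)
        sample_to_matrix(av, config)
      })
    }
    ord <- with_seed(ep_seeds[ep], sample.int(n))
    ep_loss <- 0; nb <- 0L
    i <- 1L
    while (i <= n) {
      take <- ord[i:min(i + batch_size - 1L, n)]
      X <- do.call(rbind, Xep[take])
      fw <- net_fwd_batch(model, X, length(take), keep_cache = TRUE)
      bg <- batch_grads(model, fw, labels[take], lam)
      t_glob <- t_glob + 1L
      upd <- adam_step(model$params[names(bg$grads)], bg$grads, state, lr,
                       t_glob)
      model$params[names(bg$grads)] <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bg$loss; nb <- nb + 1L
      i <- i + batch_size
    }
    # lambda budget heuristic: keep mean confidence penalty near the budget
    if (config$confidence_head) {
      take <- seq_len(min(n, 32L))
      fwc <- net_fwd_batch(model, do.call(rbind, Xs[take]), length(take))
      pen <- mean(-log(pmax(fwc$conf, 1e-6)))
      lam <- if (pen > conf_budget) lam / 1.05 else lam * 1.05
    }
    va <- NA_real_; vac <- NA_real_
    if (!is.null(Xv)) {
      dv <- eval_deltas_net(model, Xv)
      va <- auc_rank(val_labels, dv)
      vac <- mean(predict_class(dv) == val_labels)
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / nb, val_auc = va,
                             val_acc = vac, lambda = lam)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val_auc %s", ep,
                      ep_loss / nb, format(va, digits = 3)))
  }
  model$history <- do.call(rbind, hist)
  model
}

#' @export
forward.late_ensemble <- function(model, input, ...) {
  deltas <- vapply(model$models, function(m) {
    inp <- if (is.list(input) && !is.data.frame(input))
      input[[m$modality]] else input
    forward(m, inp)$delta
  }, numeric(1))
  d <- fuse_late(deltas)
  structure(list(delta = d, confidence = NULL, logits = NULL,
                 probs = c(1 - d, d), member_deltas = deltas),
            class = "model_output")
}
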