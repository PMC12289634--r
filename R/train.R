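#' Training
#'
#' Cross-entropy training of the segmentation model with the AdamW
#' optimizer (decoupled weight decay) and early stopping on validation
#' loss: training halts after `early_stop_patience` consecutive epochs
#' without a strict improvement, and the returned weights are those of the
#' best-validation epoch.
#'
#' @name train
NULL

#' Training configuration
#'
#' @param batch_size mini-batch size.
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param max_epochs maximum epochs.
#' @param early_stop_patience consecutive non-improving validation epochs
#'   tolerated before halting.
#' @param seed seed for weight init and batch shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 4L, learning_rate = 1e-4,
                         weight_decay = 1e-2, max_epochs = 50L,
                         early_stop_patience = 10L, seed = 1L) {
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (early_stop_patience < 1) stopf("early_stop_patience must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Pixel-averaged cross-entropy loss
#'
#' Softmax over class logits per pixel; the negative log-probability of
#' the true class, averaged over all pixels.
#'
#' @param logits H x W x K array.
#' @param target H x W integer mask with values in 0..K-1.
#' @return scalar loss >= 0.
#' @export
cross_entropy_loss <- function(logits, target) {
  ce_fwd(logits, target)$loss
}

ce_fwd <- function(logits, target) {
  H <- dim(logits)[1]; W <- dim(logits)[2]; K <- dim(logits)[3]
  if (!all(dim(target) == c(H, W)))
    stopf("logits and target spatial sizes differ")
  if (any(target < 0 | target >= K))
    stopf("target contains class indices outside 0..%d", K - 1)
  L <- matrix(logits, H * W, K)
  mx <- apply(L, 1, max)
  Ls <- L - mx
  E <- exp(Ls)
  Z <- rowSums(E)
  true_idx <- cbind(seq_len(H * W), as.vector(target) + 1L)
  loss <- mean(log(Z) - Ls[true_idx])
  P <- E / Z
  list(loss = loss, probs = P, true_idx = true_idx, H = H, W = W, K = K)
}

ce_bwd <- function(cache) {
  d <- cache$probs
  d[cache$true_idx] <- d[cache$true_idx] - 1
  array(d / (cache$H * cache$W), c(cache$H, cache$W, cache$K))
}

#' Early-stopping controller
#'
#' `early_stop_init()` creates the state; `early_stop_update()` folds in
#' one epoch's validation loss and reports whether to continue. A strict
#' decrease of the best seen loss counts as improvement; `patience`
#' consecutive non-improving epochs trigger a stop.
#'
#' @param patience tolerated non-improving epochs, >= 1.
#' @return state list with `best_loss`, `best_epoch`, `epoch`, `wait`,
#'   `decision` ("continue" or "stop").
#' @export
early_stop_init <- function(patience = 10L) {
  if (patience < 1) stopf("patience must be >= 1")
  list(patience = as.integer(patience), best_loss = Inf, best_epoch = 0L,
       epoch = 0L, wait = 0L, decision = "continue")
}

#' @rdname early_stop_init
#' @param state state from a previous call.
#' @param epoch_val_loss this epoch's validation loss.
#' @export
early_stop_update <- function(state, epoch_val_loss) {
  state$epoch <- state$epoch + 1L
  if (epoch_val_loss < state$best_loss) {
    state$best_loss <- epoch_val_loss
    state$best_epoch <- state$epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
  }
  state$decision <- if (state$wait >= state$patience) "stop" else "continue"
  state
}

# --- parameter-tree <-> flat-vector helpers for the optimizer --------------

tree_rebuild <- function(vec, template) {
  pos <- 0L
  rec <- function(t) {
    if (is.list(t)) return(lapply(t, rec))
    n <- length(t)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(t)
    out
  }
  rec(template)
}

adamw_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamw_step <- function(theta, g, st, lr, wd, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g * g
  mh <- st$m / (1 - beta1^st$t)
  vh <- st$v / (1 - beta2^st$t)
  theta <- theta - lr * (mh / (sqrt(vh) + eps) + wd * theta)
  list(theta = theta, st = st)
}

# forward + loss (+ gradient vector if backward = TRUE) for one sample
sample_loss <- function(config, params, s, backward = FALSE) {
  enc <- encoder_fwd(s$image, config, params)
  dec <- decoder_fwd(enc$levels, enc$padded_size, enc$input_size, config, params)
  ce <- ce_fwd(dec$logits, s$mask)
  if (!backward) return(list(loss = ce$loss))
  dlog <- ce_bwd(ce)
  db <- decoder_bwd(dlog, dec$cache, config, params)
  eb <- encoder_bwd(db$dlevels, enc, config, params)
  g <- unlist(list(stages = eb$grads$stages, decoder = db$grads),
              use.names = FALSE)
  list(loss = ce$loss, gvec = g)
}

#' Fit the segmentation model
#'
#' Mini-batch AdamW training with per-epoch validation, early stopping,
#' and checkpointing of the best-validation weights. Fully deterministic
#' for fixed data, configuration and seeds (single-threaded).
#'
#' @param model an initialized `larynx_model` (see [init_model()]); its
#'   weights are the starting point.
#' @param split a [split_dataset()] result, or a list with integer `train`
#'   and `val` index vectors into `samples`.
#' @param samples list of `larynx_sample` objects.
#' @param config a [train_config()].
#' @param verbose print one line per epoch?
#' @return list with `model` (best-validation weights) and `log`, a data
#'   frame (epoch, train_loss, val_loss) with attributes `best_epoch` and
#'   `stopped_epoch`.
#' @export
fit <- function(model, split, samples, config = train_config(),
                verbose = FALSE) {
  tr <- split$train; va <- split$val
  if (length(tr) == 0 || length(va) == 0)
    stopf("train and val splits must be non-empty")
  mc <- model$config
  theta <- unlist(model$params, use.names = FALSE)
  template <- model$params
  opt <- adamw_init(length(theta))
  es <- early_stop_init(config$early_stop_patience)
  best_theta <- theta
  log_tr <- numeric(0); log_va <- numeric(0)

  with_seed(config$seed, {
    params <- template
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        gacc <- NULL; bl <- 0
        for (idx in b) {
          r <- sample_loss(mc, params, samples[[idx]], backward = TRUE)
          if (!is.finite(r$loss))
            stopf("non-finite training loss at epoch %d", epoch)
          bl <- bl + r$loss
          gacc <- if (is.null(gacc)) r$gvec else gacc + r$gvec
        }
        ep_loss <- ep_loss + bl
        upd <- adamw_step(theta, gacc / length(b), opt,
                          config$learning_rate, config$weight_decay)
        theta <- upd$theta; opt <- upd$st
        params <- tree_rebuild(theta, template)
      }
      train_loss <- ep_loss / length(tr)
      val_loss <- mean(vapply(va, function(idx)
        sample_loss(mc, params, samples[[idx]])$loss, numeric(1)))
      if (!is.finite(val_loss)) stopf("non-finite validation loss at epoch %d", epoch)
      log_tr <- c(log_tr, train_loss); log_va <- c(log_va, val_loss)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        train_loss, val_loss))
      es <- early_stop_update(es, val_loss)
      if (es$best_epoch == epoch) best_theta <- theta
      if (es$decision == "stop") break
    }
  })

  out <- structure(list(config = mc, params = tree_rebuild(best_theta, template)),
                   class = "larynx_model")
  log <- data.frame(epoch = seq_along(log_tr), train_loss = log_tr,
                    val_loss = log_va)
  attr(log, "best_epoch") <- es$best_epoch
  attr(log, "stopped_epoch") <- es$epoch
  list(model = out, log = log)
}
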