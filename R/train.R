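#' Training configuration
#'
#' @param lr Learning rate of the AMSGrad optimizer.
#' @param beta1,beta2,eps AMSGrad moment decay rates and stabilizer.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to
#'   matrix-valued parameters; biases, gains and embeddings of length `D`
#'   are exempt.
#' @param max_epochs Passes over the training groups.
#' @param batch_size Epoch groups per optimization step.
#' @param include_fused_loss Add a unit-weight cross-entropy term on the
#'   fused logits to the weighted spatial/temporal composite. Disable to
#'   train the two streams alone through the composite term.
#' @param augment_shift Circular time-shift augmentation: at every
#'   presentation each training epoch is rolled by a random number of
#'   samples (with wrap-around, matching the epoching convention), which
#'   amounts to drawing the epoch grid phase anew and forces the encoder
#'   toward shift-invariant spectral features instead of waveform
#'   memorization. Evaluation always sees unshifted epochs.
#' @param val_fraction Fraction of training groups held out to select the
#'   best checkpoint by validation loss (0 disables; the final parameters
#'   are then those after the last epoch).
#' @param seed Seed controlling initialization order, batch shuffling and
#'   dropout.
#' @param deterministic Keep every stochastic choice tied to `seed` so a rerun
#'   is bit-identical.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0.01, max_epochs = 20,
                         batch_size = 16, include_fused_loss = TRUE,
                         augment_shift = TRUE, val_fraction = 0, seed = 1L,
                         deterministic = TRUE) {
  if (lr <= 0) stop_stteeg("lr must be positive", "stteeg_config_error")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 include_fused_loss = include_fused_loss,
                 augment_shift = augment_shift,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 deterministic = deterministic),
            class = "train_config")
}

#' Composite classification loss
#'
#' The weighted sum `alpha * CE(y_spatial) + (1 - alpha) * CE(y_temporal)`
#' of the per-stream cross entropies; when `include_fused` is `TRUE` the
#' cross entropy of the fused logits is added with unit weight, since the
#' fused output is the one ultimately reported.
#'
#' @param outs An `stt_outputs` object from [stt_forward()].
#' @param labels Emotion labels (`-1`, `0`, `+1`) or class indices.
#' @param alpha Spatial-stream weight in `[0, 1]`.
#' @param include_fused Add the fused-head term.
#' @param n_classes Class count used to code raw labels.
#' @return The scalar loss, with per-term values as attribute `"parts"`.
#' @export
composite_loss <- function(outs, labels, alpha = 0.3, include_fused = TRUE,
                           n_classes = ncol(outs$y)) {
  if (alpha < 0 || alpha > 1) {
    stop_stteeg("alpha must lie in [0, 1]", "stteeg_config_error")
  }
  idx <- if (all(labels %in% seq_len(n_classes)) && !any(labels < 0)) {
    as.integer(labels)
  } else {
    labels_to_idx(labels, n_classes)
  }
  ce_s <- cross_entropy(outs$y_spatial, idx)$loss
  ce_t <- cross_entropy(outs$y_temporal, idx)$loss
  ce_f <- cross_entropy(outs$y, idx)$loss
  total <- alpha * ce_s + (1 - alpha) * ce_t + if (include_fused) ce_f else 0
  structure(total, parts = c(spatial = ce_s, temporal = ce_t, fused = ce_f))
}

# circular time-shift of each epoch in a group by an independent uniform
# number of samples (draws from the caller's RNG stream)
roll_epochs <- function(arr, cfg) {
  sh <- sample.int(cfg$W, cfg$G, replace = TRUE) - 1L
  for (g in seq_len(cfg$G)) {
    if (sh[g] > 0L) {
      arr[, , g] <- arr[c((sh[g] + 1L):cfg$W, 1L:sh[g]), , g]
    }
  }
  arr
}

# Same augmentation applied directly to a spatial-order patch matrix.
# Tokens are column-major flattened H x W slabs, so a time shift of an
# epoch permutes the W electrode-blocks of its token columns; one gather
# per epoch replaces a full re-slabbing.
roll_patches <- function(P, cfg) {
  sh <- sample.int(cfg$W, cfg$G, replace = TRUE) - 1L
  base <- seq_len(cfg$H)
  for (g in seq_len(cfg$G)) {
    if (sh[g] > 0L) {
      block <- c((sh[g] + 1L):cfg$W, 1L:sh[g])   # source sample per slot
      cols <- rep((block - 1L) * cfg$H, each = cfg$H) + base
      rows <- (g - 1L) * cfg$n_slabs + seq_len(cfg$n_slabs)
      P[rows, ] <- P[rows, cols, drop = FALSE]
    }
  }
  P
}

# full forward + backward for one batch; returns loss and gradient tree
stt_loss_grad <- function(params, cfg, Pbig, B, label_idx, alpha,
                          include_fused = TRUE, training = TRUE) {
  perm <- batch_rowperm(cfg, B)
  fs <- stream_fwd(params$spatial, Pbig, B, cfg, training = training,
                   keep_cache = TRUE)
  ft <- stream_fwd(params$temporal, Pbig, B, cfg, rowperm = perm,
                   training = training, keep_cache = TRUE)
  fu <- fusion_fwd(params$fusion, fs$logits, ft$logits, keep_cache = TRUE)
  ce_s <- cross_entropy(fs$logits, label_idx)
  ce_t <- cross_entropy(ft$logits, label_idx)
  ce_f <- cross_entropy(fu$y, label_idx)
  loss <- alpha * ce_s$loss + (1 - alpha) * ce_t$loss +
    if (include_fused) ce_f$loss else 0

  if (include_fused) {
    fb <- fusion_bwd(params$fusion, fu$cache, ce_f$dlogits, cfg$n_classes)
    dys <- alpha * ce_s$dlogits + fb$dys
    dyt <- (1 - alpha) * ce_t$dlogits + fb$dyt
    gf <- fb$grads
  } else {
    dys <- alpha * ce_s$dlogits
    dyt <- (1 - alpha) * ce_t$dlogits
    gf <- zeros_like(params$fusion)
  }
  grads <- list(
    spatial = stream_bwd(params$spatial, fs$cache, dys, cfg),
    temporal = stream_bwd(params$temporal, ft$cache, dyt, cfg),
    fusion = gf)
  list(loss = loss, grads = grads,
       parts = c(spatial = ce_s$loss, temporal = ce_t$loss, fused = ce_f$loss))
}

# --- AMSGrad ----------------------------------------------------------------

amsgrad_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params),
       vhat = zeros_like(params), t = 0L)
}

amsgrad_step <- function(params, grads, state, tcfg) {
  state$t <- state$t + 1L
  b1 <- tcfg$beta1; b2 <- tcfg$beta2
  state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
  state$vhat <- tree_map(pmax, state$vhat, state$v)
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  wd <- tcfg$weight_decay %||% 0
  params <- tree_map(function(p, m, vh) {
    # decoupled decay on matrices (weights, position embedding); 1-d
    # tensors (biases, norm gains, class token) are exempt
    decay <- if (is.matrix(p) && wd > 0) tcfg$lr * wd * p else 0
    p - tcfg$lr * (m / bc1) / (sqrt(vh / bc2) + tcfg$eps) - decay
  }, params, state$m, state$vhat)
  list(params = params, state = state)
}

# --- training loop ----------------------------------------------------------

#' Train a dual-stream transformer on epoch groups
#'
#' Minimizes the composite loss with AMSGrad over shuffled mini-batches of
#' same-label epoch groups. Patch matrices are computed once per group and
#' reused across epochs.
#'
#' @param groups Groups tibble from [group_epochs()] (columns `label`,
#'   `epochs`).
#' @param cfg An [stt_config()].
#' @param tcfg A [train_config()].
#' @param verbose Print per-epoch loss.
#' @return The trained `stt_model`, with a `history` element (per-epoch mean
#'   training loss and, if used, validation loss).
#' @export
train_stt <- function(groups, cfg = stt_config(), tcfg = train_config(),
                      verbose = FALSE) {
  label_idx <- labels_to_idx(groups$label, cfg$n_classes)
  patches <- lapply(groups$epochs, group_patches, cfg = cfg)
  n <- length(patches)
  if (n < 1L) stop_stteeg("No training groups", "stteeg_input_error")

  # standardize inputs once: raw microvolt patches are rescaled by the
  # pooled training standard deviation so activations start near unit scale
  patch_scale <- sd(unlist(patches[seq_len(min(8L, n))], use.names = FALSE))
  if (!is.finite(patch_scale) || patch_scale <= 0) patch_scale <- 1
  patches <- lapply(patches, `/`, patch_scale)

  model <- stt_model(cfg)
  model$patch_scale <- patch_scale
  params <- model$params
  state <- amsgrad_init(params)

  withr::with_seed(tcfg$seed, {
    val_idx <- integer(0)
    if (tcfg$val_fraction > 0) {
      val_idx <- sample.int(n, max(1L, round(tcfg$val_fraction * n)))
    }
    train_idx <- setdiff(seq_len(n), val_idx)
    best <- list(loss = Inf, params = NULL)
    hist <- list()
    for (ep in seq_len(tcfg$max_epochs)) {
      ord <- sample(train_idx)
      losses <- c()
      for (b0 in seq(1L, length(ord), by = tcfg$batch_size)) {
        ids <- ord[b0:min(b0 + tcfg$batch_size - 1L, length(ord))]
        Pbig <- if (isTRUE(tcfg$augment_shift)) {
          stack_patches(lapply(patches[ids], roll_patches, cfg = cfg))
        } else {
          stack_patches(patches[ids])
        }
        lg <- stt_loss_grad(params, cfg, Pbig, length(ids), label_idx[ids],
                            alpha = cfg$alpha,
                            include_fused = tcfg$include_fused_loss)
        if (!is.finite(lg$loss)) {
          stop_stteeg(sprintf("Training loss diverged at epoch %d", ep),
                      "stteeg_training_error")
        }
        st <- amsgrad_step(params, lg$grads, state, tcfg)
        params <- st$params; state <- st$state
        losses <- c(losses, lg$loss)
      }
      val_loss <- NA_real_
      if (length(val_idx)) {
        Pv <- stack_patches(patches[val_idx])
        lv <- stt_loss_grad(params, cfg, Pv, length(val_idx),
                            label_idx[val_idx], alpha = cfg$alpha,
                            include_fused = tcfg$include_fused_loss,
                            training = FALSE)
        val_loss <- lv$loss
        if (val_loss < best$loss) best <- list(loss = val_loss, params = params)
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                   val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f%s", ep, mean(losses),
                        if (is.na(val_loss)) "" else sprintf("  val %.4f", val_loss)))
      }
    }
    if (length(val_idx) && !is.null(best$params)) params <- best$params
    model$params <- params
    model$history <- purrr::list_rbind(hist)
  })
  model
}
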