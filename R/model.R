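#' Architecture configuration for the dual-stream transformer
#'
#' All hyperparameters of the spatial-temporal transformer. An epoch group of
#' `G` 4-s epochs on `n_channels` electrodes is cut into slabs of `H`
#' consecutive electrodes by `W` samples (`C` feature channels per slab, 1
#' for raw voltage); each slab is one token. The same tokens feed two
#' weight-independent encoders: the spatial stream orders them slab-by-slab
#' within each epoch, the temporal stream epoch-by-epoch within each slab.
#'
#' @param H Electrodes per slab (patch height).
#' @param W Samples per slab (patch width); must equal the epoch length.
#' @param C Feature channels per slab.
#' @param D Token embedding length; divisible by `n_heads`.
#' @param L Encoder layers per stream.
#' @param n_heads Attention heads per layer.
#' @param G Epochs per group.
#' @param n_classes 2 (positive/negative) or 3 (+neutral).
#' @param alpha Composite-loss weight on the spatial stream, in `[0, 1]`.
#' @param mlp_mult Hidden width of the encoder MLP as a multiple of `D`.
#' @param dropout Dropout fraction applied after the embedding, the attention
#'   projection and inside the MLP during training.
#' @param n_channels Electrodes in the montage.
#' @param embed_init `"spectral"` (default) initializes the patch-embedding
#'   columns as quadrature pairs of random-frequency sinusoid filters with
#'   random electrode weighting, so training starts from a bank of
#'   band-selective features; `"normal"` uses plain truncated-normal
#'   columns. All other parameters are truncated-normal either way.
#' @param seed Seed for parameter initialization.
#' @return An `stt_config` list, with derived fields `n_slabs`, `n_tokens`
#'   and `patch_dim`.
#' @export
stt_config <- function(H = 5, W = 512, C = 1, D = 64, L = 8, n_heads = 4,
                       G = 8, n_classes = 2, alpha = 0.3, mlp_mult = 4,
                       dropout = 0.1, n_channels = 32,
                       embed_init = c("spectral", "normal"), seed = 1L) {
  embed_init <- match.arg(embed_init)
  if (D %% n_heads != 0) {
    stop_stteeg("D must be divisible by n_heads", "stteeg_config_error")
  }
  if (alpha < 0 || alpha > 1) {
    stop_stteeg("alpha must lie in [0, 1]", "stteeg_config_error")
  }
  if (H < 1 || W < 1 || C < 1 || H * W * C <= 0) {
    stop_stteeg("Patch dimensions must be positive", "stteeg_config_error")
  }
  if (!n_classes %in% c(2L, 3L)) {
    stop_stteeg("n_classes must be 2 or 3", "stteeg_config_error")
  }
  n_slabs <- as.integer(ceiling(n_channels / H))
  structure(list(H = as.integer(H), W = as.integer(W), C = as.integer(C),
                 D = as.integer(D), L = as.integer(L),
                 n_heads = as.integer(n_heads), G = as.integer(G),
                 n_classes = as.integer(n_classes), alpha = alpha,
                 mlp_mult = as.integer(mlp_mult), dropout = dropout,
                 n_channels = as.integer(n_channels),
                 embed_init = embed_init, seed = as.integer(seed),
                 n_slabs = n_slabs, n_tokens = n_slabs * as.integer(G),
                 patch_dim = as.integer(H * W * C)),
            class = "stt_config")
}

# truncated normal (+-2 sigma) initializer
trunc_normal <- function(n, sigma = 0.02) {
  u <- runif(n, pnorm(-2), pnorm(2))
  sigma * stats::qnorm(u)
}

tn_mat <- function(nr, nc, sigma = 0.02) matrix(trunc_normal(nr * nc, sigma), nr, nc)

# Glorot-scaled truncated normal for weight matrices. A fixed sigma of 0.02
# starves signal propagation at small D (an order of magnitude below the
# Glorot scale for D = 32), which leaves training stuck at the symmetric
# saddle for hundreds of steps; scaling by fan-in/fan-out removes that.
xv_mat <- function(nr, nc) tn_mat(nr, nc, sqrt(2 / (nr + nc)))

# Spectral initialization of the patch-embedding map: columns come in
# sine/cosine quadrature pairs at random frequencies (random electrode
# weighting within the slab), so the first layer starts as a bank of
# band-selective filters whose phase-invariant combinations the encoder
# learns, instead of waiting for such filters to emerge from noise. Each
# column is scaled to the same L2 norm as a truncated-normal column.
spectral_embed_init <- function(cfg) {
  W <- matrix(0, cfg$patch_dim, cfg$D)
  t_idx <- (seq_len(cfg$W) - 1L) / cfg$W          # window fraction
  target_norm <- 0.02 * sqrt(cfg$patch_dim)
  j <- 1L
  while (j <= cfg$D) {
    cycles <- runif(1, 2, cfg$W / 3)              # per-window frequency
    gains <- rnorm(cfg$H * cfg$C)                 # electrode mix in the slab
    for (phase in c(0, pi / 2)) {
      if (j > cfg$D) break
      wave <- cos(2 * pi * cycles * t_idx + phase)
      col <- as.vector(outer(gains, wave))        # electrode-major layout
      W[, j] <- col / sqrt(sum(col^2)) * target_norm
      j <- j + 1L
    }
  }
  W
}

init_stream <- function(cfg) {
  D <- cfg$D; T <- cfg$n_tokens + 1L
  layers <- lapply(seq_len(cfg$L), function(l) {
    list(ln1_g = rep(1, D), ln1_b = rep(0, D),
         Wq = xv_mat(D, D), bq = rep(0, D),
         Wk = xv_mat(D, D), bk = rep(0, D),
         Wv = xv_mat(D, D), bv = rep(0, D),
         Wo = xv_mat(D, D), bo = rep(0, D),
         ln2_g = rep(1, D), ln2_b = rep(0, D),
         W1 = xv_mat(D, D * cfg$mlp_mult), b1 = rep(0, D * cfg$mlp_mult),
         W2 = xv_mat(D * cfg$mlp_mult, D), b2 = rep(0, D))
  })
  embed_W <- if (identical(cfg$embed_init, "normal")) {
    xv_mat(cfg$patch_dim, D)
  } else {
    spectral_embed_init(cfg)
  }
  list(embed_W = embed_W, embed_b = rep(0, D),
       cls = trunc_normal(D), pos = tn_mat(T, D),
       layers = layers,
       lnf_g = rep(1, D), lnf_b = rep(0, D),
       head_W = xv_mat(D, cfg$n_classes), head_b = rep(0, cfg$n_classes))
}

#' Build an untrained dual-stream transformer
#'
#' Initializes two structurally identical but parameter-independent encoder
#' streams (truncated-normal weights, sigma 0.02) plus the fusion head that
#' layer-normalizes the concatenated stream logits and maps them to class
#' scores.
#'
#' @param cfg An [stt_config()].
#' @return An `stt_model` with elements `config` and `params`.
#' @export
stt_model <- function(cfg = stt_config()) {
  stopifnot(inherits(cfg, "stt_config"))
  params <- withr::with_seed(cfg$seed, list(
    spatial = init_stream(cfg),
    temporal = init_stream(cfg),
    fusion = list(ln_g = rep(1, 2L * cfg$n_classes),
                  ln_b = rep(0, 2L * cfg$n_classes),
                  W = xv_mat(2L * cfg$n_classes, cfg$n_classes),
                  b = rep(0, cfg$n_classes))))
  structure(list(config = cfg, params = params, patch_scale = 1),
            class = "stt_model")
}

#' Number of trainable parameters
#'
#' Deterministic in the configuration alone; independent of batch size or
#' corpus size.
#'
#' @param model An [stt_model()] or an [stt_config()].
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  if (inherits(model, "stt_config")) model <- stt_model(model)
  as.integer(tree_sum(model$params, length))
}

#' @export
print.stt_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<stt_model> dual-stream transformer: D=%d, L=%d, heads=%d, %d tokens/group (+1 class), %d classes, %s parameters\n",
    cfg$D, cfg$L, cfg$n_heads, cfg$n_tokens, cfg$n_classes,
    format(n_params(x), big.mark = ",")))
  invisible(x)
}

# --- tokenization -----------------------------------------------------------

# slab patches of one group in spatial order: for each epoch, slabs of H
# consecutive electrodes (last slab zero-padded), each flattened to H*W*C.
group_patches <- function(group_arr, cfg) {
  d <- dim(group_arr)
  if (d[1] != cfg$W) {
    stop_stteeg(sprintf("Epoch length %d does not match patch width W=%d",
                        d[1], cfg$W), "stteeg_shape_error")
  }
  if (d[3] != cfg$G) {
    stop_stteeg(sprintf("Group has %d epochs, config expects G=%d",
                        d[3], cfg$G), "stteeg_shape_error")
  }
  out <- matrix(0, cfg$n_slabs * cfg$G, cfg$patch_dim)
  row <- 0L
  for (g in seq_len(cfg$G)) {
    for (s in seq_len(cfg$n_slabs)) {
      ch <- ((s - 1L) * cfg$H + 1L):min(s * cfg$H, d[2])
      slab <- matrix(0, cfg$H, cfg$W)           # electrodes x samples
      slab[seq_along(ch), ] <- t(matrix(group_arr[, ch, g], ncol = length(ch)))
      row <- row + 1L
      out[row, ] <- as.vector(slab)
    }
  }
  out
}

# temporal-order row permutation: token (slab s, epoch g) moves from spatial
# row (g-1)*S + s to temporal row (s-1)*G + g
temporal_perm <- function(cfg) {
  S <- cfg$n_slabs; G <- cfg$G
  as.vector(vapply(seq_len(S), function(s) ((seq_len(G) - 1L) * S) + s,
                   integer(G)))
}

#' Tokenize an epoch group for the spatial stream
#'
#' Cuts each of the `G` epochs into slabs of `H` consecutive electrodes by
#' `W` samples (the final slab zero-padded when the montage size is not a
#' multiple of `H`) and flattens each slab to one token. Tokens are ordered
#' slab-by-slab within each epoch: the electrode axis varies fastest.
#'
#' @param group A `[W x channels x G]` array (one row of the `epochs`
#'   list-column from [group_epochs()]) .
#' @param cfg An [stt_config()].
#' @return `[n_tokens x (H*W*C)]` patch matrix.
#' @export
tokenize_spatial <- function(group, cfg) group_patches(group, cfg)

#' Tokenize an epoch group for the temporal stream
#'
#' Same slabs as [tokenize_spatial()], ordered epoch-by-epoch within each
#' slab, so token order encodes temporal succession within the group.
#'
#' @inheritParams tokenize_spatial
#' @return `[n_tokens x (H*W*C)]` patch matrix.
#' @export
tokenize_temporal <- function(group, cfg) {
  group_patches(group, cfg)[temporal_perm(cfg), , drop = FALSE]
}

#' Embed patch tokens
#'
#' Affine map of each flattened patch to a `D`-vector, with the learnable
#' class embedding prepended and the position embedding added.
#'
#' @param patches `[n_tokens x patch_dim]` matrix from the tokenizers.
#' @param model An [stt_model()].
#' @param stream `"spatial"` or `"temporal"` (selects the stream parameters).
#' @return `[(n_tokens + 1) x D]` token-sequence matrix, class token first.
#' @export
embed <- function(patches, model, stream = c("spatial", "temporal")) {
  stream <- match.arg(stream)
  p <- model$params[[stream]]
  if (ncol(patches) != model$config$patch_dim) {
    stop_stteeg("Patch width does not match H*W*C", "stteeg_shape_error")
  }
  e <- linear_fwd(patches, p$embed_W, p$embed_b)
  rbind(p$cls, e) + p$pos[seq_len(nrow(patches) + 1L), , drop = FALSE]
}

# --- encoder ----------------------------------------------------------------

# One stream's pre-norm encoder over a batch of token sequences stacked as a
# (B*T) x D matrix. keep_cache retains intermediates for the backward pass;
# training enables dropout (caller controls RNG).
encoder_stack_fwd <- function(p, x, B, T, cfg, training = FALSE,
                              keep_cache = FALSE, keep_attention = FALSE) {
  caches <- vector("list", cfg$L)
  attn <- if (keep_attention) vector("list", cfg$L) else NULL
  for (l in seq_len(cfg$L)) {
    lp <- p$layers[[l]]
    ln1 <- layernorm_fwd(x, lp$ln1_g, lp$ln1_b)
    q <- linear_fwd(ln1$y, lp$Wq, lp$bq)
    k <- linear_fwd(ln1$y, lp$Wk, lp$bk)
    v <- linear_fwd(ln1$y, lp$Wv, lp$bv)
    att <- attention_fwd(q, k, v, B, T, cfg$n_heads)
    proj <- linear_fwd(att$out, lp$Wo, lp$bo)
    do1 <- dropout_fwd(proj, if (training) cfg$dropout else 0)
    x_mid <- x + do1$y
    ln2 <- layernorm_fwd(x_mid, lp$ln2_g, lp$ln2_b)
    h1 <- linear_fwd(ln2$y, lp$W1, lp$b1)
    act <- gelu_fwd(h1)
    h2 <- linear_fwd(act$y, lp$W2, lp$b2)
    do2 <- dropout_fwd(h2, if (training) cfg$dropout else 0)
    x_out <- x_mid + do2$y
    if (!all(is.finite(x_out))) {
      stop_stteeg(sprintf("Non-finite activations in encoder layer %d", l),
                  "stteeg_numeric_error")
    }
    if (keep_cache) {
      caches[[l]] <- list(x_in = x, ln1 = ln1, q = q, k = k, v = v,
                          att = att, x_mid = x_mid, ln2 = ln2, h1 = h1,
                          act = act$y, phi = act$phi,
                          mask1 = do1$mask, mask2 = do2$mask)
    }
    if (keep_attention) attn[[l]] <- att$A
    x <- x_out
  }
  list(x = x, caches = caches, attention = attn)
}

encoder_stack_bwd <- function(p, caches, dx, B, T, cfg) {
  gl <- vector("list", cfg$L)
  for (l in rev(seq_len(cfg$L))) {
    lp <- p$layers[[l]]; cc <- caches[[l]]
    # MLP branch
    dh2 <- dropout_bwd(cc$mask2, dx)
    l2 <- linear_bwd(cc$act, lp$W2, dh2)
    dh1 <- gelu_bwd(cc$h1, cc$phi, l2$dx)
    l1 <- linear_bwd(cc$ln2$y, lp$W1, dh1)
    ln2b <- layernorm_bwd(cc$ln2, lp$ln2_g, l1$dx)
    dx_mid <- dx + ln2b$dx
    # attention branch
    dproj <- dropout_bwd(cc$mask1, dx_mid)
    lo <- linear_bwd(cc$att$out, lp$Wo, dproj)
    ab <- attention_bwd(cc$att, cc$q, cc$k, cc$v, lo$dx, B, T, cfg$n_heads)
    lq <- linear_bwd(cc$ln1$y, lp$Wq, ab$dq)
    lk <- linear_bwd(cc$ln1$y, lp$Wk, ab$dk)
    lv <- linear_bwd(cc$ln1$y, lp$Wv, ab$dv)
    ln1b <- layernorm_bwd(cc$ln1, lp$ln1_g, lq$dx + lk$dx + lv$dx)
    dx <- dx_mid + ln1b$dx
    gl[[l]] <- list(ln1_g = ln1b$dg, ln1_b = ln1b$db,
                    Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                    Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db,
                    ln2_g = ln2b$dg, ln2_b = ln2b$db,
                    W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db)
  }
  list(dx = dx, layers = gl)
}

#' Run one encoder stream over a token sequence
#'
#' Applies the stream's `L` pre-norm blocks (`x <- x + MSA(LN(x))`;
#' `x <- x + MLP(LN(x))`) to a single token sequence. With `L = 0` this is
#' the identity. Use `return_attention = TRUE` to inspect the softmax
#' attention maps.
#'
#' @param seq `[(n_tokens + 1) x D]` matrix from [embed()].
#' @param model An [stt_model()].
#' @param stream `"spatial"` or `"temporal"`.
#' @param return_attention Return the per-layer `[T x T x heads]` attention
#'   arrays as attribute `"attention"`.
#' @return The transformed sequence, same shape.
#' @export
encoder_forward <- function(seq, model, stream = c("spatial", "temporal"),
                            return_attention = FALSE) {
  stream <- match.arg(stream)
  res <- encoder_stack_fwd(model$params[[stream]], seq, B = 1L,
                           T = nrow(seq), cfg = model$config,
                           keep_attention = return_attention)
  out <- res$x
  if (return_attention) attr(out, "attention") <- res$attention
  out
}

# --- full forward / backward ------------------------------------------------

# stack per-group spatial patch matrices into one tall matrix
stack_patches <- function(patch_list) do.call(rbind, patch_list)

# forward of one stream for B groups; Pbig holds spatial-order patches,
# rowperm (NULL for the spatial stream) reorders embedded tokens per group.
stream_fwd <- function(p, Pbig, B, cfg, rowperm = NULL, training = FALSE,
                       keep_cache = FALSE) {
  T <- cfg$n_tokens + 1L
  e <- linear_fwd(Pbig, p$embed_W, p$embed_b)
  if (!is.null(rowperm)) e <- e[rowperm, , drop = FALSE]
  x0 <- matrix(0, B * T, cfg$D)
  cls_rows <- (seq_len(B) - 1L) * T + 1L
  x0[cls_rows, ] <- matrix(p$cls, B, cfg$D, byrow = TRUE)
  x0[-cls_rows, ] <- e
  x0 <- x0 + p$pos[rep(seq_len(T), B), , drop = FALSE]
  do0 <- dropout_fwd(x0, if (training) cfg$dropout else 0)
  enc <- encoder_stack_fwd(p, do0$y, B, T, cfg, training = training,
                           keep_cache = keep_cache)
  xc <- enc$x[cls_rows, , drop = FALSE]
  lnf <- layernorm_fwd(xc, p$lnf_g, p$lnf_b)
  logits <- linear_fwd(lnf$y, p$head_W, p$head_b)
  cache <- if (keep_cache) {
    list(Pbig = Pbig, rowperm = rowperm, enc = enc, lnf = lnf, xc = xc,
         cls_rows = cls_rows, mask0 = do0$mask, B = B, T = T)
  }
  list(logits = logits, cache = cache)
}

stream_bwd <- function(p, cache, dlogits, cfg) {
  B <- cache$B; T <- cache$T
  lh <- linear_bwd(cache$lnf$y, p$head_W, dlogits)
  lnfb <- layernorm_bwd(cache$lnf, p$lnf_g, lh$dx)
  dx <- matrix(0, B * T, cfg$D)
  dx[cache$cls_rows, ] <- lnfb$dx
  encb <- encoder_stack_bwd(p, cache$enc$caches, dx, B, T, cfg)
  dx0 <- dropout_bwd(cache$mask0, encb$dx)
  dpos <- rowsum(dx0, rep(seq_len(T), B))
  dcls <- colSums(dx0[cache$cls_rows, , drop = FALSE])
  de <- dx0[-cache$cls_rows, , drop = FALSE]
  if (!is.null(cache$rowperm)) {
    inv <- integer(length(cache$rowperm))
    inv[cache$rowperm] <- seq_along(cache$rowperm)
    de <- de[inv, , drop = FALSE]
  }
  le <- linear_bwd(cache$Pbig, p$embed_W, de, need_dx = FALSE)
  list(embed_W = le$dW, embed_b = le$db, cls = dcls, pos = dpos,
       layers = encb$layers, lnf_g = lnfb$dg, lnf_b = lnfb$db,
       head_W = lh$dW, head_b = lh$db)
}

fusion_fwd <- function(fp, ys, yt, keep_cache = FALSE) {
  z <- cbind(ys, yt)
  ln <- layernorm_fwd(z, fp$ln_g, fp$ln_b)
  y <- linear_fwd(ln$y, fp$W, fp$b)
  list(y = y, cache = if (keep_cache) ln)
}

fusion_bwd <- function(fp, cache, dy, n_classes) {
  lw <- linear_bwd(cache$y, fp$W, dy)
  lnb <- layernorm_bwd(cache, fp$ln_g, lw$dx)
  list(grads = list(ln_g = lnb$dg, ln_b = lnb$db, W = lw$dW, b = lw$db),
       dys = lnb$dx[, seq_len(n_classes), drop = FALSE],
       dyt = lnb$dx[, n_classes + seq_len(n_classes), drop = FALSE])
}

#' Forward pass of the dual-stream transformer
#'
#' Runs a batch of epoch groups through both encoder streams and the fusion
#' head. The two streams consume the same slab tokens in different orders and
#' share no parameters; the fused logits are an affine map of the
#' layer-normalized concatenation of the two stream logit vectors. Any of the
#' three logit sets can drive a classification on its own.
#'
#' @param model An [stt_model()].
#' @param groups Groups tibble from [group_epochs()], or a list of
#'   `[W x channels x G]` arrays, or a single such array.
#' @return List of class `stt_outputs`: `y_spatial`, `y_temporal`, `y`, each
#'   `[batch x n_classes]`.
#' @export
stt_forward <- function(model, groups) {
  arrs <- as_group_arrays(groups)
  cfg <- model$config
  Pbig <- stack_patches(lapply(arrs, group_patches, cfg = cfg)) /
    (model$patch_scale %||% 1)
  B <- length(arrs)
  perm <- batch_rowperm(cfg, B)
  fs <- stream_fwd(model$params$spatial, Pbig, B, cfg)
  ft <- stream_fwd(model$params$temporal, Pbig, B, cfg, rowperm = perm)
  fu <- fusion_fwd(model$params$fusion, fs$logits, ft$logits)
  structure(list(y_spatial = fs$logits, y_temporal = ft$logits, y = fu$y),
            class = "stt_outputs")
}

as_group_arrays <- function(groups) {
  if (is.array(groups) && length(dim(groups)) == 3L) return(list(groups))
  if (is.data.frame(groups)) return(groups$epochs)
  stopifnot(is.list(groups))
  groups
}

batch_rowperm <- function(cfg, B) {
  perm1 <- temporal_perm(cfg)
  n <- cfg$n_tokens
  as.vector(vapply(seq_len(B), function(b) perm1 + (b - 1L) * n,
                   integer(n)))
}

#' Predict emotion classes for epoch groups
#'
#' @param object An [stt_model()] (trained or not).
#' @param groups Groups tibble or list of group arrays (see [stt_forward()]).
#' @param head Which logit set drives the prediction: the fused output
#'   (default), or one stream alone.
#' @param ... Unused.
#' @return Integer vector of predicted class indices (`1..n_classes`,
#'   ordered as the model's class coding; see [class_levels()]).
#' @export
predict.stt_model <- function(object, groups, head = c("y", "y_spatial", "y_temporal"),
                              ...) {
  head <- match.arg(head)
  outs <- stt_forward(object, groups)
  max.col(outs[[head]], ties.method = "first")
}

#' Class index coding for a given task
#'
#' Maps emotion labels to the model's class indices: binary tasks use
#' `(-1, +1)`, ternary tasks `(-1, 0, +1)`, in that order.
#'
#' @param n_classes 2 or 3.
#' @return Integer vector of labels, position = class index.
#' @export
class_levels <- function(n_classes) {
  if (n_classes == 2L) c(-1L, 1L) else c(-1L, 0L, 1L)
}

labels_to_idx <- function(labels, n_classes) {
  idx <- match(labels, class_levels(n_classes))
  if (anyNA(idx)) {
    stop_stteeg("Label outside the model's class set", "stteeg_input_error")
  }
  idx
}

# --- checkpoints ------------------------------------------------------------

#' Save / load a model as a JSON checkpoint
#'
#' One self-describing text file holding the full configuration and every
#' named parameter tensor (numbers serialized in full precision; round-trip
#' is exact to double-precision decimal printing).
#'
#' @param model An [stt_model()].
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `stt_model` (load).
#' @export
save_model <- function(model, path) {
  pack <- function(x) {
    if (is.list(x)) lapply(x, pack)
    else if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
    else list(dim = length(x), data = as.vector(x))
  }
  obj <- list(config = unclass(model$config),
              patch_scale = model$patch_scale %||% 1,
              params = pack(model$params))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  unpack <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
      if (length(x$dim) == 2L) matrix(x$data, x$dim[1], x$dim[2])
      else as.numeric(x$data)
    } else lapply(x, unpack)
  }
  cfgl <- lapply(obj$config, function(v) if (length(v) == 1L) v[[1]] else unlist(v))
  cfg <- do.call(stt_config, cfgl[setdiff(names(cfgl),
                                          c("n_slabs", "n_tokens", "patch_dim"))])
  structure(list(config = cfg, params = unpack(obj$params),
                 patch_scale = as.numeric(obj$patch_scale)[1] %||% 1),
            class = "stt_model")
}
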