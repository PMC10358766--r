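# Dense-layer primitives with hand-derived backward passes. Everything
# operates on plain matrices with examples (or tokens) along rows, so the
# encoder can batch a whole set of epoch groups as one tall matrix and let
# BLAS do the work. Each *_fwd returns a cache consumed by its *_bwd.

LN_EPS <- 1e-5

# --- affine -----------------------------------------------------------------

linear_fwd <- function(x, W, b) {
  y <- x %*% W
  sweep(y, 2, b, `+`)
}

# returns list(dx, dW, db); set need_dx = FALSE at graph leaves
linear_bwd <- function(x, W, dy, need_dx = TRUE) {
  list(dx = if (need_dx) tcrossprod(dy, W) else NULL,
       dW = crossprod(x, dy),
       db = colSums(dy))
}

# --- layer normalization (per row, learnable gain/offset) -------------------
# compiled kernels carry the hot path; the *_ref functions are the plain-R
# reference implementations the tests cross-check against

layernorm_fwd <- function(x, g, b) cpp_layernorm_fwd(x, g, b)

layernorm_bwd <- function(cache, g, dy) {
  cpp_layernorm_bwd(cache$xhat, cache$invstd, g, dy)
}

layernorm_fwd_ref <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * invstd
  y <- sweep(xhat * rep(g, each = nrow(x)), 2, b, `+`)
  list(y = y, xhat = xhat, invstd = invstd)
}

layernorm_bwd_ref <- function(cache, g, dy) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$invstd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# --- GELU (exact, Gaussian CDF form) ----------------------------------------
# the forward caches Phi(x); the backward reuses it, paying only for phi(x)

gelu_fwd <- function(x) cpp_gelu_fwd(x)

gelu_bwd <- function(x, phi_c, dy) cpp_gelu_bwd(x, phi_c, dy)

gelu_fwd_ref <- function(x) {
  phi_c <- pnorm(x)
  list(y = x * phi_c, phi = phi_c)
}

gelu_bwd_ref <- function(x, phi_c, dy) dy * (phi_c + x * dnorm(x))

# --- softmax rows and cross entropy -----------------------------------------

softmax_rows <- function(z) cpp_softmax_rows(z)

softmax_rows_ref <- function(z) {
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z)
  e / rowSums(e)
}

# labels: integer class indices 1..K; returns mean loss and dlogits
cross_entropy <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n)
}

# --- multi-head scaled dot-product self-attention ---------------------------
# x: (B*T) x D with T contiguous rows per group. Attention never crosses
# group boundaries. Returns the concatenated head outputs (before the output
# projection) plus the softmax maps for the backward pass and diagnostics.

attention_fwd <- function(q, k, v, B, T, n_heads) {
  cpp_attention_fwd(q, k, v, B, T, n_heads)
}

attention_bwd <- function(cache, q, k, v, dout, B, T, n_heads) {
  cpp_attention_bwd(cache$A, q, k, v, dout, B, T, n_heads)
}

attention_fwd_ref <- function(q, k, v, B, T, n_heads) {
  D <- ncol(q)
  dh <- D %/% n_heads
  scale <- 1 / sqrt(dh)
  out <- matrix(0, nrow(q), D)
  A <- array(0, dim = c(T, T, B * n_heads))
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- q[, cols, drop = FALSE] * scale
    kh <- k[, cols, drop = FALSE]
    vh <- v[, cols, drop = FALSE]
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T + 1L):(b * T)
      a <- softmax_rows(tcrossprod(qh[rows, , drop = FALSE],
                                   kh[rows, , drop = FALSE]))
      A[, , (b - 1L) * n_heads + h] <- a
      out[rows, cols] <- a %*% vh[rows, , drop = FALSE]
    }
  }
  list(out = out, A = A)
}

attention_bwd_ref <- function(cache, q, k, v, dout, B, T, n_heads) {
  D <- ncol(q)
  dh <- D %/% n_heads
  scale <- 1 / sqrt(dh)
  dq <- matrix(0, nrow(q), D); dk <- dq; dv <- dq
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    kh <- k[, cols, drop = FALSE]
    vh <- v[, cols, drop = FALSE]
    qh <- q[, cols, drop = FALSE]
    doh_all <- dout[, cols, drop = FALSE]
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T + 1L):(b * T)
      a <- cache$A[, , (b - 1L) * n_heads + h]
      doh <- doh_all[rows, , drop = FALSE]
      da <- tcrossprod(doh, vh[rows, , drop = FALSE])
      dv[rows, cols] <- crossprod(a, doh)
      ds <- a * (da - rowSums(da * a))       # softmax Jacobian, row-wise
      dq[rows, cols] <- (ds %*% kh[rows, , drop = FALSE]) * scale
      dk[rows, cols] <- (crossprod(ds, qh[rows, , drop = FALSE])) * scale
    }
  }
  list(dq = dq, dk = dk, dv = dv)
}

# --- inverted dropout -------------------------------------------------------

dropout_fwd <- function(x, p) {
  if (p <= 0) return(list(y = x, mask = NULL))
  mask <- (matrix(runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(mask, dy) if (is.null(mask)) dy else dy * mask

# --- nested-parameter-tree helpers ------------------------------------------

# apply f elementwise over parallel nested lists of numeric arrays
tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- lapply(seq_along(trees[[1]]), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

tree_sum <- function(tree, f = identity) {
  if (is.list(tree)) sum(vapply(tree, tree_sum, numeric(1), f = f))
  else sum(f(tree))
}

zeros_like <- function(tree) tree_map(function(x) x * 0, tree)
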