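test_that("slab tokenization enumerates electrodes and epochs as documented", {
  cfg <- stt_config(H = 5, W = 512, G = 8, D = 16, L = 1, n_heads = 2)
  arr <- indexed_group(cfg)                # value = epoch*100 + channel
  sp <- tokenize_spatial(arr, cfg)
  expect_equal(dim(sp), c(56L, 5L * 512L)) # ceil(32/5)=7 slabs x 8 epochs

  # brute-force slab oracle: token t of epoch g holds channels of slab s
  tok <- function(m, i) unique(m[i, ])
  for (g in 1:8) for (s in 1:7) {
    ch <- ((s - 1) * 5 + 1):min(s * 5, 32)
    want <- g * 100 + ch
    if (s == 7) want <- c(want, 0)          # zero-padded final slab
    expect_setequal(tok(sp, (g - 1) * 7 + s), want)
  }

  # temporal order: same token multiset, epochs vary fastest within a slab
  tp <- tokenize_temporal(arr, cfg)
  expect_setequal(apply(tp, 1, paste, collapse = ","),
                  apply(sp, 1, paste, collapse = ","))
  for (s in 1:7) for (g in 1:8) {
    expect_equal(tp[(s - 1) * 8 + g, ], sp[(g - 1) * 7 + s, ])
  }

  # whole-montage slab: one token per epoch
  cfg32 <- stt_config(H = 32, W = 512, G = 8, D = 16, L = 1, n_heads = 2)
  expect_equal(nrow(tokenize_spatial(arr, cfg32)), 8L)
})

test_that("reversing epoch order reverses temporal tokens exactly", {
  cfg <- stt_config(H = 32, W = 64, G = 4, D = 16, L = 1, n_heads = 2)
  arr <- array(rnorm(64 * 32 * 4), c(64, 32, 4))
  rev_arr <- arr[, , 4:1]
  expect_equal(tokenize_temporal(rev_arr, cfg),
               tokenize_temporal(arr, cfg)[4:1, ])
})

test_that("permuting electrodes within one slab touches only that token", {
  cfg <- stt_config(H = 5, W = 32, G = 2, D = 16, L = 1, n_heads = 2)
  arr <- random_group(cfg)
  arr2 <- arr
  arr2[, 1:5, ] <- arr[, c(3, 1, 2, 5, 4), ]   # shuffle slab-1 electrodes
  a <- tokenize_spatial(arr, cfg)
  b <- tokenize_spatial(arr2, cfg)
  slab1_rows <- seq(1, nrow(a), by = cfg$n_slabs)
  expect_false(isTRUE(all.equal(a[slab1_rows, ], b[slab1_rows, ])))
  expect_equal(a[-slab1_rows, ], b[-slab1_rows, ])
})

test_that("epoch-length and group-size mismatches raise shape errors", {
  cfg <- tiny_cfg()
  bad_len <- array(0, c(cfg$W + 1, 32, cfg$G))
  expect_error(tokenize_spatial(bad_len, cfg), class = "stteeg_shape_error")
  bad_g <- array(0, c(cfg$W, 32, cfg$G + 1))
  expect_error(tokenize_spatial(bad_g, cfg), class = "stteeg_shape_error")
})

test_that("embedding prepends the class token and adds positions", {
  cfg <- tiny_cfg()
  m <- stt_model(cfg)
  patches <- tokenize_spatial(random_group(cfg), cfg)
  seq <- embed(patches, m, "spatial")
  expect_equal(dim(seq), c(nrow(patches) + 1L, cfg$D))

  # zero patches + zero map -> class and position embeddings alone
  m0 <- m
  m0$params$spatial$embed_W[] <- 0
  z <- embed(matrix(0, nrow(patches), cfg$patch_dim), m0, "spatial")
  p <- m0$params$spatial
  expect_equal(z[1, ], p$cls + p$pos[1, ])
  expect_equal(z[-1, ], p$pos[-1, ], ignore_attr = TRUE)

  # distinct patches map to distinct embeddings (injectivity a.s.)
  seq2 <- embed(patches + 1, m, "spatial")
  expect_false(isTRUE(all.equal(seq, seq2)))
})

test_that("attention rows sum to one across layers, heads and inputs", {
  cfg <- tiny_cfg()
  m <- stt_model(cfg)
  for (trial in 1:5) {
    seq <- embed(tokenize_spatial(random_group(cfg), cfg), m, "spatial")
    out <- encoder_forward(seq, m, "spatial", return_attention = TRUE)
    for (A in attr(out, "attention")) {
      sums <- apply(A, c(1, 3), sum)
      expect_true(all(abs(sums - 1) < 1e-6))
    }
  }
})

test_that("encoder with L = 0 is the identity", {
  cfg <- tiny_cfg(L = 0)
  m <- stt_model(cfg)
  seq <- matrix(rnorm(10 * cfg$D), 10, cfg$D)
  expect_identical(encoder_forward(seq, m, "spatial"), seq)
})

test_that("without positions the encoder is permutation-equivariant", {
  # 3-token toy + class token; permute the non-class tokens
  cfg <- stt_config(D = 16, L = 2, n_heads = 2, W = 8, G = 1, H = 4,
                    n_classes = 2, mlp_mult = 2, dropout = 0, seed = 9)
  m <- stt_model(cfg)
  x <- matrix(rnorm(4 * cfg$D), 4, cfg$D)
  perm <- c(1, 4, 2, 3)
  y <- encoder_forward(x, m, "temporal")
  y_perm <- encoder_forward(x[perm, ], m, "temporal")
  expect_equal(y_perm, y[perm, ], tolerance = 1e-5)
  expect_equal(y_perm[1, ], y[1, ], tolerance = 1e-5)  # class token fixed
})

test_that("streams share no weights and fused output needs both", {
  cfg <- tiny_cfg()
  m <- stt_model(cfg)
  g <- random_group(cfg)
  base <- stt_forward(m, g)
  expect_equal(dim(base$y), c(1L, 2L))
  expect_equal(dim(base$y_spatial), c(1L, 2L))
  expect_true(all(is.finite(unlist(base[c("y_spatial", "y_temporal", "y")]))))

  m_zero <- m
  m_zero$params$spatial <- stteeg:::zeros_like(m$params$spatial)
  z <- stt_forward(m_zero, g)
  expect_identical(z$y_temporal, base$y_temporal)     # untouched stream
  expect_false(isTRUE(all.equal(z$y_spatial, base$y_spatial)))
  expect_false(isTRUE(all.equal(z$y, base$y)))

  # initial parameters of the two streams are distinct draws
  expect_false(isTRUE(all.equal(m$params$spatial$embed_W,
                                m$params$temporal$embed_W)))
})

test_that("batching never mixes examples and reruns are bit-identical", {
  cfg <- tiny_cfg()
  m <- stt_model(cfg)
  g1 <- random_group(cfg); g2 <- random_group(cfg)
  single <- stt_forward(m, g1)
  batched <- stt_forward(m, list(g1, g2, g1, g2))
  expect_equal(batched$y[1, ], single$y[1, ], tolerance = 1e-12)
  expect_equal(batched$y[3, ], batched$y[1, ])
  expect_identical(stt_forward(m, list(g1, g2)),
                   stt_forward(m, list(g1, g2)))
})

test_that("parameter count depends on the config alone", {
  cfg <- tiny_cfg()
  expect_identical(n_params(cfg), n_params(stt_model(cfg)))
  expect_gt(n_params(tiny_cfg(L = 3)), n_params(cfg))
  # two identically shaped streams: count is even apart from the fusion head
  fusion <- 2 * (2 * cfg$n_classes) +
    2 * cfg$n_classes * cfg$n_classes + cfg$n_classes
  expect_equal((n_params(cfg) - fusion) %% 2, 0)
})

test_that("checkpoints round trip config, scale and parameters", {
  cfg <- tiny_cfg(L = 1)
  m <- stt_model(cfg)
  m$patch_scale <- 3.7
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$config$D, cfg$D)
  expect_equal(back$patch_scale, 3.7)
  g <- random_group(cfg)
  expect_equal(stt_forward(back, g)$y, stt_forward(m, g)$y,
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cfg <- stt_config(D = 8, L = 2, n_heads = 2, W = 16, G = 2, H = 16,
                    n_classes = 3, mlp_mult = 2, dropout = 0, seed = 1)
  m <- stt_model(cfg)
  set.seed(4)
  arrs <- lapply(1:3, function(i) random_group(cfg))
  Pbig <- stteeg:::stack_patches(lapply(arrs, stteeg:::group_patches,
                                        cfg = cfg))
  lab <- c(1L, 2L, 3L)
  lossfn <- function(params) {
    stteeg:::stt_loss_grad(params, cfg, Pbig, 3L, lab, alpha = 0.3,
                           training = FALSE)$loss
  }
  lg <- stteeg:::stt_loss_grad(m$params, cfg, Pbig, 3L, lab, alpha = 0.3,
                               training = FALSE)

  paths <- list()
  walk <- function(tree, prefix) {
    if (is.list(tree)) {
      for (i in seq_along(tree)) walk(tree[[i]], c(prefix, i))
    } else {
      paths[[length(paths) + 1L]] <<- prefix
    }
  }
  walk(m$params, integer(0))
  get_node <- function(tree, p) { for (i in p) tree <- tree[[i]]; tree }
  set_node <- function(tree, p, val) {
    if (length(p) == 1) { tree[[p]] <- val; return(tree) }
    tree[[p[1]]] <- set_node(tree[[p[1]]], p[-1], val)
    tree
  }
  eps <- 1e-5
  set.seed(42)
  for (p in paths[sample(length(paths), 30)]) {
    x <- get_node(m$params, p)
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    num <- (lossfn(set_node(m$params, p, xp)) -
              lossfn(set_node(m$params, p, xm))) / (2 * eps)
    ana <- get_node(lg$grads, p)[i]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})
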