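# logits engineered so that cross entropy has a closed-form value:
# two classes, label = class 1, logits (0, log(exp(v) - 1)) give CE = v
logits_with_ce <- function(v) matrix(c(0, log(exp(v) - 1)), 1, 2)

test_that("composite loss combines stream cross entropies as alpha dictates", {
  outs <- structure(list(y_spatial = logits_with_ce(2),
                         y_temporal = logits_with_ce(1),
                         y = logits_with_ce(0.5)),
                    class = "stt_outputs")
  got <- composite_loss(outs, labels = 1L, alpha = 0.3, include_fused = FALSE)
  expect_equal(as.numeric(got), 0.3 * 2 + 0.7 * 1, tolerance = 1e-12)
  parts <- attr(got, "parts")
  expect_equal(unname(parts[c("spatial", "temporal")]), c(2, 1),
               tolerance = 1e-12)

  # with the fused term the fused CE is added at unit weight
  with_f <- composite_loss(outs, 1L, alpha = 0.3, include_fused = TRUE)
  expect_equal(as.numeric(with_f), 1.3 + 0.5, tolerance = 1e-12)

  # uniform logits: CE = log(n_classes)
  zeros <- structure(list(y_spatial = matrix(0, 2, 3),
                          y_temporal = matrix(0, 2, 3),
                          y = matrix(0, 2, 3)), class = "stt_outputs")
  expect_equal(as.numeric(composite_loss(zeros, c(1L, 3L), alpha = 0.5,
                                         include_fused = FALSE)),
               log(3), tolerance = 1e-12)

  expect_error(composite_loss(outs, 1L, alpha = 1.2),
               class = "stteeg_config_error")
})

test_that("composite loss is affine in alpha at fixed logits", {
  set.seed(5)
  outs <- structure(list(y_spatial = matrix(rnorm(8), 4, 2),
                         y_temporal = matrix(rnorm(8), 4, 2),
                         y = matrix(rnorm(8), 4, 2)), class = "stt_outputs")
  labs <- c(1L, 2L, 1L, 2L)
  l0 <- as.numeric(composite_loss(outs, labs, 0, include_fused = FALSE))
  l1 <- as.numeric(composite_loss(outs, labs, 1, include_fused = FALSE))
  lh <- as.numeric(composite_loss(outs, labs, 0.5, include_fused = FALSE))
  expect_equal(lh, (l0 + l1) / 2, tolerance = 1e-10)
})

test_that("alpha = 1 silences every temporal gradient in the composite", {
  cfg <- tiny_cfg()
  m <- stt_model(cfg)
  set.seed(2)
  Pbig <- stteeg:::group_patches(random_group(cfg), cfg)
  lg <- stteeg:::stt_loss_grad(m$params, cfg, Pbig, 1L, 1L, alpha = 1,
                               include_fused = FALSE, training = FALSE)
  expect_equal(stteeg:::tree_sum(lg$grads$temporal, abs), 0)
  expect_gt(stteeg:::tree_sum(lg$grads$spatial, abs), 0)
})

test_that("AMSGrad drives a convex problem toward its minimum", {
  params <- list(x = c(1, -2))
  state <- stteeg:::amsgrad_init(params)
  tcfg <- train_config(lr = 0.05)
  for (i in 1:500) {
    grads <- list(x = 2 * params$x)            # d/dx of sum(x^2)
    st <- stteeg:::amsgrad_step(params, grads, state, tcfg)
    params <- st$params; state <- st$state
  }
  expect_lt(max(abs(params$x)), 0.05)
  # the second-moment maximum never decreases
  expect_true(all(state$vhat$x >= state$v$x - 1e-15))
})

test_that("patch-space shift augmentation equals re-slabbing shifted epochs", {
  cfg <- tiny_cfg(H = 5, W = 32, G = 4)
  arr <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  P <- stteeg:::group_patches(arr, cfg)
  a <- withr::with_seed(7, stteeg:::roll_patches(P, cfg))
  b <- withr::with_seed(7, stteeg:::group_patches(
    stteeg:::roll_epochs(arr, cfg), cfg))
  expect_equal(a, b)
})

test_that("training lowers the loss and is seed-reproducible", {
  corpus <- tiny_binary_corpus(n_subjects = 1, clip_s = 30)
  groups <- group_epochs(epoch_corpus(corpus), G = 8)
  cfg <- stt_config(D = 16, L = 1, n_heads = 2, n_classes = 2,
                    mlp_mult = 2, dropout = 0, seed = 6)
  tcfg <- train_config(max_epochs = 4, batch_size = 8, seed = 11)
  m1 <- train_stt(groups, cfg, tcfg)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_stt(groups, cfg, tcfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("cross-validation tests every group exactly once", {
  corpus <- tiny_binary_corpus(n_subjects = 1, clip_s = 30)
  groups <- group_epochs(epoch_corpus(corpus), G = 8)
  cfg <- stt_config(D = 16, L = 1, n_heads = 2, n_classes = 2,
                    mlp_mult = 2, dropout = 0, seed = 6)
  tcfg <- train_config(max_epochs = 1, batch_size = 8, seed = 11)
  r <- run_cv(groups, cfg, tcfg, k = 3)
  expect_s3_class(r, "stt_cv")
  fused <- r$per_fold[r$per_fold$head == "y", ]
  expect_equal(sum(fused$n_test), nrow(groups))
  expect_equal(sum(r$fold_sizes), nrow(groups))
  expect_true(all(r$per_fold$accuracy >= 0 & r$per_fold$accuracy <= 1))
  # three logit heads evaluated per fold
  expect_equal(nrow(r$per_fold), 3 * 3)

  td <- tidy(r)
  expect_identical(td, r$per_fold)
  gl <- glance(r)
  expect_equal(gl$n_groups, nrow(groups))
  expect_equal(gl$accuracy,
               mean(fused$accuracy))
})

test_that("a single-cell grid reproduces a plain cross-validation run", {
  corpus <- tiny_binary_corpus(n_subjects = 1, clip_s = 30)
  groups <- group_epochs(epoch_corpus(corpus), G = 8)
  cfg <- stt_config(D = 16, L = 1, n_heads = 2, n_classes = 2,
                    mlp_mult = 2, dropout = 0, seed = 6)
  tcfg <- train_config(max_epochs = 1, batch_size = 8, seed = 11)
  cell <- ablation_grid(groups, heads_set = 2, layers_set = 1,
                        cfg = cfg, tcfg = tcfg, k = 2)
  plain <- run_cv(groups, cfg, tcfg, k = 2)
  agg <- plain$aggregate[plain$aggregate$head == "y", ]
  expect_equal(cell$accuracy, agg$accuracy)
  expect_equal(cell$sensitivity, agg$sensitivity)
  expect_equal(nrow(cell), 1L)
})

test_that("a single-label corpus scores perfectly with undefined specificity", {
  corpus <- generate_corpus(synth_spec(n_subjects = 1, clip_s = 30,
                                       classes = 1L, seed = 9))
  groups <- group_epochs(epoch_corpus(corpus), G = 8)
  cfg <- stt_config(D = 16, L = 1, n_heads = 2, n_classes = 2,
                    mlp_mult = 2, dropout = 0, seed = 6)
  tcfg <- train_config(max_epochs = 5, batch_size = 8, seed = 11)
  suppressWarnings(r <- run_cv(groups, cfg, tcfg, k = 2))
  fused <- r$per_fold[r$per_fold$head == "y", ]
  expect_true(all(fused$accuracy == 1))
  expect_true(all(is.na(fused$specificity)))
})

test_that("non-finite activations abort with a diagnostic error", {
  corpus <- tiny_binary_corpus(n_subjects = 1, clip_s = 30)
  groups <- group_epochs(epoch_corpus(corpus), G = 8)
  # poison one epoch: non-finite input overwhelms the first layer norm
  groups$epochs[[1]][1, 1, 1] <- Inf
  cfg <- stt_config(D = 16, L = 1, n_heads = 2, n_classes = 2,
                    mlp_mult = 2, dropout = 0, seed = 6)
  tcfg <- train_config(max_epochs = 1, batch_size = nrow(groups), seed = 1)
  expect_error(train_stt(groups, cfg, tcfg), class = "stteeg_error")
})
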