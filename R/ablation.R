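#' Channel ablation: spatial-only vs temporal-only vs combined
#'
#' Trains and cross-validates three model variants on identical fold splits:
#' the spatial stream alone (`alpha = 1`, no fused-loss term, spatial-head
#' predictions), the temporal stream alone (`alpha = 0`, temporal head), and
#' the full dual-stream model with fusion.
#'
#' @inheritParams run_cv
#' @return Tibble of class `stt_ablation`: one row per variant with the
#'   aggregate sensitivity, specificity and accuracy; per-variant `stt_cv`
#'   reports in attribute `"reports"`.
#' @export
ablation_channels <- function(corpus, cfg = stt_config(),
                              tcfg = train_config(), k = 10,
                              window_s = 4, overlap_frac = 0.5,
                              split_by = "group", verbose = FALSE) {
  groups <- as_groups(corpus, cfg, window_s, overlap_frac)
  groups <- groups[groups$label %in% class_levels(cfg$n_classes), ,
                   drop = FALSE]
  folds <- kfold_split(groups, k = k, seed = tcfg$seed, by = split_by)

  variants <- list(
    spatial = list(alpha = 1, fused = FALSE, head = "y_spatial"),
    temporal = list(alpha = 0, fused = FALSE, head = "y_temporal"),
    combined = list(alpha = cfg$alpha, fused = TRUE, head = "y"))

  reports <- purrr::imap(variants, function(v, nm) {
    cfg_v <- cfg
    cfg_v$alpha <- v$alpha
    tcfg_v <- tcfg
    tcfg_v$include_fused_loss <- v$fused
    if (verbose) message("variant: ", nm)
    run_cv(groups, cfg_v, tcfg_v, folds = folds, eval_head = v$head,
           verbose = verbose)
  })
  out <- purrr::list_rbind(purrr::imap(reports, function(r, nm) {
    agg <- r$aggregate[r$aggregate$head == r$eval_head, ]
    tibble::tibble(variant = nm, sensitivity = agg$sensitivity,
                   specificity = agg$specificity, accuracy = agg$accuracy)
  }))
  class(out) <- c("stt_ablation", class(out))
  attr(out, "reports") <- reports
  out
}

#' Heads-by-layers ablation grid
#'
#' Cross-validates the full model over the cross-product of attention-head
#' and encoder-depth settings, sharing fold splits and seeds across cells.
#' Completed cells can be checkpointed to a CSV so an interrupted sweep
#' resumes where it stopped.
#'
#' @inheritParams run_cv
#' @param heads_set,layers_set Integer vectors to sweep.
#' @param checkpoint_path Optional CSV path; completed `(heads, layers)`
#'   cells found there are reused instead of recomputed, and each finished
#'   cell is appended.
#' @return Tibble of class `stt_grid`: `n_heads`, `n_layers`, `sensitivity`,
#'   `specificity`, `accuracy`, one row per cell.
#' @export
ablation_grid <- function(corpus, heads_set = c(1, 2, 4),
                          layers_set = c(4, 8, 12), cfg = stt_config(),
                          tcfg = train_config(), k = 10, window_s = 4,
                          overlap_frac = 0.5, split_by = "group",
                          checkpoint_path = NULL, verbose = FALSE) {
  groups <- as_groups(corpus, cfg, window_s, overlap_frac)
  groups <- groups[groups$label %in% class_levels(cfg$n_classes), ,
                   drop = FALSE]
  folds <- kfold_split(groups, k = k, seed = tcfg$seed, by = split_by)

  done <- NULL
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    done <- tibble::as_tibble(utils::read.csv(checkpoint_path))
  }
  cells <- tidyr::expand_grid(n_heads = as.integer(heads_set),
                              n_layers = as.integer(layers_set))
  rows <- purrr::pmap(cells, function(n_heads, n_layers) {
    if (!is.null(done)) {
      hit <- done[done$n_heads == n_heads & done$n_layers == n_layers, ]
      if (nrow(hit)) return(tibble::as_tibble(hit[1, ]))
    }
    cfg_c <- cfg
    cfg_c$n_heads <- n_heads
    cfg_c$L <- n_layers
    if (cfg_c$D %% n_heads != 0) {
      stop_stteeg(sprintf("D=%d not divisible by %d heads", cfg_c$D, n_heads),
                  "stteeg_config_error")
    }
    if (verbose) message(sprintf("grid cell: heads=%d layers=%d", n_heads, n_layers))
    r <- run_cv(groups, cfg_c, tcfg, folds = folds)
    agg <- r$aggregate[r$aggregate$head == "y", ]
    row <- tibble::tibble(n_heads = n_heads, n_layers = n_layers,
                          sensitivity = agg$sensitivity,
                          specificity = agg$specificity,
                          accuracy = agg$accuracy)
    if (!is.null(checkpoint_path)) {
      utils::write.table(row, checkpoint_path, sep = ",", row.names = FALSE,
                         col.names = !file.exists(checkpoint_path),
                         append = file.exists(checkpoint_path))
    }
    row
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("stt_grid", class(out))
  out
}

#' Loss-weight sweep
#'
#' Cross-validates the full model at several values of the composite-loss
#' weight `alpha`, sharing folds and seeds, to expose the spatial/temporal
#' trade-off.
#'
#' @inheritParams run_cv
#' @param alphas Values of the spatial-stream weight to evaluate.
#' @return Tibble of class `stt_alpha_sweep`: `alpha`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
sweep_alpha <- function(corpus, alphas = seq(0, 1, by = 0.1),
                        cfg = stt_config(), tcfg = train_config(), k = 10,
                        window_s = 4, overlap_frac = 0.5,
                        split_by = "group", verbose = FALSE) {
  groups <- as_groups(corpus, cfg, window_s, overlap_frac)
  groups <- groups[groups$label %in% class_levels(cfg$n_classes), ,
                   drop = FALSE]
  folds <- kfold_split(groups, k = k, seed = tcfg$seed, by = split_by)
  out <- purrr::list_rbind(purrr::map(alphas, function(a) {
    cfg_a <- cfg
    cfg_a$alpha <- a
    if (verbose) message("alpha = ", a)
    r <- run_cv(groups, cfg_a, tcfg, folds = folds)
    agg <- r$aggregate[r$aggregate$head == "y", ]
    tibble::tibble(alpha = a, sensitivity = agg$sensitivity,
                   specificity = agg$specificity, accuracy = agg$accuracy)
  }))
  class(out) <- c("stt_alpha_sweep", class(out))
  out
}
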