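#' One-vs-rest confusion counts
#'
#' Tabulates TP/FN/TN/FP per class. For a binary task the positive class is
#' the last class level (`+1`), giving the usual single 2x2 view; for a
#' ternary task every class gets its own one-vs-rest view.
#'
#' @param truth,pred Integer class indices (`1..n_classes`).
#' @param n_classes Number of classes.
#' @return Tibble with columns `class` (emotion label), `TP`, `FN`, `TN`,
#'   `FP`; one row per one-vs-rest view.
#' @export
confusion_counts <- function(truth, pred, n_classes) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  levels <- class_levels(n_classes)
  views <- if (n_classes == 2L) n_classes else seq_len(n_classes)
  purrr::list_rbind(purrr::map(views, function(k) {
    tibble::tibble(
      class = levels[k],
      TP = sum(truth == k & pred == k),
      FN = sum(truth == k & pred != k),
      TN = sum(truth != k & pred != k),
      FP = sum(truth != k & pred == k))
  }))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + FN + TN + FP)`, computed per one-vs-rest
#' view and macro-averaged over views for multiclass input. A zero
#' denominator yields `NA` (with a warning), never 0.
#'
#' @param counts Tibble from [confusion_counts()] (columns `TP`, `FN`, `TN`,
#'   `FP`, optionally `class`).
#' @return One-row tibble: `sensitivity`, `specificity`, `accuracy`, with the
#'   per-view values as attribute `"per_class"`.
#' @export
compute_metrics <- function(counts) {
  if (!nrow(counts) || sum(counts$TP + counts$FN + counts$TN + counts$FP) == 0) {
    stop_stteeg("No evaluated samples", "stteeg_input_error")
  }
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, NA_real_)
    if (anyNA(out)) {
      warn(sprintf("%s undefined (zero denominator) for %d class view(s)",
                   what, sum(is.na(out))))
    }
    out
  }
  per <- dplyr::mutate(
    counts,
    sensitivity = safe_div(.data$TP, .data$TP + .data$FN, "sensitivity"),
    specificity = safe_div(.data$TN, .data$TN + .data$FP, "specificity"),
    accuracy = (.data$TP + .data$TN) /
      (.data$TP + .data$FN + .data$TN + .data$FP))
  agg <- tibble::tibble(
    sensitivity = mean(per$sensitivity),
    specificity = mean(per$specificity),
    accuracy = mean(per$accuracy))
  attr(agg, "per_class") <- per
  agg
}

#' Stratified k-fold assignment of epoch groups
#'
#' Deals groups to folds label stratum by label stratum in one continuing
#' round-robin, so fold sizes differ by at most one overall and within each
#' label. With `by = "subject"` whole subjects are dealt instead, giving
#' subject-disjoint folds (no shared recordings between train and test; see
#' the leakage discussion in the vignette).
#'
#' @param groups Groups tibble from [group_epochs()].
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @param by `"group"` (sample-wise, the reference protocol) or `"subject"`.
#' @return Integer fold id (`1..k`) per row of `groups`.
#' @export
kfold_split <- function(groups, k = 10, seed = 1L, by = c("group", "subject")) {
  by <- match.arg(by)
  n <- nrow(groups)
  if (by == "group") {
    if (k > n) stop_stteeg("More folds than groups", "stteeg_input_error")
    fold <- integer(n)
    withr::with_seed(seed, {
      dealt <- 0L
      for (lbl in sort(unique(groups$label))) {
        ids <- sample(which(groups$label == lbl))
        fold[ids] <- ((dealt + seq_along(ids) - 1L) %% k) + 1L
        dealt <- dealt + length(ids)
      }
    })
    fold
  } else {
    subj <- unique(groups$subject_id)
    if (k > length(subj)) {
      stop_stteeg("More folds than subjects", "stteeg_input_error")
    }
    withr::with_seed(seed, {
      subj <- sample(subj)
    })
    sf <- ((seq_along(subj) - 1L) %% k) + 1L
    sf[match(groups$subject_id, subj)]
  }
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Cross-validated training and evaluation
#'
#' The full evaluation protocol: epoch the corpus (4-s windows, 50% overlap
#' by default), assemble same-label groups of `G` epochs, split them into `k`
#' stratified folds, train a freshly initialized model per fold on the
#' remaining folds, and evaluate the held-out fold with the fused logits.
#' Per-fold metrics from the spatial-only and temporal-only heads are
#' recorded alongside for ablation use; the aggregate is the arithmetic mean
#' over folds.
#'
#' @param corpus Corpus tibble ([generate_corpus()] / [load_corpus()]), or a
#'   pre-built groups tibble from [group_epochs()].
#' @param cfg An [stt_config()].
#' @param tcfg A [train_config()].
#' @param k Number of folds.
#' @param window_s,overlap_frac Epoching parameters (ignored when `corpus`
#'   is already grouped).
#' @param split_by `"group"` or `"subject"` (see [kfold_split()]).
#' @param folds Optional precomputed fold assignment (shared across ablation
#'   variants).
#' @param eval_head Logit set whose predictions fill the headline metrics.
#' @param verbose Print per-fold progress.
#' @return An `stt_cv` report: `per_fold` (fold x head metrics), `aggregate`
#'   (mean over folds per head), `per_class`, `fold_sizes`, and the config
#'   snapshots. [tidy()] and [glance()] methods apply.
#' @export
run_cv <- function(corpus, cfg = stt_config(), tcfg = train_config(),
                   k = 10, window_s = 4, overlap_frac = 0.5,
                   split_by = c("group", "subject"), folds = NULL,
                   eval_head = "y", verbose = FALSE) {
  split_by <- match.arg(split_by)
  groups <- as_groups(corpus, cfg, window_s, overlap_frac)
  classes <- class_levels(cfg$n_classes)
  groups <- groups[groups$label %in% classes, , drop = FALSE]
  if (is.null(folds)) {
    folds <- kfold_split(groups, k = k, seed = tcfg$seed, by = split_by)
  }
  stopifnot(length(folds) == nrow(groups))
  k <- max(folds)
  heads <- c("y", "y_spatial", "y_temporal")

  fold_rows <- list()
  class_rows <- list()
  for (f in sort(unique(folds))) {
    tr <- groups[folds != f, , drop = FALSE]
    te <- groups[folds == f, , drop = FALSE]
    cfg_f <- cfg
    cfg_f$seed <- derive_seed(cfg$seed, f)
    tcfg_f <- tcfg
    tcfg_f$seed <- derive_seed(tcfg$seed, f + 1000L)
    model <- train_stt(tr, cfg_f, tcfg_f)
    truth <- labels_to_idx(te$label, cfg$n_classes)
    outs <- stt_forward(model, te)
    for (h in heads) {
      pred <- max.col(outs[[h]], ties.method = "first")
      counts <- confusion_counts(truth, pred, cfg$n_classes)
      m <- compute_metrics(counts)
      fold_rows[[length(fold_rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(fold = f, head = h, n_test = nrow(te)), m)
      class_rows[[length(class_rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(fold = f, head = h),
                         attr(m, "per_class"))
    }
    if (verbose) {
      acc <- fold_rows[[length(fold_rows) - 2L]]$accuracy
      message(sprintf("fold %d/%d: fused accuracy %.3f", f, k, acc))
    }
  }
  per_fold <- purrr::list_rbind(fold_rows)
  aggregate <- dplyr::summarise(
    dplyr::group_by(per_fold, .data$head),
    dplyr::across(c("sensitivity", "specificity", "accuracy"),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  structure(
    list(per_fold = per_fold, aggregate = aggregate,
         per_class = purrr::list_rbind(class_rows),
         fold_sizes = as.integer(table(folds)),
         eval_head = eval_head, config = cfg, train_config = tcfg),
    class = "stt_cv")
}

as_groups <- function(corpus, cfg, window_s, overlap_frac) {
  if ("epochs" %in% names(corpus)) return(corpus)
  if (!"recording" %in% names(corpus)) {
    stop_stteeg("Expected a corpus tibble or a groups tibble",
                "stteeg_input_error")
  }
  epochs <- epoch_corpus(corpus, window_s = window_s,
                         overlap_frac = overlap_frac)
  group_epochs(epochs, G = cfg$G)
}

#' @export
print.stt_cv <- function(x, ...) {
  agg <- x$aggregate[x$aggregate$head == x$eval_head, ]
  cat(sprintf(
    "<stt_cv> %d-fold cross-validation (%s head)\n  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
    length(x$fold_sizes), x$eval_head,
    agg$sensitivity, agg$specificity, agg$accuracy))
  invisible(x)
}
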