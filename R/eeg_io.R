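#' Construct an EEG recording
#'
#' Bundles a samples-by-channels matrix with its sampling rate, montage and
#' emotion label. All functions in the package store EEG time-major: one row
#' per sample, one column per electrode, in montage order.
#'
#' @param samples Numeric matrix `[time x channels]`, microvolts.
#' @param fs Sampling rate, Hz.
#' @param label Emotion label: `-1` negative, `0` neutral, `+1` positive.
#' @param subject_id,clip_id Identifiers carried through epoching.
#' @param montage Electrode labels matching the columns of `samples`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(samples, fs, label,
                          subject_id = "s01", clip_id = "c01",
                          montage = canonical_montage()) {
  samples <- as.matrix(samples)
  dimnames(samples) <- NULL          # montage order carries channel identity
  if (!is.numeric(samples) || anyNA(samples)) {
    stop_stteeg("Recording samples must be a numeric matrix without NAs",
                "stteeg_format_error")
  }
  if (nrow(samples) < 1L) {
    stop_stteeg("Recording has no samples", "stteeg_input_error")
  }
  if (ncol(samples) != length(montage)) {
    stop_stteeg(
      sprintf("Recording has %d channels but montage lists %d",
              ncol(samples), length(montage)),
      "stteeg_montage_error")
  }
  if (!is.numeric(fs) || fs <= 0) {
    stop_stteeg("Sampling rate must be positive", "stteeg_input_error")
  }
  if (!label %in% c(-1L, 0L, 1L)) {
    stop_stteeg("Label must be -1 (negative), 0 (neutral) or +1 (positive)",
                "stteeg_input_error")
  }
  structure(
    list(samples = samples, fs = fs, montage = montage,
         label = as.integer(label),
         subject_id = as.character(subject_id),
         clip_id = as.character(clip_id)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %.1f s @ %g Hz, %d channels, label %+d\n",
              x$subject_id, x$clip_id, nrow(x$samples) / x$fs, x$fs,
              ncol(x$samples), x$label))
  invisible(x)
}

#' Read one EEG recording from disk
#'
#' Accepts EDF, or a delimited text file whose header row names the channels
#' (comma-, tab- or semicolon-separated, one sample per row, `.` decimal).
#' Columns are reordered to match `expected_montage`; the `FC`/`FC2` alias
#' and case differences are tolerated.
#'
#' @param path Path to an `.edf` file or a delimited text file.
#' @param expected_montage Electrode labels the caller requires, in order.
#' @param fs Sampling rate in Hz; required for text input, ignored for EDF
#'   (which records its own rate).
#' @param label,subject_id,clip_id Metadata attached to the recording.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, expected_montage = canonical_montage(),
                           fs = NULL, label = 0L,
                           subject_id = "s01", clip_id = "c01") {
  if (!file.exists(path)) {
    stop_stteeg(paste0("No such file: ", path), "stteeg_input_error")
  }
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    edf <- read_edf(path)
    idx <- match_montage(edf$channel_names, expected_montage)
    return(eeg_recording(edf$samples[, idx, drop = FALSE], edf$fs, label,
                         subject_id, clip_id, expected_montage))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "numeric")
  if (!ncol(df) || !all(vapply(df, is.numeric, TRUE))) {
    stop_stteeg("Non-numeric payload in delimited EEG file",
                "stteeg_format_error")
  }
  idx <- match_montage(names(df), expected_montage)
  if (is.null(fs)) {
    stop_stteeg("Text input needs an explicit sampling rate `fs`",
                "stteeg_input_error")
  }
  eeg_recording(as.matrix(df)[, idx, drop = FALSE], fs, label,
                subject_id, clip_id, expected_montage)
}

#' Write a recording as delimited text
#'
#' Inverse of the text branch of [read_recording()]: a header row of channel
#' names followed by one sample per row.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  df <- as.data.frame(rec$samples)
  names(df) <- rec$montage
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cut a recording into overlapped fixed-length epochs
#'
#' Epoch starts sit on a fixed grid: `0, stride, 2 stride, ...` over the whole
#' recording `[0, T)`, where `stride = window_s * (1 - overlap_frac)`. Windows
#' whose end runs past `T` wrap circularly to the start of the recording, so
#' the epoch count is exactly `floor(T / stride)`. With the 4-s window and 50%
#' overlap used throughout, a 60-s clip yields 30 epochs of 512 samples at
#' 128 Hz.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Epoch length in seconds; `window_s * fs` must be integer.
#' @param overlap_frac Fraction of the window shared by consecutive epochs,
#'   in `[0, 1)`.
#' @return A tibble with one row per epoch: `subject_id`, `clip_id`, `label`,
#'   `start_s` (0-based offset of the window start) and `samples`
#'   (list-column of `[window x channels]` matrices).
#' @export
epoch_recording <- function(rec, window_s = 4, overlap_frac = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop_stteeg("overlap_frac must lie in [0, 1)", "stteeg_input_error")
  }
  w <- window_s * rec$fs
  if (abs(w - round(w)) > 1e-9) {
    stop_stteeg("window_s * fs must be an integer number of samples",
                "stteeg_input_error")
  }
  w <- as.integer(round(w))
  n <- nrow(rec$samples)
  if (w > n) {
    stop_stteeg("Window is longer than the recording", "stteeg_input_error")
  }
  stride <- w * (1 - overlap_frac)
  if (abs(stride - round(stride)) > 1e-9) {
    stop_stteeg("window_s * fs * (1 - overlap_frac) must be an integer",
                "stteeg_input_error")
  }
  stride <- as.integer(round(stride))
  n_epochs <- n %/% stride
  starts <- (seq_len(n_epochs) - 1L) * stride
  cut_one <- function(s0) {
    idx <- ((s0 + seq_len(w) - 1L) %% n) + 1L   # circular wrap past T
    rec$samples[idx, , drop = FALSE]
  }
  tibble::tibble(
    subject_id = rec$subject_id,
    clip_id = rec$clip_id,
    label = rec$label,
    start_s = starts / rec$fs,
    samples = lapply(starts, cut_one))
}

#' Epoch every recording of a corpus
#'
#' @param corpus A corpus tibble as returned by [generate_corpus()] or
#'   [load_corpus()] (list-column `recording` of [eeg_recording()] objects).
#' @inheritParams epoch_recording
#' @return One epoch tibble (see [epoch_recording()]) covering all recordings.
#' @export
epoch_corpus <- function(corpus, window_s = 4, overlap_frac = 0.5) {
  purrr::list_rbind(lapply(corpus$recording, epoch_recording,
                           window_s = window_s, overlap_frac = overlap_frac))
}

#' Assemble epochs into same-label groups for the transformer
#'
#' The model consumes groups of `G` epochs sharing one label. Within each
#' subject-by-label stratum, epochs are ordered by clip and then by start
#' offset and split into consecutive non-overlapping runs of `G`; leftovers
#' shorter than `G` are dropped (with a warning if a stratum yields no group
#' at all). The `seed` shuffles only the order of the resulting groups, never
#' their contents.
#'
#' @param epochs Epoch tibble from [epoch_recording()]/[epoch_corpus()].
#' @param G Epochs per group (8 in the reference configuration).
#' @param seed Integer seed for the group-order shuffle, or `NULL` to keep
#'   deterministic stratum order.
#' @return Tibble with one row per group: `group_id`, `subject_id`, `label`,
#'   and `epochs`, a list-column of `[window x channels x G]` arrays.
#' @export
group_epochs <- function(epochs, G = 8, seed = NULL) {
  stopifnot(G >= 1)
  strata <- dplyr::group_split(epochs, .data$subject_id, .data$label)
  groups <- purrr::list_rbind(purrr::map(strata, function(st) {
    st <- dplyr::arrange(st, .data$clip_id, .data$start_s)
    n_full <- nrow(st) %/% G
    if (n_full == 0L) {
      warn(sprintf("subject %s label %+d: %d epoch(s) < group size %d, dropped",
                   st$subject_id[1], st$label[1], nrow(st), G))
      return(NULL)
    }
    purrr::list_rbind(purrr::map(seq_len(n_full), function(g) {
      rows <- ((g - 1L) * G + 1L):(g * G)
      arr <- array(unlist(st$samples[rows], use.names = FALSE),
                   dim = c(dim(st$samples[[1]]), G))
      tibble::tibble(subject_id = st$subject_id[1], label = st$label[1],
                     epochs = list(arr))
    }))
  }))
  if (is.null(groups) || !nrow(groups)) {
    stop_stteeg("No label stratum yielded a full group", "stteeg_input_error")
  }
  if (!is.null(seed)) {
    ord <- withr::with_seed(seed, sample.int(nrow(groups)))
    groups <- groups[ord, ]
  }
  dplyr::mutate(groups, group_id = dplyr::row_number(), .before = 1)
}
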