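# Shared fixtures, built in code at test time.

# a recording of pure sinusoids: channel i gets amplitude amps[i] at freqs[i]
sine_recording <- function(amps, freqs, fs = 128, dur_s = 5, label = 1L,
                           montage = canonical_montage()) {
  t <- seq_len(dur_s * fs) / fs
  x <- vapply(seq_along(montage), function(i) {
    amps[(i - 1) %% length(amps) + 1] *
      sin(2 * pi * freqs[(i - 1) %% length(freqs) + 1] * t)
  }, numeric(length(t)))
  eeg_recording(x, fs, label, montage = montage)
}

# minimal epoch tibble with known start offsets and a recognizable payload:
# sample value = clip_rank * 1000 + start_s
toy_epochs <- function(n, label = 1L, subject = "s01", clip = "c1",
                       w = 8L, nch = 4L) {
  tibble::tibble(
    subject_id = subject, clip_id = clip, label = as.integer(label),
    start_s = as.numeric(seq_len(n) - 1),
    samples = lapply(seq_len(n) - 1, function(s) {
      matrix(s, w, nch)
    }))
}

# group array whose epoch g / channel c is constant g * 100 + c, so token
# provenance is readable off the patch values
indexed_group <- function(cfg, nch = 32L) {
  arr <- array(0, c(cfg$W, nch, cfg$G))
  for (g in seq_len(cfg$G)) for (ch in seq_len(nch)) {
    arr[, ch, g] <- g * 100 + ch
  }
  arr
}

# tiny model config used across model tests
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(D = 16, L = 2, n_heads = 2, W = 32, G = 2, H = 16,
         n_classes = 2, mlp_mult = 2, dropout = 0, seed = 42L),
    list(...))
  do.call(stt_config, args)
}

random_group <- function(cfg, nch = 32L) {
  array(rnorm(cfg$W * nch * cfg$G), c(cfg$W, nch, cfg$G))
}

# independent spectral oracle: base-R raw periodogram, averaged over columns
welch_psd_for_test <- function(x, fs) {
  x <- as.matrix(x)
  specs <- apply(x, 2, function(col) {
    stats::spec.pgram(col, taper = 0, plot = FALSE, detrend = FALSE)$spec
  })
  freq <- stats::spec.pgram(x[, 1], taper = 0, plot = FALSE,
                            detrend = FALSE)$freq * fs
  list(freq = freq, power = rowMeans(as.matrix(specs)))
}

# small, quickly separable binary corpus for training tests
tiny_binary_corpus <- function(n_subjects = 2, clip_s = 60, seed = 7) {
  generate_corpus(synth_spec(n_subjects = n_subjects, clip_s = clip_s,
                             classes = c(1L, -1L), seed = seed))
}
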