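#' Default class-conditional band-power effects
#'
#' Emotion classes are encoded as band-limited oscillations added on top of
#' the 1/f background: positive clips get a theta (4-8 Hz) boost over the
#' frontal midline (Fz, Cz, AF3, AF4), negative clips a beta (13-30 Hz)
#' boost over frontal electrodes, and neutral clips no boost. The topography
#' follows the frontal-midline theta / frontal beta effects reported for
#' liked and disliked music; amplitudes are conventions chosen to give a
#' clearly separable corpus, not measurements.
#'
#' @return Named list (`"1"`, `"-1"`, `"0"`) of lists of effects, each with
#'   `band` (Hz), `channels` (electrode labels) and `gain` (oscillation RMS
#'   as a multiple of the background standard deviation).
#' @export
default_class_effects <- function() {
  list(
    "1"  = list(list(band = c(4, 8),  gain = 1,
                     channels = c("Fz", "Cz", "AF3", "AF4"))),
    "-1" = list(list(band = c(13, 30), gain = 1,
                     channels = c("Fp1", "Fp2", "F3", "F4", "F7", "F8"))),
    "0"  = list())
}

#' Specification of a synthetic EEG corpus
#'
#' Describes a balanced music-listening corpus: `n_subjects` subjects each
#' contribute `clips_per_class` one-minute clips per emotion class, recorded
#' on a 32-channel montage at 128 Hz. Each channel is Gaussian 1/f^`exponent`
#' background noise (standard deviation `bg_sd` uV) plus the class-conditional
#' oscillations of `class_effects`, with phases drawn independently per
#' subject-by-clip. Defaults mirror a 32-subject, 12-clip protocol.
#'
#' @param n_subjects Number of subjects.
#' @param clips_per_class Clips per emotion class per subject.
#' @param clip_s Clip duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param montage Electrode labels.
#' @param classes Labels to generate (subset of `-1, 0, 1`).
#' @param class_effects See [default_class_effects()].
#' @param noise_exponent Spectral slope of the background (power ~ 1/f^exp).
#' @param snr Global multiplier on every effect gain; oscillation RMS on an
#'   affected channel is `gain * snr * bg_sd`.
#' @param bg_sd Background standard deviation, uV.
#' @param seed Integer seed; the corpus is a pure function of this spec.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_subjects = 32, clips_per_class = 4, clip_s = 60,
                       fs = 128, montage = canonical_montage(),
                       classes = c(1L, -1L, 0L),
                       class_effects = default_class_effects(),
                       noise_exponent = 1, snr = 1, bg_sd = 10, seed = 1L) {
  nyq <- fs / 2
  for (lbl in names(class_effects)) {
    for (eff in class_effects[[lbl]]) {
      if (eff$band[1] <= 0 || eff$band[2] >= nyq || eff$band[1] >= eff$band[2]) {
        stop_stteeg(sprintf("Effect band [%g, %g] must lie within (0, %g)",
                            eff$band[1], eff$band[2], nyq),
                    "stteeg_spec_error")
      }
      if (eff$gain < 0) stop_stteeg("Effect gains must be >= 0", "stteeg_spec_error")
      if (anyNA(match(montage_key(eff$channels), montage_key(montage)))) {
        stop_stteeg("Effect channel not in montage", "stteeg_spec_error")
      }
    }
  }
  if (clip_s <= 0 || n_subjects < 1 || clips_per_class < 1) {
    stop_stteeg("Corpus dimensions must be positive", "stteeg_spec_error")
  }
  structure(list(n_subjects = n_subjects, clips_per_class = clips_per_class,
                 clip_s = clip_s, fs = fs, montage = montage,
                 classes = as.integer(classes), class_effects = class_effects,
                 noise_exponent = noise_exponent, snr = snr, bg_sd = bg_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Gaussian background with power spectrum ~ 1/f^exponent, unit variance,
# shaped in the frequency domain.
onef_noise <- function(n, fs, exponent) {
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n %/% 2 + 1)]
  amp <- c(0, freqs[-1]^(-exponent / 2))          # drop DC
  re <- rnorm(length(amp)); im <- rnorm(length(amp))
  half <- complex(real = re, imaginary = im) * amp
  spec <- c(half, Conj(rev(half[2:(length(half) - (n %% 2 == 0))])))
  x <- Re(fft(spec, inverse = TRUE)) / length(spec)
  as.numeric(x / sd(x))
}

# Band-limited oscillation with target RMS: sum of k equally spaced
# sinusoids across the band, shared phase set across channels of one effect.
band_oscillation <- function(n, fs, band, rms, k = 8) {
  t <- seq_len(n) / fs
  f <- seq(band[1], band[2], length.out = k)
  ph <- runif(k, 0, 2 * pi)
  a <- rms * sqrt(2 / k)                          # k sines, RMS a*sqrt(k/2)
  rowSums(vapply(seq_len(k), function(i) a * sin(2 * pi * f[i] * t + ph[i]),
                 numeric(n)))
}

#' Generate a synthetic EEG corpus
#'
#' One recording per subject-by-clip, in deterministic order (subjects, then
#' classes as listed in the spec, then clips), so identical specs give
#' bit-identical corpora.
#'
#' @param spec A [synth_spec()].
#' @return Corpus tibble: `subject_id`, `clip_id`, `label`, and `recording`,
#'   a list-column of [eeg_recording()] objects.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- as.integer(round(spec$clip_s * spec$fs))
  nch <- length(spec$montage)
  withr::with_seed(spec$seed, {
    rows <- list()
    for (s in seq_len(spec$n_subjects)) {
      for (lbl in spec$classes) {
        effects <- spec$class_effects[[as.character(lbl)]] %||% list()
        for (cl in seq_len(spec$clips_per_class)) {
          x <- vapply(seq_len(nch), function(i)
            spec$bg_sd * onef_noise(n, spec$fs, spec$noise_exponent),
            numeric(n))
          for (eff in effects) {
            osc <- band_oscillation(n, spec$fs, eff$band,
                                    rms = eff$gain * spec$snr * spec$bg_sd)
            ch <- match(montage_key(eff$channels), montage_key(spec$montage))
            x[, ch] <- x[, ch] + osc
          }
          rec <- eeg_recording(
            x, spec$fs, lbl,
            subject_id = sprintf("s%02d", s),
            clip_id = sprintf("%s_c%d", class_tag(lbl), cl),
            montage = spec$montage)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            subject_id = rec$subject_id, clip_id = rec$clip_id,
            label = rec$label, recording = list(rec))
        }
      }
    }
    purrr::list_rbind(rows)
  })
}

class_tag <- function(label) {
  c("-1" = "neg", "0" = "neu", "1" = "pos")[as.character(label)]
}

#' Mean band power of a recording
#'
#' Welch-averaged periodogram power, averaged over a frequency band and a
#' channel subset. Fixed estimator settings: Hann windows of `nperseg`
#' samples with 50% overlap.
#'
#' @param rec An [eeg_recording()].
#' @param band Two-element frequency band in Hz, inside `(0, fs/2)`.
#' @param channels Electrode labels to average over (default: all).
#' @param nperseg Welch segment length in samples.
#' @return Mean power density over the band and channels (uV^2/Hz scale).
#' @export
band_power <- function(rec, band, channels = rec$montage, nperseg = 512) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!length(channels)) {
    stop_stteeg("Empty channel subset", "stteeg_input_error")
  }
  if (band[1] < 0 || band[2] > rec$fs / 2 || band[1] >= band[2]) {
    stop_stteeg("Band must lie within (0, fs/2)", "stteeg_input_error")
  }
  ch <- match(montage_key(channels), montage_key(rec$montage))
  if (anyNA(ch)) {
    stop_stteeg("Unknown channel in subset", "stteeg_montage_error")
  }
  pw <- vapply(ch, function(i) {
    w <- welch_psd(rec$samples[, i], rec$fs, nperseg)
    sel <- w$freq >= band[1] & w$freq <= band[2]
    mean(w$power[sel])
  }, numeric(1))
  mean(pw)
}

# Welch PSD: Hann window, 50% overlap, one-sided density.
welch_psd <- function(x, fs, nperseg = 512) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / nperseg)
  u <- sum(w^2)
  nfreq <- nperseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)] * w
    p <- Mod(fft(seg))^2 / (fs * u)
    acc <- acc + p[seq_len(nfreq)]
  }
  power <- acc / length(starts)
  if (nperseg %% 2 == 0) {
    power[2:(nfreq - 1)] <- 2 * power[2:(nfreq - 1)]
  } else {
    power[2:nfreq] <- 2 * power[2:nfreq]
  }
  list(freq = seq(0, fs / 2, length.out = nfreq), power = power)
}

#' Write a corpus to disk with a JSON manifest
#'
#' One file per recording (`csv` or `edf`) plus `manifest.json` recording the
#' sampling rate, montage, labels and per-file metadata, in the same layout
#' [load_corpus()] reads.
#'
#' @param corpus Corpus tibble from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"edf"`.
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_stteeg(paste0("Cannot create output directory: ", dir),
                "stteeg_input_error")
  }
  entries <- purrr::pmap(corpus, function(subject_id, clip_id, label, recording) {
    fname <- sprintf("%s_%s.%s", subject_id, clip_id, format)
    path <- file.path(dir, fname)
    if (format == "csv") {
      write_recording_csv(recording, path)
    } else {
      write_edf(recording$samples, recording$fs, recording$montage, path)
    }
    list(file = fname, subject_id = subject_id, clip_id = clip_id,
         label = label)
  })
  rec1 <- corpus$recording[[1]]
  manifest <- list(fs = rec1$fs, montage = rec1$montage, format = format,
                   recordings = entries)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}

#' Load a corpus written by [write_corpus()]
#'
#' @param dir Directory containing `manifest.json` and the recording files.
#' @return Corpus tibble (see [generate_corpus()]).
#' @export
load_corpus <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop_stteeg(paste0("No manifest.json in ", dir), "stteeg_input_error")
  }
  m <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  montage <- unlist(m$montage)
  purrr::list_rbind(purrr::map(m$recordings, function(e) {
    rec <- read_recording(file.path(dir, e$file), expected_montage = montage,
                          fs = m$fs, label = as.integer(e$label),
                          subject_id = e$subject_id, clip_id = e$clip_id)
    tibble::tibble(subject_id = rec$subject_id, clip_id = rec$clip_id,
                   label = rec$label, recording = list(rec))
  }))
}
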