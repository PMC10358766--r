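test_that("delimited input is read and reordered to the canonical montage", {
  mont <- canonical_montage()
  df <- as.data.frame(matrix(seq_len(640 * 32) %% 97, 640, 32))
  names(df) <- rev(mont)                      # shuffled header
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)

  rec <- read_recording(path, fs = 128)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(dim(rec$samples), c(640L, 32L))
  expect_equal(nrow(rec$samples) / rec$fs, 5)
  # reordering is a permutation: per-channel means survive, mapped by name
  expect_equal(colMeans(rec$samples),
               rev(colMeans(as.matrix(df))),
               ignore_attr = TRUE)
  expect_equal(sort(colMeans(rec$samples)),
               sort(unname(colMeans(as.matrix(df)))))
})

test_that("montage errors: missing, unknown and duplicate channels", {
  mont <- canonical_montage()
  df <- as.data.frame(matrix(rnorm(64 * 31), 64, 31))
  names(df) <- setdiff(mont, "Oz")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path, fs = 128), class = "stteeg_montage_error")
  expect_error(read_recording(path, fs = 128), "Oz")

  expect_error(match_montage(c(mont[-1], "Bogus")),
               class = "stteeg_montage_error")
  expect_error(match_montage(c(mont, "FP1")),      # duplicate of Fp1 by case
               class = "stteeg_montage_error")
  # FC2 is an accepted alias for the montage's literal "FC"
  hdr <- mont
  hdr[hdr == "FC"] <- "FC2"
  expect_equal(match_montage(hdr), seq_len(32))
})

test_that("EDF round trip preserves sinusoid RMS to the 16-bit grid", {
  amps <- seq(2, 64, by = 2)
  rec <- sine_recording(amps, freqs = rep(c(5, 10, 20, 40), 8), dur_s = 4)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec$samples, rec$fs, rec$montage, path)

  back <- read_recording(path)
  expect_equal(back$fs, 128)
  rms <- sqrt(colMeans(back$samples^2))
  # closed form: RMS of a sine of amplitude A is A / sqrt(2)
  expected <- amps[(seq_len(32) - 1) %% length(amps) + 1] / sqrt(2)
  expect_equal(rms, expected, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("non-numeric payload raises a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(canonical_montage(), collapse = ","),
               paste(c("a", rep("1", 31)), collapse = ",")), path)
  expect_error(read_recording(path, fs = 128))
})

test_that("epoch grid: counts, starts and the circular wrap rule", {
  # 240 s at 4-s windows with 50% overlap -> exactly 120 epochs
  rec <- eeg_recording(matrix(rnorm(240 * 128 * 32), ncol = 32), 128, 1L)
  ep <- epoch_recording(rec, window_s = 4, overlap_frac = 0.5)
  expect_equal(nrow(ep), 120L)
  expect_true(all(vapply(ep$samples, nrow, 1L) == 512L))

  # brute-force enumeration oracle: starts on the stride grid over [0, T)
  rec10 <- eeg_recording(matrix(seq_len(10 * 16 * 32), ncol = 32), 16, 0L)
  ep10 <- epoch_recording(rec10, window_s = 2, overlap_frac = 0)
  oracle_starts <- seq(0, 10 - 1e-9, by = 2)[seq_len(10 %/% 2)]
  expect_equal(ep10$start_s, oracle_starts)
  expect_equal(nrow(ep10), 5L)

  # 4-s recording, 4-s window, 50% overlap: one whole + one wrapped epoch
  rec4 <- eeg_recording(matrix(seq_len(4 * 128 * 32), ncol = 32), 128, 1L)
  ep4 <- epoch_recording(rec4, 4, 0.5)
  expect_equal(nrow(ep4), 2L)
  wrapped <- ep4$samples[[2]]
  expect_equal(wrapped[1:256, ], rec4$samples[257:512, ])   # tail of source
  expect_equal(wrapped[257:512, ], rec4$samples[1:256, ])   # wraps to start

  expect_error(epoch_recording(rec4, window_s = 8),
               class = "stteeg_input_error")
})

test_that("epoch count equals T / stride whenever stride divides T", {
  for (trial in list(c(60, 4, 0.5), c(60, 4, 0), c(12, 2, 0.5), c(30, 3, 2/3))) {
    T_s <- trial[1]; w <- trial[2]; ov <- trial[3]
    rec <- eeg_recording(matrix(rnorm(T_s * 16 * 32), ncol = 32), 16, 1L)
    ep <- epoch_recording(rec, w, ov)
    stride <- w * (1 - ov)
    expect_equal(nrow(ep), T_s / stride)
  }
})

test_that("non-overlapping epochs concatenate back to the source exactly", {
  rec <- eeg_recording(matrix(rnorm(8 * 32 * 32), ncol = 32), 32, 1L)
  ep <- epoch_recording(rec, window_s = 2, overlap_frac = 0)
  expect_identical(do.call(rbind, ep$samples), rec$samples)
})

test_that("grouping partitions per stratum, drops leftovers, warns on none", {
  g15 <- group_epochs(toy_epochs(120), G = 8)
  expect_equal(nrow(g15), 15L)
  expect_true(all(vapply(g15$epochs, function(a) dim(a)[3], 1L) == 8L))

  expect_warning(
    expect_error(group_epochs(toy_epochs(7), G = 8),
                 class = "stteeg_input_error"),
    "dropped")

  # 17 epochs -> 2 groups made of the 16 earliest starts (brute-force oracle)
  ep17 <- toy_epochs(17)[sample(17), ]
  g2 <- group_epochs(ep17, G = 8)
  expect_equal(nrow(g2), 2L)
  used_starts <- sort(unlist(lapply(g2$epochs, function(a) unique(a[1, 1, ]))))
  expect_equal(used_starts, as.numeric(0:15))

  # strata kept apart: labels never mix inside one group
  mixed <- dplyr::bind_rows(toy_epochs(16, label = 1L),
                            toy_epochs(16, label = -1L))
  gm <- group_epochs(mixed, G = 8)
  expect_equal(sort(gm$label), c(-1L, -1L, 1L, 1L))

  # seed shuffles group order only
  a <- group_epochs(toy_epochs(32), G = 8, seed = 1)
  b <- group_epochs(toy_epochs(32), G = 8, seed = 2)
  expect_setequal(
    vapply(a$epochs, function(x) x[1, 1, 1], 1),
    vapply(b$epochs, function(x) x[1, 1, 1], 1))
})

test_that("corpus round trip through csv + manifest preserves everything", {
  corpus <- generate_corpus(synth_spec(n_subjects = 1, clips_per_class = 1,
                                       clip_s = 2, seed = 3))
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir, format = "csv")
  back <- load_corpus(dir)
  expect_equal(nrow(back), 3L)
  expect_equal(back$label, corpus$label)
  expect_equal(back$recording[[1]]$samples, corpus$recording[[1]]$samples,
               tolerance = 1e-6)
})
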