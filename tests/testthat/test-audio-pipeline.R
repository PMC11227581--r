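test_that("resampling preserves duration and spectral content", {
  w <- waveform(sin(2 * pi * 1000 * (0:47999) / 48000), 48000)
  r <- resample_waveform(w, 24000)
  expect_equal(r$rate, 24000)
  expect_length(r$samples, 24000)
  # 0.6 s at 48 kHz -> 14400 samples at 24 kHz
  w06 <- waveform(rnorm(28800), 48000)
  expect_length(resample_waveform(w06, 24000)$samples, 14400)
  # identity when rates agree
  expect_identical(resample_waveform(w, 48000)$samples, w$samples)
  # dominant FFT peak stays at 1 kHz
  sp <- abs(fft(r$samples))[1:12000]
  expect_equal(which.max(sp) - 1, 1000, tolerance = 2)
  expect_error(resample_waveform(w, -1), "positive")
})

test_that("energy VAD finds the voiced interval and scales invariantly", {
  rate <- 8000
  x <- numeric(3 * rate)
  idx <- (rate + 1):(2 * rate)            # tone on [1, 2) s
  x[idx] <- sin(2 * pi * 440 * seq_along(idx) / rate)
  w <- waveform(x, rate)
  seg <- detect_voice_segments(w, frame_s = 0.02, energy_quantile = 0.5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_s, 1, tolerance = 0.02)
  expect_equal(seg$end_s, 2, tolerance = 0.02)
  # silence -> nothing
  expect_equal(nrow(detect_voice_segments(waveform(numeric(800), 8000))), 0)
  # amplitude scaling leaves the segmentation unchanged
  seg2 <- detect_voice_segments(waveform(0.01 * x, rate), 0.02, 0.5)
  expect_equal(seg, seg2)
  # intervals are sorted and disjoint
  noisy <- waveform(rnorm(3 * rate) * rep(c(0.01, 1), each = rate / 2), rate)
  s3 <- detect_voice_segments(noisy)
  if (nrow(s3) > 1) {
    expect_true(all(diff(s3$start_s) > 0))
    expect_true(all(s3$end_s[-nrow(s3)] <= s3$start_s[-1]))
  }
})

test_that("dominant-speaker rule picks counts, then duration, then name", {
  seg <- function(sp, s, e) data.frame(speaker = sp, start_s = s, end_s = e)
  s1 <- do.call(rbind, list(seg("A", 0, 1), seg("A", 2, 3), seg("A", 4, 5),
                            seg("B", 6, 7)))
  expect_equal(select_sonographer(s1), "A")
  expect_equal(select_sonographer(seg("Z", 0, 1)), "Z")
  # equal counts -> duration breaks the tie
  s2 <- rbind(seg("A", 0, 2.5), seg("A", 3, 5.5), seg("B", 6, 7.5),
              seg("B", 8, 9.5))
  expect_equal(select_sonographer(s2), "A")
  # full tie -> lexicographic
  s3 <- rbind(seg("b", 0, 1), seg("a", 2, 3))
  expect_equal(select_sonographer(s3), "a")
  expect_error(select_sonographer(data.frame()), "empty")
})

test_that("log-spectrograms are exactly 256x256 with correct band mapping", {
  w <- waveform(sin(2 * pi * 6000 * (0:14399) / 24000), 24000)
  sp <- log_spectrogram(w)
  expect_identical(dim(sp$values), c(256L, 256L))
  # 6 kHz on a 0-12 kHz axis of 256 bands -> band 128 (0-based) = row 129
  expect_equal(which.max(rowMeans(sp$values)), 129)
  expect_equal(sp$freq_hz[129], 6000)
  # silence maps to log(1+0) = 0 everywhere
  z <- log_spectrogram(waveform(numeric(14400), 24000))
  expect_true(all(z$values == 0))
  # duration jitter still yields 256x256
  for (dur in c(0.55, 0.58, 0.65)) {
    wj <- waveform(rnorm(round(dur * 24000)), 24000)
    expect_identical(dim(log_spectrogram(wj)$values), c(256L, 256L))
  }
  expect_error(log_spectrogram(waveform(rnorm(100), 24000)), "window")
})

test_that("keyword selection flags tokens by dictionary membership", {
  dict <- keyword_dictionary(c("heart", "femur"))
  segs <- data.frame(start_s = c(0, 2, 4), end_s = c(1, 3, 5),
                     speaker = "s")
  segs$tokens <- I(list(c("this", "is", "the", "Heart"),
                        c("how", "are", "you"),
                        character(0)))
  out <- select_keyword_segments(segs, dict)
  expect_identical(out$is_anatomy, c(TRUE, FALSE, FALSE))
  # idempotent
  expect_identical(select_keyword_segments(out, dict), out)
})

test_that("keyword dictionaries load from one-term-per-line files", {
  f <- tempfile()
  writeLines(c("Heart", "femur", "", "LIPS"), f)
  d <- read_keyword_dictionary(f)
  expect_setequal(d$terms, c("heart", "femur", "lips"))
  unlink(f)
})

test_that("audio windows are half-open, zero-padded 0.6 s slices", {
  w <- waveform(seq(0, 1, length.out = 24000 * 2), 24000)
  aw <- audio_window(w, t = 1, half = 0.3)
  expect_length(aw$samples, 14400)
  expect_equal(aw$samples[1], w$samples[round(0.7 * 24000) + 1])
  # off the start: padded with zeros
  aw0 <- audio_window(w, t = 0.1, half = 0.3)
  expect_length(aw0$samples, 14400)
  expect_true(all(aw0$samples[1:100] == 0))
})
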