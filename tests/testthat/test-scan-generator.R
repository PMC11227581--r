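test_that("generation is deterministic and dimensioned by the config", {
  cfg <- scan_config(duration_s = 10, fps = 6, seed = 9)
  r1 <- generate_scan(cfg)
  r2 <- generate_scan(cfg)
  expect_identical(r1, r2)
  expect_length(r1$frames, 60)
  expect_length(r1$waveform$samples, round(10 * cfg$sample_rate))
  expect_true(all(abs(vapply(r1$gaze_maps, sum, numeric(1)) - 1) < 1e-6))
})

test_that("clean configs emit only in-vocabulary tokens with aligned keywords", {
  cfg <- scan_config(duration_s = 25, p_offtopic = 0, p_invalid_token = 0,
                     seed = 4)
  rec <- generate_scan(cfg)
  tokens <- unlist(rec$segments$tokens)
  expect_true(all(tokens %in% c(filler_words, cfg$anatomy_vocab)))
  # every event narrated, keyword within +/- 0.3 s of the event interval
  mids <- (rec$segments$start_s + rec$segments$end_s) / 2
  for (ev in rec$events) {
    hit <- vapply(seq_len(nrow(rec$segments)), function(i)
      ev$keyword %in% rec$segments$tokens[[i]] &&
        mids[i] >= ev$t_start - 0.3 && mids[i] <= ev$t_end + 0.3,
      logical(1))
    expect_true(any(hit))
  }
})

test_that("plane labels match the covering event, else background", {
  rec <- tiny_scans()[[1]]
  fps <- rec$config$fps
  bg <- rec$config$n_anatomy_classes + 1L
  for (i in seq_along(rec$frames)) {
    t <- (i - 1) / fps
    cov <- Filter(function(ev) t >= ev$t_start && t < ev$t_end, rec$events)
    expected <- if (length(cov) > 0) cov[[1]]$anatomy_id else bg
    expect_identical(rec$plane_labels[i], expected)
  }
})

test_that("rendered frames have class-specific bright shapes on dark noise", {
  fr <- render_frame(3, c(32, 32), 64, noise_sigma = 0, seed = 1)
  expect_true(all(fr$image[!fr$region_mask] == 0))
  expect_true(all(fr$image >= 0 & fr$image <= 1))
  fr2 <- render_frame(5, c(32, 32), 64, noise_sigma = 0, seed = 1)
  expect_false(isTRUE(all.equal(fr$image[fr$region_mask | fr2$region_mask],
                                fr2$image[fr$region_mask | fr2$region_mask])))
  # contrast holds under noise (Monte-Carlo over renders)
  contrast <- replicate(100, {
    f <- render_frame(sample(1:13, 1), c(32, 32), 64, noise_sigma = 0.1)
    mean(f$image[f$region_mask]) > mean(f$image[!f$region_mask])
  })
  expect_true(all(contrast))
  expect_error(render_frame(1, c(80, 10), 64), "outside")
})

test_that("gaze maps are normalised Gaussians peaked at the mask centroid", {
  mask <- matrix(FALSE, 64, 64)
  mask[20:28, 30:40] <- TRUE
  g <- make_gaze_map(mask, sigma_px = 5)
  expect_equal(sum(g), 1, tolerance = 1e-9)
  peak <- which(g == max(g), arr.ind = TRUE)[1, ]
  idx <- which(mask, arr.ind = TRUE)
  expect_equal(unname(peak), c(round(mean(idx[, 1])), round(mean(idx[, 2]))))
  # very wide sigma approaches uniform
  gu <- make_gaze_map(mask, sigma_px = 10 * 64)
  expect_lt(max(gu) / min(gu), 1.5)
  expect_error(make_gaze_map(matrix(FALSE, 8, 8), 2), "empty")
})

test_that("scan directories round-trip transcripts and audio", {
  dir <- withr::local_tempdir()
  rec <- generate_scan(scan_config(duration_s = 6, seed = 2))
  write_scan(rec, dir, write_gaze = FALSE)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(file.path(dir, "frames")), length(rec$frames))
  w <- read_wav(file.path(dir, "audio.wav"))
  expect_equal(w$rate, rec$waveform$rate)
  expect_lt(max(abs(w$samples - rec$waveform$samples)), 1e-4)  # PCM16 quantisation
  tr <- read_transcript(file.path(dir, "transcript.jsonl"))
  expect_equal(nrow(tr), nrow(rec$segments))
  expect_identical(tr$tokens[[1]], rec$segments$tokens[[1]])
})

test_that("configs with too few keywords are rejected", {
  expect_error(scan_config(n_anatomy_classes = 5, anatomy_vocab = c("a", "b")),
               "keyword")
})
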