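test_that("positive pairs use the co-timed 0.6 s window", {
  scans <- tiny_scans()
  pairs <- sample_pairs(scans, 50, p_negative = 0, seed = 1)
  for (ex in pairs) {
    expect_identical(ex$label, 1L)
    expect_identical(ex$donor_scan, ex$scan)
    expect_identical(ex$donor_t, ex$t)
  }
  # the realised audio window spans [t - 0.3, t + 0.3)
  w <- scans[[pairs[[1]]$scan]]$waveform
  aw <- audio_window(w, pairs[[1]]$t)
  expect_equal(length(aw$samples) / aw$rate, 0.6, tolerance = 1e-9)
})

test_that("negatives substitute foreign windows and hit the target rate", {
  scans <- tiny_scans()
  pairs <- sample_pairs(scans, 1000, p_negative = 0.5, seed = 3)
  labels <- vapply(pairs, `[[`, integer(1), "label")
  frac_neg <- mean(labels == 0)
  expect_gte(frac_neg, 0.45)
  expect_lte(frac_neg, 0.55)
  for (ex in pairs) {
    if (ex$label == 0L) {
      expect_true(ex$donor_scan != ex$scan || abs(ex$donor_t - ex$t) >= 5)
    }
  }
  # single short scan with negatives requested must fail
  short <- generate_scan(scan_config(duration_s = 6, seed = 5))
  expect_error(sample_pairs(list(short), 10, p_negative = 0.5), "negatives")
})

test_that("pair sampling is deterministic under a fixed seed", {
  scans <- tiny_scans()
  expect_identical(sample_pairs(scans, 30, 0.5, seed = 11),
                   sample_pairs(scans, 30, 0.5, seed = 11))
})

test_that("one epoch of pretraining runs, logs, and checkpoints", {
  scans <- tiny_scans()
  mc <- model_config(embed_dim = 8, widths = c(2, 4, 4), head_hidden = 4,
                     gate_hidden = 2, text_embed_dim = 8)
  pr <- pretrain(scans, "full", mc, epochs = 1, n_pairs = 24,
                 batch_size = 12, lr = 0.01, heldout_scans = 2,
                 polish_epochs = 0, seed = 7)
  expect_s3_class(pr, "pretrain_result")
  expect_equal(nrow(pr$log), 1)
  expect_true(is.finite(pr$log$loss))
  expect_true(pr$log$heldout_acc >= 0 && pr$log$heldout_acc <= 1)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(pr, f)
  m2 <- load_checkpoint(f)
  expect_s3_class(m2, "sonossl_model")
  unlink(f)
})

test_that("training reduces the loss and is seed-deterministic", {
  scans <- tiny_scans()
  mc <- model_config(embed_dim = 8, widths = c(2, 4, 4), head_hidden = 4,
                     gate_hidden = 2, text_embed_dim = 8)
  run <- function() pretrain(scans, "contrastive", mc, epochs = 6,
                             n_pairs = 48, batch_size = 16, lr = 0.02,
                             polish_epochs = 0, seed = 3)
  pr1 <- run()
  expect_lt(pr1$log$loss[6], pr1$log$loss[1])
  pr2 <- run()
  expect_equal(pr1$log$loss, pr2$log$loss, tolerance = 1e-6)
})

test_that("each variant trains end to end for one epoch", {
  scans <- tiny_scans()
  mc <- model_config(embed_dim = 8, widths = c(2, 4, 4), head_hidden = 4,
                     gate_hidden = 2, text_embed_dim = 8)
  for (v in c("base", "contrastive", "spatial", "text")) {
    pr <- pretrain(scans, v, mc, epochs = 1, n_pairs = 16, batch_size = 8,
                   lr = 0.01, polish_epochs = 0, seed = 1)
    expect_true(is.finite(pr$log$loss), info = v)
  }
})
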