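test_that("correspondence loss matches hand-computed values", {
  # maximum-entropy prediction
  expect_equal(loss_base(rep(0.5, 8), rep(c(1, 0), 4)), log(2),
               tolerance = 1e-9)
  # perfect prediction tends to zero (under clamping)
  expect_lt(loss_base(c(1, 0), c(1, 0)), 1e-9)
  # N = 2 hand evaluation: -(log 0.8 + log 0.7)/2
  expect_equal(loss_base(c(0.8, 0.3), c(1, 0)),
               -(log(0.8) + log(0.7)) / 2, tolerance = 1e-9)
  expect_equal(loss_base(c(0.8, 0.3), c(1, 0)), 0.2899092, tolerance = 1e-6)
  expect_gte(loss_base(runif(10), rbinom(10, 1, 0.5)), 0)
  expect_error(loss_base(c(1.2, 0.5), c(1, 0)), "0, 1")
})

test_that("contrastive loss handles literal and infonce forms", {
  # raw scores s11 = s22 = 1, s12 = s21 = 0, exponentiated
  S <- exp(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(loss_contrastive(S, "literal"), -1, tolerance = 1e-9)
  expect_equal(loss_contrastive(S, "infonce"), log(1 + exp(-1)),
               tolerance = 1e-9)
  # uniform similarities -> ln N
  for (n in c(2, 5, 9)) {
    expect_equal(loss_contrastive(matrix(1, n, n), "infonce"), log(n),
                 tolerance = 1e-9)
  }
  # strictly decreasing in the diagonal entry
  S2 <- matrix(exp(runif(16)), 4, 4)
  l0 <- loss_contrastive(S2, "infonce")
  S2[1, 1] <- S2[1, 1] * 1.1
  expect_lt(loss_contrastive(S2, "infonce"), l0)
  expect_error(loss_contrastive(matrix(1, 1, 1)), "2 samples")
})

test_that("similarity matrices are exponentiated cosines", {
  set.seed(3)
  v <- matrix(rnorm(8 * 3), 8, 3)
  a <- matrix(rnorm(8 * 3), 8, 3)
  S <- similarity_matrix(v, a, tau = 0.1)
  expect_true(all(S$values > 0))
  cos11 <- sum(v[, 1] * a[, 1]) / sqrt(sum(v[, 1]^2) * sum(a[, 1]^2))
  expect_equal(S$values[1, 1], exp(cos11 / 0.1), tolerance = 1e-9)
})

test_that("concat fusion yields probabilities and flags dim mismatches", {
  m <- tiny_model()
  D <- m$config$embed_dim
  set.seed(1)
  p <- fuse_concat(m, rnorm(D), rnorm(D))
  expect_true(p > 0 && p < 1)
  # zero head weights -> exactly 0.5
  m0 <- m
  m0$params$head_va <- lapply(m$params$head_va, function(x) x * 0)
  expect_equal(fuse_concat(m0, rnorm(D), rnorm(D)), 0.5, tolerance = 1e-15)
  expect_error(fuse_concat(m, rnorm(D + 1), rnorm(D + 1)), "mismatch")
})

test_that("spatial response map equals the explicit-loop oracle", {
  # tiny hand case: a = (1, 0); cells (1,0),(0,1),(2,0),(0,3)
  vmap <- array(0, c(2, 2, 2))
  vmap[1, 1, ] <- c(1, 0); vmap[1, 2, ] <- c(0, 1)
  vmap[2, 1, ] <- c(2, 0); vmap[2, 2, ] <- c(0, 3)
  expect_equal(spatial_response(vmap, c(1, 0)),
               matrix(c(1, 2, 0, 0), 2, 2), tolerance = 1e-12)
  # zero audio vector -> all-zero response
  expect_true(all(spatial_response(vmap, c(0, 0)) == 0))
  # random instances against a double loop
  set.seed(8)
  for (rep in 1:5) {
    vm <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
    a <- rnorm(6)
    oracle <- matrix(0, 4, 4)
    for (h in 1:4) for (w in 1:4) oracle[h, w] <- sum(vm[h, w, ] * a)
    expect_lt(max(abs(spatial_response(vm, a) - oracle)), 1e-6)
  }
})

test_that("spatial objective decomposes into its two terms", {
  m <- tiny_model()
  D <- m$config$embed_dim
  set.seed(2)
  maps <- lapply(1:4, function(i) array(rnorm(4 * 4 * D), c(4, 4, D)))
  avecs <- matrix(rnorm(D * 4), D, 4)
  labels <- c(1, 0, 1, 0)
  so <- spatial_objective(m, maps, avecs, labels)
  expect_equal(so$loss, so$loss_base + so$loss_contrastive, tolerance = 1e-12)
  p <- vapply(1:4, function(i) fuse_spatial(m, maps[[i]], avecs[, i])$p,
              numeric(1))
  expect_equal(so$loss_base, loss_base(p, labels), tolerance = 1e-12)
  # zero audio vectors -> all sims equal -> contrastive term is ln N
  so0 <- spatial_objective(m, maps, avecs * 0, labels)
  expect_equal(so0$loss_contrastive, log(4), tolerance = 1e-9)
})

test_that("joint loss is the weighted sum of its four components", {
  m <- tiny_model()
  D <- m$config$embed_dim
  set.seed(4)
  batch <- list(video = matrix(rnorm(D * 5), D, 5),
                audio = matrix(rnorm(D * 5), D, 5),
                text = matrix(rnorm(D * 5), D, 5),
                text_empty = rep(FALSE, 5),
                labels = c(1, 0, 1, 1, 0))
  jl <- joint_loss(m, batch, objective_weights())
  manual <- 0.25 * loss_base(fuse_concat(m, batch$video, batch$audio, "va"),
                             batch$labels) +
    0.25 * loss_base(fuse_concat(m, batch$video, batch$text, "vt"),
                     batch$labels) +
    0.25 * loss_contrastive(similarity_matrix(batch$video, batch$audio,
                                              m$config$tau)) +
    0.25 * loss_contrastive(similarity_matrix(batch$video, batch$text,
                                              m$config$tau))
  expect_equal(jl$loss, manual, tolerance = 1e-9)
  # degenerate weights select a single term
  jl_a <- joint_loss(m, batch, objective_weights(1, 0, 0, 0))
  expect_equal(jl_a$loss, jl_a$loss_base_va, tolerance = 1e-12)
  # all-empty text renormalises over the audio terms
  batch2 <- batch
  batch2$text_empty <- rep(TRUE, 5)
  jl2 <- joint_loss(m, batch2, objective_weights())
  expect_equal(jl2$loss, 0.5 * jl2$loss_base_va + 0.5 * jl2$loss_contra_va,
               tolerance = 1e-12)
})

test_that("objective weights must be a convex combination", {
  expect_error(objective_weights(0.5, 0.5, 0.5, 0.5), "sum to 1")
  expect_error(objective_weights(-0.5, 0.5, 0.5, 0.5), "non-negative")
  w <- objective_weights(1, 0, 0, 0)
  expect_equal(w$alpha, 1)
})
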