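test_that("classification report matches hand counts", {
  # pred = (1,1,2,2), true = (1,2,2,2): class-2 precision 1, recall 2/3
  r <- classification_report(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  expect_equal(r$per_class$precision[2], 1.0)
  expect_equal(r$per_class$recall[2], 2 / 3)
  expect_equal(r$per_class$f1[2], 0.8)
  expect_equal(sum(r$confusion), 4)
  # perfect predictions
  rp <- classification_report(c(1, 2, 3), c(1, 2, 3), 3)
  expect_equal(rp$macro_f1, 1)
  expect_equal(rp$accuracy, 1)
  expect_error(classification_report(1:3, 1:2, 3), "mismatch")
  expect_error(classification_report(c(1, 5), c(1, 2), 3), "outside")
})

test_that("classification report agrees with a counting oracle", {
  set.seed(10)
  pred <- sample(1:5, 1000, replace = TRUE)
  true <- sample(1:5, 1000, replace = TRUE)
  r <- classification_report(pred, true, 5)
  for (k in 1:5) {
    tp <- sum(pred == k & true == k)
    expect_equal(r$per_class$precision[k], tp / sum(pred == k))
    expect_equal(r$per_class$recall[k], tp / sum(true == k))
    expect_equal(r$confusion[k, k], tp)
  }
  expect_equal(r$accuracy, mean(pred == true))
})

test_that("saliency metrics satisfy their identity and degenerate cases", {
  set.seed(2)
  g <- matrix(abs(rnorm(64)), 8, 8); g <- g / sum(g)
  id <- saliency_metrics(g, g)
  expect_equal(id$KL, 0, tolerance = 1e-6)
  expect_equal(id$CC, 1, tolerance = 1e-6)
  expect_equal(id$SIM, 1, tolerance = 1e-6)
  # constant prediction: NSS 0, AUC 0.5
  u <- matrix(1 / 64, 8, 8)
  fix <- cbind(c(2, 5), c(3, 7))
  cu <- saliency_metrics(u, g, fixations = fix)
  expect_equal(cu$NSS, 0)
  expect_equal(cu$AUC, 0.5)
  # informative prediction beats uniform at its own fixations
  pk <- g
  mi <- saliency_metrics(pk, g, fixations = which(g > quantile(g, 0.9),
                                                  arr.ind = TRUE))
  expect_gt(mi$AUC, 0.5)
  expect_gt(mi$NSS, 0)
  expect_error(saliency_metrics(u * 2, g), "normalised")
  expect_error(saliency_metrics(u, g, fixations = matrix(0, 0, 2)), "empty")
})

test_that("SIM matches the 2x2 hand example", {
  gt <- matrix(c(0.7, 0.1, 0.1, 0.1), 2, 2)
  pred <- matrix(c(0.4, 0.2, 0.2, 0.2), 2, 2)
  expect_equal(saliency_metrics(pred, gt)$SIM, 0.7, tolerance = 1e-12)
})

test_that("compactness metric matches the worked 4x4 example", {
  pred <- matrix(0, 4, 4)
  pred[1, 1] <- 1; pred[1, 2] <- 1; pred[2, 1] <- 0.4; pred[2, 2] <- 0.4
  ref <- matrix(0, 4, 4)
  ref[1:2, 1:2] <- 1
  cr <- comp_metric(pred, ref, thres = 0.5)
  expect_equal(cr$alpha_S, 0.25)
  expect_equal(cr$alpha_H, 0.125)
  expect_equal(cr$eta_H, 0.5)
  expect_equal(cr$iou, 1)
  expect_equal(cr$comp, 2.0, tolerance = 1e-12)
  # disjoint supports -> comp 0
  ref2 <- matrix(0, 4, 4); ref2[4, 4] <- 1
  expect_equal(comp_metric(pred, ref2)$comp, 0)
  # empty prediction -> undefined flag
  expect_true(comp_metric(matrix(0, 4, 4), ref)$undefined)
})

test_that("compactness rises as the support shrinks at fixed IoU and eta", {
  # both predictions have eta_H = 1 and IoU = 1 against their own support
  small <- matrix(0, 8, 8); small[1:2, 1:2] <- 1
  big <- matrix(0, 8, 8); big[1:4, 1:4] <- 1
  cs <- comp_metric(small, small, thres = 0.5)
  cb <- comp_metric(big, big, thres = 0.5)
  expect_gt(cs$comp, cb$comp)
})

test_that("fractional areas make comp resolution-invariant", {
  pred <- matrix(0, 4, 4); pred[1:2, 1:2] <- c(1, 1, 0.4, 0.4)
  ref <- matrix(0, 4, 4); ref[1:2, 1:2] <- 1
  # nearest-neighbour upsample x2
  up <- function(m) m[rep(1:4, each = 2), rep(1:4, each = 2)]
  c1 <- comp_metric(pred, ref)
  c2 <- comp_metric(up(pred), up(ref))
  expect_equal(c1$comp, c2$comp, tolerance = 1e-12)
  # raw-count mode scales with resolution instead
  c1r <- comp_metric(pred, ref, raw_counts = TRUE)
  c2r <- comp_metric(up(pred), up(ref), raw_counts = TRUE)
  expect_equal(c2r$comp, c1r$comp / 4, tolerance = 1e-12)
})
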