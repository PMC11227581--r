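# The reverse-mode tape is the substrate for every trainable component, so
# its adjoints are checked directly against central finite differences.

ad <- function(name) getFromNamespace(name, "sonossl")

grad_check <- function(build, x0, tol = 1e-5) {
  tape_new <- ad("ad_tape"); const <- ad("ad_const"); back <- ad("ad_backward")
  f <- function(x) {
    tp <- tape_new()
    as.numeric(build(tp, const(tp, x))$value)
  }
  tp <- tape_new()
  nd <- const(tp, x0)
  back(tp, build(tp, nd))
  max(abs(nd$grad - fd_grad(f, x0)))
}

test_that("core op adjoints match finite differences", {
  set.seed(42)
  X <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(6), 2, 3)
  M <- matrix(rnorm(12), 3, 4)
  tape_new <- ad("ad_tape"); const <- ad("ad_const")
  mm <- ad("ad_matmul"); relu <- ad("ad_relu"); mean_all <- ad("ad_mean_all")
  mul <- ad("ad_mul")

  expect_lt(grad_check(function(tp, nd)
    mean_all(tp, relu(tp, mm(tp, const(tp, W), nd))), X), 1e-5)
  expect_lt(grad_check(function(tp, nd)
    mean_all(tp, ad("ad_sigmoid")(tp, nd)), X), 1e-5)
  expect_lt(grad_check(function(tp, nd)
    mean_all(tp, ad("ad_softplus")(tp, nd)), X), 1e-5)
  expect_lt(grad_check(function(tp, nd)
    mean_all(tp, mul(tp, ad("ad_l2norm_cols")(tp, nd), const(tp, M))), X), 1e-5)
  expect_lt(grad_check(function(tp, nd)
    mean_all(tp, mul(tp, ad("ad_softmax_cols")(tp, nd), const(tp, M))), X), 1e-5)
})

test_that("loss op adjoints match finite differences", {
  set.seed(7)
  expect_lt(grad_check(function(tp, nd)
    ad("ad_bce_logits")(tp, nd, c(1, 0, 1, 0)), matrix(rnorm(4), 1, 4)), 1e-5)
  S <- matrix(rnorm(16), 4, 4)
  expect_lt(grad_check(function(tp, nd)
    ad("ad_contrastive")(tp, nd, "infonce"), S), 1e-5)
  expect_lt(grad_check(function(tp, nd)
    ad("ad_contrastive")(tp, nd, "literal"), S), 1e-5)
  Tg <- abs(matrix(rnorm(12), 3, 4))
  Tg <- sweep(Tg, 2, colSums(Tg), "/")
  expect_lt(grad_check(function(tp, nd)
    ad("ad_softmax_xent")(tp, nd, Tg), matrix(rnorm(12), 3, 4)), 1e-5)
})

test_that("convolution and pooling adjoints match finite differences", {
  set.seed(11)
  Xc <- matrix(rnorm(2 * 36 * 2), 2, 72)  # [C=2, 6x6, N=2]
  Wc <- matrix(rnorm(3 * 18) * 0.3, 3, 18)
  bc <- matrix(rnorm(3), 3, 1)
  M2 <- matrix(rnorm(4), 2, 2)
  M3 <- matrix(rnorm(2 * 144 * 2), 2, 288)
  conv <- ad("ad_conv2d"); const <- ad("ad_const")
  mean_all <- ad("ad_mean_all"); relu <- ad("ad_relu"); mul <- ad("ad_mul")

  expect_lt(grad_check(function(tp, nd)
    mean_all(tp, relu(tp, conv(tp, nd, const(tp, Wc), const(tp, bc),
                               6, 6, 2, 3, 2, 1))), Xc), 1e-5)
  expect_lt(grad_check(function(tp, nd)
    mean_all(tp, relu(tp, conv(tp, const(tp, Xc), nd, const(tp, bc),
                               6, 6, 2, 3, 2, 1))), Wc), 1e-5)
  expect_lt(grad_check(function(tp, nd)
    mean_all(tp, mul(tp, ad("ad_gap")(tp, nd, 36, 2), const(tp, M2))), Xc),
    1e-5)
  expect_lt(grad_check(function(tp, nd)
    mean_all(tp, mul(tp, ad("ad_upsample2x")(tp, nd, 6, 6, 2),
                     const(tp, M3))), Xc), 1e-5)
})

test_that("whole-model training gradient matches finite differences", {
  scans <- tiny_scans()
  model <- tiny_model()
  pairs <- sample_pairs(scans, 6, 0.5, seed = 2)
  exs <- getFromNamespace("build_examples", "sonossl")(scans, pairs, model)
  bg <- getFromNamespace("batch_graph", "sonossl")
  wrapp <- getFromNamespace("wrap_params", "sonossl")
  lossfn <- function(m) {
    tp <- ad("ad_tape")()
    pn <- wrapp(tp, m$params)
    res <- bg(tp, pn, m, exs, scans, "full", objective_weights(), "infonce",
              frame_seed = 5)
    list(tp = tp, pn = pn, loss = res$loss)
  }
  g <- lossfn(model)
  ad("ad_backward")(g$tp, g$loss)
  # probe one weight in each major parameter group
  probes <- list(list("video", "blocks", 1L, "w"), list("audio", "merge", "w"),
                 list("text", "proj2", "w"), list("head_sp", "w1"))
  for (pr in probes) {
    i <- 3L
    getp <- function(l) Reduce(function(x, k) x[[k]], pr, l)
    eps <- 1e-5
    bump <- function(d) {
      m <- model
      setp <- function(l, path, v) {
        if (length(path) == 1) { l[[path[[1]]]] <- v; return(l) }
        l[[path[[1]]]] <- setp(l[[path[[1]]]], path[-1], v)
        l
      }
      v <- getp(m$params); v[i] <- v[i] + d
      m$params <- setp(m$params, pr, v)
      m
    }
    fdv <- (as.numeric(lossfn(bump(eps))$loss$value) -
              as.numeric(lossfn(bump(-eps))$loss$value)) / (2 * eps)
    an <- getp(g$pn)$grad[i]
    expect_lt(abs(fdv - an), 1e-4 * max(1, abs(fdv)))
  }
})
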