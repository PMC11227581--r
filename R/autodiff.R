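# Minimal reverse-mode autodiff over numeric matrices.
#
# Nodes live on a tape (creation order = topological order); backward walks the
# tape in reverse accumulating gradients. Values are plain numeric matrices;
# convolutional activations are stored as [C, H*W*N] matrices with spatial dims
# carried by the ops that need them. This is deliberately small: just the ops
# the encoders, fusion heads and objectives require, each with a hand-derived
# adjoint that is checked against finite differences in the test suite.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd$idx <- tape$n
  nd
}

ad_const <- function(tape, value) ad_node(tape, value)
ad_param <- ad_const  # params are ordinary leaves; caller reads $grad after backward

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

#' @keywords internal
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) ad_accum(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(loss)
}

# ---- elementwise / linear algebra ----

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    list(nd$grad %*% t(b$value), crossprod(a$value, nd$grad))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(nd) list(nd$grad, nd$grad))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(nd) list(nd$grad, -nd$grad))
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(nd) {
    list(nd$grad * b$value, nd$grad * a$value)
  })
}

ad_scale <- function(tape, a, s) {  # s: plain scalar
  ad_node(tape, a$value * s, list(a), function(nd) list(nd$grad * s))
}

# add a bias column vector to every column of a matrix
ad_add_bias <- function(tape, a, b) {
  ad_node(tape, a$value + as.vector(b$value), list(a, b), function(nd) {
    list(nd$grad, rowSums(nd$grad))
  })
}

ad_relu <- function(tape, a) {
  ad_node(tape, pmax(a$value, 0), list(a), function(nd) list(nd$grad * (a$value > 0)))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, list(a), function(nd) list(nd$grad * s * (1 - s)))
}

ad_softplus <- function(tape, a) {
  v <- ifelse(a$value > 30, a$value, log1p(exp(pmin(a$value, 30))))
  ad_node(tape, v, list(a), function(nd) list(nd$grad / (1 + exp(-a$value))))
}

ad_mean_all <- function(tape, a) {
  n <- length(a$value)
  ad_node(tape, matrix(mean(a$value)), list(a), function(nd) {
    list(array(as.numeric(nd$grad) / n, dim = dim(a$value) %||% length(a$value)))
  })
}

ad_sum_all <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value)), list(a), function(nd) {
    list(array(as.numeric(nd$grad), dim = dim(a$value) %||% length(a$value)))
  })
}

ad_rowsums <- function(tape, a) {
  ad_node(tape, matrix(rowSums(a$value), ncol = 1), list(a), function(nd) {
    list(matrix(nd$grad, nrow(a$value), ncol(a$value)))
  })
}

ad_select_cols <- function(tape, a, idx) {
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(nd) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    for (k in seq_along(idx)) g[, idx[k]] <- g[, idx[k]] + nd$grad[, k]
    list(g)
  })
}

ad_concat_cols <- function(tape, nodes) {
  if (length(nodes) == 1L) return(nodes[[1L]])
  ncols <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ad_node(tape, do.call(cbind, lapply(nodes, `[[`, "value")), nodes,
          function(nd) {
            lapply(seq_along(nodes), function(j)
              nd$grad[, starts[j]:ends[j], drop = FALSE])
          })
}

# C = t(A) %*% B
ad_crossprod <- function(tape, a, b) {
  ad_node(tape, crossprod(a$value, b$value), list(a, b), function(nd) {
    list(b$value %*% t(nd$grad), a$value %*% nd$grad)
  })
}

ad_reshape <- function(tape, a, nr, nc) {
  ad_node(tape, matrix(a$value, nr, nc), list(a), function(nd) {
    list(matrix(nd$grad, nrow(a$value), ncol(a$value)))
  })
}

ad_concat_rows <- function(tape, a, b) {
  na <- nrow(a$value)
  ad_node(tape, rbind(a$value, b$value), list(a, b), function(nd) {
    list(nd$grad[seq_len(na), , drop = FALSE],
         nd$grad[-seq_len(na), , drop = FALSE])
  })
}

# L2-normalise each column; guard against zero columns
ad_l2norm_cols <- function(tape, a, eps = 1e-12) {
  nrm <- sqrt(colSums(a$value^2) + eps)
  y <- sweep(a$value, 2, nrm, "/")
  ad_node(tape, y, list(a), function(nd) {
    g <- nd$grad
    dots <- colSums(y * g)
    list(sweep(g - sweep(y, 2, dots, "*"), 2, nrm, "/"))
  })
}

# column-wise softmax
ad_softmax_cols <- function(tape, a) {
  z <- sweep(a$value, 2, apply(a$value, 2, max), "-")
  e <- exp(z)
  y <- sweep(e, 2, colSums(e), "/")
  ad_node(tape, y, list(a), function(nd) {
    g <- nd$grad
    list(y * sweep(g, 2, colSums(y * g), "-"))
  })
}

# multiply column j of x by scalar w[j] (w a [L,1] node)
ad_scale_cols <- function(tape, x, w) {
  wv <- as.vector(w$value)
  ad_node(tape, sweep(x$value, 2, wv, "*"), list(x, w), function(nd) {
    list(sweep(nd$grad, 2, wv, "*"),
         matrix(colSums(nd$grad * x$value), ncol = 1))
  })
}

# y = x / s, s a scalar node
ad_div_scalar <- function(tape, x, s) {
  sv <- as.numeric(s$value)
  ad_node(tape, x$value / sv, list(x, s), function(nd) {
    list(nd$grad / sv, matrix(-sum(nd$grad * x$value) / sv^2))
  })
}

# ---- losses ----

# mean binary cross-entropy from logits z (any shape) with labels c in {0,1}:
# mean(softplus(z) - c*z); numerically stable form of -mean(c log p + (1-c) log(1-p))
ad_bce_logits <- function(tape, z, cvec) {
  cvec <- as.vector(cvec)
  zv <- as.vector(z$value)
  sp <- ifelse(zv > 30, zv, log1p(exp(pmin(zv, 30))))
  n <- length(zv)
  ad_node(tape, matrix(mean(sp - cvec * zv)), list(z), function(nd) {
    p <- 1 / (1 + exp(-zv))
    list(matrix((p - cvec) / n * as.numeric(nd$grad),
                nrow(z$value), ncol(z$value)))
  })
}

# InfoNCE / literal contrastive loss from a raw-score matrix S (entry [j,i] is
# the score of video j against audio anchor i, already divided by temperature).
# infonce: mean_i( logsumexp_j S[,i] - S[i,i] )
# literal: mean_i( logsumexp_{j != i} S[,i] - S[i,i] )  (paper-printed form)
ad_contrastive <- function(tape, s, mode = c("infonce", "literal")) {
  mode <- match.arg(mode)
  sv <- s$value
  n <- ncol(sv)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  li <- numeric(n)
  for (i in seq_len(n)) {
    col <- sv[, i]
    denom <- if (mode == "literal") lse(col[-i]) else lse(col)
    li[i] <- denom - col[i]
  }
  ad_node(tape, matrix(mean(li)), list(s), function(nd) {
    g <- matrix(0, n, n)
    for (i in seq_len(n)) {
      col <- sv[, i]
      if (mode == "literal") {
        w <- exp(col - max(col[-i])); w[i] <- 0; w <- w / sum(w)
      } else {
        w <- exp(col - max(col)); w <- w / sum(w)
      }
      g[, i] <- w / n
      g[i, i] <- g[i, i] - 1 / n
    }
    list(g * as.numeric(nd$grad))
  })
}

# mean over columns of cross-entropy between column-softmax(z) and target
# distribution t (columns sum to 1): mean_i( lse(z_i) - sum(t_i * z_i) )
ad_softmax_xent <- function(tape, z, target) {
  zv <- z$value
  n <- ncol(zv)
  mx <- apply(zv, 2, max)
  lse <- mx + log(colSums(exp(sweep(zv, 2, mx, "-"))))
  ad_node(tape, matrix(mean(lse - colSums(target * zv))), list(z), function(nd) {
    e <- exp(sweep(zv, 2, mx, "-"))
    sm <- sweep(e, 2, colSums(e), "/")
    list((sm - target) / n * as.numeric(nd$grad))
  })
}

# ---- convolution / pooling (conv activations: [C, H*W*N] matrices) ----

# 2-D convolution, kernel k, given stride/pad/dilation; x value is [Cin, H*W*N]
ad_conv2d <- function(tape, x, w, b, H, W, N, k, stride, pad, dil = 1L) {
  cin <- nrow(x$value)
  cols <- im2col_nchw(as.numeric(x$value), cin, H, W, N, k, stride, pad, dil)
  out <- w$value %*% cols + as.vector(b$value)
  ad_node(tape, out, list(x, w, b), function(nd) {
    g <- nd$grad
    dcols <- crossprod(w$value, g)
    dx <- col2im_nchw(dcols, cin, H, W, N, k, stride, pad, dil)
    list(matrix(dx, nrow = cin), tcrossprod(g, cols), rowSums(g))
  })
}

conv_out_dim <- function(H, k, stride, pad, dil = 1L) {
  (H + 2L * pad - ((k - 1L) * dil + 1L)) %/% stride + 1L
}

# global average pool: [C, H*W*N] -> [C, N]
ad_gap <- function(tape, x, hw, N) {
  C <- nrow(x$value)
  x3 <- array(x$value, c(C, hw, N))
  y <- colMeans(aperm(x3, c(2, 1, 3)))  # [C, N]
  if (is.null(dim(y))) y <- matrix(y, nrow = C)
  ad_node(tape, y, list(x), function(nd) {
    list(nd$grad[, rep(seq_len(N), each = hw), drop = FALSE] / hw)
  })
}

# nearest-neighbour 2x upsample on [C, H*W*N]
ad_upsample2x <- function(tape, x, H, W, N) {
  C <- nrow(x$value)
  x4 <- array(x$value, c(C, H, W, N))
  y4 <- x4[, rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), , drop = FALSE]
  ad_node(tape, matrix(y4, nrow = C), list(x), function(nd) {
    ds <- avgpool_nchw(as.numeric(nd$grad), C, 2L * H, 2L * W, N, 2L) * 4
    list(matrix(ds, nrow = C))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
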