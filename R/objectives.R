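# Fusion strategies and training objectives.
#
# Correspondence loss: standard negative-mean binary cross-entropy over
# matched/mismatched cross-modal pairs. Contrastive loss: softmax-style loss
# over an exponentiated cosine-similarity matrix, in two forms — "infonce"
# (positive term included in the denominator; bounded below by 0; default)
# and "literal" (positive term excluded, which can go negative). The spatial
# objective pairs the audio vector against every cell of the video feature
# map; the joint loss is the convex combination of the four terms.

#' Objective weights for the joint loss
#'
#' @param alpha,beta,gamma,delta non-negative weights of the video-audio
#'   correspondence, video-text correspondence, video-audio contrastive and
#'   video-text contrastive terms; must sum to 1.
#' @export
objective_weights <- function(alpha = 0.25, beta = 0.25, gamma = 0.25,
                              delta = 0.25) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(w < 0)) stop("objective weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("objective weights must sum to 1 (got ", sum(w), ")")
  }
  structure(as.list(w), class = "objective_weights")
}

#' Correspondence (binary cross-entropy) loss
#'
#' `mean(-(c*log(p) + (1-c)*log(1-p)))`; always non-negative, equals `log(2)`
#' at `p = 0.5`, and tends to 0 as predictions approach the labels.
#'
#' @param p predicted correspondence probabilities in (0, 1).
#' @param c binary labels (0/1).
#' @param clamp probabilities are clamped to `[clamp, 1 - clamp]`.
#' @return scalar loss.
#' @export
loss_base <- function(p, c, clamp = 1e-12) {
  stopifnot(length(p) == length(c), all(c %in% c(0, 1)))
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  p <- pmin(pmax(p, clamp), 1 - clamp)
  -mean(c * log(p) + (1 - c) * log(1 - p))
}

#' Exponentiated-cosine similarity matrix
#'
#' Entry `(j, i)` is `exp(cos(v_j, a_i) / tau)`: the similarity of video
#' feature j against audio anchor i.
#'
#' @param v,a D x N feature matrices (columns are samples).
#' @param tau temperature.
#' @return a `similarity_matrix` (N x N, all entries positive).
#' @export
similarity_matrix <- function(v, a, tau = 0.1) {
  v <- as.matrix(v); a <- as.matrix(a)
  stopifnot(nrow(v) == nrow(a), ncol(v) == ncol(a))
  vn <- sweep(v, 2, sqrt(colSums(v^2) + 1e-12), "/")
  an <- sweep(a, 2, sqrt(colSums(a^2) + 1e-12), "/")
  structure(list(values = exp(crossprod(vn, an) / tau), tau = tau),
            class = "similarity_matrix")
}

#' Cross-modal contrastive loss
#'
#' For each anchor i (column of `S`), the positive is the diagonal entry.
#' `mode = "infonce"` (default) uses `-log(S[i,i] / sum_j S[j,i])`;
#' `mode = "literal"` uses `-log(S[i,i] / sum_{j != i} S[j,i])`, the printed
#' form whose denominator excludes the positive (and which can be negative).
#' The batch loss is the mean over anchors.
#'
#' @param S a [similarity_matrix()] or a positive N x N matrix.
#' @param mode `"infonce"` or `"literal"`.
#' @return scalar loss.
#' @export
loss_contrastive <- function(S, mode = c("infonce", "literal")) {
  mode <- match.arg(mode)
  sv <- if (inherits(S, "similarity_matrix")) S$values else S
  n <- ncol(sv)
  if (n < 2) stop("contrastive loss needs at least 2 samples (no negatives)")
  if (any(sv <= 0)) stop("similarity entries must be positive (exponentiated)")
  li <- vapply(seq_len(n), function(i) {
    denom <- if (mode == "literal") sum(sv[-i, i]) else sum(sv[, i])
    -log(sv[i, i] / denom)
  }, numeric(1))
  mean(li)
}

# head forward on plain matrices (numeric path shared with training via tape)
head_prob <- function(hp, x) {
  h <- pmax(hp$w1 %*% x + as.vector(hp$b1), 0)
  z <- hp$w2 %*% h + hp$w3 %*% x + as.vector(hp$b2)
  as.numeric(1 / (1 + exp(-z)))
}

l2n <- function(x) sweep(x, 2, sqrt(colSums(x^2) + 1e-12), "/")

#' Concatenation fusion (basic strategy)
#'
#' Concatenates the pooled video and audio embeddings and passes them through
#' the model's fully-connected correspondence head to a sigmoid probability.
#'
#' @param model a `sonossl_model`.
#' @param v,a length-D vectors or D x N matrices.
#' @param head which head to use: `"va"` (audio) or `"vt"` (text features).
#' @return probability vector in (0, 1).
#' @export
fuse_concat <- function(model, v, a, head = c("va", "vt")) {
  head <- match.arg(head)
  v <- as.matrix(v); a <- as.matrix(a)
  if (nrow(v) != model$config$embed_dim || nrow(v) != nrow(a)) {
    stop("feature dimension mismatch with model embed_dim")
  }
  hp <- if (head == "va") model$params$head_va else model$params$head_vt
  head_prob(hp, rbind(l2n(v), l2n(a)))
}

#' Spatial response map of an audio vector against a video feature map
#'
#' `response[h, w] = <map[h, w, ], a>`.
#'
#' @param vmap H' x W' x D array (spatial video feature).
#' @param a length-D audio embedding.
#' @return H' x W' matrix.
#' @export
spatial_response <- function(vmap, a) {
  d <- dim(vmap)
  if (length(a) != d[3]) stop("feature dimension mismatch")
  matrix(matrix(vmap, d[1] * d[2], d[3]) %*% a, d[1], d[2])
}

#' Spatial-aware fusion
#'
#' Fuses the audio vector with every cell of the spatial video feature map by
#' element-wise product, giving an H' x W' x D fused tensor; the per-cell
#' channel sums of that tensor are the dot-product response map (exposed for
#' localisation), and its global average pool over cells is the fused
#' D-vector fed through fully-connected layers to a sigmoid correspondence
#' probability.
#'
#' @param model a `sonossl_model`.
#' @param vmap H' x W' x D array from `encode_video(spatial = TRUE)`.
#' @param a length-D audio embedding.
#' @return list with `response_map` (H' x W') and `p` (probability).
#' @export
fuse_spatial <- function(model, vmap, a) {
  resp <- spatial_response(vmap, a)
  d <- dim(vmap)
  cells <- matrix(vmap, d[1] * d[2], d[3])             # rows = cells
  cells <- cells / sqrt(rowSums(cells^2) + 1e-12)
  an <- a / sqrt(sum(a^2) + 1e-12)
  fused <- matrix(colMeans(cells) * an * sqrt(d[3]), ncol = 1)
  p <- head_prob(model$params$head_sp, fused)
  list(response_map = resp, p = p)
}

# mean per-cell cosine between the cells of map_j and vector a_i -- the
# pooled-response raw score used by the spatial contrastive term
spatial_raw_scores <- function(maps, avecs) {
  n <- length(maps)
  an <- sweep(avecs, 2, sqrt(colSums(avecs^2) + 1e-12), "/")
  s <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- dim(maps[[j]])
    cells <- matrix(maps[[j]], d[1] * d[2], d[3])
    cells <- sweep(cells, 1, sqrt(rowSums(cells^2) + 1e-12), "/")
    s[j, ] <- colMeans(cells %*% an)
  }
  s
}

#' Spatial-feature objective
#'
#' Sum of the correspondence loss on spatial-fusion probabilities and the
#' contrastive loss whose raw score for a (video j, audio i) pair is the
#' pooled response of the map cells against the audio vector (mean per-cell
#' cosine, temperature-scaled and exponentiated).
#'
#' @param model a `sonossl_model`.
#' @param maps list of H' x W' x D spatial video features.
#' @param avecs D x N matrix of audio embeddings.
#' @param labels binary correspondence labels.
#' @param mode contrastive mode, see [loss_contrastive()].
#' @return list with `loss`, `loss_base`, `loss_contrastive`.
#' @export
spatial_objective <- function(model, maps, avecs, labels,
                              mode = c("infonce", "literal")) {
  mode <- match.arg(mode)
  avecs <- as.matrix(avecs)
  stopifnot(length(maps) == ncol(avecs), length(labels) == length(maps))
  p <- vapply(seq_along(maps), function(i)
    fuse_spatial(model, maps[[i]], avecs[, i])$p, numeric(1))
  lb <- loss_base(p, labels)
  S <- exp(spatial_raw_scores(maps, avecs) / model$config$tau)
  lc <- loss_contrastive(S, mode)
  list(loss = lb + lc, loss_base = lb, loss_contrastive = lc)
}

#' Joint multi-modal loss
#'
#' `alpha*L_base(V,A) + beta*L_base(V,T) + gamma*L_contra(V,A) +
#' delta*L_contra(V,T)`. Pairs whose gated text feature is flagged empty are
#' excluded from the two text terms; if any are excluded the weights of the
#' active terms are renormalised to sum to 1 (if no pair has text, the text
#' terms are dropped entirely).
#'
#' @param model a `sonossl_model`.
#' @param batch list with `video` (D x N), `audio` (D x N), `labels` (0/1
#'   length N), and optionally `text` (D x N) + `text_empty` (logical N).
#' @param weights an [objective_weights()].
#' @param mode contrastive mode.
#' @return list with `loss` and the four component losses.
#' @export
joint_loss <- function(model, batch, weights = objective_weights(),
                       mode = c("infonce", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(weights, "objective_weights"))
  V <- as.matrix(batch$video); A <- as.matrix(batch$audio)
  cvec <- batch$labels
  tau <- model$config$tau
  l_va <- loss_base(fuse_concat(model, V, A, "va"), cvec)
  c_va <- loss_contrastive(similarity_matrix(V, A, tau), mode)
  has_text <- !is.null(batch$text)
  keep <- if (has_text) which(!batch$text_empty) else integer(0)
  if (length(keep) > 0) {
    Tm <- as.matrix(batch$text)[, keep, drop = FALSE]
    l_vt <- loss_base(fuse_concat(model, V[, keep, drop = FALSE], Tm, "vt"),
                      cvec[keep])
    c_vt <- if (length(keep) >= 2)
      loss_contrastive(similarity_matrix(V[, keep, drop = FALSE], Tm, tau),
                       mode) else NA_real_
    active <- c(TRUE, TRUE, TRUE, length(keep) >= 2)
  } else {
    l_vt <- NA_real_; c_vt <- NA_real_
    active <- c(TRUE, FALSE, TRUE, FALSE)
  }
  w <- c(weights$alpha, weights$beta, weights$gamma, weights$delta)
  terms <- c(l_va, l_vt, c_va, c_vt)
  wa <- w * active
  wa <- wa / sum(wa)
  list(loss = sum(wa * ifelse(active, terms, 0)),
       loss_base_va = l_va, loss_base_vt = l_vt,
       loss_contra_va = c_va, loss_contra_vt = c_vt,
       effective_weights = wa)
}
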