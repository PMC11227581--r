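# Multi-modal encoder model: video, audio and text branches in a shared
# embedding dimension, plus the fusion heads and task heads.
#
# The video and audio branches share the same architecture (a 4-block strided
# convolutional net, widths 16/32/64/D) but are initialised and optimised with
# disjoint weights. The audio branch takes the 256x256 log-spectrogram and
# mean-pools it 4x at the stem so both branches run on 64x64 inputs. The text
# branch is a fixed word-embedding table (seeded from a vocabulary hash)
# followed by two trainable projection layers; gating over tokens lives in
# sig_filter_outliers()/sig_keyword_spot().
#
# All forward passes are built on the autodiff tape, so the user-facing
# encode_* functions and the training loop share one code path.

#' Model configuration
#'
#' @param embed_dim shared embedding dimension D at the fusion point.
#' @param image_size frame side length the video branch expects.
#' @param widths channel widths of the first three conv blocks (the fourth
#'   block emits `embed_dim` channels).
#' @param text_embed_dim width E of the fixed word-embedding table.
#' @param gate_hidden hidden width of the SIG gate network.
#' @param head_hidden hidden width of the fusion heads.
#' @param tau softmax temperature of the contrastive similarity.
#' @param lambda depression factor for off-dictionary tokens in keyword
#'   spotting (0 = hard selection).
#' @param spec_pool stem pooling factor applied to spectrograms.
#' @param n_plane_classes output classes of the plane-detection head.
#' @param preset `"tiny"` (default, desk scale) or `"paper"` (256->224
#'   centre-crop preprocessing; same block structure, wider input).
#' @return a `sonossl_config` list.
#' @export
model_config <- function(embed_dim = 128, image_size = 64,
                         widths = c(16, 32, 64), text_embed_dim = 64,
                         gate_hidden = 16, head_hidden = 32, tau = 0.1,
                         lambda = 0, spec_pool = 4, n_plane_classes = 14,
                         preset = c("tiny", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") image_size <- 224
  stopifnot(embed_dim >= 2, length(widths) == 3)
  structure(list(embed_dim = as.integer(embed_dim),
                 image_size = as.integer(image_size),
                 widths = as.integer(widths),
                 text_embed_dim = as.integer(text_embed_dim),
                 gate_hidden = as.integer(gate_hidden),
                 head_hidden = as.integer(head_hidden),
                 tau = tau, lambda = lambda,
                 spec_pool = as.integer(spec_pool),
                 n_plane_classes = as.integer(n_plane_classes),
                 preset = preset),
            class = "sonossl_config")
}

he_init <- function(nout, nin, gain = 1) {
  matrix(stats::rnorm(nout * nin, 0, gain * sqrt(2 / nin)), nout, nin)
}

init_conv_stack <- function(in_ch, widths, out_ch) {
  chs <- c(in_ch, widths, out_ch)
  lapply(seq_len(length(chs) - 1L), function(i) {
    list(w = he_init(chs[i + 1L], chs[i] * 9L), b = matrix(0, chs[i + 1L], 1))
  })
}

init_branch <- function(cfg, in_mult = 1L) {
  D <- cfg$embed_dim
  list(blocks = init_conv_stack(1L, cfg$widths, D),
       merge = list(w = he_init(D, D * in_mult), b = matrix(0, D, 1)),
       out = list(w = he_init(D, D), b = matrix(0, D, 1)))
}

# two-layer head with a linear skip path (the skip lets similarity-structured
# inputs reach the logit directly; the hidden path adds nonlinearity)
init_mlp_head <- function(nin, hidden, nout = 1L) {
  list(w1 = he_init(hidden, nin), b1 = matrix(0, hidden, 1),
       w2 = he_init(nout, hidden) * 0.1, b2 = matrix(0, nout, 1),
       w3 = he_init(nout, nin) * 0.1)
}

#' Initialise a multi-modal model
#'
#' @param cfg a [model_config()].
#' @param vocab character vector; the word-embedding table rows (plus a
#'   reserved unk row) are a fixed deterministic function of this vocabulary.
#' @param seed integer seed for the trainable weights.
#' @return a `sonossl_model` list with `$config`, `$vocab` and `$params`.
#' @export
init_model <- function(cfg, vocab, seed = 0L) {
  stopifnot(inherits(cfg, "sonossl_config"), length(vocab) > 0)
  D <- cfg$embed_dim; E <- cfg$text_embed_dim; Hh <- cfg$head_hidden
  params <- local_seed(as.integer(seed), {
    list(
      video = init_branch(cfg, in_mult = 2L),
      audio = init_branch(cfg, in_mult = 1L),
      text = list(proj1 = list(w = he_init(D, E), b = matrix(0, D, 1)),
                  proj2 = list(w = he_init(D, D), b = matrix(0, D, 1)),
                  gate = list(w1 = he_init(cfg$gate_hidden, D),
                              b1 = matrix(0, cfg$gate_hidden, 1),
                              w2 = he_init(1L, cfg$gate_hidden) * 0.1,
                              b2 = matrix(0, 1, 1))),
      head_va = init_mlp_head(2L * D, Hh),
      head_vt = init_mlp_head(2L * D, Hh),
      head_sp = init_mlp_head(D, Hh),
      decoder = init_decoder(cfg),
      spd = list(w = he_init(cfg$n_plane_classes, D) * 0.1,
                 b = matrix(0, cfg$n_plane_classes, 1)))
  })
  structure(list(config = cfg, vocab = vocab,
                 embedding = word_embedding_table(vocab, E),
                 params = params),
            class = "sonossl_model")
}

init_decoder <- function(cfg) {
  # upsample+conv blocks from the 4x4 map back to image resolution
  chs <- c(cfg$embed_dim, 32L, 16L, 8L, 4L)
  dec <- lapply(seq_len(4L), function(i)
    list(w = he_init(chs[i + 1L], chs[i] * 9L), b = matrix(0, chs[i + 1L], 1)))
  dec$final <- list(w = he_init(1L, 4L) * 0.1, b = matrix(0, 1, 1))
  dec
}

#' @export
print.sonossl_model <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, numeric(1)))
  cat(sprintf("<sonossl_model> D=%d, image %dx%d, vocab %d, %d parameters\n",
              x$config$embed_dim, x$config$image_size, x$config$image_size,
              length(x$vocab), np))
  invisible(x)
}

# deterministic per-vocabulary embedding table: seed from a vocabulary hash
word_embedding_table <- function(vocab, E) {
  h <- sum(utf8ToInt(paste(vocab, collapse = "|")) *
             seq_along(utf8ToInt(paste(vocab, collapse = "|")))) %% 2147483647
  tab <- local_seed(as.integer(h), {
    matrix(stats::rnorm((length(vocab) + 1L) * E, 0, 1), E, length(vocab) + 1L)
  })
  colnames(tab) <- c(vocab, "<unk>")
  tab
}

# ---- tape graph builders (internal) ----

wrap_params <- function(tape, p) {
  if (is.matrix(p)) return(ad_param(tape, p))
  lapply(p, function(q) wrap_params(tape, q))
}

collect_grads <- function(np) {
  if (is.environment(np)) return(np$grad %||% 0)
  lapply(np, collect_grads)
}

# four stride-2 blocks (64 px input -> 4x4 map, stride 16). For dense
# localisation maps the last `n_dense` blocks are evaluated at stride 1 with
# doubling dilation: every 2^n_dense-th position of the dense map coincides
# exactly with the strided features the model was trained with.
conv_stack_graph <- function(tape, blocks, x, H, W, N, n_dense = 0L) {
  L <- length(blocks)
  dil <- 1L
  for (i in seq_along(blocks)) {
    bl <- blocks[[i]]
    if (i > L - n_dense) {
      x <- ad_relu(tape, ad_conv2d(tape, x, bl$w, bl$b, H, W, N, 3L, 1L,
                                   dil, dil))
      dil <- dil * 2L
    } else {
      x <- ad_relu(tape, ad_conv2d(tape, x, bl$w, bl$b, H, W, N, 3L, 2L, 1L))
      H <- conv_out_dim(H, 3L, 2L, 1L); W <- conv_out_dim(W, 3L, 2L, 1L)
    }
  }
  list(x = x, H = H, W = W)
}

# video branch: input matrix [1, S*S*(2N)] with the two frames of example j in
# columns-of-samples 2j-1, 2j; returns spatial map [D, hw*N] and pooled [D, N]
video_graph <- function(tape, vp, x_node, side, N, dense = FALSE) {
  st <- conv_stack_graph(tape, vp$blocks, x_node, side, side, 2L * N,
                         n_dense = if (dense) 2L else 0L)
  hw <- st$H * st$W
  idx_all <- matrix(seq_len(hw * 2L * N), nrow = hw)  # column = one frame
  f1 <- as.vector(idx_all[, 2L * seq_len(N) - 1L])
  f2 <- as.vector(idx_all[, 2L * seq_len(N)])
  cat2 <- ad_concat_rows(tape, ad_select_cols(tape, st$x, f1),
                         ad_select_cols(tape, st$x, f2))
  map <- ad_conv2d(tape, cat2, vp$merge$w, vp$merge$b, st$H, st$W, N, 1L, 1L, 0L)
  vec <- ad_add_bias(tape, ad_matmul(tape, vp$out$w, ad_gap(tape, map, hw, N)),
                     vp$out$b)
  list(map = map, vec = vec, H = st$H, W = st$W, hw = hw)
}

# audio branch: input [1, side*side*N] (already stem-pooled spectrograms)
audio_graph <- function(tape, ap, x_node, side, N) {
  st <- conv_stack_graph(tape, ap$blocks, x_node, side, side, N)
  hw <- st$H * st$W
  map <- ad_conv2d(tape, st$x, ap$merge$w, ap$merge$b, st$H, st$W, N, 1L, 1L, 0L)
  vec <- ad_add_bias(tape, ad_matmul(tape, ap$out$w, ad_gap(tape, map, hw, N)),
                     ap$out$b)
  list(map = map, vec = vec, H = st$H, W = st$W, hw = hw)
}

# project token embeddings E->D through the two text projection layers
text_project_graph <- function(tape, tp, emb_node) {
  h <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, tp$proj1$w, emb_node),
                                 tp$proj1$b))
  ad_add_bias(tape, ad_matmul(tape, tp$proj2$w, h), tp$proj2$b)
}

# per-token gate weights (softplus, strictly positive before masking)
gate_graph <- function(tape, gp, proj_node) {
  h <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, gp$w1, proj_node),
                                 gp$b1))
  raw <- ad_add_bias(tape, ad_matmul(tape, gp$w2, h), gp$b2)
  ad_softplus(tape, raw)  # [1, L]
}

mlp_head_graph <- function(tape, hp, x) {
  h <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, hp$w1, x), hp$b1))
  ad_add_bias(tape,
              ad_add(tape, ad_matmul(tape, hp$w2, h),
                     ad_matmul(tape, hp$w3, x)),
              hp$b2)  # logits [1, N]
}

# stack a list of images/matrices into the [C=1, H*W*N] input layout
stack_images <- function(imgs) {
  matrix(unlist(imgs, use.names = FALSE), nrow = 1)
}

# integer translation with zero padding (training-time augmentation)
shift_image <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# randomly shift each frame by up to max_px in both axes (uses current RNG)
augment_frames <- function(frames, max_px = 12L) {
  lapply(frames, function(f)
    shift_image(f, sample(-max_px:max_px, 1), sample(-max_px:max_px, 1)))
}

#' Visual preprocessing for a frame
#'
#' In the `"paper"` preset the frame is bilinearly rescaled to 256 x 256 and
#' centre-cropped to 224 x 224; the `"tiny"` desk preset passes frames
#' through unchanged.
#'
#' @param frame grayscale matrix.
#' @param preset `"tiny"` or `"paper"`.
#' @return processed matrix.
#' @export
preprocess_frame <- function(frame, preset = c("tiny", "paper")) {
  preset <- match.arg(preset)
  if (preset == "tiny") return(frame)
  scaled <- bilinear_upsample(frame, 256L)
  off <- (256L - 224L) %/% 2L
  scaled[off + seq_len(224L), off + seq_len(224L)]
}

# pool a 256x256 spectrogram to the encoder input resolution
pool_spectrogram <- function(values, f) {
  n <- nrow(values)
  matrix(avgpool_nchw(as.numeric(values), 1L, n, ncol(values), 1L, as.integer(f)),
         n %/% f, ncol(values) %/% f)
}

# ---- user-facing encoders ----

#' Encode a video clip
#'
#' Samples 2 frames uniformly at random from the clip (deterministic under
#' `seed`), encodes each through the shared video conv stack, concatenates
#' the two feature maps channel-wise, and merges them with a 1x1 conv.
#'
#' @param model a `sonossl_model`.
#' @param clip list of at least 2 grayscale frame matrices of the configured
#'   size.
#' @param spatial if `TRUE` return the H' x W' x D spatial feature map (the
#'   feature before the final pooling); otherwise the pooled length-D vector.
#' @param seed optional seed for frame sampling.
#' @param dense evaluate the last two conv blocks at stride 1 (with dilated
#'   kernels), quadrupling the spatial resolution of the returned map for
#'   localisation; every 4th map position equals the strided features
#'   exactly.
#' @return numeric vector (length D) or 3-D array \[H', W', D\].
#' @export
encode_video <- function(model, clip, spatial = FALSE, seed = NULL,
                         dense = FALSE) {
  stopifnot(inherits(model, "sonossl_model"))
  if (length(clip) < 2) stop("clip must contain at least 2 frames")
  pick <- if (is.null(seed)) sort(sample.int(length(clip), 2L))
          else local_seed(seed, sort(sample.int(length(clip), 2L)))
  sz <- model$config$image_size
  stopifnot(all(vapply(clip[pick], function(f)
    all(dim(f) == c(sz, sz)), logical(1))))
  tape <- ad_tape()
  vp <- wrap_params(tape, model$params$video)
  x <- ad_const(tape, stack_images(clip[pick]))
  vg <- video_graph(tape, vp, x, sz, 1L, dense = dense && spatial)
  if (spatial) {
    arr <- array(vg$map$value, c(model$config$embed_dim, vg$H, vg$W))
    structure(aperm(arr, c(2, 3, 1)), stride = sz %/% vg$H)
  } else {
    as.numeric(vg$vec$value)
  }
}

#' Encode a log-spectrogram
#'
#' @param model a `sonossl_model`.
#' @param spec a `spectrogram` (256 x 256) or a bare matrix.
#' @return pooled length-D embedding vector.
#' @export
encode_audio <- function(model, spec) {
  vals <- if (inherits(spec, "spectrogram")) spec$values else spec
  if (!is.matrix(vals) || nrow(vals) != 256 || ncol(vals) != 256) {
    stop("encode_audio expects a 256x256 spectrogram")
  }
  pooled <- pool_spectrogram(vals, model$config$spec_pool)
  tape <- ad_tape()
  ap <- wrap_params(tape, model$params$audio)
  ag <- audio_graph(tape, ap, ad_const(tape, stack_images(list(pooled))),
                    nrow(pooled), 1L)
  as.numeric(ag$vec$value)
}

#' Embed a token sequence
#'
#' Looks each token up in the model's fixed word-embedding table;
#' out-of-vocabulary tokens map to the reserved unk row and are flagged.
#'
#' @param model a `sonossl_model`.
#' @param tokens non-empty character vector.
#' @return list with `embeddings` (E x L matrix), `unk_mask` (logical L),
#'   `tokens`.
#' @export
embed_text <- function(model, tokens) {
  if (length(tokens) == 0) stop("empty token list")
  tl <- tolower(tokens)
  hit <- match(tl, model$vocab)
  unk <- is.na(hit)
  hit[unk] <- length(model$vocab) + 1L
  list(embeddings = model$embedding[, hit, drop = FALSE],
       unk_mask = unk, tokens = tokens)
}
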