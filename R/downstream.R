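# Downstream transfer tasks: standard plane detection (SPD), eye-gaze
# saliency prediction, and audio-guided anatomy localisation.

# labelled-frame table from scans: one row per frame
frame_table <- function(scans, idx = seq_along(scans)) {
  do.call(rbind, lapply(idx, function(s) data.frame(
    scan = s, frame = seq_along(scans[[s]]$frames),
    label = scans[[s]]$plane_labels)))
}

# balanced subsample: cap per-class count so background does not dominate
balance_frames <- function(tab, per_class, seed) {
  local_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$label), function(ix) {
      if (length(ix) > per_class) sample(ix, per_class) else ix
    }))
    tab[sort(keep), , drop = FALSE]
  })
}

# build the duplicated-frame video input for a set of (scan, frame) rows;
# augment = random translation (training only)
spd_batch_input <- function(scans, tab, rows, augment = FALSE) {
  frames <- unlist(lapply(rows, function(r)
    rep(scans[[tab$scan[r]]]$frames[tab$frame[r]], 2L)), recursive = FALSE)
  if (augment) frames <- augment_frames(frames)
  stack_images(frames)
}

#' Fine-tune a pretrained model for standard plane detection
#'
#' Replaces the task head with an `n_plane_classes`-way linear classifier on
#' the pooled video feature and fine-tunes the video branch and head with
#' momentum SGD on softmax cross-entropy. Single frames are duplicated
#' through the 2-frame clip sampler. Fold assignment is by scan, never by
#' frame.
#'
#' @param model a `sonossl_model` (pretrained or freshly initialised for the
#'   random-init control arm).
#' @param scans labelled scans.
#' @param train_scans,val_scans scan indices for the two folds.
#' @param epochs,lr,batch_size,momentum optimiser settings.
#' @param per_class training frames retained per class (balances background).
#' @param seed RNG seed.
#' @return an `spd_classifier`: `model` (fine-tuned), `report` (validation
#'   [classification_report()]), `log`.
#' @export
finetune_spd <- function(model, scans, train_scans, val_scans, epochs = 10,
                         lr = 0.01, batch_size = 40, momentum = 0.9,
                         per_class = 40, seed = 0L) {
  stopifnot(inherits(model, "sonossl_model"))
  nc <- model$config$n_plane_classes
  tab <- frame_table(scans, train_scans)
  if (any(tab$label < 1 | tab$label > nc)) stop("plane label outside 1..", nc)
  tab <- balance_frames(tab, per_class, seed = (seed * 3L + 1L) %% 100000L)
  sz <- model$config$image_size
  vel <- list(video = zeros_like(model$params$video),
              spd = zeros_like(model$params$spd))
  log <- data.frame()
  for (epoch in seq_len(epochs)) {
    ord <- local_seed((seed * 11L + epoch) %% 100000L, sample.int(nrow(tab)))
    losses <- c()
    for (b in seq_len(ceiling(nrow(tab) / batch_size))) {
      rows <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, nrow(tab))]
      if (length(rows) < 2) next
      tape <- ad_tape()
      vp <- wrap_params(tape, model$params$video)
      hp <- wrap_params(tape, model$params$spd)
      xin <- local_seed((seed * 7L + epoch * 61L + b) %% 100000L,
                        spd_batch_input(scans, tab, rows, augment = TRUE))
      vg <- video_graph(tape, vp, ad_const(tape, xin), sz, length(rows))
      z <- ad_add_bias(tape, ad_matmul(tape, hp$w, vg$vec), hp$b)
      onehot <- matrix(0, nc, length(rows))
      onehot[cbind(tab$label[rows], seq_along(rows))] <- 1
      loss <- ad_softmax_xent(tape, z, onehot)
      if (!is.finite(loss$value)) stop("SPD fine-tuning diverged")
      ad_backward(tape, loss)
      st <- sgd_momentum_update(model$params$video, collect_grads(vp),
                                vel$video, lr, momentum)
      model$params$video <- st$p; vel$video <- st$v
      st <- sgd_momentum_update(model$params$spd, collect_grads(hp),
                                vel$spd, lr * HEAD_LR_MULT, momentum)
      model$params$spd <- st$p; vel$spd <- st$v
      losses <- c(losses, as.numeric(loss$value))
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = mean(losses)))
  }
  val <- predict_spd(model, scans, val_scans,
                     seed = (seed * 13L + 5L) %% 100000L)
  structure(list(model = model,
                 report = classification_report(val$pred, val$true, nc),
                 predictions = val, log = log),
            class = "spd_classifier")
}

#' Predict plane labels for the frames of the given scans
#'
#' @param model a `sonossl_model` with a trained SPD head.
#' @param scans scan list.
#' @param idx scan indices to predict.
#' @param per_class cap on frames per class drawn for evaluation.
#' @param seed RNG seed for the frame subsample.
#' @return data.frame with `scan`, `frame`, `true`, `pred` and class
#'   probability columns `prob_1..prob_K`.
#' @export
predict_spd <- function(model, scans, idx, per_class = 30, seed = 0L) {
  nc <- model$config$n_plane_classes
  tab <- balance_frames(frame_table(scans, idx), per_class, seed)
  sz <- model$config$image_size
  probs <- matrix(0, nrow(tab), nc)
  bs <- 40L
  for (b in seq_len(ceiling(nrow(tab) / bs))) {
    rows <- ((b - 1L) * bs + 1L):min(b * bs, nrow(tab))
    tape <- ad_tape()
    vp <- wrap_params(tape, model$params$video)
    vg <- video_graph(tape, vp,
                      ad_const(tape, spd_batch_input(scans, tab, rows)),
                      sz, length(rows))
    z <- model$params$spd$w %*% vg$vec$value + as.vector(model$params$spd$b)
    e <- exp(sweep(z, 2, apply(z, 2, max), "-"))
    probs[rows, ] <- t(sweep(e, 2, colSums(e), "/"))
  }
  out <- data.frame(scan = tab$scan, frame = tab$frame, true = tab$label,
                    pred = max.col(probs))
  colnames(probs) <- paste0("prob_", seq_len(nc))
  cbind(out, probs)
}

# decoder graph: spatial map [D, hw*N] at side s -> per-pixel logits
decoder_graph <- function(tape, dp, map, side, N) {
  x <- map; H <- side
  for (i in 1:4) {
    x <- ad_upsample2x(tape, x, H, H, N); H <- 2L * H
    x <- ad_relu(tape, ad_conv2d(tape, x, dp[[i]]$w, dp[[i]]$b,
                                 H, H, N, 3L, 1L, 1L))
  }
  ad_conv2d(tape, x, dp$final$w, dp$final$b, H, H, N, 1L, 1L, 0L)  # [1, H*H*N]
}

#' Fine-tune for eye-gaze saliency prediction
#'
#' Attaches an upsampling decoder to the spatial video feature, softmaxes the
#' per-pixel logits so every prediction is a distribution, and trains with
#' the KL objective against the ground-truth gaze maps.
#'
#' @param model a `sonossl_model`.
#' @param scans scans with normalised gaze maps.
#' @param train_scans,val_scans fold indices (by scan).
#' @param n_frames training frames sampled per epoch.
#' @param epochs,lr,batch_size,momentum optimiser settings.
#' @param seed RNG seed.
#' @return a `saliency_regressor`: `model`, `log`, `val_kl` (held-out mean
#'   KL), `baseline_kl` (KL of predicting the mean training map).
#' @export
finetune_saliency <- function(model, scans, train_scans, val_scans,
                              n_frames = 120, epochs = 8, lr = 0.01,
                              batch_size = 20, momentum = 0.9, seed = 0L) {
  for (s in val_scans) {
    sums <- vapply(scans[[s]]$gaze_maps, sum, numeric(1))
    if (any(abs(sums - 1) > 1e-6)) stop("gaze maps must be normalised")
  }
  sz <- model$config$image_size
  tab <- frame_table(scans, train_scans)
  vel <- list(video = zeros_like(model$params$video),
              decoder = zeros_like(model$params$decoder))
  log <- data.frame()
  for (epoch in seq_len(epochs)) {
    rows <- local_seed((seed * 19L + epoch) %% 100000L,
                       sample.int(nrow(tab), min(n_frames, nrow(tab))))
    losses <- c()
    for (b in seq_len(ceiling(length(rows) / batch_size))) {
      rws <- rows[((b - 1L) * batch_size + 1L):min(b * batch_size, length(rows))]
      if (length(rws) < 2) next
      N <- length(rws)
      tape <- ad_tape()
      vp <- wrap_params(tape, model$params$video)
      dp <- wrap_params(tape, model$params$decoder)
      vg <- video_graph(tape, vp,
                        ad_const(tape, spd_batch_input(scans, tab, rws)), sz, N)
      zl <- decoder_graph(tape, dp, vg$map, vg$H, N)
      gt <- vapply(rws, function(r)
        as.vector(scans[[tab$scan[r]]]$gaze_maps[[tab$frame[r]]]),
        numeric(sz * sz))
      loss <- ad_softmax_xent(tape, ad_reshape(tape, zl, sz * sz, N), gt)
      if (!is.finite(loss$value)) stop("saliency fine-tuning diverged")
      ad_backward(tape, loss)
      st <- sgd_momentum_update(model$params$video, collect_grads(vp),
                                vel$video, lr, momentum)
      model$params$video <- st$p; vel$video <- st$v
      st <- sgd_momentum_update(model$params$decoder, collect_grads(dp),
                                vel$decoder, lr, momentum)
      model$params$decoder <- st$p; vel$decoder <- st$v
      losses <- c(losses, as.numeric(loss$value))
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = mean(losses)))
  }
  # held-out KL vs the mean-training-map baseline
  vtab <- balance_frames(frame_table(scans, val_scans), 20,
                         (seed * 29L + 3L) %% 100000L)
  mean_map <- Reduce(`+`, lapply(sample(seq_len(nrow(tab)),
                                        min(100, nrow(tab))), function(r)
    scans[[tab$scan[r]]]$gaze_maps[[tab$frame[r]]]))
  mean_map <- mean_map / sum(mean_map)
  kls <- vapply(seq_len(nrow(vtab)), function(r) {
    gtm <- scans[[vtab$scan[r]]]$gaze_maps[[vtab$frame[r]]]
    pm <- predict_saliency(model, scans[[vtab$scan[r]]]$frames[[vtab$frame[r]]])
    c(saliency_metrics(pm, gtm)$KL, saliency_metrics(mean_map, gtm)$KL)
  }, numeric(2))
  structure(list(model = model, log = log, val_kl = mean(kls[1, ]),
                 baseline_kl = mean(kls[2, ])),
            class = "saliency_regressor")
}

#' Predict a saliency map for one frame
#'
#' @param model a `sonossl_model` with a trained decoder.
#' @param frame grayscale matrix of the configured image size.
#' @return non-negative matrix summing to 1.
#' @export
predict_saliency <- function(model, frame) {
  sz <- model$config$image_size
  tape <- ad_tape()
  vp <- wrap_params(tape, model$params$video)
  dp <- wrap_params(tape, model$params$decoder)
  vg <- video_graph(tape, vp, ad_const(tape, stack_images(list(frame, frame))),
                    sz, 1L)
  zl <- decoder_graph(tape, dp, vg$map, vg$H, 1L)
  z <- matrix(zl$value, sz, sz)
  e <- exp(z - max(z))
  e / sum(e)
}

# bilinear upsampling of a small matrix to (n x n)
bilinear_upsample <- function(m, n) {
  src <- nrow(m)
  # cell-centre alignment
  pos <- (seq_len(n) - 0.5) * src / n + 0.5
  i0 <- pmin(pmax(floor(pos), 1), src)
  i1 <- pmin(i0 + 1, src)
  fr <- pmin(pmax(pos - i0, 0), 1)
  rows <- m[i0, , drop = FALSE] * (1 - fr) + m[i1, , drop = FALSE] * fr
  rows[, i0, drop = FALSE] %*% diag(1 - fr, n) +
    rows[, i1, drop = FALSE] %*% diag(fr, n)
}

#' Audio-guided anatomy localisation
#'
#' Computes the spatial response map of the audio embedding against the video
#' feature map, bilinearly upsamples it to frame resolution and min-max
#' normalises it. Inference is text-free: only the video and audio branch
#' weights are consulted.
#'
#' @param model a `sonossl_model` pretrained with spatial fusion.
#' @param clip list of frames (>= 2).
#' @param audio a `spectrogram`, a 256x256 matrix, or a [waveform] (0.6 s)
#'   which is converted via [log_spectrogram()].
#' @param seed frame-sampling seed.
#' @return a `localisation_map`: `values` (image-size matrix in \[0,1\]),
#'   `response_map` (raw H' x W' responses).
#' @export
localise_from_audio <- function(model, clip, audio, seed = 0L) {
  if (inherits(audio, "waveform")) audio <- log_spectrogram(audio)
  a <- encode_audio(model, audio)
  vmap <- encode_video(model, clip, spatial = TRUE, seed = seed, dense = TRUE)
  resp <- spatial_response(vmap, a)
  up <- bilinear_upsample(resp, model$config$image_size)
  rng <- range(up)
  vals <- if (diff(rng) < 1e-12) matrix(0, nrow(up), ncol(up))
          else (up - rng[1]) / diff(rng)
  structure(list(values = vals, response_map = resp),
            class = "localisation_map")
}

#' Localisation hit rate over held-out clips
#'
#' Fraction of anatomy events whose localisation-map argmax falls inside the
#' ground-truth region mask, using each event's own audio window.
#'
#' @param model pretrained `sonossl_model` (spatial variant).
#' @param scans held-out scans.
#' @param max_events cap on evaluated events.
#' @param seed RNG seed.
#' @return list with `hit_rate`, `n`.
#' @export
localisation_hit_rate <- function(model, scans, max_events = 60, seed = 0L) {
  hits <- logical(0)
  for (si in seq_along(scans)) {
    sc <- scans[[si]]
    segs <- select_keyword_segments(sc$segments, sc$config$anatomy_vocab)
    for (ei in seq_along(sc$events)) {
      ev <- sc$events[[ei]]
      if (!ev$narrated) next
      mids <- (segs$start_s + segs$end_s) / 2
      ok <- which(segs$is_anatomy & mids >= ev$t_start - 0.3 &
                    mids <= ev$t_end + 0.3)
      if (length(ok) == 0) next
      t <- mids[ok[1]]
      clip <- sc$frames[clip_frame_idx(sc, (ev$t_start + ev$t_end) / 2)]
      loc <- localise_from_audio(model, clip,
                                 audio_window(sc$waveform, t),
                                 seed = (seed + 31L * ei + si) %% 100000L)
      am <- which(loc$values == max(loc$values), arr.ind = TRUE)[1, ]
      hits <- c(hits, sc$events[[ei]]$region_mask[am[1], am[2]])
      if (length(hits) >= max_events) break
    }
    if (length(hits) >= max_events) break
  }
  list(hit_rate = mean(hits), n = length(hits))
}

#' Three-fold cross-validation split by scan
#'
#' @param n_scans number of scans.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list of `k` lists with `train` and `val` scan indices.
#' @export
cv_folds <- function(n_scans, k = 3, seed = 0L) {
  ord <- local_seed(as.integer(seed), sample.int(n_scans))
  fold <- rep(seq_len(k), length.out = n_scans)
  lapply(seq_len(k), function(f)
    list(train = sort(ord[fold != f]), val = sort(ord[fold == f])))
}
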