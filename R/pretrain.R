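# Positive/negative pair construction and the self-supervised training loop.
#
# Anchors are the keyword-selected transcript segments (the output of the
# audio cleaning chain): for a video sample at time t, the corresponding
# audio and text are taken from the 0.6 s window t +/- 0.3 s. Negatives
# substitute the audio/text window of an anchor from a different scan (or,
# with a single scan, the same scan shifted by at least 5 s). Training runs
# plain SGD on the variant-selected objective; all randomness fans out from
# one master seed into named substreams so data, sampling and initialisation
# can be reproduced independently.

PAIR_HALF_WINDOW_S <- 0.3   # audio/text half-window around t
NEG_MIN_SHIFT_S <- 5        # minimum same-scan shift for a negative
HEAD_LR_MULT <- 10          # fusion/task heads train faster than encoders

# anchor times = midpoints of anatomy-keyword segments
scan_anchors <- function(scan) {
  dict <- scan$config$anatomy_vocab
  segs <- select_keyword_segments(scan$segments, dict)
  mids <- (segs$start_s + segs$end_s) / 2
  dur <- length(scan$waveform$samples) / scan$waveform$rate
  keep <- segs$is_anatomy & mids > 1 & mids < dur - 1
  mids[keep]
}

#' Sample positive/negative training pairs from scans
#'
#' @param scans list of `scan_record`s.
#' @param n number of examples.
#' @param p_negative fraction of examples whose audio/text window is
#'   substituted from elsewhere (label 0).
#' @param seed RNG seed.
#' @return list of examples: `scan` (index), `t` (video timestamp),
#'   `donor_scan`, `donor_t` (source of the audio/text window;
#'   `[donor_t - 0.3, donor_t + 0.3)`), `label`.
#' @export
sample_pairs <- function(scans, n, p_negative = 0.5, seed = 0L) {
  anchors <- lapply(scans, scan_anchors)
  usable <- which(vapply(anchors, length, integer(1)) > 0)
  if (length(usable) == 0) stop("no keyword-anchored segments in any scan")
  if (p_negative > 0 && length(usable) < 2) {
    durs <- vapply(scans, function(s)
      length(s$waveform$samples) / s$waveform$rate, numeric(1))
    if (max(durs[usable]) < 2 * NEG_MIN_SHIFT_S) {
      stop("negatives need at least 2 scans or one scan long enough to shift by ",
           NEG_MIN_SHIFT_S, " s")
    }
  }
  local_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      si <- sample(usable, 1)
      t <- sample(anchors[[si]], 1)
      neg <- stats::runif(1) < p_negative
      if (!neg) {
        list(scan = si, t = t, donor_scan = si, donor_t = t, label = 1L)
      } else {
        others <- setdiff(usable, si)
        if (length(others) > 0) {
          dj <- if (length(others) == 1L) others else sample(others, 1)
          dt <- sample(anchors[[dj]], 1)
        } else {
          dj <- si
          far <- anchors[[si]][abs(anchors[[si]] - t) >= NEG_MIN_SHIFT_S]
          dt <- if (length(far) > 0) {
            if (length(far) == 1L) far else sample(far, 1)
          } else {
            dur <- length(scans[[si]]$waveform$samples) / scans[[si]]$waveform$rate
            (t + NEG_MIN_SHIFT_S) %% dur
          }
        }
        list(scan = si, t = t, donor_scan = dj, donor_t = dt, label = 0L)
      }
    })
  })
}

# tokens of donor segments overlapping the donor window
window_tokens <- function(scan, t, half = PAIR_HALF_WINDOW_S) {
  s <- scan$segments
  hit <- s$start_s < t + half & s$end_s > t - half
  unlist(s$tokens[hit], use.names = FALSE)
}

# frame indices of the clip centred at t (at least 2 frames); the clip is
# co-extensive with the 0.6 s audio/text window by default
clip_frame_idx <- function(scan, t, clip_s = 2 * PAIR_HALF_WINDOW_S) {
  fps <- scan$config$fps
  n <- length(scan$frames)
  i0 <- max(1L, floor((t - clip_s / 2) * fps) + 1L)
  i1 <- min(n, ceiling((t + clip_s / 2) * fps))
  if (i1 - i0 < 1L) { i0 <- max(1L, i1 - 1L) }
  i0:i1
}

# materialise model inputs for a list of pairs (spectrograms pooled to the
# encoder stem resolution; text embedded + SIG masks resolved). Anchors
# recur across epochs, so windows can be memoised in `cache`.
build_examples <- function(scans, pairs, model, cache = NULL) {
  cfg <- model$config
  lapply(pairs, function(ex) {
    key <- sprintf("%d|%.4f", ex$donor_scan, ex$donor_t)
    win <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(win)) {
      donor <- scans[[ex$donor_scan]]
      aw <- audio_window(donor$waveform, ex$donor_t, PAIR_HALF_WINDOW_S)
      toks <- window_tokens(donor, ex$donor_t)
      win <- list(
        spec_pooled = pool_spectrogram(log_spectrogram(aw)$values,
                                       cfg$spec_pool),
        text = if (length(toks) > 0) embed_text(model, toks) else NULL)
      if (!is.null(cache)) cache[[key]] <- win
    }
    list(scan = ex$scan, frames = clip_frame_idx(scans[[ex$scan]], ex$t),
         spec_pooled = win$spec_pooled, text = win$text, label = ex$label)
  })
}

sig_mask_for <- function(txt, variant, dict, lambda) {
  if (is.null(txt)) return(numeric(0))
  if (variant == "full") {
    in_dict <- tolower(txt$tokens) %in% dict
    ifelse(txt$unk_mask, 0, ifelse(in_dict, 1, lambda))
  } else {
    as.numeric(!txt$unk_mask)
  }
}

# one differentiable forward over a batch; returns loss node + diagnostics
batch_graph <- function(tape, pn, model, exs, scans, variant, weights, mode,
                        frame_seed, augment = TRUE) {
  cfg <- model$config
  N <- length(exs)
  sz <- cfg$image_size
  labels <- vapply(exs, `[[`, integer(1), "label")

  frames <- local_seed(frame_seed, {
    fr <- unlist(lapply(exs, function(ex) {
      idx <- ex$frames[sort(sample.int(length(ex$frames), 2L))]
      scans[[ex$scan]]$frames[idx]
    }), recursive = FALSE)
    if (augment) augment_frames(fr) else fr
  })
  vx <- ad_const(tape, stack_images(frames))
  vg <- video_graph(tape, pn$video, vx, sz, N)

  ax <- ad_const(tape, stack_images(lapply(exs, `[[`, "spec_pooled")))
  aside <- nrow(exs[[1]]$spec_pooled)
  ag <- audio_graph(tape, pn$audio, ax, aside, N)

  use_text <- variant %in% c("text", "full")
  use_spatial <- variant %in% c("spatial", "full")
  pos <- which(labels == 1L)

  # ---- video-audio correspondence probability ----
  if (use_spatial) {
    # element-wise product of the (unit) audio vector with every (unit) map
    # cell, pooled over cells and rescaled to O(1) head inputs
    mn <- ad_l2norm_cols(tape, vg$map)
    an_all <- ad_l2norm_cols(tape, ag$vec)
    aexp <- ad_node(tape, an_all$value[, rep(seq_len(N), each = vg$hw),
                                       drop = FALSE],
                    list(an_all), function(nd) {
                      g3 <- array(nd$grad, c(cfg$embed_dim, vg$hw, N))
                      list(colMeans(aperm(g3, c(2, 1, 3))) * vg$hw)
                    })
    fused <- ad_scale(tape, ad_gap(tape, ad_mul(tape, mn, aexp), vg$hw, N),
                      sqrt(cfg$embed_dim))
    z_va <- mlp_head_graph(tape, pn$head_sp, fused)
  } else {
    z_va <- mlp_head_graph(tape, pn$head_va,
                           ad_concat_rows(tape, ad_l2norm_cols(tape, vg$vec),
                                          ad_l2norm_cols(tape, ag$vec)))
  }
  l_va <- ad_bce_logits(tape, z_va, labels)

  terms <- list(alpha = l_va)
  wts <- c(alpha = weights$alpha)

  # ---- video-audio contrastive (positives as anchors) ----
  if (variant != "base" && length(pos) >= 2) {
    if (use_spatial) {
      mpos_idx <- as.vector(vapply(pos, function(j)
        (j - 1L) * vg$hw + seq_len(vg$hw), integer(vg$hw)))
      mn <- ad_l2norm_cols(tape, ad_select_cols(tape, vg$map, mpos_idx))
      an <- ad_l2norm_cols(tape, ad_select_cols(tape, ag$vec, pos))
      R <- ad_crossprod(tape, mn, an)               # [hw*P, P]
      P <- length(pos)
      poolm <- matrix(0, P, vg$hw * P)
      for (j in seq_len(P)) poolm[j, (j - 1L) * vg$hw + seq_len(vg$hw)] <- 1 / vg$hw
      S <- ad_matmul(tape, ad_const(tape, poolm), R)  # [P, P] raw scores
    } else {
      vn <- ad_l2norm_cols(tape, ad_select_cols(tape, vg$vec, pos))
      an <- ad_l2norm_cols(tape, ad_select_cols(tape, ag$vec, pos))
      S <- ad_crossprod(tape, vn, an)
    }
    terms$gamma <- ad_contrastive(tape, ad_scale(tape, S, 1 / cfg$tau), mode)
    wts["gamma"] <- weights$gamma
  }

  # ---- text terms ----
  if (use_text) {
    dict <- scans[[1]]$config$anatomy_vocab
    masks <- lapply(exs, function(ex)
      sig_mask_for(ex$text, variant, dict, cfg$lambda))
    keep <- which(vapply(masks, function(m) length(m) > 0 && any(m > 0),
                         logical(1)))
    if (length(keep) > 0) {
      tvecs <- lapply(keep, function(i)
        sig_graph(tape, pn$text, ad_const(tape, exs[[i]]$text$embeddings),
                  masks[[i]])$vec)
      Tm <- ad_concat_cols(tape, tvecs)              # [D, K]
      Vk <- ad_select_cols(tape, vg$vec, keep)
      z_vt <- mlp_head_graph(tape, pn$head_vt,
                             ad_concat_rows(tape, ad_l2norm_cols(tape, Vk),
                                            ad_l2norm_cols(tape, Tm)))
      terms$beta <- ad_bce_logits(tape, z_vt, labels[keep])
      wts["beta"] <- weights$beta
      kp <- keep[labels[keep] == 1L]
      if (length(kp) >= 2) {
        sel <- match(kp, keep)
        Sn <- ad_crossprod(tape,
                           ad_l2norm_cols(tape, ad_select_cols(tape, vg$vec, kp)),
                           ad_l2norm_cols(tape, ad_select_cols(tape, Tm, sel)))
        terms$delta <- ad_contrastive(tape, ad_scale(tape, Sn, 1 / cfg$tau),
                                      mode)
        wts["delta"] <- weights$delta
      }
    }
  }

  wts <- wts / sum(wts)
  loss <- NULL
  for (nm in names(terms)) {
    contrib <- ad_scale(tape, terms[[nm]], wts[[nm]])
    loss <- if (is.null(loss)) contrib else ad_add(tape, loss, contrib)
  }
  list(loss = loss, p_va = as.numeric(1 / (1 + exp(-z_va$value))),
       labels = labels, terms = lapply(terms, function(t) as.numeric(t$value)))
}

sgd_update <- function(params, grads, lr) {
  if (is.matrix(params)) return(params - lr * grads)
  mapply(sgd_update, params, grads, MoreArgs = list(lr = lr), SIMPLIFY = FALSE)
}

# classical momentum: v <- mu*v + g; p <- p - lr*v
sgd_momentum_update <- function(params, grads, vel, lr, mu) {
  if (is.matrix(params)) {
    v <- mu * vel + grads
    return(list(p = params - lr * v, v = v))
  }
  out <- mapply(function(p, g, ve) sgd_momentum_update(p, g, ve, lr, mu),
                params, grads, vel, SIMPLIFY = FALSE)
  list(p = lapply(out, `[[`, "p"), v = lapply(out, `[[`, "v"))
}

zeros_like <- function(params) {
  if (is.matrix(params)) return(params * 0)
  lapply(params, zeros_like)
}

variant_param_names <- function(variant) {
  base <- c("video", "audio", "head_va")
  switch(variant,
         base = base, contrastive = base,
         spatial = c("video", "audio", "head_sp"),
         text = c(base, "text", "head_vt"),
         full = c("video", "audio", "head_sp", "text", "head_vt"))
}

#' Self-supervised pretraining
#'
#' Runs SGD on the objective selected by `variant`: `"base"` (correspondence
#' BCE only), `"contrastive"` (+ cross-modal contrastive), `"spatial"`
#' (spatial-aware fusion + spatial contrastive), `"text"` (+ text terms with
#' outlier-filtering SIG), `"full"` (spatial fusion + keyword-spotting SIG;
#' the complete joint objective). Logs per-epoch training loss and held-out
#' correspondence accuracy; aborts if the loss becomes non-finite.
#'
#' @param scans list of `scan_record`s.
#' @param variant objective variant.
#' @param model_cfg a [model_config()].
#' @param epochs number of epochs.
#' @param n_pairs training examples per epoch list (resampled each epoch from
#'   an epoch-indexed stream).
#' @param batch_size SGD batch size.
#' @param lr initial learning rate; divided by 10 every `lr_decay_every`
#'   epochs.
#' @param lr_decay_every epochs between learning-rate drops.
#' @param weights an [objective_weights()].
#' @param mode contrastive mode.
#' @param heldout_scans indices of scans reserved for evaluation (no training
#'   examples are drawn from them).
#' @param heldout_every evaluate held-out accuracy every this many epochs
#'   (always at the final epoch).
#' @param polish_epochs head-calibration epochs appended after the main loop:
#'   encoders are frozen and only the active correspondence head trains on
#'   the correspondence term, without frame augmentation, so the decision
#'   threshold is calibrated under inference conditions.
#' @param polish_lr learning rate of the calibration phase (dropped 5x for
#'   its final three epochs).
#' @param p_negative negative-pair fraction.
#' @param seed master seed.
#' @param verbose print one line per epoch.
#' @return a `pretrain_result`: `model` (trained), `log` (data.frame with
#'   epoch, lr, loss, heldout_acc), `variant`.
#' @export
pretrain <- function(scans, variant = c("full", "base", "contrastive",
                                        "spatial", "text"),
                     model_cfg = model_config(), epochs = 15, n_pairs = 240,
                     batch_size = 40, lr = 1e-3, lr_decay_every = 20,
                     weights = objective_weights(), mode = "infonce",
                     momentum = 0.9, heldout_scans = integer(0),
                     heldout_every = 1L, polish_epochs = 8L, polish_lr = 0.1,
                     p_negative = 0.5, seed = 0L, verbose = FALSE) {
  variant <- match.arg(variant)
  seed <- as.integer(seed)
  vocab <- unique(c(scans[[1]]$config$anatomy_vocab, filler_words,
                    scans[[1]]$config$distractor_vocab))
  model <- init_model(model_cfg, vocab, seed = (seed * 7L + 1L) %% 100000L)
  train_idx <- setdiff(seq_along(scans), heldout_scans)
  stopifnot(length(train_idx) > 0)
  log <- data.frame()
  upd <- variant_param_names(variant)
  vel <- lapply(model$params[upd], zeros_like)
  win_cache <- new.env(parent = emptyenv())
  for (epoch in seq_len(epochs)) {
    lr_e <- lr / 10^((epoch - 1) %/% lr_decay_every)
    pairs <- sample_pairs(scans[train_idx], n_pairs, p_negative,
                          seed = (seed * 131L + epoch) %% 100000L)
    exs <- build_examples(scans[train_idx], pairs, model, cache = win_cache)
    ord <- local_seed((seed * 17L + epoch) %% 100000L,
                      sample.int(length(exs)))
    losses <- c()
    for (b in seq_len(ceiling(length(exs) / batch_size))) {
      take <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, length(exs))]
      if (length(take) < 4) next
      tape <- ad_tape()
      pn <- wrap_params(tape, model$params)
      res <- batch_graph(tape, pn, model, exs[take], scans[train_idx],
                         variant, weights, mode,
                         frame_seed = (seed * 59L + epoch * 101L + b) %% 100000L)
      if (!is.finite(res$loss$value)) {
        stop("training diverged: non-finite loss at epoch ", epoch)
      }
      ad_backward(tape, res$loss)
      for (nm in upd) {
        lr_g <- if (startsWith(nm, "head_")) lr_e * HEAD_LR_MULT else lr_e
        st <- sgd_momentum_update(model$params[[nm]], collect_grads(pn[[nm]]),
                                  vel[[nm]], lr_g, momentum)
        model$params[[nm]] <- st$p
        vel[[nm]] <- st$v
      }
      losses <- c(losses, as.numeric(res$loss$value))
    }
    acc <- if (length(heldout_scans) > 0 &&
               (epoch %% heldout_every == 0L || epoch == epochs)) {
      evaluate_correspondence(model, scans[heldout_scans], variant,
                              seed = (seed * 23L + 7L) %% 100000L)
    } else NA_real_
    log <- rbind(log, data.frame(epoch = epoch, lr = lr_e,
                                 loss = mean(losses), heldout_acc = acc))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.1e  loss %.4f  heldout %.3f",
                      epoch, lr_e, mean(losses), acc))
    }
  }

  # head-calibration phase: frozen encoders, correspondence term only,
  # no augmentation (matches inference conditions)
  if (polish_epochs > 0L) {
    polish_variant <- if (variant %in% c("spatial", "full")) "spatial"
                      else "base"
    head_nm <- if (polish_variant == "spatial") "head_sp" else "head_va"
    pvel <- zeros_like(model$params[[head_nm]])
    for (pe in seq_len(polish_epochs)) {
      lr_p <- if (pe <= polish_epochs - 3L) polish_lr else polish_lr / 5
      pairs <- sample_pairs(scans[train_idx], n_pairs, p_negative,
                            seed = (seed * 131L + epochs + pe) %% 100000L)
      exs <- build_examples(scans[train_idx], pairs, model, cache = win_cache)
      ord <- local_seed((seed * 17L + epochs + pe) %% 100000L,
                        sample.int(length(exs)))
      losses <- c()
      for (b in seq_len(ceiling(length(exs) / batch_size))) {
        take <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size,
                                                     length(exs))]
        if (length(take) < 4) next
        tape <- ad_tape()
        pn <- wrap_params(tape, model$params)
        res <- batch_graph(tape, pn, model, exs[take], scans[train_idx],
                           polish_variant, objective_weights(1, 0, 0, 0),
                           mode, frame_seed = (seed * 59L +
                             (epochs + pe) * 101L + b) %% 100000L,
                           augment = FALSE)
        if (!is.finite(res$loss$value)) {
          stop("head calibration diverged at polish epoch ", pe)
        }
        ad_backward(tape, res$loss)
        st <- sgd_momentum_update(model$params[[head_nm]],
                                  collect_grads(pn[[head_nm]]),
                                  pvel, lr_p, 0.5)
        model$params[[head_nm]] <- st$p
        pvel <- st$v
        losses <- c(losses, as.numeric(res$loss$value))
      }
      acc <- if (length(heldout_scans) > 0 && pe == polish_epochs) {
        evaluate_correspondence(model, scans[heldout_scans], variant,
                                seed = (seed * 23L + 7L) %% 100000L)
      } else NA_real_
      log <- rbind(log, data.frame(epoch = epochs + pe, lr = lr_p,
                                   loss = mean(losses), heldout_acc = acc))
      if (verbose) {
        message(sprintf("polish %2d  lr %.1e  loss %.4f  heldout %.3f",
                        pe, lr_p, mean(losses), acc))
      }
    }
  }
  structure(list(model = model, log = log, variant = variant, seed = seed),
            class = "pretrain_result")
}

#' @export
print.pretrain_result <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<pretrain_result> variant '%s', %d epochs, final loss %.4f, heldout acc %s\n",
              x$variant, nrow(x$log), last$loss,
              ifelse(is.na(last$heldout_acc), "n/a",
                     sprintf("%.3f", last$heldout_acc))))
  invisible(x)
}

#' Held-out correspondence accuracy
#'
#' Samples balanced pairs from the given scans and scores the fraction where
#' the variant-matched correspondence probability lands on the right side of
#' 0.5.
#'
#' @param model a `sonossl_model`.
#' @param scans evaluation scans.
#' @param variant which head was trained (decides concat vs spatial fusion).
#' @param n_pairs number of evaluation pairs.
#' @param seed RNG seed.
#' @return accuracy in \[0, 1\].
#' @export
evaluate_correspondence <- function(model, scans, variant = "full",
                                    n_pairs = 120, seed = 0L) {
  pairs <- sample_pairs(scans, n_pairs, p_negative = 0.5, seed = seed)
  exs <- build_examples(scans, pairs, model)
  use_spatial <- variant %in% c("spatial", "full")
  correct <- vapply(seq_along(exs), function(i) {
    ex <- exs[[i]]
    clip <- scans[[ex$scan]]$frames[ex$frames]
    a <- encode_audio_pooled(model, ex$spec_pooled)
    p <- if (use_spatial) {
      vmap <- encode_video(model, clip, spatial = TRUE,
                           seed = (seed + i) %% 100000L)
      fuse_spatial(model, vmap, a)$p
    } else {
      v <- encode_video(model, clip, seed = (seed + i) %% 100000L)
      fuse_concat(model, v, a, "va")
    }
    (p > 0.5) == (ex$label == 1L)
  }, logical(1))
  mean(correct)
}

# audio forward from an already stem-pooled spectrogram
encode_audio_pooled <- function(model, pooled) {
  tape <- ad_tape()
  ap <- wrap_params(tape, model$params$audio)
  ag <- audio_graph(tape, ap, ad_const(tape, stack_images(list(pooled))),
                    nrow(pooled), 1L)
  as.numeric(ag$vec$value)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the named weight arrays,
#' the config and the vocabulary.
#'
#' @param model a `sonossl_model` (or `pretrain_result`).
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "pretrain_result")) model <- model$model
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
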