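# Synthetic multi-modal "scan" generator.
#
# Emulates the structure of a clinical ultrasound session: a long grayscale
# video in which abstract anatomy shapes appear for a few seconds at a time,
# concurrent narration in which most anatomy appearances are named by a keyword
# within +/-0.3 s while some narration is off-topic chatter, transcription
# noise that corrupts tokens into invalid strings, per-frame plane labels,
# anatomy masks and gaze maps. Every generated quantity is ground truth for
# the evaluation suite.

#' Standard plane category names
#'
#' The 14-way label set used by the plane-detection head: 13 fetal standard
#' planes plus a background class (always the last index).
#' @export
spd_classes <- c("3VT", "4CH", "LVOT", "RVOT", "BrainTv.", "BrainCb.",
                 "Abdomen", "Femur", "Kidneys", "Lips", "Profile",
                 "SpineCor.", "SpineSag.", "Background")

#' Fixed filler vocabulary emitted between keywords
#' @export
filler_words <- c("this", "is", "the", "looking", "good", "here", "we",
                  "can", "see", "now", "a", "nice")

default_anatomy_vocab <- c("trachea", "heart", "outflow", "ventricle",
                           "brain", "cerebellum", "abdomen", "femur",
                           "kidneys", "lips", "profile", "spine", "sacrum")

default_distractor_vocab <- c("how", "are", "you", "today", "weather",
                              "lovely", "room", "appointment", "holiday",
                              "did", "go", "well")

#' Configuration for the synthetic scan generator
#'
#' @param duration_s scan length in seconds.
#' @param fps video frame rate (frames per second).
#' @param image_size side length of the square frames, pixels.
#' @param sample_rate audio sampling rate, Hz.
#' @param n_anatomy_classes number of anatomy classes rendered (the plane
#'   label set is these classes plus background).
#' @param anatomy_vocab one keyword per anatomy class, in class order.
#' @param distractor_vocab words used for off-topic chatter.
#' @param p_offtopic probability that an anatomy appearance is narrated with
#'   unrelated chatter instead of its keyword.
#' @param p_invalid_token probability that a transcript token is corrupted to
#'   an out-of-vocabulary string (transcription noise).
#' @param noise_sigma additive noise scale shared by frames and audio.
#' @param seed integer seed; the record is a deterministic function of the
#'   configuration.
#' @return a `scan_config` object.
#' @export
scan_config <- function(duration_s = 60, fps = 6, image_size = 64,
                        sample_rate = 24000, n_anatomy_classes = 13,
                        anatomy_vocab = default_anatomy_vocab,
                        distractor_vocab = default_distractor_vocab,
                        p_offtopic = 0.3, p_invalid_token = 0.1,
                        noise_sigma = 0.05, seed = 0L) {
  stopifnot(duration_s > 0, fps > 0, image_size >= 32,
            p_offtopic >= 0, p_offtopic <= 1,
            p_invalid_token >= 0, p_invalid_token <= 1,
            n_anatomy_classes >= 1, noise_sigma >= 0)
  if (length(anatomy_vocab) < n_anatomy_classes) {
    stop("anatomy_vocab must provide at least one keyword per anatomy class")
  }
  structure(list(duration_s = duration_s, fps = fps, image_size = image_size,
                 sample_rate = sample_rate,
                 n_anatomy_classes = as.integer(n_anatomy_classes),
                 anatomy_vocab = anatomy_vocab,
                 distractor_vocab = distractor_vocab,
                 p_offtopic = p_offtopic, p_invalid_token = p_invalid_token,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scan_config")
}

#' Mono waveform container
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\].
#' @param rate sampling rate, Hz.
#' @export
waveform <- function(samples, rate) {
  stopifnot(rate > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

# run code under a temporary RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# distinct parametric geometry per anatomy class, centred at `centroid`
# (row, col), returned as a logical mask
anatomy_shape_mask <- function(anatomy_id, image_size, centroid) {
  r0 <- centroid[1]; c0 <- centroid[2]
  rr <- matrix(seq_len(image_size), image_size, image_size) - r0
  cc <- matrix(seq_len(image_size), image_size, image_size, byrow = TRUE) - c0
  s <- image_size / 6
  m <- switch(((anatomy_id - 1L) %% 13L) + 1L,
    (rr / (1.4 * s))^2 + (cc / (0.7 * s))^2 <= 1,                    # wide ellipse
    (rr / (0.7 * s))^2 + (cc / (1.4 * s))^2 <= 1,                    # tall ellipse
    { d <- sqrt(rr^2 + cc^2); d <= s & d >= 0.6 * s },               # ring
    { d <- sqrt(rr^2 + cc^2); d <= 1.2 * s & d >= 0.9 * s },         # thin ring
    (abs(rr) <= 0.3 * s & abs(cc) <= 1.3 * s) |
      (abs(cc) <= 0.3 * s & abs(rr) <= 1.3 * s),                     # cross
    abs(rr - cc) <= 0.45 * s & abs(rr + cc) <= 1.8 * s,              # diagonal bar
    abs(rr) <= 0.9 * s & abs(cc) <= 0.9 * s,                         # square
    abs(rr) <= 0.35 * s & abs(cc) <= 1.6 * s,                        # horizontal bar
    { d1 <- sqrt((rr - 0.8 * s)^2 + cc^2)
      d2 <- sqrt((rr + 0.8 * s)^2 + cc^2)
      d1 <= 0.6 * s | d2 <= 0.6 * s },                               # two blobs
    sqrt(rr^2 + cc^2) <= 0.55 * s,                                   # small disc
    { d <- sqrt(rr^2 + cc^2)
      d <= 1.2 * s & sqrt((rr - 0.5 * s)^2 + cc^2) > 0.85 * s },     # crescent
    abs(cc) <= 0.35 * s & abs(rr) <= 1.6 * s,                        # vertical bar
    abs(rr) + abs(cc) <= 1.2 * s                                     # diamond
  )
  m
}

#' Render one synthetic frame
#'
#' Draws the class-specific anatomy shape at `centroid` over a speckle-noise
#' background; pixel values are clipped to \[0, 1\]. With `noise_sigma = 0`
#' the background is exactly zero.
#'
#' @param anatomy_id anatomy class index (1-based).
#' @param centroid `(row, col)` pixel position, inside the image.
#' @param image_size side length of the square frame.
#' @param noise_sigma additive speckle scale.
#' @param seed optional seed for the noise draw; `NULL` uses the current RNG
#'   stream.
#' @return list with `image` (matrix in \[0,1\]) and `region_mask` (logical).
#' @export
render_frame <- function(anatomy_id, centroid, image_size, noise_sigma = 0.05,
                         seed = NULL) {
  if (any(centroid < 1) || any(centroid > image_size)) {
    stop("centroid lies outside the image bounds")
  }
  draw <- function() {
    mask <- anatomy_shape_mask(anatomy_id, image_size, centroid)
    img <- matrix(0, image_size, image_size)
    if (noise_sigma > 0) {
      img[] <- abs(stats::rnorm(image_size^2, 0, noise_sigma))
    }
    inten <- 0.75 + 0.1 * sin(seq_len(image_size) / 3)  # mild banding texture
    img[mask] <- (matrix(inten, image_size, image_size)[mask] +
                    if (noise_sigma > 0)
                      stats::rnorm(sum(mask), 0, noise_sigma) else 0)
    img[] <- pmax(pmin(img, 1), 0)
    list(image = img, region_mask = mask)
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Gaussian gaze map over an anatomy region
#'
#' Isotropic Gaussian centred at the mask centroid, truncated at the image
#' bounds and normalised to sum to one.
#'
#' @param region_mask logical matrix; must contain at least one `TRUE` pixel.
#' @param sigma_px Gaussian standard deviation in pixels.
#' @return matrix of the same size summing to 1.
#' @export
make_gaze_map <- function(region_mask, sigma_px) {
  if (!any(region_mask)) stop("empty region mask")
  n <- nrow(region_mask)
  idx <- which(region_mask, arr.ind = TRUE)
  ctr <- c(round(mean(idx[, 1])), round(mean(idx[, 2])))
  rr <- matrix(seq_len(n), n, ncol(region_mask)) - ctr[1]
  cc <- matrix(seq_len(ncol(region_mask)), n, ncol(region_mask), byrow = TRUE) - ctr[2]
  g <- exp(-(rr^2 + cc^2) / (2 * sigma_px^2))
  g / sum(g)
}

# two-tone amplitude-modulated signature for anatomy class k; class 0 gives
# the neutral (non-anatomy) signature used for off-topic speech
anatomy_tone <- function(anatomy_id, t) {
  if (anatomy_id == 0L) { f1 <- 150; f2 <- 250 }
  else { f1 <- 500 + 400 * anatomy_id; f2 <- 6000 + 400 * anatomy_id }
  am <- 0.5 + 0.5 * sin(2 * pi * 4 * t)      # 4 Hz speech-like envelope
  0.4 * am * (sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t)) / 2
}

corrupt_token <- function() {
  paste(sample(c("q", "x", "z", "v", "k", "j", "w"), 5, replace = TRUE),
        collapse = "")
}

#' Generate a complete synthetic scan record
#'
#' Builds a timeline of anatomy events separated by background gaps. Each
#' event renders its class shape in the overlapping frames and, unless the
#' narration is off-topic, is accompanied by a transcript segment containing
#' its keyword (midpoint within +/-0.3 s of the event) and by the class's
#' acoustic signature in the waveform. Off-topic narration draws words from
#' the distractor vocabulary over a neutral signature. Tokens are corrupted
#' to out-of-vocabulary strings with probability `p_invalid_token`.
#'
#' @param config a [scan_config()].
#' @return a `scan_record`: list with `frames` (list of matrices), `waveform`,
#'   `segments` (data.frame with list-column `tokens`), `events`,
#'   `plane_labels` (per frame, 1-based; background = `n_anatomy_classes+1`),
#'   `gaze_maps` and the originating `config`.
#' @export
generate_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  local_seed(config$seed, {
    n_frames <- round(config$duration_s * config$fps)
    n_samp <- round(config$duration_s * config$sample_rate)
    sz <- config$image_size
    bg_class <- config$n_anatomy_classes + 1L

    # --- event timeline ---
    events <- list()
    t <- stats::runif(1, 0.3, 1.0)
    while (t < config$duration_s - 2.5) {
      len <- stats::runif(1, 2.2, 3.4)
      aid <- sample.int(config$n_anatomy_classes, 1)
      ctr <- c(stats::runif(1, 0.3 * sz, 0.7 * sz),
               stats::runif(1, 0.3 * sz, 0.7 * sz))
      offtopic <- stats::runif(1) < config$p_offtopic
      events[[length(events) + 1L]] <- list(
        anatomy_id = aid, t_start = t, t_end = t + len,
        centroid = round(ctr), keyword = config$anatomy_vocab[aid],
        narrated = !offtopic)
      t <- t + len + stats::runif(1, 0.6, 1.6)
    }

    # --- frames, labels, masks, gaze ---
    frames <- vector("list", n_frames)
    gaze <- vector("list", n_frames)
    plane_labels <- rep(bg_class, n_frames)
    frame_t <- (seq_len(n_frames) - 1) / config$fps
    bg_gaze <- make_gaze_map(matrix(TRUE, sz, sz), sz / 2)
    ev_for_frame <- rep(0L, n_frames)
    for (e in seq_along(events)) {
      ev <- events[[e]]
      hit <- frame_t >= ev$t_start & frame_t < ev$t_end
      ev_for_frame[hit] <- e
      plane_labels[hit] <- ev$anatomy_id
    }
    ev_masks <- lapply(events, function(ev)
      anatomy_shape_mask(ev$anatomy_id, sz, ev$centroid))
    ev_gaze <- lapply(ev_masks, function(m) make_gaze_map(m, sz / 10))
    for (i in seq_len(n_frames)) {
      e <- ev_for_frame[i]
      if (e > 0L) {
        ev <- events[[e]]
        fr <- render_frame(ev$anatomy_id, ev$centroid, sz, config$noise_sigma)
        frames[[i]] <- fr$image
        gaze[[i]] <- ev_gaze[[e]]
      } else {
        img <- matrix(0, sz, sz)
        if (config$noise_sigma > 0)
          img[] <- pmin(abs(stats::rnorm(sz^2, 0, config$noise_sigma)), 1)
        frames[[i]] <- img
        gaze[[i]] <- bg_gaze
      }
    }
    for (e in seq_along(events)) events[[e]]$region_mask <- ev_masks[[e]]

    # --- transcript segments + audio ---
    wav <- if (config$noise_sigma > 0)
      stats::rnorm(n_samp, 0, config$noise_sigma * 0.6) else numeric(n_samp)
    segs <- list()
    for (ev in events) {
      mid <- (ev$t_start + ev$t_end) / 2 + stats::runif(1, -0.25, 0.25)
      half <- stats::runif(1, 0.55, 0.8)
      s0 <- max(0, mid - half); s1 <- min(config$duration_s, mid + half)
      if (ev$narrated) {
        pre <- sample(filler_words, sample(1:2, 1))
        post <- sample(filler_words, sample(1:2, 1))
        toks <- c(pre, ev$keyword, post)
        speaker <- "sonographer"
        tone_id <- ev$anatomy_id
      } else {
        toks <- sample(config$distractor_vocab, sample(3:5, 1), replace = FALSE)
        speaker <- if (stats::runif(1) < 0.5) "visitor" else "sonographer"
        tone_id <- 0L
      }
      toks <- vapply(toks, function(tk)
        if (stats::runif(1) < config$p_invalid_token) corrupt_token() else tk,
        character(1), USE.NAMES = FALSE)
      i0 <- floor(s0 * config$sample_rate) + 1
      i1 <- min(n_samp, ceiling(s1 * config$sample_rate))
      tt <- (seq(i0, i1) - 1) / config$sample_rate
      wav[i0:i1] <- wav[i0:i1] + anatomy_tone(tone_id, tt)
      segs[[length(segs) + 1L]] <- list(start_s = s0, end_s = s1,
                                        speaker = speaker, tokens = toks)
    }
    segments <- data.frame(
      start_s = vapply(segs, `[[`, numeric(1), "start_s"),
      end_s = vapply(segs, `[[`, numeric(1), "end_s"),
      speaker = vapply(segs, `[[`, character(1), "speaker"),
      stringsAsFactors = FALSE)
    segments$tokens <- I(lapply(segs, `[[`, "tokens"))

    structure(list(frames = frames,
                   waveform = waveform(pmax(pmin(wav, 1), -1),
                                       config$sample_rate),
                   segments = segments, events = events,
                   plane_labels = plane_labels, gaze_maps = gaze,
                   config = config),
              class = "scan_record")
  })
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf("<scan_record> %d frames @ %g fps, %.1f s audio @ %g Hz, %d events, %d transcript segments\n",
              length(x$frames), x$config$fps,
              length(x$waveform$samples) / x$waveform$rate, x$waveform$rate,
              length(x$events), nrow(x$segments)))
  invisible(x)
}

#' Write a scan record to a directory
#'
#' Layout: `frames/` (8-bit grayscale PNG), `audio.wav` (PCM16),
#' `transcript.jsonl` (one JSON object per segment), `events.json`,
#' `gaze/` (one CSV matrix per frame) and `manifest.json`.
#'
#' @param record a `scan_record`.
#' @param dir output directory (created if absent).
#' @param write_gaze also write the per-frame gaze maps (slowest part).
#' @return `dir`, invisibly.
#' @export
write_scan <- function(record, dir, write_gaze = TRUE) {
  stopifnot(inherits(record, "scan_record"))
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(record$frames)) {
    png::writePNG(record$frames[[i]],
                  file.path(dir, "frames", sprintf("frame_%05d.png", i)))
  }
  write_wav(record$waveform, file.path(dir, "audio.wav"))
  con <- file(file.path(dir, "transcript.jsonl"), "w")
  for (i in seq_len(nrow(record$segments))) {
    writeLines(jsonlite::toJSON(list(
      start_s = record$segments$start_s[i], end_s = record$segments$end_s[i],
      speaker = record$segments$speaker[i],
      text = paste(record$segments$tokens[[i]], collapse = " ")),
      auto_unbox = TRUE), con)
  }
  close(con)
  ev <- lapply(record$events, function(e)
    e[c("anatomy_id", "t_start", "t_end", "centroid", "keyword", "narrated")])
  jsonlite::write_json(ev, file.path(dir, "events.json"), auto_unbox = TRUE,
                       digits = NA)
  if (write_gaze) {
    dir.create(file.path(dir, "gaze"), showWarnings = FALSE)
    for (i in seq_along(record$gaze_maps)) {
      utils::write.table(record$gaze_maps[[i]],
                         file.path(dir, "gaze", sprintf("gaze_%05d.csv", i)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  jsonlite::write_json(list(
    n_frames = length(record$frames), fps = record$config$fps,
    sample_rate = record$waveform$rate, image_size = record$config$image_size,
    seed = record$config$seed,
    paths = list(frames = "frames", audio = "audio.wav",
                 transcript = "transcript.jsonl", events = "events.json",
                 gaze = if (write_gaze) "gaze" else NULL)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read transcript segments from a JSONL file
#'
#' @param path `transcript.jsonl` as written by [write_scan()].
#' @return data.frame with `start_s`, `end_s`, `speaker` and list-column
#'   `tokens`.
#' @export
read_transcript <- function(path) {
  lines <- readLines(path)
  objs <- lapply(lines, jsonlite::fromJSON)
  out <- data.frame(
    start_s = vapply(objs, `[[`, numeric(1), "start_s"),
    end_s = vapply(objs, `[[`, numeric(1), "end_s"),
    speaker = vapply(objs, `[[`, character(1), "speaker"),
    stringsAsFactors = FALSE)
  out$tokens <- I(lapply(objs, function(o) strsplit(o$text, " ")[[1]]))
  out
}
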