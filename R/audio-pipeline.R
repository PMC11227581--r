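# Audio cleaning chain and the log-spectrogram front end.
#
# The cleaning chain mirrors the standard clinical-speech preprocessing
# pipeline: denoise -> voice activity detection -> speaker selection ->
# keyword-based segment selection. Heavy pretrained components (neural VAD,
# diarization embeddings, ASR) are out of scope; this module supplies an
# energy-based VAD, the dominant-speaker rule, and dictionary matching over
# transcripts, with plug-in points for real models (any function mapping a
# waveform to a waveform can serve as the denoiser, and any function mapping
# a waveform to transcript segments as the transcriber).

#' Resample a waveform
#'
#' Polyphase resampling (via the signal package). Duration is preserved to
#' within one sample.
#'
#' @param w a [waveform].
#' @param target_rate desired rate, Hz.
#' @return a [waveform] at `target_rate`.
#' @export
resample_waveform <- function(w, target_rate) {
  stopifnot(inherits(w, "waveform"))
  if (target_rate <= 0) stop("target_rate must be positive")
  if (target_rate == w$rate) return(w)
  g <- gcd_int(round(target_rate), round(w$rate))
  p <- round(target_rate) / g
  q <- round(w$rate) / g
  y <- signal::resample(w$samples, p, q)
  n_expect <- round(length(w$samples) * target_rate / w$rate)
  if (length(y) > n_expect) y <- y[seq_len(n_expect)]
  if (length(y) < n_expect) y <- c(y, rep(0, n_expect - length(y)))
  waveform(y, target_rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Energy-based voice activity detection
#'
#' Splits the waveform into non-overlapping frames and marks maximal runs of
#' frames whose RMS energy strictly exceeds the given quantile of all frame
#' energies. Invariant to global amplitude scaling.
#'
#' @param w a [waveform].
#' @param frame_s analysis frame length, seconds.
#' @param energy_quantile quantile of frame RMS used as the threshold.
#' @return data.frame with `start_s`, `end_s` (disjoint, sorted, half-open).
#' @export
detect_voice_segments <- function(w, frame_s = 0.02, energy_quantile = 0.5) {
  stopifnot(inherits(w, "waveform"), frame_s > 0)
  if (length(w$samples) == 0) stop("empty waveform")
  flen <- max(1L, round(frame_s * w$rate))
  nfr <- floor(length(w$samples) / flen)
  if (nfr == 0) nfr <- 1L
  en <- vapply(seq_len(nfr), function(i) {
    idx <- ((i - 1L) * flen + 1L):min(i * flen, length(w$samples))
    sqrt(mean(w$samples[idx]^2))
  }, numeric(1))
  thr <- stats::quantile(en, energy_quantile, names = FALSE)
  act <- en > thr
  runs <- rle(act)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(start_s = (starts[keep] - 1L) * flen / w$rate,
             end_s = pmin(ends[keep] * flen / w$rate,
                          length(w$samples) / w$rate))
}

#' Dominant-speaker selection
#'
#' Picks the sonographer as the speaker with the most transcript segments;
#' ties broken by greatest total speech duration, then lexicographically.
#'
#' @param segments data.frame with `speaker`, `start_s`, `end_s`.
#' @return the selected speaker id (character scalar).
#' @export
select_sonographer <- function(segments) {
  if (NROW(segments) == 0) stop("empty segment list")
  agg <- stats::aggregate(cbind(n = rep(1, nrow(segments)),
                                dur = segments$end_s - segments$start_s),
                          by = list(speaker = segments$speaker), FUN = sum)
  agg <- agg[order(-agg$n, -agg$dur, agg$speaker), ]
  agg$speaker[1]
}

#' Log-spectrogram of a short speech segment
#'
#' Short-time Fourier transform with a 10 ms Hann window, 5 ms hop and 256
#' frequency bands (FFT size 512, linear bins up to Nyquist), magnitude
#' compressed by `log(1 + x)`. The time axis is linearly interpolated to 256
#' columns so the output is always exactly 256 x 256.
#'
#' @param w a [waveform]; intended use is a 0.6 s segment at 24 kHz.
#' @param n_bands number of frequency bands (rows).
#' @param window_s,hop_s STFT window and hop, seconds.
#' @param out_frames number of output time columns.
#' @return a `spectrogram`: list with `values` (`n_bands x out_frames`, rows =
#'   frequency from 0 upward), `freq_hz` (band centre frequencies), `rate`,
#'   `window_s`, `hop_s`.
#' @export
log_spectrogram <- function(w, n_bands = 256, window_s = 0.010,
                            hop_s = 0.005, out_frames = 256) {
  stopifnot(inherits(w, "waveform"))
  wlen <- round(window_s * w$rate)
  if (length(w$samples) < wlen) stop("waveform shorter than one STFT window")
  nfft <- 2L * n_bands
  sp <- signal::specgram(w$samples, n = nfft, Fs = w$rate,
                         window = signal::hanning(wlen),
                         overlap = wlen - round(hop_s * w$rate))
  mag <- log1p(abs(sp$S))          # [n_bands, n_frames]
  nt <- ncol(mag)
  vals <- if (nt == out_frames) mag else if (nt == 1L) {
    mag[, rep(1L, out_frames), drop = FALSE]
  } else {
    t(apply(mag, 1, function(row)
      stats::approx(seq_len(nt), row, n = out_frames)$y))
  }
  structure(list(values = vals, freq_hz = sp$f, rate = w$rate,
                 window_s = window_s, hop_s = hop_s),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bands x %d frames, 0-%g Hz\n",
              nrow(x$values), ncol(x$values), max(x$freq_hz)))
  invisible(x)
}

#' Flag anatomy-keyword segments
#'
#' Sets `is_anatomy` true for a segment iff at least one of its tokens
#' (case-folded) is in the keyword dictionary. Idempotent.
#'
#' @param segments data.frame with list-column `tokens`.
#' @param dictionary character vector of lowercase keywords (or a
#'   `keyword_dictionary`).
#' @return `segments` with an `is_anatomy` logical column.
#' @export
select_keyword_segments <- function(segments, dictionary) {
  if (inherits(dictionary, "keyword_dictionary")) dictionary <- dictionary$terms
  stopifnot(length(dictionary) > 0)
  segments$is_anatomy <- vapply(segments$tokens, function(tk)
    any(tolower(tk) %in% dictionary), logical(1))
  segments
}

#' Load a keyword dictionary from a text file (one lowercase term per line)
#'
#' @param path file path.
#' @return a `keyword_dictionary` with element `terms`.
#' @examples
#' dict <- read_keyword_dictionary(
#'   system.file("extdata", "anatomy_keywords.txt", package = "sonossl"))
#' dict$terms
#' @export
read_keyword_dictionary <- function(path) {
  terms <- tolower(trimws(readLines(path)))
  terms <- terms[nzchar(terms)]
  keyword_dictionary(terms)
}

#' Construct a keyword dictionary
#' @param terms character vector of anatomy keywords.
#' @export
keyword_dictionary <- function(terms) {
  stopifnot(length(terms) > 0)
  structure(list(terms = unique(tolower(terms))), class = "keyword_dictionary")
}

#' Extract a fixed-length audio window centred at a timestamp
#'
#' Returns the `[t - half, t + half)` slice, zero-padded at the scan
#' boundaries so the length is always `2 * half` seconds.
#'
#' @param w a [waveform].
#' @param t centre time, seconds.
#' @param half half-width, seconds (0.3 by default, giving a 0.6 s window).
#' @return a [waveform].
#' @export
audio_window <- function(w, t, half = 0.3) {
  n <- round(2 * half * w$rate)
  i0 <- round((t - half) * w$rate)
  idx <- i0 + seq_len(n) - 1L
  out <- numeric(n)
  ok <- idx >= 0 & idx < length(w$samples)
  out[ok] <- w$samples[idx[ok] + 1L]
  waveform(out, w$rate)
}
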