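# Evaluation suite: classification report, the five standard saliency
# metrics (KL, NSS, AUC, CC, SIM), and the saliency-compactness metric that
# scores how concentrated and how correctly placed a predicted saliency
# region is.

#' Per-class classification report
#'
#' Standard precision/recall/F1 per class, unweighted macro averages over
#' classes with positive support, and the confusion matrix (rows = true
#' class).
#'
#' @param pred,true integer labels in `1..n_classes`.
#' @param n_classes number of classes.
#' @return list with `per_class` (data.frame), `macro_precision`,
#'   `macro_recall`, `macro_f1`, `accuracy`, `confusion` (matrix).
#' @export
classification_report <- function(pred, true, n_classes) {
  if (length(pred) != length(true)) stop("pred/true length mismatch")
  if (any(c(pred, true) < 1) || any(c(pred, true) > n_classes)) {
    stop("labels outside 1..n_classes")
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(pred)) cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  sup <- support > 0
  list(per_class = data.frame(class = seq_len(n_classes), support = support,
                              precision = prec, recall = rec, f1 = f1),
       macro_precision = mean(prec[sup]), macro_recall = mean(rec[sup]),
       macro_f1 = mean(f1[sup]), accuracy = sum(tp) / length(pred),
       confusion = cm)
}

#' Saliency prediction metrics
#'
#' `KL = sum(gt * log(gt / max(pred, eps)))` (the floor keeps the
#' identity case exactly zero); `CC` = Pearson correlation over
#' pixels; `SIM = sum(pmin(pred, gt))`; `NSS` = mean z-scored prediction
#' value at fixation pixels (0 when the prediction is constant); `AUC` = ROC
#' area of prediction values at fixations vs all other pixels.
#'
#' @param pred,gt non-negative maps summing to 1 (same size).
#' @param fixations optional 2-column matrix of (row, col) fixation pixels;
#'   required for NSS and AUC.
#' @param eps numerical floor inside the KL logarithm.
#' @return list with `KL`, `CC`, `SIM` and, given fixations, `NSS`, `AUC`.
#' @export
saliency_metrics <- function(pred, gt, fixations = NULL, eps = 1e-8) {
  stopifnot(all(dim(pred) == dim(gt)))
  if (abs(sum(pred) - 1) > 1e-4 || abs(sum(gt) - 1) > 1e-4) {
    stop("pred and gt must be normalised to sum to 1")
  }
  if (any(pred < 0) || any(gt < 0)) stop("maps must be non-negative")
  kl <- sum(gt * log(ifelse(gt > 0, gt / pmax(pred, eps), 1)))
  cc <- if (stats::sd(pred) == 0 || stats::sd(gt) == 0) 0 else
    stats::cor(as.vector(pred), as.vector(gt))
  sim <- sum(pmin(pred, gt))
  out <- list(KL = kl, CC = cc, SIM = sim)
  if (!is.null(fixations)) {
    if (NROW(fixations) == 0) stop("empty fixation list")
    fixations <- as.matrix(fixations)
    fidx <- (fixations[, 2] - 1) * nrow(pred) + fixations[, 1]
    s <- stats::sd(pred)
    out$NSS <- if (s == 0) 0 else
      mean((pred[fidx] - mean(pred)) / s)
    pos <- pred[fidx]
    negv <- pred[-fidx]
    if (s == 0) {
      out$AUC <- 0.5
    } else {
      r <- rank(c(pos, negv))
      out$AUC <- (sum(r[seq_along(pos)]) -
                    length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(negv))
    }
  }
  out
}

#' Saliency compactness metric
#'
#' Decomposes a min-max-normalised predicted saliency map `pred` against a
#' reference map/mask `ref` into: support-area fraction `alpha_S`
#' (fraction of pixels with `pred > 0`), high-confidence area fraction
#' `alpha_H` (`pred > thres`), high-response intensity
#' `eta_H = alpha_H / alpha_S`, support IoU against the reference, and
#' `comp = iou * eta_H / alpha_S`. Areas are reported as fractions of total
#' pixels so the score is resolution-invariant; `raw_counts = TRUE` uses raw
#' pixel counts instead (the literal count-based reading, which makes comp
#' scale with resolution).
#'
#' @param pred predicted saliency map, min-max normalised to \[0, 1\].
#' @param ref reference map or mask; support = pixels with value > 0.
#' @param thres high-confidence threshold on the normalised map.
#' @param raw_counts report areas as raw pixel counts instead of fractions.
#' @param iou_at_thres binarise the prediction support at `thres` (instead of
#'   at > 0) when computing the IoU.
#' @return a `comp_result` list: `alpha_S`, `alpha_H`, `eta_H`, `iou`,
#'   `thres`, `comp`, `undefined` (all-zero prediction).
#' @export
comp_metric <- function(pred, ref, thres = 0.5, raw_counts = FALSE,
                        iou_at_thres = FALSE) {
  stopifnot(all(dim(pred) == dim(ref)))
  if (any(pred < -1e-12) || any(pred > 1 + 1e-12)) {
    stop("pred must be min-max normalised to [0, 1]")
  }
  npix <- length(pred)
  supp_p <- if (iou_at_thres) pred > thres else pred > 0
  supp_r <- ref > 0
  a_s <- sum(pred > 0)
  a_h <- sum(pred > thres)
  if (a_s == 0) {
    return(structure(list(alpha_S = 0, alpha_H = 0, eta_H = NA_real_,
                          iou = NA_real_, thres = thres, comp = NA_real_,
                          undefined = TRUE), class = "comp_result"))
  }
  uni <- sum(supp_p | supp_r)
  iou <- if (uni == 0) 0 else sum(supp_p & supp_r) / uni
  eta <- a_h / a_s
  denom <- if (raw_counts) a_s else a_s / npix
  structure(list(alpha_S = if (raw_counts) a_s else a_s / npix,
                 alpha_H = if (raw_counts) a_h else a_h / npix,
                 eta_H = eta, iou = iou, thres = thres,
                 comp = iou * eta / denom, undefined = FALSE),
            class = "comp_result")
}

#' @export
print.comp_result <- function(x, ...) {
  if (x$undefined) cat("<comp_result> undefined (empty prediction support)\n")
  else cat(sprintf(
    "<comp_result> alpha_S=%.4g alpha_H=%.4g eta_H=%.3f IoU=%.3f comp=%.4g\n",
    x$alpha_S, x$alpha_H, x$eta_H, x$iou, x$comp))
  invisible(x)
}
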