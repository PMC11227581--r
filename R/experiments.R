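# Standard synthetic experiment configurations.
#
# Two scales are used throughout the package's evaluation harness:
#  - the recovery scale (6 scans x 60 s, D = 64): one full-variant
#    pretraining run for held-out correspondence accuracy and audio-guided
#    localisation;
#  - the ablation scale (4 scans x 45 s, D = 32, shorter schedule): cheap
#    enough to repeat over 5 seeds x 2 variants for direction comparisons.
# The vignette discusses the choice of problem sizes.

#' Scans of the standard synthetic study
#'
#' @param seed master seed; scan i uses `seed * 1000 + i`.
#' @param n_scans,duration_s study size.
#' @return list of `scan_record`s.
#' @export
standard_scan_set <- function(seed = 0L, n_scans = 6L, duration_s = 60) {
  lapply(seq_len(n_scans), function(i)
    generate_scan(scan_config(duration_s = duration_s,
                              seed = (as.integer(seed) * 1000L + i) %% 100000L)))
}

#' Pretraining at the recovery scale
#'
#' Full-size run of the standard synthetic study: the last two scans are held
#' out, the model is the tiny backbone at D = 64 with contrastive temperature
#' 0.05, and the schedule is 110 epochs (learning-rate drop at 80) plus head
#' calibration.
#'
#' @param scans output of [standard_scan_set()].
#' @param variant objective variant, see [pretrain()].
#' @param seed training seed.
#' @param verbose print per-epoch progress.
#' @return a `pretrain_result`.
#' @export
standard_pretrain <- function(scans, variant = "full", seed = 0L,
                              verbose = FALSE) {
  pretrain(scans, variant, model_config(embed_dim = 64, tau = 0.05),
           epochs = 110, n_pairs = 320, lr = 0.02, lr_decay_every = 80,
           heldout_scans = (length(scans) - 1L):length(scans),
           heldout_every = 10, seed = seed, verbose = verbose)
}

#' Pretraining at the ablation scale
#'
#' Reduced schedule (D = 32, 35 epochs + 6 calibration epochs) used to
#' repeat the variant comparison over several seeds.
#'
#' @param scans scan list (the last scan is held out).
#' @param variant objective variant.
#' @param seed training seed.
#' @param epochs main-loop epochs.
#' @return a `pretrain_result`.
#' @export
ablation_pretrain <- function(scans, variant, seed = 0L, epochs = 35) {
  pretrain(scans, variant, model_config(embed_dim = 32),
           epochs = epochs, n_pairs = 160, lr = 0.02, lr_decay_every = 80,
           heldout_scans = length(scans), heldout_every = epochs,
           polish_epochs = 6L, seed = seed)
}

#' Variant comparison over seeds
#'
#' Runs [ablation_pretrain()] for each variant and seed and (optionally)
#' transfers each pretrained encoder to plane detection.
#'
#' @param scans scan list.
#' @param variants objective variants to compare.
#' @param seeds integer vector of training seeds.
#' @param spd also fine-tune each run on plane detection and record
#'   validation macro-F1.
#' @return data.frame with `variant`, `seed`, `heldout_acc` and optionally
#'   `spd_macro_f1`.
#' @export
run_ablation <- function(scans, variants = c("full", "base"), seeds = 0:4,
                         spd = TRUE) {
  out <- data.frame()
  n <- length(scans)
  for (v in variants) {
    for (s in seeds) {
      pr <- ablation_pretrain(scans, v, seed = s)
      acc <- pr$log$heldout_acc[nrow(pr$log)]
      f1 <- NA_real_
      if (spd) {
        cl <- finetune_spd(pr$model, scans, train_scans = seq_len(n - 1L),
                           val_scans = n, epochs = 3, per_class = 10,
                           lr = 0.02, seed = s)
        f1 <- cl$report$macro_f1
      }
      out <- rbind(out, data.frame(variant = v, seed = s, heldout_acc = acc,
                                   spd_macro_f1 = f1))
    }
  }
  out
}
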