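# Configuration loading and the unified command dispatcher.
#
# A run configuration is a nested list with defaults for every field; a YAML
# file overrides defaults, and command-line style `key=value` overrides (dot
# paths) override the file. Unknown keys and type mismatches are rejected by
# name. Every run directory receives the resolved config, a JSONL log and
# the declared outputs, so a run is reproducible from its directory alone.

default_run_config <- function() {
  list(
    data = list(n_scans = 6L, duration_s = 60, fps = 6, image_size = 64L,
                sample_rate = 24000, p_offtopic = 0.3, p_invalid_token = 0.1,
                noise_sigma = 0.05),
    model = list(embed_dim = 32L, text_embed_dim = 64L, head_hidden = 32L,
                 gate_hidden = 16L, tau = 0.1, lambda = 0, preset = "tiny"),
    objective = list(alpha = 0.25, beta = 0.25, gamma = 0.25, delta = 0.25,
                     mode = "infonce"),
    schedule = list(epochs = 15L, n_pairs = 240L, batch_size = 40L,
                    lr = 1e-3, lr_decay_every = 20L, momentum = 0.9,
                    p_negative = 0.5),
    seed = 0L)
}

coerce_like <- function(value, template, key) {
  if (is.numeric(template)) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) stop("config key '", key, "' expects a number, got '",
                       value, "'")
    if (is.integer(template)) as.integer(round(v)) else v
  } else if (is.character(template)) {
    as.character(value)
  } else value
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) stop("unknown config key: '", key, "'")
    if (is.list(base[[k]])) {
      if (!is.list(override[[k]]))
        stop("config key '", key, "' expects a section")
      base[[k]] <- merge_config(base[[k]], override[[k]], key)
    } else {
      base[[k]] <- coerce_like(override[[k]], base[[k]], key)
    }
  }
  base
}

#' Load a run configuration
#'
#' Resolution order: package defaults < YAML file < `overrides`. Overrides
#' use dotted paths, e.g. `c("objective.alpha" = "1")`. The objective
#' weights are validated to sum to 1.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named character vector of dotted-key overrides.
#' @return a `run_config` list with attribute `config_hash`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (length(y) > 0) cfg <- merge_config(cfg, y)
  }
  if (length(overrides) > 0) {
    for (i in seq_along(overrides)) {
      ks <- strsplit(names(overrides)[i], ".", fixed = TRUE)[[1]]
      ov <- Reduce(function(inner, k) stats::setNames(list(inner), k),
                   rev(ks), overrides[[i]])
      cfg <- merge_config(cfg, ov)
    }
  }
  w <- cfg$objective
  if (abs(w$alpha + w$beta + w$gamma + w$delta - 1) > 1e-9) {
    stop("objective weights must sum to 1 (alpha+beta+gamma+delta = ",
         w$alpha + w$beta + w$gamma + w$delta, ")")
  }
  ser <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  attr(cfg, "config_hash") <- sprintf("%08x", sum(utf8ToInt(ser) *
                                                    (seq_len(nchar(ser)) %% 97)))
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", attr(x, "config_hash"), "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

log_event <- function(con, level, msg, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                level = level, msg = msg), list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  writeLines(line, con)
  message(sprintf("[%s] %s", level, msg))
}

#' Run a pipeline command
#'
#' Commands: `generate` (write synthetic scans), `pretrain` (self-supervised
#' training; variant via `variant`), `finetune-spd`, `finetune-saliency`,
#' `localise`, `evaluate` (correspondence accuracy + localisation hit rate of
#' a checkpoint). Each run writes `config.json`, `log.jsonl` and its outputs
#' into `out_dir`.
#'
#' @param command one of the commands above.
#' @param config a `run_config` from [load_config()].
#' @param out_dir run directory.
#' @param variant pretraining variant (for `pretrain`/`evaluate`).
#' @param checkpoint path to a checkpoint RDS (commands that consume one).
#' @param scan_dir directory of generated scans (defaults to `out_dir`).
#' @return exit status 0 on success (errors raise conditions); invisibly, a
#'   list of computed artifacts.
#' @export
run_command <- function(command, config = load_config(), out_dir = "run",
                        variant = "full", checkpoint = NULL,
                        scan_dir = NULL) {
  commands <- c("generate", "pretrain", "finetune-spd", "finetune-saliency",
                "localise", "evaluate")
  if (!command %in% commands) {
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  logcon <- file(file.path(out_dir, "log.jsonl"), "a")
  on.exit(close(logcon))
  d <- config$data
  gen_scans <- function() {
    lapply(seq_len(d$n_scans), function(i) generate_scan(scan_config(
      duration_s = d$duration_s, fps = d$fps, image_size = d$image_size,
      sample_rate = d$sample_rate, p_offtopic = d$p_offtopic,
      p_invalid_token = d$p_invalid_token, noise_sigma = d$noise_sigma,
      seed = config$seed * 1000L + i)))
  }
  mc <- model_config(embed_dim = config$model$embed_dim,
                     image_size = d$image_size,
                     text_embed_dim = config$model$text_embed_dim,
                     head_hidden = config$model$head_hidden,
                     gate_hidden = config$model$gate_hidden,
                     tau = config$model$tau, lambda = config$model$lambda)
  out <- switch(command,
    generate = {
      scans <- gen_scans()
      for (i in seq_along(scans)) {
        write_scan(scans[[i]], file.path(out_dir, sprintf("scan_%02d", i)),
                   write_gaze = FALSE)
      }
      log_event(logcon, "info", sprintf("wrote %d scans", length(scans)))
      list(scans = length(scans))
    },
    pretrain = {
      scans <- gen_scans()
      held <- if (d$n_scans > 2) (d$n_scans - 1L):d$n_scans else integer(0)
      pr <- pretrain(scans, variant, mc, epochs = config$schedule$epochs,
                     n_pairs = config$schedule$n_pairs,
                     batch_size = config$schedule$batch_size,
                     lr = config$schedule$lr,
                     lr_decay_every = config$schedule$lr_decay_every,
                     momentum = config$schedule$momentum,
                     weights = objective_weights(config$objective$alpha,
                                                 config$objective$beta,
                                                 config$objective$gamma,
                                                 config$objective$delta),
                     mode = config$objective$mode,
                     heldout_scans = held,
                     p_negative = config$schedule$p_negative,
                     seed = config$seed)
      save_checkpoint(pr, file.path(out_dir, "checkpoint.rds"))
      for (i in seq_len(nrow(pr$log))) {
        log_event(logcon, "info", "epoch", epoch = pr$log$epoch[i],
                  lr = pr$log$lr[i], loss = pr$log$loss[i],
                  heldout_acc = pr$log$heldout_acc[i])
      }
      list(result = pr)
    },
    `finetune-spd` = {
      scans <- gen_scans()
      model <- load_checkpoint(checkpoint %||%
                                 stop("finetune-spd needs a checkpoint"))
      folds <- cv_folds(length(scans), seed = config$seed)
      cl <- finetune_spd(model, scans, folds[[1]]$train, folds[[1]]$val,
                         seed = config$seed)
      utils::write.csv(cl$predictions, file.path(out_dir, "spd_predictions.csv"),
                       row.names = FALSE)
      log_event(logcon, "info", "spd", macro_f1 = cl$report$macro_f1)
      list(classifier = cl)
    },
    `finetune-saliency` = {
      scans <- gen_scans()
      model <- load_checkpoint(checkpoint %||%
                                 stop("finetune-saliency needs a checkpoint"))
      folds <- cv_folds(length(scans), seed = config$seed)
      rg <- finetune_saliency(model, scans, folds[[1]]$train, folds[[1]]$val,
                              seed = config$seed)
      log_event(logcon, "info", "saliency", val_kl = rg$val_kl,
                baseline_kl = rg$baseline_kl)
      list(regressor = rg)
    },
    localise = {
      scans <- gen_scans()
      model <- load_checkpoint(checkpoint %||%
                                 stop("localise needs a checkpoint"))
      hr <- localisation_hit_rate(model, scans, seed = config$seed)
      # write heat maps for the first narrated events of the first scan
      dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
      sc <- scans[[1]]
      evs <- Filter(function(e) e$narrated, sc$events)
      for (k in seq_len(min(5, length(evs)))) {
        ev <- evs[[k]]
        lm <- localise_from_audio(
          model, sc$frames[clip_frame_idx(sc, (ev$t_start + ev$t_end) / 2)],
          audio_window(sc$waveform, (ev$t_start + ev$t_end) / 2),
          seed = config$seed + k)
        png::writePNG(lm$values,
                      file.path(out_dir, "maps", sprintf("map_%02d.png", k)))
      }
      log_event(logcon, "info", "localisation", hit_rate = hr$hit_rate,
                n = hr$n)
      list(localisation = hr)
    },
    evaluate = {
      scans <- gen_scans()
      model <- load_checkpoint(checkpoint %||%
                                 stop("evaluate needs a checkpoint"))
      acc <- evaluate_correspondence(model, scans, variant,
                                     seed = config$seed)
      metrics <- list(correspondence_accuracy = acc)
      jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      log_event(logcon, "info", "evaluate", acc = acc)
      list(metrics = metrics)
    })
  invisible(out)
}
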