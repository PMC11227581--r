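# Shared fixtures, built once per test run.
# Tiny scans + a tiny model keep the unit tests fast; the acceptance tests
# build their own standard-size experiment.

fixture_env <- new.env()

tiny_scans <- function() {
  if (is.null(fixture_env$scans)) {
    fixture_env$scans <- lapply(c(1, 3), function(i)
      generate_scan(scan_config(duration_s = 20, seed = i)))
  }
  fixture_env$scans
}

tiny_model <- function() {
  if (is.null(fixture_env$model)) {
    sc <- tiny_scans()[[1]]$config
    fixture_env$model <- init_model(
      model_config(embed_dim = 16, widths = c(4, 8, 8), head_hidden = 8,
                   gate_hidden = 4, text_embed_dim = 16),
      vocab = unique(c(sc$anatomy_vocab, filler_words, sc$distractor_vocab)),
      seed = 1)
  }
  fixture_env$model
}

# numeric finite-difference gradient of f at x
fd_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
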