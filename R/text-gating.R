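# Selective information gating (SIG) over transcribed text.
#
# Two variants: outlier filtering (zero the gates of corrupted <unk> tokens)
# and keyword spotting (additionally depress tokens absent from the anatomy
# keyword dictionary by a factor lambda, 0 by default). Gates are per-token
# (a 1x1 convolution over the token axis followed by a fully-connected layer,
# softplus output), applied after the E->D projection; the pooled feature is
# the gate-weighted sum of projected token embeddings normalised by the sum
# of gates. Because the gate of each token depends only on that token's own
# embedding and masked gates are exactly zero, the output is exactly
# invariant to the embedding content at masked positions.

# internal: build the SIG graph for one token sequence.
# mask: numeric vector in [0,1] per token (0 kills, 1 keeps, lambda depresses)
sig_graph <- function(tape, tp, emb_node, mask) {
  proj <- text_project_graph(tape, tp, emb_node)         # [D, L]
  gates <- gate_graph(tape, tp$gate, proj)               # [1, L]
  gated <- ad_mul(tape, gates, ad_const(tape, matrix(mask, 1)))
  wcol <- ad_node(tape, matrix(as.vector(gated$value), ncol = 1), list(gated),
                  function(nd) list(matrix(nd$grad, nrow = 1)))
  num <- ad_rowsums(tape, ad_scale_cols(tape, proj, wcol))   # [D, 1]
  den <- ad_sum_all(tape, gated)
  vec <- ad_div_scalar(tape, num, den)
  list(vec = vec, gates = gated, proj = proj)
}

sig_run <- function(model, seq, mask) {
  if (all(mask == 0)) {
    D <- model$config$embed_dim
    return(structure(list(vector = rep(NA_real_, D),
                          gate_weights = rep(0, length(mask)),
                          empty = TRUE),
                     class = "gated_text_feature"))
  }
  tape <- ad_tape()
  tp <- wrap_params(tape, model$params$text)
  g <- sig_graph(tape, tp, ad_const(tape, seq$embeddings), mask)
  structure(list(vector = as.numeric(g$vec$value),
                 gate_weights = as.numeric(g$gates$value),
                 empty = FALSE),
            class = "gated_text_feature")
}

#' SIG, outlier-filtering variant
#'
#' Produces per-token gate weights, forces the gates of out-of-vocabulary
#' (unk) tokens to exactly zero, and returns the gate-normalised weighted sum
#' of the projected token embeddings. If every token is unk the result is
#' flagged empty and must be excluded from text losses.
#'
#' @param model a `sonossl_model`.
#' @param seq output of [embed_text()].
#' @return a `gated_text_feature`: `vector` (length D, `NA` when empty),
#'   `gate_weights` (length L, non-negative), `empty` flag.
#' @export
sig_filter_outliers <- function(model, seq) {
  stopifnot(length(seq$unk_mask) == ncol(seq$embeddings))
  sig_run(model, seq, as.numeric(!seq$unk_mask))
}

#' SIG, keyword-spotting variant
#'
#' As [sig_filter_outliers()], but tokens absent from the keyword dictionary
#' have their gates multiplied by the depression factor `lambda` (default
#' taken from the model config, 0 = keep dictionary words only); unk tokens
#' stay at exactly zero. With `lambda = 1` this reduces to the
#' outlier-filtering variant.
#'
#' @param model a `sonossl_model`.
#' @param seq output of [embed_text()].
#' @param dictionary a [keyword_dictionary()] or character vector.
#' @param lambda depression factor in \[0, 1\].
#' @return a `gated_text_feature` (flagged empty when nothing survives the
#'   gate mask).
#' @export
sig_keyword_spot <- function(model, seq, dictionary,
                             lambda = model$config$lambda) {
  if (inherits(dictionary, "keyword_dictionary")) dictionary <- dictionary$terms
  stopifnot(lambda >= 0, lambda <= 1)
  in_dict <- tolower(seq$tokens) %in% dictionary
  mask <- ifelse(seq$unk_mask, 0, ifelse(in_dict, 1, lambda))
  sig_run(model, seq, mask)
}

#' @export
print.gated_text_feature <- function(x, ...) {
  if (x$empty) cat("<gated_text_feature> EMPTY (all tokens gated out)\n")
  else cat(sprintf("<gated_text_feature> D=%d, %d tokens, gate mass %.3f\n",
                   length(x$vector), length(x$gate_weights),
                   sum(x$gate_weights)))
  invisible(x)
}
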