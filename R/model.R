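#' Model configuration
#'
#' Defines the encoder-decoder message-passing network: 3 encoder and 3
#' decoder layers of 128 hidden dimensions by default, a x4 position-wise
#' feed-forward expansion, a 21-letter vocabulary (20 amino acids plus
#' unknown), and encoder edge updates. All geometry enters through edge
#' features; node inputs start at zero, which makes the network rigid-motion
#' invariant by construction.
#'
#' @param n_encoder_layers,n_decoder_layers Layer counts (default 3 each).
#' @param hidden_dim Hidden width (default 128).
#' @param ffn_multiplier Feed-forward expansion factor (default 4).
#' @param vocab Vocabulary size (default 21).
#' @param dropout Dropout probability in training mode (default 0.1).
#' @param edge_updates Update encoder edge embeddings as well as nodes.
#' @param featurizer A [featurizer_config()].
#' @return A `model_config` list.
#' @export
model_config <- function(n_encoder_layers = 3L, n_decoder_layers = 3L,
                         hidden_dim = 128L, ffn_multiplier = 4L, vocab = 21L,
                         dropout = 0.1, edge_updates = TRUE,
                         featurizer = featurizer_config()) {
  stopifnot(n_encoder_layers >= 1L, n_decoder_layers >= 1L, hidden_dim >= 1L,
            ffn_multiplier >= 1L, vocab >= 2L, dropout >= 0, dropout < 1)
  structure(list(n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 hidden_dim = as.integer(hidden_dim),
                 ffn_multiplier = as.integer(ffn_multiplier),
                 vocab = as.integer(vocab), dropout = dropout,
                 edge_updates = isTRUE(edge_updates), featurizer = featurizer),
            class = "model_config")
}

# layer-internal block shapes ------------------------------------------------

# a message/feed-forward stack shared by encoder node update, encoder edge
# update, and decoder: 3-layer transform from 3h -> h (message), or the
# 2-layer position-wise FFN h -> f*h -> h; each followed by a layer norm.

.msg_block_skeleton <- function(h) {
  list(W1 = matrix(0, 3L * h, h), b1 = numeric(h),
       W2 = matrix(0, h, h), b2 = numeric(h),
       W3 = matrix(0, h, h), b3 = numeric(h))
}

.ffn_skeleton <- function(h, f) {
  list(Wf1 = matrix(0, h, f * h), bf1 = numeric(f * h),
       Wf2 = matrix(0, f * h, h), bf2 = numeric(h))
}

.ln_skeleton <- function(h) list(g = rep(1, h), b = numeric(h))

.node_layer_skeleton <- function(h, f) {
  c(.msg_block_skeleton(h), list(ln1 = .ln_skeleton(h)),
    .ffn_skeleton(h, f), list(ln2 = .ln_skeleton(h)))
}

.edge_layer_skeleton <- function(h) {
  c(.msg_block_skeleton(h), list(lne = .ln_skeleton(h)))
}

# full parameter skeleton (all zeros / identity norms)
params_skeleton <- function(config) {
  h <- config$hidden_dim
  f <- config$ffn_multiplier
  ein <- edge_feature_dim(config$featurizer)
  enc <- lapply(seq_len(config$n_encoder_layers), function(l) {
    lay <- list(node = .node_layer_skeleton(h, f))
    if (config$edge_updates) lay$edge <- .edge_layer_skeleton(h)
    lay
  })
  dec <- lapply(seq_len(config$n_decoder_layers), function(l) {
    list(node = .node_layer_skeleton(h, f))
  })
  list(W_e = matrix(0, ein, h),           # bias-free edge input projection
       tok_emb = matrix(0, config$vocab, h),
       enc = enc, dec = dec,
       W_out = matrix(0, h, config$vocab), b_out = numeric(config$vocab))
}

#' Exact trainable-parameter count for a model configuration
#'
#' Closed-form sum over the weight inventory: the bias-free edge input
#' projection (`edge_dim * h`), the token embedding (`vocab * h`), per
#' encoder layer a 3-layer message transform `(3h+1)h + 2(h+1)h`, norm `2h`,
#' feed-forward `(h+1)fh + (fh+1)h`, norm `2h`, plus (when edge updates are
#' enabled) an edge block `(3h+1)h + 2(h+1)h + 2h`; per decoder layer the
#' same node-update shape; and the output projection `(h+1) * vocab`.
#'
#' @param config A [model_config()].
#' @return Integer scalar.
#' @export
count_parameters <- function(config) {
  h <- config$hidden_dim
  f <- config$ffn_multiplier
  v <- config$vocab
  ein <- edge_feature_dim(config$featurizer)
  msg <- (3 * h + 1) * h + 2 * (h + 1) * h
  ffn <- (h + 1) * f * h + (f * h + 1) * h
  node_layer <- msg + 2 * h + ffn + 2 * h
  edge_layer <- msg + 2 * h
  total <- ein * h + v * h +
    config$n_encoder_layers * (node_layer +
                               if (config$edge_updates) edge_layer else 0) +
    config$n_decoder_layers * node_layer +
    (h + 1) * v
  as.integer(total)
}

# glorot-uniform fill of every 2-D weight in a skeleton (in place, recursive);
# biases stay 0, norm gains stay 1.
.fill_weights <- function(x) {
  if (is.matrix(x)) {
    a <- sqrt(6 / (nrow(x) + ncol(x)))
    x[] <- stats::runif(length(x), -a, a)
    return(x)
  }
  if (is.list(x)) {
    for (i in seq_along(x)) x[[i]] <- .fill_weights(x[[i]])
  }
  x
}

#' Initialize model parameters
#'
#' Affine weights are drawn from a Glorot (fan-in + fan-out scaled) uniform
#' distribution, biases are zero, and normalization gains/offsets start at
#' 1/0. Reproducible given `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return A `model_params` nested list; `attr(., "n_params")` matches
#'   [count_parameters()].
#' @export
init_params <- function(config, seed = 0L) {
  sk <- params_skeleton(config)
  p <- with_seed(substream_seed(seed, "init"), .fill_weights(sk))
  class(p) <- "model_params"
  attr(p, "n_params") <- length(unlist(p, use.names = FALSE))
  p
}

# flatten / restore for the optimizer and gradient checks
params_to_vector <- function(params) {
  unlist(params, use.names = FALSE)
}

vector_to_params <- function(v, skeleton) {
  p <- utils::relist(v, unclass(skeleton))
  class(p) <- "model_params"
  p
}

# zero-valued gradient accumulator with the same shape as params
zero_like <- function(params) {
  utils::relist(numeric(length(unlist(params, use.names = FALSE))),
                unclass(params))
}
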