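# Encoder-decoder message-passing network: forward passes with caches and
# hand-written reverse-mode gradients. All tensors are dense matrices; edges
# are flattened (row = edge) with integer endpoint indices `src`/`nbr` into
# the valid-residue ordering and a 0/1 `emask`. Aggregation over neighbor
# messages is a masked sum (fixed k makes sum and mean equivalent up to a
# scale absorbed by the following layer norm).
#
# Hot-path style notes: bias adds and per-column gains use `rep(x, each =
# nrow)` recycling rather than sweep() (no aperm copies), and the 3h-wide
# message input is handled as three h-wide blocks so the concatenated matrix
# is never materialized.

.LN_EPS <- 1e-5

relu <- function(x) x * (x > 0)

# add a row vector to every row / multiply every column by a gain
addb <- function(m, b) m + rep(b, each = nrow(m))
mulg <- function(m, g) m * rep(g, each = nrow(m))

# --- layer norm -------------------------------------------------------------

ln_forward <- function(X, ln) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * inv
  list(Y = addb(mulg(xhat, ln$g), ln$b), xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, ln) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- mulg(dY, ln$g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

# --- 3-layer message transform on three h-wide input blocks -----------------

msg_forward <- function(A, B, C, blk, h) {
  i1 <- seq_len(h); i2 <- h + i1; i3 <- 2L * h + i1
  Z1 <- A %*% blk$W1[i1, , drop = FALSE] + B %*% blk$W1[i2, , drop = FALSE] +
    C %*% blk$W1[i3, , drop = FALSE]
  A1 <- relu(addb(Z1, blk$b1))
  A2 <- relu(addb(A1 %*% blk$W2, blk$b2))
  M <- addb(A2 %*% blk$W3, blk$b3)
  list(M = M, A = A, B = B, C = C, A1 = A1, A2 = A2)
}

# returns input-block gradients dA, dB, dC and parameter grads
msg_backward <- function(dM, cache, blk, h) {
  i1 <- seq_len(h); i2 <- h + i1; i3 <- 2L * h + i1
  dW3 <- crossprod(cache$A2, dM)
  db3 <- colSums(dM)
  dA2 <- tcrossprod(dM, blk$W3)
  dZ2 <- dA2 * (cache$A2 > 0)
  dW2 <- crossprod(cache$A1, dZ2)
  db2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, blk$W2)
  dZ1 <- dA1 * (cache$A1 > 0)
  dW1 <- rbind(crossprod(cache$A, dZ1), crossprod(cache$B, dZ1),
               crossprod(cache$C, dZ1))
  db1 <- colSums(dZ1)
  list(dA = tcrossprod(dZ1, blk$W1[i1, , drop = FALSE]),
       dB = tcrossprod(dZ1, blk$W1[i2, , drop = FALSE]),
       dC = tcrossprod(dZ1, blk$W1[i3, , drop = FALSE]),
       g = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3))
}

# --- position-wise feed-forward (h -> f*h -> h) -----------------------------

ffn_forward <- function(X, blk) {
  A1 <- relu(addb(X %*% blk$Wf1, blk$bf1))
  list(F = addb(A1 %*% blk$Wf2, blk$bf2), X = X, A1 = A1)
}

ffn_backward <- function(dF, cache, blk) {
  dWf2 <- crossprod(cache$A1, dF)
  dbf2 <- colSums(dF)
  dA1 <- tcrossprod(dF, blk$Wf2)
  dZ1 <- dA1 * (cache$A1 > 0)
  dWf1 <- crossprod(cache$X, dZ1)
  dbf1 <- colSums(dZ1)
  list(dX = tcrossprod(dZ1, blk$Wf1),
       g = list(Wf1 = dWf1, bf1 = dbf1, Wf2 = dWf2, bf2 = dbf2))
}

# dropout mask (inverted scaling); NULL in evaluation mode
.drop_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - p) / (1 - p), nr, nc)
}

# --- node update (shared by encoder and decoder layers) ---------------------
# message inputs: A = center-node stream gathered on edges, B/C = the two
# neighbor-side blocks (neighbor nodes + edges, or edges + token context)

node_update_forward <- function(H, A, B, C, blk, graph, p_drop, h) {
  msg <- msg_forward(A, B, C, blk, h)
  M <- msg$M * graph$emask
  S <- rowsum_n(M, graph$src, graph$n)
  d1 <- .drop_mask(nrow(S), ncol(S), p_drop)
  if (!is.null(d1)) S <- S * d1
  l1 <- ln_forward(H + S, blk$ln1)
  ffn <- ffn_forward(l1$Y, blk)
  F <- ffn$F
  d2 <- .drop_mask(nrow(F), ncol(F), p_drop)
  if (!is.null(d2)) F <- F * d2
  l2 <- ln_forward(l1$Y + F, blk$ln2)
  list(H = l2$Y, msg = msg, l1 = l1, ffn = ffn, l2 = l2, d1 = d1, d2 = d2)
}

# returns dH (w.r.t. layer input H), input-block grads, and parameter grads
node_update_backward <- function(dH2, cache, blk, graph, h) {
  b2 <- ln_backward(dH2, cache$l2, blk$ln2)
  dF <- b2$dX
  if (!is.null(cache$d2)) dF <- dF * cache$d2
  bf <- ffn_backward(dF, cache$ffn, blk)
  dH1 <- b2$dX + bf$dX
  b1 <- ln_backward(dH1, cache$l1, blk$ln1)
  dS <- b1$dX
  if (!is.null(cache$d1)) dS <- dS * cache$d1
  dM <- dS[graph$src, , drop = FALSE] * graph$emask
  bm <- msg_backward(dM, cache$msg, blk, h)
  g <- c(bm$g, list(ln1 = list(g = b1$dg, b = b1$db)), bf$g,
         list(ln2 = list(g = b2$dg, b = b2$db)))
  list(dH = b1$dX, dA = bm$dA, dB = bm$dB, dC = bm$dC, g = g)
}

# --- encoder ----------------------------------------------------------------

#' Run the message-passing encoder over a featurized graph
#'
#' Projects edge features to the hidden width (bias-free), initializes node
#' embeddings at zero, and applies `n_encoder_layers` rounds of masked-sum
#' neighbor message passing with residual layer-norm updates, a position-wise
#' feed-forward block, and (when enabled) an edge-embedding update of the
#' same shape.
#'
#' @param params A `model_params` from [init_params()].
#' @param config A [model_config()].
#' @param graph A featurized graph from [featurize_graph()].
#' @param train Logical; enables dropout (caller controls the RNG seed).
#' @param need_cache Keep intermediate activations for backpropagation.
#' @return List with node embeddings `H` (n-by-h), edge embeddings `Eh`
#'   (E-by-h), the `graph`, and (optionally) `cache`.
#' @export
encode_graph <- function(params, config, graph, train = FALSE,
                         need_cache = FALSE) {
  h <- config$hidden_dim
  p_drop <- if (train) config$dropout else 0
  Eh <- graph$feat %*% params$W_e
  H <- matrix(0, graph$n, h)
  caches <- vector("list", config$n_encoder_layers)
  for (l in seq_len(config$n_encoder_layers)) {
    lay <- params$enc[[l]]
    Hs <- H[graph$src, , drop = FALSE]
    Hn <- H[graph$nbr, , drop = FALSE]
    nu <- node_update_forward(H, Hs, Hn, Eh, lay$node, graph, p_drop, h)
    H_new <- nu$H
    ecache <- NULL
    if (config$edge_updates) {
      Hs2 <- H_new[graph$src, , drop = FALSE]
      Hn2 <- H_new[graph$nbr, , drop = FALSE]
      em <- msg_forward(Hs2, Hn2, Eh, lay$edge, h)
      Me <- em$M * graph$emask
      de <- .drop_mask(nrow(Me), ncol(Me), p_drop)
      if (!is.null(de)) Me <- Me * de
      le <- ln_forward(Eh + Me, lay$edge$lne)
      ecache <- list(em = em, le = le, de = de)
      Eh <- le$Y
    }
    if (need_cache) caches[[l]] <- list(node = nu, edge = ecache)
    H <- H_new
  }
  out <- list(H = H, Eh = Eh, graph = graph)
  if (need_cache) out$cache <- list(layers = caches)
  out
}

# backward through the encoder given dH (n x h) and dEh (E x h) at its output
encode_backward <- function(dH, dEh, enc, params, config) {
  graph <- enc$graph
  h <- config$hidden_dim
  g_enc <- vector("list", config$n_encoder_layers)
  for (l in rev(seq_len(config$n_encoder_layers))) {
    lay <- params$enc[[l]]
    cache <- enc$cache$layers[[l]]
    g_edge <- NULL
    if (config$edge_updates) {
      be <- ln_backward(dEh, cache$edge$le, lay$edge$lne)
      dMe <- be$dX
      if (!is.null(cache$edge$de)) dMe <- dMe * cache$edge$de
      dMe <- dMe * graph$emask
      bm <- msg_backward(dMe, cache$edge$em, lay$edge, h)
      dH <- dH + rowsum_n(bm$dA, graph$src, graph$n) +
        rowsum_n(bm$dB, graph$nbr, graph$n)
      dEh <- be$dX + bm$dC
      g_edge <- c(bm$g, list(lne = list(g = be$dg, b = be$db)))
    }
    nb <- node_update_backward(dH, cache$node, lay$node, graph, h)
    dH <- nb$dH + rowsum_n(nb$dA, graph$src, graph$n) +
      rowsum_n(nb$dB, graph$nbr, graph$n)
    dEh <- dEh + nb$dC
    g_enc[[l]] <- if (is.null(g_edge)) list(node = nb$g) else
      list(node = nb$g, edge = g_edge)
  }
  dW_e <- crossprod(graph$feat, dEh)
  list(g_enc = g_enc, dW_e = dW_e)
}

# --- decoder ----------------------------------------------------------------

# Teacher-forced decoder over all positions. `ar_flag` is the per-edge 0/1
# indicator that the neighbor's identity is visible (decoded earlier, or a
# known fixed context). The query stream starts from the encoder node
# embeddings; the per-edge context slot carries the neighbor's token
# embedding when its identity is visible and falls back to the neighbor's
# (sequence-independent) encoder embedding otherwise, so a position's logits
# depend on exactly the identities its flag exposes.
decoder_forward <- function(params, config, enc, tokens, ar_flag,
                            train = FALSE, need_cache = FALSE) {
  graph <- enc$graph
  h <- config$hidden_dim
  p_drop <- if (train) config$dropout else 0
  vis <- ar_flag * graph$emask
  hid <- graph$emask - vis
  Ctx <- params$tok_emb[tokens[graph$nbr], , drop = FALSE] * vis +
    enc$H[graph$nbr, , drop = FALSE] * hid
  G <- enc$H
  caches <- vector("list", config$n_decoder_layers)
  for (l in seq_len(config$n_decoder_layers)) {
    lay <- params$dec[[l]]
    Gs <- G[graph$src, , drop = FALSE]
    nu <- node_update_forward(G, Gs, enc$Eh, Ctx, lay$node, graph, p_drop, h)
    if (need_cache) caches[[l]] <- nu
    G <- nu$H
  }
  logits <- addb(G %*% params$W_out, params$b_out)
  out <- list(logits = logits, G = G)
  if (need_cache) out$cache <- list(layers = caches, Ctx = Ctx, vis = vis,
                                    hid = hid)
  out
}

# backward through decoder; returns parameter grads plus dH/dEh at encoder out
decoder_backward <- function(dlogits, dec, enc, params, config, tokens) {
  graph <- enc$graph
  h <- config$hidden_dim
  dW_out <- crossprod(dec$G, dlogits)
  db_out <- colSums(dlogits)
  dG <- tcrossprod(dlogits, params$W_out)
  dEh <- 0
  dCtx <- 0
  g_dec <- vector("list", config$n_decoder_layers)
  for (l in rev(seq_len(config$n_decoder_layers))) {
    nb <- node_update_backward(dG, dec$cache$layers[[l]],
                               params$dec[[l]]$node, graph, h)
    dG <- nb$dH + rowsum_n(nb$dA, graph$src, graph$n)
    dEh <- dEh + nb$dB
    dCtx <- dCtx + nb$dC
    g_dec[[l]] <- list(node = nb$g)
  }
  dtok <- rowsum_n(dCtx * dec$cache$vis, tokens[graph$nbr], config$vocab)
  # encoder embeddings also feed the context slot of still-hidden neighbors
  dH <- dG + rowsum_n(dCtx * dec$cache$hid, graph$nbr, graph$n)
  list(g_dec = g_dec, dW_out = dW_out, db_out = db_out, dtok = dtok,
       dH = dH, dEh = dEh)
}

#' Teacher-forced per-position logits under a decoding order
#'
#' Runs the decoder with the full sequence as context, exposing to each
#' position only the identities of neighbors decoded before it in `order`.
#'
#' @param enc Encoder output from [encode_graph()].
#' @param tokens Integer token vector (length n) over [aa_alphabet()].
#' @param order Integer permutation of `1:n` (decoding order), or a
#'   `decoding_order` object.
#' @param params,config Model parameters and configuration.
#' @return n-by-vocab matrix of logits.
#' @export
decode_logits <- function(enc, tokens, order, params, config) {
  n <- enc$graph$n
  rank <- order_rank(order, n)
  ar <- as.numeric(rank[enc$graph$nbr] < rank[enc$graph$src])
  decoder_forward(params, config, enc, tokens, ar)$logits
}

# rank vector from either a permutation or a decoding_order object
order_rank <- function(order, n) {
  if (inherits(order, "decoding_order")) {
    rank <- integer(n)
    for (s in seq_along(order$slots)) rank[order$slots[[s]]] <- s
    return(rank)
  }
  if (length(order) != n || !setequal(order, seq_len(n))) {
    stop("decoding order is not a permutation of 1..n")
  }
  rank <- integer(n)
  rank[order] <- seq_len(n)
  rank
}

# Decoder logits for a subset of positions given partially known context.
# Used during sequential sampling: the query stream of a position never
# depends on other positions' decoder states, so only the subset's edges are
# processed.
decoder_logits_positions <- function(enc, params, config, tokens, known,
                                     positions) {
  graph <- enc$graph
  n <- graph$n
  k <- graph$k
  h <- config$hidden_dim
  np <- length(positions)
  # edge rows for src == positions (column-major layout)
  idx <- as.integer(outer(positions, (seq_len(k) - 1L) * n, "+"))
  src_map <- rep(seq_len(np), times = k)
  nbr_sub <- graph$nbr[idx]
  emask_sub <- graph$emask[idx]
  vis <- emask_sub * as.numeric(known[nbr_sub])
  tok_safe <- ifelse(is.na(tokens[nbr_sub]), 1L, tokens[nbr_sub])
  Ctx <- params$tok_emb[tok_safe, , drop = FALSE] * vis +
    enc$H[nbr_sub, , drop = FALSE] * (emask_sub - vis)
  Eh_sub <- enc$Eh[idx, , drop = FALSE]
  sub_graph <- list(n = np, src = src_map, emask = emask_sub)
  G <- enc$H[positions, , drop = FALSE]
  for (l in seq_len(config$n_decoder_layers)) {
    lay <- params$dec[[l]]
    Gs <- G[src_map, , drop = FALSE]
    nu <- node_update_forward(G, Gs, Eh_sub, Ctx, lay$node, sub_graph, 0, h)
    G <- nu$H
  }
  addb(G %*% params$W_out, params$b_out)
}
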