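#' Training configuration
#'
#' @param epochs Number of passes over the training partition.
#' @param batch_size Structures per gradient step.
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Master seed; all noise, order, dropout and shuffling streams
#'   derive from it.
#' @param noise_std Gaussian backbone noise in Angstrom applied freshly at
#'   every training visit (0.02 for noise-augmented training; validation is
#'   always evaluated without noise).
#' @param gradient_clip Global gradient-norm clip (default 1).
#' @param lr_decay Multiplicative step-decay factor applied to the learning
#'   rate late in training (default 0.2; 1 disables).
#' @param lr_decay_at Fraction of epochs after which the decay applies
#'   (default 0.6).
#' @param weight_decay Decoupled weight decay on affine weight matrices
#'   (biases and normalization parameters excluded; default 0).
#' @param warmup_steps Linear learning-rate warmup over this many optimizer
#'   steps (default 50; stabilizes early Adam updates through the layer
#'   norms).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_size = 16L, learning_rate = 1e-3,
                         seed = 0L, noise_std = 0, gradient_clip = 1,
                         lr_decay = 0.2, lr_decay_at = 0.6,
                         weight_decay = 0, warmup_steps = 50L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0, noise_std >= 0,
            lr_decay > 0, lr_decay <= 1, lr_decay_at >= 0, lr_decay_at <= 1,
            weight_decay >= 0, warmup_steps >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 noise_std = noise_std, gradient_clip = gradient_clip,
                 lr_decay = lr_decay, lr_decay_at = lr_decay_at,
                 weight_decay = weight_decay,
                 warmup_steps = as.integer(warmup_steps)),
            class = "train_config")
}

# 0/1 mask over the flattened parameter vector marking 2-D weight matrices
# (the only parameters subject to decoupled weight decay)
.decay_mask <- function(params) {
  mark <- function(x) {
    if (is.matrix(x)) return(rep(1, length(x)))
    if (is.list(x)) return(unlist(lapply(x, mark), use.names = FALSE))
    rep(0, length(x))
  }
  mark(unclass(params))
}

# concatenate per-structure featurized graphs into one block graph
batch_graphs <- function(graphs) {
  ns <- vapply(graphs, `[[`, 0L, "n")
  off <- cumsum(c(0L, ns[-length(ns)]))
  list(
    n = sum(ns),
    src = unlist(Map(function(g, o) g$src + o, graphs, off)),
    nbr = unlist(Map(function(g, o) g$nbr + o, graphs, off)),
    emask = unlist(lapply(graphs, `[[`, "emask")),
    feat = do.call(rbind, lapply(graphs, `[[`, "feat")),
    node_struct = rep(seq_along(graphs), ns),
    offsets = off, ns = ns
  )
}

# teacher-forced cross-entropy over a prepared batch graph; optionally with
# parameter gradients. `rank` is the per-node decode rank (within structure).
.batch_loss <- function(params, config, graph, tokens, rank, grad = FALSE,
                        train = FALSE) {
  ar <- as.numeric(rank[graph$nbr] < rank[graph$src])
  enc <- encode_graph(params, config, graph, train = train, need_cache = grad)
  dec <- decoder_forward(params, config, enc, tokens, ar, train = train,
                         need_cache = grad)
  include <- tokens != config$vocab          # X never a target
  P <- row_softmax(dec$logits)
  n_inc <- sum(include)
  lp <- log(P[cbind(seq_along(tokens), tokens)])
  loss <- -sum(lp[include]) / n_inc
  out <- list(loss = loss, log_probs = lp, n_included = n_inc)
  if (grad) {
    dlogits <- P
    dlogits[cbind(seq_along(tokens), tokens)] <-
      dlogits[cbind(seq_along(tokens), tokens)] - 1
    dlogits <- dlogits * include / n_inc
    db <- decoder_backward(dlogits, dec, enc, params, config, tokens)
    eb <- encode_backward(db$dH, db$dEh, enc, params, config)
    out$grads <- list(W_e = eb$dW_e, tok_emb = db$dtok, enc = eb$g_enc,
                      dec = db$g_dec, W_out = db$dW_out, b_out = db$db_out)
  }
  out
}

# featurize a list of (structure, tokens) records into a batch graph + labels
.prepare_batch <- function(records, config, noise_std, seed) {
  graphs <- vector("list", length(records))
  toks <- vector("list", length(records))
  fcfg <- config$featurizer
  fcfg$noise_std <- noise_std
  for (i in seq_along(records)) {
    r <- records[[i]]
    g <- featurize_graph(r$structure, fcfg,
                         noise_seed = substream_seed(seed, "noise", i))
    tk <- if (is.character(r$sequence)) seq_to_tokens(r$sequence) else r$sequence
    if (length(tk) != g$n) {
      stop("sequence length ", length(tk), " does not match ", g$n,
           " valid residues")
    }
    graphs[[i]] <- g
    toks[[i]] <- tk
  }
  bg <- batch_graphs(graphs)
  bg$tokens <- unlist(toks)
  bg
}

# one random decoding rank per structure in a batch graph
.batch_ranks <- function(bg, seed) {
  rank <- integer(bg$n)
  with_seed(seed, {
    for (s in seq_along(bg$ns)) {
      idx <- which(bg$node_struct == s)
      rank[idx] <- sample.int(length(idx))
    }
  })
  rank
}

#' Order-agnostic autoregressive training loss
#'
#' For each structure in the batch: apply fresh Gaussian backbone noise,
#' featurize, draw one uniformly random decoding order, teacher-force the
#' true sequence, and accumulate the categorical cross entropy of each valid
#' residue. Returns the mean over residues in the batch (so
#' `exp(loss)` is the batch perplexity). Deterministic given `seed`.
#'
#' @param params,config Model parameters and configuration.
#' @param batch List of records, each `list(structure =, sequence =)`.
#' @param noise_std Coordinate noise in Angstrom.
#' @param seed Integer seed controlling noise and decoding orders.
#' @param grad Also return parameter gradients (`$grads`).
#' @param train Enable dropout (seeded).
#' @return List with `loss` and optionally `grads`.
#' @export
training_loss <- function(params, config, batch, noise_std = 0, seed = 0L,
                          grad = FALSE, train = FALSE) {
  if (length(batch) == 0L) stop("training_loss: empty batch")
  bg <- .prepare_batch(batch, config, noise_std, seed)
  rank <- .batch_ranks(bg, substream_seed(seed, "order"))
  res <- with_seed(substream_seed(seed, "dropout"),
                   .batch_loss(params, config, bg, bg$tokens, rank,
                               grad = grad, train = train))
  res[c("loss", if (grad) "grads")]
}

# Adam step on flat vectors; state carries first/second moments and t.
.adam_step <- function(theta, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train a model on a cluster-aware dataset split
#'
#' Seeded minibatch Adam on the order-agnostic autoregressive loss, with
#' optional Gaussian backbone-noise augmentation (fresh noise every visit).
#' Validation perplexity is computed each epoch without noise; the
#' best-validation parameters are retained.
#'
#' @param config A [model_config()].
#' @param train_cfg A [train_config()].
#' @param split A dataset split from [cluster_split()] (or any list with
#'   `records` and `partition`).
#' @param verbose Print per-epoch progress.
#' @return List with `params` (best validation), `final_params`, and
#'   `history` (data.frame: epoch, train_loss, val_perplexity).
#' @export
train_model <- function(config, train_cfg, split, verbose = FALSE) {
  tr_idx <- which(split$partition == "train")
  va_idx <- which(split$partition == "validation")
  if (length(tr_idx) == 0L) stop("train_model: empty train partition")
  tr <- split$records[tr_idx]
  va <- split$records[va_idx]
  params <- init_params(config, seed = train_cfg$seed)
  skeleton <- params
  theta <- params_to_vector(params)
  state <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
  wd_mask <- if (train_cfg$weight_decay > 0) .decay_mask(params) else NULL
  # with no noise the featurization (and batch graphs) can be built once
  static <- train_cfg$noise_std == 0
  cache_bg <- NULL
  va_bg <- if (length(va) > 0L) .prepare_batch(va, config, 0, 0L) else NULL
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_perplexity = numeric())
  best <- list(ppl = Inf, theta = theta)
  n_tr <- length(tr)
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- with_seed(substream_seed(train_cfg$seed, "shuffle", ep),
                     sample.int(n_tr))
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    ep_loss <- 0; ep_n <- 0L
    for (bi in seq_along(batches)) {
      ids <- batches[[bi]]
      bseed <- substream_seed(train_cfg$seed, "batch", ep * 100003L + bi)
      if (static) {
        if (is.null(cache_bg)) {
          cache_bg <- lapply(seq_len(n_tr), function(i)
            .prepare_batch(tr[i], config, 0, 0L))
        }
        bg <- batch_graphs(cache_bg[ids])
        bg$tokens <- unlist(lapply(cache_bg[ids], `[[`, "tokens"))
      } else {
        bg <- .prepare_batch(tr[ids], config, train_cfg$noise_std, bseed)
      }
      rank <- .batch_ranks(bg, substream_seed(bseed, "order"))
      params <- vector_to_params(theta, skeleton)
      res <- with_seed(substream_seed(bseed, "dropout"),
                       .batch_loss(params, config, bg, bg$tokens, rank,
                                   grad = TRUE, train = config$dropout > 0))
      if (!is.finite(res$loss)) {
        stop("train_model: divergent (non-finite) loss at epoch ", ep)
      }
      g <- unlist(res$grads, use.names = FALSE)
      gn <- sqrt(sum(g * g))
      if (is.finite(train_cfg$gradient_clip) && gn > train_cfg$gradient_clip) {
        g <- g * (train_cfg$gradient_clip / gn)
      }
      lr <- train_cfg$learning_rate *
        if (ep > train_cfg$lr_decay_at * train_cfg$epochs)
          train_cfg$lr_decay else 1
      if (train_cfg$warmup_steps > 0L && state$t < train_cfg$warmup_steps) {
        lr <- lr * (state$t + 1L) / train_cfg$warmup_steps
      }
      if (train_cfg$weight_decay > 0) {
        theta <- theta - lr * train_cfg$weight_decay * wd_mask * theta
      }
      upd <- .adam_step(theta, g, state, lr)
      theta <- upd$theta
      state <- upd$state
      ep_loss <- ep_loss + res$loss * length(ids)
      ep_n <- ep_n + length(ids)
    }
    params <- vector_to_params(theta, skeleton)
    val_ppl <- NA_real_
    if (!is.null(va_bg)) {
      vrank <- .batch_ranks(va_bg, substream_seed(train_cfg$seed, "valorder"))
      vres <- .batch_loss(params, config, va_bg, va_bg$tokens, vrank)
      val_ppl <- exp(vres$loss)
      if (val_ppl < best$ppl) best <- list(ppl = val_ppl, theta = theta)
    } else {
      best <- list(ppl = NA_real_, theta = theta)
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                         val_perplexity = val_ppl))
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f, val perplexity %s", ep,
                      ep_loss / ep_n,
                      ifelse(is.na(val_ppl), "-", sprintf("%.3f", val_ppl))))
    }
  }
  final <- vector_to_params(theta, skeleton)
  bestp <- vector_to_params(best$theta, skeleton)
  list(params = bestp, final_params = final, history = history)
}

#' Cluster-aware train/validation/test split
#'
#' Shuffles cluster labels with the seed and assigns whole clusters greedily
#' to the train, validation, and test partitions until each partition's
#' record-count target is met, so that no cluster ever spans two partitions
#' (the no-leakage property of sequence-identity-clustered splits).
#'
#' @param records List of records.
#' @param cluster_id Per-record cluster labels.
#' @param fractions Length-3 numeric summing to 1 (train, validation, test).
#' @param seed Integer seed.
#' @return A `dataset_split`: list(records, cluster_id, partition).
#' @export
cluster_split <- function(records, cluster_id, fractions = c(0.8, 0.1, 0.1),
                          seed = 0L) {
  stopifnot(length(cluster_id) == length(records))
  if (abs(sum(fractions) - 1) > 1e-8) stop("cluster_split: fractions must sum to 1")
  clusters <- unique(cluster_id)
  n_part <- sum(fractions > 0)
  if (length(clusters) < n_part) {
    stop("cluster_split: fewer clusters (", length(clusters),
         ") than partitions (", n_part, ")")
  }
  clusters <- with_seed(substream_seed(seed, "split"),
                        sample(clusters))
  n <- length(records)
  targets <- fractions * n
  part_names <- c("train", "validation", "test")
  partition <- character(n)
  counts <- c(0, 0, 0)
  p <- 1L
  for (cl in clusters) {
    idx <- which(cluster_id == cl)
    while (p < 3L && counts[p] >= targets[p]) p <- p + 1L
    partition[idx] <- part_names[p]
    counts[p] <- counts[p] + length(idx)
  }
  structure(list(records = records, cluster_id = cluster_id,
                 partition = partition),
            class = "dataset_split")
}
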