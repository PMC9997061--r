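#' Design constraints
#'
#' Describes how sequences are sampled for a backbone: positions with fixed
#' identities (decoded first, as context for the rest), tied groups whose
#' members share one identity drawn from a signed linear combination of
#' their logits, letters never sampled, the sampling temperature, sample
#' count and seed.
#'
#' @param fixed Named character vector or list mapping positions (1-based
#'   indices over the valid residues) to amino-acid letters, e.g.
#'   `c("3" = "G")`.
#' @param tied_groups List of groups; each group is an integer vector of
#'   positions (unit coefficients) or a list of `(position, coefficient)`
#'   pairs.
#' @param omit Letters never sampled (default `"X"`).
#' @param temperature Positive sampling temperature (default 0.1).
#' @param n_samples Number of sequences to draw.
#' @param seed Integer seed.
#' @param tie_mode `"logits"` (coefficient-combined logits, the default) or
#'   `"probabilities"` (per-member softmax first, then weighted average).
#' @return A `design_constraints` object.
#' @export
design_constraints <- function(fixed = NULL, tied_groups = list(),
                               omit = "X", temperature = 0.1, n_samples = 1L,
                               seed = 0L, tie_mode = c("logits", "probabilities")) {
  tie_mode <- match.arg(tie_mode)
  if (temperature <= 0) stop("design_constraints: temperature must be > 0")
  fixed_pos <- integer(0)
  fixed_letters <- character(0)
  if (length(fixed)) {
    fixed_pos <- as.integer(names(fixed))
    fixed_letters <- unname(toupper(unlist(fixed, use.names = FALSE)))
    if (anyNA(fixed_pos)) stop("design_constraints: fixed positions must be integer names")
  }
  groups <- lapply(tied_groups, function(g) {
    if (is.list(g)) {
      pos <- vapply(g, function(p) as.integer(p[[1]]), 0L)
      coef <- vapply(g, function(p) as.numeric(p[[2]]), 0)
    } else {
      pos <- as.integer(g)
      coef <- rep(1, length(pos))
    }
    if (length(pos) < 1L) stop("design_constraints: empty tied group")
    list(pos = pos, coef = coef)
  })
  tied_pos <- unlist(lapply(groups, `[[`, "pos"))
  if (anyDuplicated(tied_pos)) {
    stop("design_constraints: a position appears in more than one tied group")
  }
  if (anyDuplicated(fixed_pos)) {
    stop("design_constraints: duplicate fixed positions")
  }
  if (length(intersect(fixed_pos, tied_pos))) {
    stop("design_constraints: fixed and tied positions must be disjoint")
  }
  omit <- unique(toupper(omit))
  if (any(fixed_letters %in% omit)) {
    stop("design_constraints: a fixed letter is in the omit set")
  }
  structure(list(fixed_pos = fixed_pos, fixed_letters = fixed_letters,
                 tied_groups = groups, omit = omit, temperature = temperature,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 tie_mode = tie_mode),
            class = "design_constraints")
}

#' Sample a decoding order under constraints
#'
#' Decoding proceeds over slots: each fixed position is its own slot, each
#' tied group is decoded simultaneously as one slot, and every remaining
#' position is a singleton slot. All fixed slots precede all free slots (the
#' fixed context is decoded first); within each class the order is uniformly
#' random and deterministic given the seed.
#'
#' @param constraints A [design_constraints()].
#' @param n_positions Number of designable positions.
#' @param seed Integer seed.
#' @return A `decoding_order` with `slots` (list of integer vectors) and
#'   `fixed_slots` (indices of the fixed slots).
#' @export
sample_decoding_order <- function(constraints, n_positions, seed = 0L) {
  all_pos <- seq_len(n_positions)
  bad <- setdiff(c(constraints$fixed_pos,
                   unlist(lapply(constraints$tied_groups, `[[`, "pos"))),
                 all_pos)
  if (length(bad)) stop("sample_decoding_order: positions out of range: ",
                        paste(bad, collapse = ", "))
  tied_pos <- unlist(lapply(constraints$tied_groups, `[[`, "pos"))
  free <- setdiff(all_pos, c(constraints$fixed_pos, tied_pos))
  fixed_slots <- lapply(constraints$fixed_pos, identity)
  free_slots <- c(lapply(constraints$tied_groups, `[[`, "pos"),
                  lapply(free, identity))
  with_seed(seed, {
    if (length(fixed_slots) > 1L) fixed_slots <- sample(fixed_slots)
    if (length(free_slots) > 1L) free_slots <- sample(free_slots)
  })
  slots <- c(fixed_slots, free_slots)
  structure(list(slots = slots,
                 fixed_slots = seq_along(fixed_slots)),
            class = "decoding_order")
}

#' Combine logits of tied positions into one sampling distribution
#'
#' The combined logits are `sum(c_i * l_i) / sum(|c_i|)` — a plain average
#' for symmetric (unit-coefficient) tying, and a scale-stable signed
#' combination for multi-state design. Omitted letters are masked to -Inf
#' before the temperature softmax. In `"probabilities"` mode each member is
#' soft-maxed first (with omit mask and temperature), then the coefficient-
#' weighted average is clipped at zero and renormalized.
#'
#' @param logits_list List of equal-length numeric logit vectors.
#' @param coefficients Numeric coefficients, not all zero.
#' @param temperature Positive temperature.
#' @param omit Letters masked out of the distribution.
#' @param mode `"logits"` or `"probabilities"`.
#' @return Probability vector over the vocabulary (omitted letters get 0).
#' @export
combine_tied_logits <- function(logits_list, coefficients = NULL,
                                temperature = 1, omit = character(0),
                                mode = c("logits", "probabilities")) {
  mode <- match.arg(mode)
  stopifnot(length(logits_list) >= 1L)
  if (is.null(coefficients)) coefficients <- rep(1, length(logits_list))
  stopifnot(length(coefficients) == length(logits_list))
  if (sum(abs(coefficients)) == 0) {
    stop("combine_tied_logits: all coefficients are zero")
  }
  v <- length(logits_list[[1]])
  omit_idx <- match(unique(toupper(omit)), aa_alphabet())
  omit_idx <- omit_idx[!is.na(omit_idx) & omit_idx <= v]
  if (mode == "logits") {
    comb <- Reduce(`+`, Map(`*`, logits_list, coefficients)) /
      sum(abs(coefficients))
    comb[omit_idx] <- -Inf
    softmax_vec(comb / temperature)
  } else {
    probs <- lapply(logits_list, function(l) {
      l[omit_idx] <- -Inf
      softmax_vec(l / temperature)
    })
    w <- coefficients / sum(abs(coefficients))
    p <- pmax(Reduce(`+`, Map(`*`, probs, w)), 0)
    p / sum(p)
  }
}

#' Sample sequences for a backbone under constraints
#'
#' Runs the encoder once, then for each sample draws a decoding order
#' (fixed context first), iterates over slots, predicts logits at every slot
#' member given the current sequence context, combines tied logits, and
#' draws one letter per slot at the requested temperature. The reported
#' average log probability is the mean over positions of the temperature-1
#' log-softmax of each position's own logits at its chosen letter (the
#' ranking score), independent of the omit mask and temperature used for
#' drawing.
#'
#' @param params,config Model parameters and configuration.
#' @param structure A [backbone_structure()].
#' @param constraints A [design_constraints()].
#' @param reference Optional reference sequence for recovery reporting.
#' @return A `design_result` with one entry per sample: per-chain sequences,
#'   tokens, the decoding order, per-position sampling probabilities,
#'   avg_log_prob, recovery.
#' @export
sample_sequence <- function(params, config, structure,
                            constraints = design_constraints(),
                            reference = NULL) {
  fcfg <- config$featurizer
  fcfg$noise_std <- 0
  graph <- featurize_graph(structure, fcfg)
  enc <- encode_graph(params, config, graph)
  n <- graph$n
  alpha <- aa_alphabet()[seq_len(config$vocab)]
  fixed_tok <- match(constraints$fixed_letters, alpha)
  if (anyNA(fixed_tok)) stop("sample_sequence: fixed letter outside vocabulary")
  ref_tok <- if (!is.null(reference)) {
    if (is.character(reference)) seq_to_tokens(reference) else reference
  }
  samples <- vector("list", constraints$n_samples)
  for (s in seq_len(constraints$n_samples)) {
    sseed <- substream_seed(constraints$seed, "sample", s)
    ord <- sample_decoding_order(constraints, n,
                                 seed = substream_seed(sseed, "order"))
    tokens <- rep(NA_integer_, n)
    known <- logical(n)
    probs <- matrix(0, n, config$vocab)
    logp <- numeric(n)
    set.seed(substream_seed(sseed, "draw"))
    for (si in seq_along(ord$slots)) {
      members <- ord$slots[[si]]
      logits <- decoder_logits_positions(enc, params, config, tokens, known,
                                         members)
      lp1 <- logits - row_logsumexp(logits)   # T=1 full-vocab log-softmax
      if (si %in% ord$fixed_slots) {
        tok <- fixed_tok[match(members, constraints$fixed_pos)]
        p <- numeric(config$vocab)
        p[tok] <- 1
        probs[members, ] <- rep(p, each = length(members))
      } else {
        g <- constraints$tied_groups
        gi <- which(vapply(g, function(x) identical(sort(x$pos), sort(members)),
                           TRUE))
        coef <- if (length(gi)) g[[gi]]$coef[match(members, g[[gi]]$pos)] else
          rep(1, length(members))
        p <- combine_tied_logits(lapply(seq_along(members),
                                        function(i) logits[i, ]),
                                 coef, constraints$temperature,
                                 constraints$omit, constraints$tie_mode)
        tok <- rep(sample.int(config$vocab, 1L, prob = p), length(members))
        probs[members, ] <- rep(p, each = length(members))
      }
      tokens[members] <- tok
      known[members] <- TRUE
      logp[members] <- lp1[cbind(seq_along(members), tok)]
    }
    ch <- graph$chain
    chains <- vapply(unique(ch), function(cid)
      tokens_to_seq(tokens[ch == cid]), "")
    samples[[s]] <- list(
      tokens = tokens, chains = chains, order = ord, probs = probs,
      avg_log_prob = mean(logp),
      recovery = if (!is.null(ref_tok)) mean(tokens == ref_tok) else NULL
    )
  }
  structure(list(samples = samples, constraints = constraints,
                 seed = constraints$seed,
                 chain_ids = unique(graph$chain)),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> ", length(x$samples), " sample(s), T=",
      x$constraints$temperature, "\n", sep = "")
  for (i in seq_len(min(5L, length(x$samples)))) {
    s <- x$samples[[i]]
    cat(sprintf("  %d: %s (avg_log_prob %.3f%s)\n", i,
                paste(s$chains, collapse = "/"), s$avg_log_prob,
                if (!is.null(s$recovery))
                  sprintf(", recovery %.3f", s$recovery) else ""))
  }
  invisible(x)
}

#' Tied groups from chain or repeat symmetry
#'
#' `tie_chains` ties position i across all (equal-length) chains —
#' cyclic-symmetric homomer design. `tie_repeats` additionally ties
#' positions `i, i + r, i + 2r, ...` within every chain (repeat-protein
#' design); on a multi-chain structure this couples both within and between
#' chains. Coefficients are all 1.
#'
#' @param structure A [backbone_structure()].
#' @param mode `"none"`, `"tie_chains"`, or `"tie_repeats"`.
#' @param repeat_length Repeat unit length (for `tie_repeats`).
#' @return List of integer position groups (over valid residues), suitable
#'   for [design_constraints()].
#' @export
tying_from_symmetry <- function(structure, mode = c("none", "tie_chains",
                                                    "tie_repeats"),
                                repeat_length = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(list())
  valid <- which(structure$residue_mask)
  ch <- structure$chain[valid]
  chains <- unique(ch)
  lens <- vapply(chains, function(cid) sum(ch == cid), 0L)
  if (length(unique(lens)) != 1L) {
    stop("tying_from_symmetry: all chains must have equal length")
  }
  L <- lens[1]
  pos_by_chain <- lapply(chains, function(cid) which(ch == cid))
  if (mode == "tie_chains") {
    return(lapply(seq_len(L), function(i)
      vapply(pos_by_chain, `[`, 0L, i)))
  }
  if (is.null(repeat_length)) stop("tying_from_symmetry: repeat_length required")
  r <- as.integer(repeat_length)
  if (L %% r != 0L) {
    stop("tying_from_symmetry: chain length ", L,
         " not divisible by repeat_length ", r)
  }
  lapply(seq_len(r), function(i) {
    within <- seq(i, L, by = r)
    as.integer(unlist(lapply(pos_by_chain, `[`, within)))
  })
}

#' Multi-state sequence design
#'
#' Draws a single sequence compatible with several backbone states: each
#' state is featurized and encoded independently, and at every decoding slot
#' the per-state logits at the same positions are combined with the signed
#' state coefficients (positive to favor a state, negative to disfavor it)
#' before sampling. States are matched by position index and must have equal
#' numbers of valid residues.
#'
#' @param params,config Model parameters and configuration.
#' @param structures List of [backbone_structure()] states.
#' @param state_coefficients Numeric vector, one per state, not all zero.
#' @param constraints A [design_constraints()] (tied groups not supported
#'   here; positions are implicitly tied across states).
#' @return A `design_result`; chain sequences follow the first state.
#' @export
sample_multistate <- function(params, config, structures, state_coefficients,
                              constraints = design_constraints()) {
  stopifnot(length(structures) >= 2L,
            length(state_coefficients) == length(structures))
  if (sum(abs(state_coefficients)) == 0) {
    stop("sample_multistate: all state coefficients are zero")
  }
  if (length(constraints$tied_groups)) {
    stop("sample_multistate: tied groups are not supported in multi-state mode")
  }
  fcfg <- config$featurizer
  fcfg$noise_std <- 0
  encs <- lapply(structures, function(st)
    encode_graph(params, config, featurize_graph(st, fcfg)))
  ns <- vapply(encs, function(e) e$graph$n, 0L)
  if (length(unique(ns)) != 1L) {
    stop("sample_multistate: states must have equal numbers of valid residues")
  }
  n <- ns[1]
  alpha <- aa_alphabet()[seq_len(config$vocab)]
  fixed_tok <- match(constraints$fixed_letters, alpha)
  samples <- vector("list", constraints$n_samples)
  for (s in seq_len(constraints$n_samples)) {
    sseed <- substream_seed(constraints$seed, "msample", s)
    ord <- sample_decoding_order(constraints, n,
                                 seed = substream_seed(sseed, "order"))
    tokens <- rep(NA_integer_, n)
    known <- logical(n)
    logp <- numeric(n)
    set.seed(substream_seed(sseed, "draw"))
    for (si in seq_along(ord$slots)) {
      members <- ord$slots[[si]]
      state_logits <- lapply(encs, function(e)
        decoder_logits_positions(e, params, config, tokens, known, members))
      if (si %in% ord$fixed_slots) {
        tok <- fixed_tok[match(members, constraints$fixed_pos)]
      } else {
        p <- combine_tied_logits(lapply(state_logits, function(l)
          colMeans(l[, , drop = FALSE])), state_coefficients,
          constraints$temperature, constraints$omit, constraints$tie_mode)
        tok <- rep(sample.int(config$vocab, 1L, prob = p), length(members))
      }
      comb <- Reduce(`+`, Map(`*`, state_logits, state_coefficients)) /
        sum(abs(state_coefficients))
      lp1 <- comb - row_logsumexp(comb)
      tokens[members] <- tok
      known[members] <- TRUE
      logp[members] <- lp1[cbind(seq_along(members), tok)]
    }
    ch <- encs[[1]]$graph$chain
    samples[[s]] <- list(tokens = tokens,
                         chains = vapply(unique(ch), function(cid)
                           tokens_to_seq(tokens[ch == cid]), ""),
                         order = ord, avg_log_prob = mean(logp))
  }
  structure(list(samples = samples, constraints = constraints,
                 seed = constraints$seed),
            class = "design_result")
}

#' Parse a JSON design-constraint specification
#'
#' Schema: `{"fixed": {"A12": "G"}, "tied": [[["A1", 1.0], ["B1", 1.0]]],
#' "omit": ["C"], "temperature": 0.1, "n_samples": 8, "seed": 0}`.
#' Position keys are chain letter + author residue number and are resolved
#' against the structure's numbering.
#'
#' @param json Path to a JSON file, or a JSON string.
#' @param structure The [backbone_structure()] the constraints refer to.
#' @return A [design_constraints()].
#' @export
parse_constraints_json <- function(json, structure) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  valid <- which(structure$residue_mask)
  keys <- paste0(structure$chain[valid], structure$resno[valid])
  resolve <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("parse_constraints_json: unknown position key '", key, "'")
    i
  }
  fixed <- NULL
  if (!is.null(x$fixed) && length(x$fixed)) {
    fixed <- stats::setNames(unlist(x$fixed),
                             vapply(names(x$fixed), resolve, 0L))
  }
  tied <- lapply(x$tied %||% list(), function(grp) {
    lapply(grp, function(pc) list(resolve(pc[[1]]), as.numeric(pc[[2]])))
  })
  design_constraints(
    fixed = fixed, tied_groups = tied,
    omit = unlist(x$omit %||% "X"),
    temperature = x$temperature %||% 0.1,
    n_samples = x$n_samples %||% 1L,
    seed = x$seed %||% 0L,
    tie_mode = x$tie_mode %||% "logits"
  )
}
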