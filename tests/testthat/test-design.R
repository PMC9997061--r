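test_that("decoding orders are uniform over permutations", {
  cons <- design_constraints()
  counts <- table(vapply(1:6000, function(i) {
    ord <- sample_decoding_order(cons, 3L, seed = i)
    paste(unlist(ord$slots), collapse = "")
  }, ""))
  expect_length(counts, 6L)
  expect_true(all(abs(counts / 6000 - 1 / 6) < 0.02))
})

test_that("fixed positions are decoded first and tied groups share a slot", {
  cons <- design_constraints(fixed = c("2" = "G"))
  for (s in 1:25) {
    ord <- sample_decoding_order(cons, 4L, seed = s)
    expect_equal(ord$slots[[1]], 2L)
  }
  cons2 <- design_constraints(tied_groups = list(c(1L, 4L)))
  ord2 <- sample_decoding_order(cons2, 5L, seed = 3L)
  has_both <- vapply(ord2$slots, function(s) all(c(1L, 4L) %in% s), TRUE)
  expect_equal(sum(has_both), 1L)
  expect_equal(sum(lengths(ord2$slots)), 5L)
})

test_that("constraint validation rejects inconsistent specifications", {
  expect_error(design_constraints(fixed = c("1" = "A"),
                                  tied_groups = list(c(1L, 2L))), "disjoint")
  expect_error(design_constraints(tied_groups = list(c(1L, 2L), c(2L, 3L))),
               "more than one")
  expect_error(design_constraints(fixed = c("1" = "C"), omit = c("C")),
               "omit")
  expect_error(design_constraints(temperature = 0), "temperature")
  expect_error(sample_decoding_order(design_constraints(fixed = c("9" = "A")),
                                     4L), "out of range")
})

test_that("tied logit combination follows the signed-coefficient rule", {
  l1 <- c(1, 2, 3, -1, 0)
  # single member at temperature T is softmax(logits / T)
  p <- combine_tied_logits(list(l1), 1, temperature = 0.5)
  expect_equal(p, exp(l1 / 0.5) / sum(exp(l1 / 0.5)), tolerance = 1e-12)
  # duplicated member with unit coefficients is idempotent
  p2 <- combine_tied_logits(list(l1, l1), c(1, 1), temperature = 0.5)
  expect_equal(p2, p, tolerance = 1e-12)
  # opposing coefficients on identical logits cancel to uniform
  p3 <- combine_tied_logits(list(l1, l1), c(1, -1), temperature = 1)
  expect_equal(p3, rep(0.2, 5), tolerance = 1e-12)
  # omit masking removes letters and renormalizes
  p4 <- combine_tied_logits(list(c(0, 0, 0)), 1, omit = "A")  # A is index 1
  expect_equal(p4, c(0, 0.5, 0.5), tolerance = 1e-12)
  expect_error(combine_tied_logits(list(l1, l1), c(0, 0)), "zero")
  # probability-averaging mode agrees for a single member
  p5 <- combine_tied_logits(list(l1), 1, temperature = 0.5,
                            mode = "probabilities")
  expect_equal(p5, p, tolerance = 1e-12)
})

test_that("sampling honors fixed letters, ties, and omit sets", {
  cfg <- tiny_config(hidden = 8L, k = 8L, layers = 1L)
  p <- init_params(cfg, 2L)
  rec <- toy_record(8L)
  cons <- design_constraints(fixed = c("3" = "G", "5" = "W"),
                             tied_groups = list(c(1L, 8L)),
                             omit = c("X", "C"), n_samples = 6L, seed = 11L,
                             temperature = 0.5)
  res <- sample_sequence(p, cfg, rec$structure, cons)
  for (s in res$samples) {
    letters <- strsplit(s$chains[[1]], "")[[1]]
    expect_equal(letters[3], "G")
    expect_equal(letters[5], "W")
    expect_equal(letters[1], letters[8])
    expect_false(any(letters[-c(3, 5)] %in% c("X", "C")))
    # sampling probabilities sum to 1 over the non-omitted vocabulary
    expect_equal(rowSums(s$probs), rep(1, 8), tolerance = 1e-9)
    expect_true(all(s$probs[, match(c("X", "C"), aa_alphabet())][-c(3, 5), ] == 0))
  }
  # a fully fixed design returns the fixed sequence and still scores it
  full <- stats::setNames(strsplit(rec$sequence, "")[[1]],
                          as.character(1:8))
  res2 <- sample_sequence(p, cfg, rec$structure,
                          design_constraints(fixed = full, n_samples = 1L))
  expect_equal(res2$samples[[1]]$chains[[1]], rec$sequence)
  expect_true(is.finite(res2$samples[[1]]$avg_log_prob))
  expect_lt(res2$samples[[1]]$avg_log_prob, 0)
})

test_that("a fully tied homodimer designs identical chains", {
  cfg <- tiny_config(hidden = 8L, k = 10L, layers = 1L)
  p <- init_params(cfg, 5L)
  dim_st <- make_cyclic_assembly(make_backbone(synthetic_spec("helix", 7L)),
                                 2L, radius = 9)
  cons <- design_constraints(tied_groups = tying_from_symmetry(dim_st, "tie_chains"),
                             n_samples = 4L, seed = 2L, temperature = 0.8)
  res <- sample_sequence(p, cfg, dim_st, cons)
  for (s in res$samples) expect_equal(s$chains[[1]], s$chains[[2]])
})

test_that("the low-temperature limit reproduces greedy argmax decoding", {
  cfg <- tiny_config(hidden = 8L, k = 8L, layers = 1L)
  p <- init_params(cfg, 7L)
  rec <- toy_record(9L)
  g <- featurize_graph(rec$structure, cfg$featurizer)
  enc <- encode_graph(p, cfg, g)
  cons <- design_constraints(temperature = 1e-6, n_samples = 1L, seed = 4L)
  res <- sample_sequence(p, cfg, rec$structure, cons)
  s <- res$samples[[1]]
  # replay the same decoding order greedily by hand
  tokens <- rep(NA_integer_, 9L); known <- logical(9L)
  for (slot in s$order$slots) {
    lg <- invfold:::decoder_logits_positions(enc, p, cfg, tokens, known, slot)
    lg[, 21L] <- -Inf    # omit X
    tokens[slot] <- which.max(lg[1, ])
    known[slot] <- TRUE
  }
  expect_equal(s$tokens, tokens)
})

test_that("untied design equals singleton-tied design under the same seed", {
  cfg <- tiny_config(hidden = 8L, k = 8L, layers = 1L)
  p <- init_params(cfg, 9L)
  rec <- toy_record(7L)
  c_untied <- design_constraints(n_samples = 2L, seed = 6L, temperature = 0.7)
  c_tied <- design_constraints(tied_groups = as.list(1:7), n_samples = 2L,
                               seed = 6L, temperature = 0.7)
  r1 <- sample_sequence(p, cfg, rec$structure, c_untied)
  r2 <- sample_sequence(p, cfg, rec$structure, c_tied)
  expect_identical(lapply(r1$samples, `[[`, "tokens"),
                   lapply(r2$samples, `[[`, "tokens"))
})

test_that("sampling entropy and sequence diversity grow with temperature", {
  # per-slot distribution entropy is non-decreasing in T for fixed logits
  l <- c(2, 1, 0.5, -1, 0)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  es <- vapply(c(0.1, 0.5, 1, 2), function(T)
    ent(combine_tied_logits(list(l), 1, temperature = T)), 0)
  expect_true(all(diff(es) > 0))
  # mean pairwise hamming diversity rises from T = 0.1 to T = 1.0
  cfg <- tiny_config(hidden = 8L, k = 8L, layers = 1L)
  p <- init_params(cfg, 13L)
  rec <- toy_record(10L)
  divers <- function(T) {
    res <- sample_sequence(p, cfg, rec$structure,
                           design_constraints(temperature = T,
                                              n_samples = 20L, seed = 3L))
    toks <- do.call(rbind, lapply(res$samples, `[[`, "tokens"))
    pairs <- utils::combn(nrow(toks), 2)
    mean(apply(pairs, 2, function(ij) mean(toks[ij[1], ] != toks[ij[2], ])))
  }
  expect_gt(divers(1.0), divers(0.1))
})

test_that("symmetry tying builds the expected groups", {
  tri <- make_cyclic_assembly(make_backbone(synthetic_spec("helix", 10L)),
                              3L, radius = 9)
  g1 <- tying_from_symmetry(tri, "tie_chains")
  expect_length(g1, 10L)
  expect_true(all(lengths(g1) == 3L))
  # single chain of 12, repeat length 4: 4 groups of 3
  ch <- make_backbone(synthetic_spec("helix", 12L))
  g2 <- tying_from_symmetry(ch, "tie_repeats", repeat_length = 4L)
  expect_length(g2, 4L)
  expect_true(all(lengths(g2) == 3L))
  # trimer of 12-residue chains with repeats: 4 groups of 9
  tri12 <- make_cyclic_assembly(make_backbone(synthetic_spec("helix", 12L)),
                                3L, radius = 10)
  g3 <- tying_from_symmetry(tri12, "tie_repeats", repeat_length = 4L)
  expect_length(g3, 4L)
  expect_true(all(lengths(g3) == 9L))
  expect_error(tying_from_symmetry(ch, "tie_repeats", repeat_length = 5L),
               "divisible")
})

test_that("JSON constraints resolve chain-and-number position keys", {
  dim_st <- make_cyclic_assembly(make_backbone(synthetic_spec("helix", 5L)),
                                 2L, radius = 9)
  js <- '{"fixed": {"A2": "G"}, "tied": [[["A1", 1.0], ["B1", 1.0]]],
          "omit": ["C"], "temperature": 0.25, "n_samples": 3, "seed": 7}'
  cons <- parse_constraints_json(js, dim_st)
  expect_equal(cons$fixed_pos, 2L)
  expect_equal(cons$fixed_letters, "G")
  expect_equal(cons$tied_groups[[1]]$pos, c(1L, 6L))
  expect_equal(cons$temperature, 0.25)
  expect_equal(cons$n_samples, 3L)
  expect_true("C" %in% cons$omit)
  expect_error(parse_constraints_json('{"fixed": {"Z9": "G"}}', dim_st),
               "unknown position")
})

test_that("multi-state design ties positions across backbone states", {
  cfg <- tiny_config(hidden = 8L, k = 8L, layers = 1L)
  p <- init_params(cfg, 15L)
  st1 <- make_backbone(synthetic_spec("helix", 8L, seed = 1L, jitter_std = 0.1))
  st2 <- make_backbone(synthetic_spec("strand", 8L, seed = 2L, jitter_std = 0.1))
  res <- sample_multistate(p, cfg, list(st1, st2), c(1, -0.5),
                           design_constraints(n_samples = 2L, seed = 3L))
  expect_length(res$samples, 2L)
  expect_equal(nchar(res$samples[[1]]$chains[[1]]), 8L)
  expect_error(sample_multistate(p, cfg, list(st1, st2), c(0, 0)),
               "zero")
  st3 <- make_backbone(synthetic_spec("helix", 9L))
  expect_error(sample_multistate(p, cfg, list(st1, st3), c(1, 1)),
               "equal numbers")
})
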