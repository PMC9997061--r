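test_that("RBF expansion matches its closed form and saturates smoothly", {
  cfg <- featurizer_config()
  mu <- seq(2, 22, length.out = 16)
  sigma <- mu[2] - mu[1]
  # component at its own center is exactly 1
  v <- rbf_encode(mu[5], cfg)
  expect_equal(v[1, 5], 1)
  # far tail is vanishingly small
  expect_lt(rbf_encode(mu[3] + 10 * sigma, cfg)[1, 3], 1e-40)
  # full vector at d = 12 equals the hand-computed expression
  d <- 12
  expect_equal(as.numeric(rbf_encode(d, cfg)),
               exp(-((d - mu) / sigma)^2), tolerance = 1e-12)
  expect_true(all(rbf_encode(c(0, 5, 50), cfg) <= 1))
})

test_that("positional encoding clips offsets and separates chains", {
  cfg <- featurizer_config()
  v <- positional_encoding(5L, 7L, "A", "A", cfg)
  expect_equal(which(v[1:65] == 1), 2 + 32 + 1)  # offset +2
  expect_equal(v[67], 1)
  v2 <- positional_encoding(1L, 101L, "A", "A", cfg)
  expect_equal(which(v2[1:65] == 1), 32 + 32 + 1) # clipped to +32
  v3 <- positional_encoding(4L, 9L, "A", "B", cfg)
  expect_equal(sum(v3[1:65]), 0)
  expect_equal(v3[66], 1)   # dedicated inter-chain class
  expect_equal(v3[67], 0)
})

test_that("edge feature width follows 25*n_rbf + 66 + 1 for any config", {
  for (nr in c(4L, 16L, 9L)) {
    cfg <- featurizer_config(n_rbf = nr)
    expect_equal(edge_feature_dim(cfg), 25L * nr + 67L)
    st <- make_backbone(synthetic_spec("helix", 6L))
    expect_length(edge_features(st, 1L, 3L, cfg), edge_feature_dim(cfg))
  }
  expect_equal(edge_feature_dim(featurizer_config(atom_set = "ca_only")),
               16L + 67L)
})

test_that("knn graph clamps k, breaks ties by index, and crosses chains", {
  st <- make_backbone(synthetic_spec("helix", 5L))
  g <- knn_graph(st, featurizer_config(k_neighbors = 48L))
  expect_equal(rowSums(g$edge_mask), rep(5, 5))
  expect_equal(g$neighbor_index[, 1], 1:5)   # self first at distance 0
  # collinear equally spaced trace of 3, middle node, no self
  st3 <- backbone_structure(rep("A", 3), as.character(1:3),
                            n = cbind(0:2 * 4, 1, 0), ca = cbind(0:2 * 4, 0, 0),
                            c = cbind(0:2 * 4 + 1, 0, 1), o = cbind(0:2 * 4, 2, 2))
  g3 <- knn_graph(st3, featurizer_config(k_neighbors = 2L, include_self = FALSE))
  expect_equal(g3$neighbor_index[2, 1:2], c(1L, 3L))  # tie broken toward node 1
  # two far-apart chains: neighbor lists cross chains once k exceeds chain size
  mono <- make_backbone(synthetic_spec("helix", 4L))
  far <- backbone_structure(
    c(mono$chain, rep("B", 4)), c(mono$resno, mono$resno),
    rbind(mono$n, mono$n + 100), rbind(mono$ca, mono$ca + 100),
    rbind(mono$c, mono$c + 100), rbind(mono$o, mono$o + 100))
  gf <- knn_graph(far, featurizer_config(k_neighbors = 8L))
  expect_equal(rowSums(gf$edge_mask), rep(8, 8))
  expect_true(any(gf$neighbor_index[1, ] > 4))
  expect_error(knn_graph(backbone_structure("A", "1",
    matrix(NA_real_, 1, 3), matrix(0, 1, 3), matrix(1, 1, 3), matrix(2, 1, 3),
    atom_mask = matrix(c(FALSE, TRUE, TRUE, TRUE), 1))), "no valid")
})

test_that("edge features are distance-based: symmetric grid, rigid invariant", {
  st <- make_backbone(synthetic_spec("helix", 8L, seed = 3L, jitter_std = 0.1))
  cfg <- featurizer_config(n_rbf = 8L)
  # self-edge: diagonal atom pairs at distance 0 give the d=0 RBF row
  v_self <- edge_features(st, 2L, 2L, cfg)
  r0 <- as.numeric(rbf_encode(0, cfg))
  for (p in c(1, 7, 13, 19, 25)) {   # N-N, Ca-Ca, C-C, O-O, Cb-Cb diagonal
    expect_equal(v_self[((p - 1) * 8 + 1):(p * 8)], r0, tolerance = 1e-12)
  }
  # swap (i, j): atom-pair grid transposes
  v_ij <- edge_features(st, 2L, 5L, cfg)
  v_ji <- edge_features(st, 5L, 2L, cfg)
  grid <- function(v) matrix(seq_len(25), 5, 5, byrow = TRUE)
  for (a in 1:5) for (b in 1:5) {
    p_ab <- (a - 1) * 5 + b
    p_ba <- (b - 1) * 5 + a
    expect_equal(v_ij[((p_ab - 1) * 8 + 1):(p_ab * 8)],
                 v_ji[((p_ba - 1) * 8 + 1):(p_ba * 8)], tolerance = 1e-12)
  }
  # rigid motion leaves the full feature vector unchanged
  st2 <- rigid_transform(st, seed = 9L)
  expect_equal(edge_features(st2, 2L, 5L, cfg), v_ij, tolerance = 1e-6)
})

test_that("full featurization is rigid-motion invariant and reproducible", {
  st <- make_backbone(synthetic_spec("bundle", 8L, n_chains = 3L, seed = 5L,
                                     jitter_std = 0.15))
  cfg <- featurizer_config(k_neighbors = 10L, n_rbf = 8L)
  g1 <- featurize_graph(st, cfg)
  g2 <- featurize_graph(rigid_transform(st, 11L), cfg)
  expect_equal(g1$nbr, g2$nbr)
  expect_lt(max(abs(g1$feat - g2$feat)), 1e-5)
  g3 <- featurize_graph(st, cfg)
  expect_identical(g1$feat, g3$feat)    # bit-reproducible without noise
})

test_that("backbone noise is seeded, scaled, and recomputes the virtual Cb", {
  st <- make_backbone(synthetic_spec("helix", 20L))
  expect_identical(add_backbone_noise(st, 0, 1L), st)
  a <- add_backbone_noise(st, 0.02, 7L)
  b <- add_backbone_noise(st, 0.02, 7L)
  expect_identical(a$ca, b$ca)
  expect_false(identical(a$ca, add_backbone_noise(st, 0.02, 8L)$ca))
  expect_error(add_backbone_noise(st, -1, 1L), "non-negative")
  # Cb is recomputed from the noised backbone, not translated
  expect_equal(a$cb, place_virtual_cb(a$n, a$ca, a$c), tolerance = 1e-12)
  # law of large numbers: sample std of ~1e5 components within 2% of 0.02
  big <- make_backbone(synthetic_spec("helix", 3000L))
  noisy <- add_backbone_noise(big, 0.02, 123L)
  delta <- c(noisy$n - big$n, noisy$ca - big$ca, noisy$c - big$c,
             noisy$o - big$o)
  expect_gt(length(delta), 3e4)
  expect_lt(abs(stats::sd(delta) - 0.02) / 0.02, 0.02)
})

test_that("burial metric is rigid-invariant, clamped, and orders compactness", {
  st <- make_backbone(synthetic_spec("bundle", 10L, n_chains = 3L, seed = 2L))
  b1 <- burial_metric(st)
  b2 <- burial_metric(rigid_transform(st, 3L))
  expect_equal(b1, b2, tolerance = 1e-9)
  # 3-residue structure averages over the 2 available neighbors
  st3 <- make_backbone(synthetic_spec("helix", 4L))
  b3 <- burial_metric(st3)
  d <- as.matrix(dist(st3$cb))
  expect_equal(b3[1], mean(sort(d[1, -1])[1:3]))
  expect_error(burial_metric(backbone_structure("A", "1", matrix(0, 1, 3),
    matrix(c(1, 0, 0), 1), matrix(c(1, 1, 0), 1), matrix(2, 1, 3))),
    "at least 2")
  # buried bundle core residue is more buried than an extended chain residue
  bun <- make_backbone(synthetic_spec("bundle", 12L, n_chains = 3L, radius = 7))
  ext <- make_backbone(synthetic_spec("strand", 36L))
  expect_lt(min(burial_metric(bun), na.rm = TRUE),
            min(burial_metric(ext)[10:26]))
})
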