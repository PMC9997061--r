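# atom order used for the 25 ordered distance pairs
.ATOMS5 <- c("N", "CA", "C", "O", "CB")

#' Featurizer configuration
#'
#' Controls the k-nearest-neighbor residue graph and its edge features:
#' Gaussian radial-basis expansion of the 25 interatomic distances between
#' the N, Ca, C, O and virtual Cb atoms of a residue pair, a per-chain
#' relative positional encoding capped at +/-32 residues, and a binary
#' same-chain flag. Coordinate noise (`noise_std`) is used during training
#' only.
#'
#' @param k_neighbors Number of nearest Ca neighbors per residue (default 48).
#' @param n_rbf Number of radial basis functions per distance (default 16).
#' @param rbf_min,rbf_max Range of RBF centers in Angstrom (2 to 22).
#' @param cap Relative-position cap in residues (fixed at 32).
#' @param noise_std Gaussian coordinate noise in Angstrom (0 at inference).
#' @param include_self Include the self-edge (encodes intra-residue geometry).
#' @param atom_set `"full"` for all 25 atom pairs, `"ca_only"` for the single
#'   Ca-Ca distance (the ancestral distance feature set).
#' @return A `featurizer_config` list.
#' @export
featurizer_config <- function(k_neighbors = 48L, n_rbf = 16L, rbf_min = 2,
                              rbf_max = 22, cap = 32L, noise_std = 0,
                              include_self = TRUE,
                              atom_set = c("full", "ca_only")) {
  atom_set <- match.arg(atom_set)
  stopifnot(k_neighbors >= 1L, n_rbf >= 2L, rbf_min < rbf_max, noise_std >= 0)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 n_rbf = as.integer(n_rbf),
                 rbf_min = rbf_min, rbf_max = rbf_max, cap = as.integer(cap),
                 noise_std = noise_std, include_self = isTRUE(include_self),
                 atom_set = atom_set),
            class = "featurizer_config")
}

# number of ordered atom pairs under the config
n_atom_pairs <- function(config) if (config$atom_set == "full") 25L else 1L

#' Edge feature dimensionality for a featurizer configuration
#'
#' `pairs * n_rbf` RBF values plus 65 clipped-offset classes, one inter-chain
#' class, and the same-chain bit.
#'
#' @param config A [featurizer_config()].
#' @return Integer feature width.
#' @export
edge_feature_dim <- function(config) {
  n_atom_pairs(config) * config$n_rbf + (2L * config$cap + 1L) + 1L + 1L
}

#' Gaussian radial basis expansion of a distance
#'
#' Centers are evenly spaced on `[rbf_min, rbf_max]`; the width equals the
#' center spacing, so distances beyond the range saturate smoothly.
#'
#' @param d Numeric vector of distances (Angstrom, non-negative).
#' @param config A [featurizer_config()].
#' @return A `length(d)`-by-`n_rbf` matrix with entries in (0, 1].
#' @export
rbf_encode <- function(d, config = featurizer_config()) {
  stopifnot(all(d >= 0))
  mu <- seq(config$rbf_min, config$rbf_max, length.out = config$n_rbf)
  sigma <- mu[2] - mu[1]
  exp(-(outer(d, mu, "-") / sigma)^2)
}

#' Per-chain relative positional encoding with chain flag
#'
#' Same-chain pairs one-hot encode the sequence offset `pos_j - pos_i`
#' clipped to `[-cap, +cap]` (65 classes at the default cap of 32) and set
#' the same-chain bit; pairs from different chains use a dedicated 66th
#' inter-chain class with the bit cleared.
#'
#' @param pos_i,pos_j Within-chain residue indices (any consistent base).
#' @param chain_i,chain_j Chain labels.
#' @param config A [featurizer_config()].
#' @return Numeric vector of length `2*cap + 3`.
#' @export
positional_encoding <- function(pos_i, pos_j, chain_i, chain_j,
                                config = featurizer_config()) {
  cap <- config$cap
  out <- numeric(2L * cap + 3L)
  if (identical(chain_i, chain_j)) {
    off <- max(-cap, min(cap, pos_j - pos_i))
    out[off + cap + 1L] <- 1
    out[2L * cap + 3L] <- 1          # same-chain bit
  } else {
    out[2L * cap + 2L] <- 1          # inter-chain class; bit stays 0
  }
  out
}

# per-residue within-chain 1-based positional index
chain_positions <- function(structure) {
  pos <- integer(length(structure$chain))
  for (cid in structure$chain_ids) {
    idx <- which(structure$chain == cid)
    pos[idx] <- seq_along(idx)
  }
  pos
}

#' k-nearest-neighbor residue graph
#'
#' Neighbors are selected by Ca-Ca Euclidean distance jointly across all
#' chains; invalid residues (missing N/Ca/C) never appear as neighbors and
#' get no neighbor list of their own. Ties are broken by lower residue
#' index. With `include_self` the first neighbor of every residue is itself.
#'
#' @param structure A [backbone_structure()].
#' @param config A [featurizer_config()].
#' @return List with `nodes` (indices of valid residues), `neighbor_index`
#'   (n_valid-by-k matrix of structure residue indices, NA for unused
#'   slots), and `edge_mask` (logical, same shape).
#' @export
knn_graph <- function(structure, config = featurizer_config()) {
  valid <- which(structure$residue_mask)
  nv <- length(valid)
  if (nv == 0L) stop("knn_graph: structure has no valid residues")
  k_eff <- min(config$k_neighbors,
               if (config$include_self) nv else nv - 1L)
  k_eff <- max(k_eff, 0L)
  ca <- structure$ca[valid, , drop = FALSE]
  d2 <- as.matrix(stats::dist(ca))^2
  if (!config$include_self) diag(d2) <- Inf
  nbr <- matrix(NA_integer_, nv, max(k_eff, 1L))
  for (i in seq_len(nv)) {
    ord <- order(d2[i, ], seq_len(nv))   # tie-break by lower index
    nbr[i, seq_len(k_eff)] <- valid[ord[seq_len(k_eff)]]
  }
  k_out <- max(config$k_neighbors, 1L)
  if (ncol(nbr) < k_out) {
    nbr <- cbind(nbr, matrix(NA_integer_, nv, k_out - ncol(nbr)))
  }
  list(nodes = valid, neighbor_index = nbr[, seq_len(k_out), drop = FALSE],
       edge_mask = !is.na(nbr[, seq_len(k_out), drop = FALSE]))
}

# stack the five atom coordinate matrices used for pair distances
.atom_stack <- function(structure) {
  list(N = structure$n, CA = structure$ca, C = structure$c, O = structure$o,
       CB = structure$cb)
}

#' Edge feature vector for one residue pair
#'
#' The 25 ordered atom-pair distances (atom of residue `i` first, fixed
#' order N, Ca, C, O, Cb crossed with itself), each RBF-expanded, followed by
#' the positional/chain encoding. Pairs touching a masked atom have their
#' RBF block zero-filled. Depends on coordinates only through distances, so
#' it is invariant under global rigid motion.
#'
#' @param structure A [backbone_structure()].
#' @param i,j Residue indices (1-based, both valid).
#' @param config A [featurizer_config()].
#' @return Numeric vector of length [edge_feature_dim()].
#' @export
edge_features <- function(structure, i, j, config = featurizer_config()) {
  stopifnot(structure$residue_mask[i], structure$residue_mask[j])
  at <- .atom_stack(structure)
  atoms <- if (config$atom_set == "full") .ATOMS5 else "CA"
  blocks <- list()
  ok <- function(idx, a) {
    if (a == "CB") structure$residue_mask[idx] else structure$atom_mask[idx, a]
  }
  for (a in atoms) for (b in atoms) {
    if (ok(i, a) && ok(j, b)) {
      d <- sqrt(sum((at[[a]][i, ] - at[[b]][j, ])^2))
      blocks[[length(blocks) + 1L]] <- as.numeric(rbf_encode(d, config))
    } else {
      blocks[[length(blocks) + 1L]] <- numeric(config$n_rbf)
    }
  }
  pos <- chain_positions(structure)
  c(unlist(blocks),
    positional_encoding(pos[i], pos[j], structure$chain[i], structure$chain[j],
                        config))
}

#' Add Gaussian coordinate noise to a backbone
#'
#' Perturbs every stored N/Ca/C/O coordinate component independently with
#' `N(0, std^2)` noise and recomputes the virtual Cb afterwards, exactly as
#' during noise-augmented training. Deterministic given `seed`.
#'
#' @param structure A [backbone_structure()].
#' @param std Noise standard deviation in Angstrom (>= 0).
#' @param seed Integer seed.
#' @return A new [backbone_structure()].
#' @export
add_backbone_noise <- function(structure, std, seed) {
  if (!is.numeric(std) || length(std) != 1L || std < 0) {
    stop("add_backbone_noise: std must be a single non-negative number")
  }
  if (std == 0) return(structure)
  nres <- n_residues(structure)
  noise <- with_seed(seed, matrix(stats::rnorm(nres * 12L, 0, std), nres, 12L))
  backbone_structure(
    structure$chain, structure$resno,
    structure$n + noise[, 1:3], structure$ca + noise[, 4:6],
    structure$c + noise[, 7:9], structure$o + noise[, 10:12],
    atom_mask = structure$atom_mask
  )
}

#' Per-residue burial metric
#'
#' Mean virtual-Cb distance from each residue to its 8 nearest other
#' residues (fewer when the structure has fewer than 9 valid residues).
#' Small values indicate buried (core) positions, large values exposed ones.
#'
#' @param structure A [backbone_structure()].
#' @param n_neighbors Number of closest neighbors averaged (default 8).
#' @return Numeric vector over all residues (NA for invalid residues).
#' @export
burial_metric <- function(structure, n_neighbors = 8L) {
  valid <- which(structure$residue_mask)
  if (length(valid) < 2L) {
    stop("burial_metric: needs at least 2 valid residues")
  }
  cb <- structure$cb[valid, , drop = FALSE]
  d <- as.matrix(stats::dist(cb))
  diag(d) <- Inf
  m <- min(n_neighbors, length(valid) - 1L)
  vals <- apply(d, 1L, function(r) mean(sort(r)[seq_len(m)]))
  out <- rep(NA_real_, n_residues(structure))
  out[valid] <- vals
  out
}

#' Full graph featurization of a backbone
#'
#' Builds the k-NN graph over valid residues and assembles the flattened
#' edge-feature matrix consumed by the network: for every (residue,
#' neighbor-slot) pair, the RBF-expanded atom-pair distances plus the
#' positional/chain encoding. Optionally applies Gaussian coordinate noise
#' first (virtual Cb recomputed after noising).
#'
#' @param structure A [backbone_structure()].
#' @param config A [featurizer_config()].
#' @param noise_seed Seed for coordinate noise; used when
#'   `config$noise_std > 0`.
#' @return List with `n` (valid residue count), `k`, `src`/`nbr` (flattened
#'   edge endpoint indices into the valid-residue ordering), `emask`
#'   (numeric 0/1 edge validity), `feat` (E-by-d feature matrix), `nodes`
#'   (valid residue indices in the structure), `chain`/`pos` (per valid
#'   residue).
#' @export
featurize_graph <- function(structure, config = featurizer_config(),
                            noise_seed = 0L) {
  if (config$noise_std > 0) {
    structure <- add_backbone_noise(structure, config$noise_std, noise_seed)
  }
  g <- knn_graph(structure, config)
  nodes <- g$nodes
  nv <- length(nodes)
  k <- ncol(g$neighbor_index)
  loc <- match(g$neighbor_index, nodes)        # structure idx -> valid idx
  loc_m <- matrix(loc, nv, k)
  src <- rep(seq_len(nv), times = k)           # column-major flatten
  nbr <- as.integer(loc_m)
  emask <- as.numeric(!is.na(nbr))
  nbr_f <- ifelse(is.na(nbr), 1L, nbr)         # placeholder; masked later
  at <- .atom_stack(structure)
  atoms <- if (config$atom_set == "full") .ATOMS5 else "CA"
  E <- nv * k
  n_pairs <- n_atom_pairs(config)
  feat <- matrix(0, E, edge_feature_dim(config))
  mu <- seq(config$rbf_min, config$rbf_max, length.out = config$n_rbf)
  sigma <- mu[2] - mu[1]
  src_s <- nodes[src]                          # structure indices
  nbr_s <- nodes[nbr_f]
  o_ok_i <- structure$atom_mask[src_s, "O"]
  o_ok_j <- structure$atom_mask[nbr_s, "O"]
  p <- 0L
  for (a in atoms) for (b in atoms) {
    p <- p + 1L
    d <- sqrt(rowSums((at[[a]][src_s, , drop = FALSE] -
                       at[[b]][nbr_s, , drop = FALSE])^2))
    block <- exp(-(outer(d, mu, "-") / sigma)^2)
    if (a == "O") block[!o_ok_i, ] <- 0
    if (b == "O") block[!o_ok_j, ] <- 0
    feat[, ((p - 1L) * config$n_rbf + 1L):(p * config$n_rbf)] <- block
  }
  # positional / chain encoding
  pos_all <- chain_positions(structure)
  pos <- pos_all[nodes]
  ch <- structure$chain[nodes]
  same <- ch[src] == ch[nbr_f]
  off <- pmax(-config$cap, pmin(config$cap, pos[nbr_f] - pos[src]))
  base <- n_pairs * config$n_rbf
  cls <- ifelse(same, off + config$cap + 1L, 2L * config$cap + 2L)
  feat[cbind(seq_len(E), base + cls)] <- 1
  feat[same, base + 2L * config$cap + 3L] <- 1
  feat <- feat * emask
  list(n = nv, k = k, src = src, nbr = nbr_f, emask = emask, feat = feat,
       nodes = nodes, chain = ch, pos = pos)
}
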