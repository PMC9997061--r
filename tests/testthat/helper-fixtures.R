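# shared fixture builders: tiny PDB texts, small models, toy structures

# minimal PDB ATOM record writer for hand-built test structures
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1, insert = "") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, "", resname, chain, resno, ifelse(insert == "", " ", insert),
          xyz[1], xyz[2], xyz[3], occ, 0)
}

# write a toy PDB with `n_res` residues on a helix-like trace; returns path
write_toy_pdb <- function(n_res = 3L, chain = "A", path = tempfile(fileext = ".pdb"),
                          drop_atom = NULL) {
  st <- make_backbone(synthetic_spec("helix", length = max(n_res, 4L)))
  lines <- character(0)
  serial <- 0L
  atoms <- c("N", "CA", "C", "O")
  slots <- c("n", "ca", "c", "o")
  for (i in seq_len(n_res)) {
    for (a in seq_along(atoms)) {
      if (!is.null(drop_atom) && drop_atom$res == i && drop_atom$atom == atoms[a]) next
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, atoms[a], "ALA", chain, i,
                                      st[[slots[a]]][i, ]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# small model + featurizer used throughout network tests
tiny_config <- function(hidden = 16L, k = 12L, layers = 2L, dropout = 0,
                        n_rbf = 8L, edge_updates = TRUE) {
  model_config(layers, layers, hidden_dim = hidden, dropout = dropout,
               edge_updates = edge_updates,
               featurizer = featurizer_config(k_neighbors = k, n_rbf = n_rbf))
}

# jittered helix with geometric-code sequence, as a ready (structure, seq) pair
toy_record <- function(length = 10L, seed = 1L, kind = "helix") {
  st <- make_backbone(synthetic_spec(kind, length = length, seed = seed,
                                     jitter_std = 0.1))
  list(structure = st, sequence = geometric_code_labels(st))
}

# apply a random rigid motion (rotation + translation) to a structure
rigid_transform <- function(st, seed = 1L) {
  R <- with_seed(seed, {
    m <- matrix(stats::rnorm(9), 3L)
    qr.Q(qr(m))
  })
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- with_seed(seed + 1L, stats::rnorm(3, 0, 10))
  mv <- function(m) m %*% R + rep(1, nrow(m)) %o% tr
  backbone_structure(st$chain, st$resno, mv(st$n), mv(st$ca), mv(st$c),
                     mv(st$o), atom_mask = st$atom_mask)
}

# expose a couple of internals used in tests
with_seed <- invfold:::with_seed
substream_seed <- invfold:::substream_seed
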