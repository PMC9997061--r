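test_that("a toy single-chain PDB is transcribed faithfully", {
  path <- write_toy_pdb(3L)
  st <- read_backbone(path, "pdb")
  expect_s3_class(st, "backbone_structure")
  expect_equal(st$chain_ids, "A")
  expect_equal(n_residues(st), 3L)
  expect_true(all(st$atom_mask))
  expect_true(all(st$residue_mask))
  expect_equal(st$resno, c("1", "2", "3"))
})

test_that("a missing O atom clears its mask but keeps the residue valid", {
  path <- write_toy_pdb(3L, drop_atom = list(res = 2L, atom = "O"))
  st <- read_backbone(path)
  expect_false(st$atom_mask[2, "O"])
  expect_true(st$residue_mask[2])
  # a missing backbone anchor invalidates the residue instead
  path2 <- write_toy_pdb(3L, drop_atom = list(res = 2L, atom = "CA"))
  st2 <- read_backbone(path2)
  expect_false(st2$residue_mask[2])
  expect_true(all(st2$residue_mask[c(1, 3)]))
})

test_that("two-chain files keep chain order and per-chain lengths", {
  p1 <- write_toy_pdb(4L, chain = "A")
  p2 <- write_toy_pdb(2L, chain = "B")
  atoms <- c(grep("^ATOM", readLines(p1), value = TRUE),
             grep("^ATOM", readLines(p2), value = TRUE))
  # renumber atom serials across the concatenated chains
  atoms <- vapply(seq_along(atoms), function(i)
    paste0("ATOM  ", formatC(i, width = 5), substring(atoms[i], 12L)), "")
  path <- tempfile(fileext = ".pdb")
  writeLines(c(atoms, "END"), path)
  st <- read_backbone(path)
  expect_equal(st$chain_ids, c("A", "B"))
  expect_equal(as.integer(table(factor(st$chain, levels = c("A", "B")))),
               c(4L, 2L))
})

test_that("alternate locations resolve to highest occupancy, ties to first", {
  st0 <- make_backbone(synthetic_spec("helix", 4L))
  l1 <- pdb_atom_line(1, "N", "ALA", "A", 1, st0$n[1, ], occ = 0.4)
  l2 <- pdb_atom_line(2, "N", "ALA", "A", 1, st0$n[1, ] + 5, occ = 0.6)
  rest <- c(pdb_atom_line(3, "CA", "ALA", "A", 1, st0$ca[1, ]),
            pdb_atom_line(4, "C", "ALA", "A", 1, st0$c[1, ]),
            pdb_atom_line(5, "O", "ALA", "A", 1, st0$o[1, ]))
  path <- tempfile(fileext = ".pdb")
  writeLines(c(l1, l2, rest, "END"), path)
  st <- read_backbone(path)
  expect_equal(st$n[1, ], unname(st0$n[1, ] + 5), tolerance = 1e-3)
})

test_that("unparseable and empty inputs raise informative errors", {
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a structure file", bad)
  expect_error(read_backbone(bad))
  expect_error(read_backbone(tempfile(fileext = ".pdb")), "no such file")
})

test_that("the mmCIF dialect reads the same backbone as PDB", {
  st <- make_backbone(synthetic_spec("helix", 5L, seed = 2L, jitter_std = 0.1))
  hdr <- c("data_synth", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  atoms <- c("N", "CA", "C", "O")
  slots <- c("n", "ca", "c", "o")
  rows <- character(0)
  k <- 0L
  for (i in 1:5) for (a in 1:4) {
    k <- k + 1L
    xyz <- st[[slots[a]]][i, ]
    rows <- c(rows, sprintf(
      "ATOM %d %s %s . ALA A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA A %s 1",
      k, substr(atoms[a], 1, 1), atoms[a], i, xyz[1], xyz[2], xyz[3], i,
      atoms[a]))
  }
  path <- tempfile(fileext = ".cif")
  writeLines(c(hdr, rows), path)
  stc <- read_backbone(path)           # dialect auto-detected from .cif
  expect_equal(n_residues(stc), 5L)
  expect_equal(stc$ca, st$ca, tolerance = 1e-3)
  expect_equal(stc$chain, rep("A", 5))
  expect_true(all(stc$residue_mask))
})

test_that("virtual Cb placement is rigid-motion equivariant", {
  with_seed(42, {
    for (rep in 1:5) {
      n <- stats::rnorm(3); ca <- stats::rnorm(3) + c(2, 0, 0)
      c3 <- stats::rnorm(3) + c(0, 2, 0)
      cb <- place_virtual_cb(n, ca, c3)
      tr <- stats::rnorm(3, 0, 10)
      expect_equal(place_virtual_cb(n + tr, ca + tr, c3 + tr), cb + tr,
                   tolerance = 1e-9)
      R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      expect_equal(place_virtual_cb(c(R %*% n), c(R %*% ca), c(R %*% c3)),
                   c(R %*% cb), tolerance = 1e-9)
    }
  })
})

test_that("virtual Cb matches an ideal tetrahedral placement oracle", {
  # ideal peptide triad: N-Ca 1.458 A, Ca-C 1.525 A, N-Ca-C angle 111 deg
  ca <- c(0, 0, 0)
  n <- 1.458 * c(1, 0, 0)
  ang <- 111 * pi / 180
  c3 <- 1.525 * c(cos(ang), sin(ang), 0)
  cb <- place_virtual_cb(n, ca, c3)
  expect_lt(abs(sqrt(sum((cb - ca)^2)) - 1.53), 0.05)
  # brute-force oracle: search the sphere for the direction making ideal
  # tetrahedral angles (109.5 deg) with both bonds, on the correct side
  u <- (n - ca) / sqrt(sum((n - ca)^2))
  v <- (c3 - ca) / sqrt(sum((c3 - ca)^2))
  best <- NULL; best_err <- Inf
  for (th in seq(0, pi, length.out = 181)) {
    for (ph in seq(-pi, pi, length.out = 361)) {
      d <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      err <- (acos(sum(d * u)) - 1.9111)^2 + (acos(sum(d * v)) - 1.9111)^2
      if (det(cbind(u, v, d)) < 0) next   # chirality: L-amino-acid side
      if (err < best_err) { best_err <- err; best <- d }
    }
  }
  oracle <- ca + 1.53 * best
  expect_lt(sqrt(sum((cb - oracle)^2)), 0.12)
})

test_that("degenerate collinear triads are rejected", {
  expect_error(place_virtual_cb(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("PDB round-trip preserves coordinates and masks", {
  st <- make_backbone(synthetic_spec("bundle", 8L, n_chains = 3L,
                                     seed = 7L, jitter_std = 0.2))
  path <- tempfile(fileext = ".pdb")
  write_backbone_pdb(st, path)
  st2 <- read_backbone(path)
  expect_equal(st2$ca, st$ca, tolerance = 1e-3)
  expect_equal(st2$n, st$n, tolerance = 1e-3)
  expect_equal(st2$o, st$o, tolerance = 1e-3)
  expect_equal(st2$atom_mask, st$atom_mask)
  expect_equal(st2$chain, st$chain)
})

test_that("design FASTA output carries samples, scores, and tied chains", {
  rec <- toy_record(8L, kind = "helix")
  cfg <- tiny_config(hidden = 8L, k = 6L, layers = 1L)
  params <- init_params(cfg, 1L)
  res <- sample_sequence(params, cfg, rec$structure,
                         design_constraints(n_samples = 2L, seed = 4L),
                         reference = rec$sequence)
  path <- tempfile(fileext = ".fasta")
  write_designs(res, path)
  lines <- readLines(path)
  heads <- grep("^>", lines, value = TRUE)
  expect_length(heads, 2L)
  expect_match(heads[1], "avg_log_prob=")
  expect_match(heads[1], "recovery=")
  # empty result errors and creates nothing
  res$samples <- list()
  p2 <- tempfile(fileext = ".fasta")
  expect_error(write_designs(res, p2), "no samples")
  expect_false(file.exists(p2))
  # tied homodimer: both chains identical in the description
  dim_st <- make_cyclic_assembly(make_backbone(synthetic_spec("helix", 6L)),
                                 2L, radius = 9)
  cons <- design_constraints(tied_groups = tying_from_symmetry(dim_st, "tie_chains"),
                             n_samples = 1L, seed = 1L)
  res2 <- sample_sequence(params, cfg, dim_st, cons)
  expect_equal(res2$samples[[1]]$chains[[1]], res2$samples[[1]]$chains[[2]])
})
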