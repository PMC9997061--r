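# Ideal-tetrahedral virtual-Cb weights for Cb = Ca + w1*(b x c) + w2*b + w3*c
# with b = Ca - N, c = C - Ca.
.CB_W <- c(-0.58273431, 0.56802827, -0.54067466)

#' Place a virtual beta-carbon from backbone N, Ca, C atoms
#'
#' Computes the ideal-geometry Cb position as an affine combination of the
#' vectors `b = Ca - N`, `c = C - Ca` and their cross product. The placement
#' depends on the three backbone atoms only, so featurization never needs the
#' (unknown) sequence, and glycine receives a virtual Cb like every other
#' residue. The construction is equivariant under rigid motion of its inputs.
#'
#' @param n,ca,c Numeric length-3 vectors, or n-by-3 matrices of coordinates
#'   in Angstrom.
#' @return Coordinates of the virtual Cb, same shape as the inputs.
#' @export
place_virtual_cb <- function(n, ca, c) {
  vec_in <- is.null(dim(n))
  if (vec_in) {
    n <- matrix(n, 1L); ca <- matrix(ca, 1L); c <- matrix(c, 1L)
  }
  if (!all(is.finite(n)) || !all(is.finite(ca)) || !all(is.finite(c))) {
    stop("place_virtual_cb: non-finite input coordinates")
  }
  b <- ca - n
  cc <- c - ca
  a <- cbind(
    b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
    b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
    b[, 1] * cc[, 2] - b[, 2] * cc[, 1]
  )
  # collinearity check: |b x c| relative to |b||c|
  na <- sqrt(rowSums(a^2))
  scale <- sqrt(rowSums(b^2)) * sqrt(rowSums(cc^2))
  if (any(scale < 1e-12) || any(na < 1e-8 * scale)) {
    stop("place_virtual_cb: degenerate (collinear) N/Ca/C triad")
  }
  cb <- ca + .CB_W[1] * a + .CB_W[2] * b + .CB_W[3] * cc
  if (vec_in) cb[1L, ] else cb
}

#' Construct a backbone structure object
#'
#' The container for all geometric inputs: per-residue N/Ca/C/O coordinates,
#' chain labels, author residue numbering (insertion codes appended), atom
#' presence masks, and a per-residue validity flag. The virtual Cb is
#' (re)computed here from N/Ca/C, so it is always consistent with the stored
#' coordinates. Residues missing any of N, Ca or C are kept in the record but
#' flagged invalid (`residue_mask = FALSE`); a missing O only clears its
#' entry in `atom_mask`.
#'
#' @param chain Character vector of per-residue chain labels.
#' @param resno Character vector of per-residue author numbers (insertion
#'   code appended, e.g. `"52A"`).
#' @param n,ca,c,o n-by-3 coordinate matrices (Angstrom); rows of missing
#'   atoms may hold any finite placeholder and are governed by `atom_mask`.
#' @param atom_mask n-by-4 logical matrix for atoms N, Ca, C, O. Defaults to
#'   all present.
#' @return An object of class `backbone_structure`.
#' @export
backbone_structure <- function(chain, resno, n, ca, c, o, atom_mask = NULL) {
  nres <- length(chain)
  stopifnot(length(resno) == nres, nrow(n) == nres, nrow(ca) == nres,
            nrow(c) == nres, nrow(o) == nres)
  if (is.null(atom_mask)) {
    atom_mask <- matrix(TRUE, nres, 4L)
  }
  colnames(atom_mask) <- c("N", "CA", "C", "O")
  residue_mask <- atom_mask[, "N"] & atom_mask[, "CA"] & atom_mask[, "C"] &
    apply(is.finite(n) & is.finite(ca) & is.finite(c), 1L, all)
  # zero-fill coordinates of absent atoms so arithmetic stays finite
  n[!atom_mask[, "N"], ] <- 0
  ca[!atom_mask[, "CA"], ] <- 0
  c[!atom_mask[, "C"], ] <- 0
  o[!atom_mask[, "O"], ] <- 0
  cb <- matrix(0, nres, 3L)
  if (any(residue_mask)) {
    cb[residue_mask, ] <- place_virtual_cb(
      n[residue_mask, , drop = FALSE],
      ca[residue_mask, , drop = FALSE],
      c[residue_mask, , drop = FALSE]
    )
  }
  structure(
    list(
      chain_ids = unique(chain),
      chain = as.character(chain),
      resno = as.character(resno),
      n = unname(n), ca = unname(ca), c = unname(c), o = unname(o),
      cb = unname(cb),
      atom_mask = atom_mask,
      residue_mask = residue_mask
    ),
    class = "backbone_structure"
  )
}

#' @export
print.backbone_structure <- function(x, ...) {
  per_chain <- table(factor(x$chain, levels = x$chain_ids))
  cat("<backbone_structure> ", length(x$chain), " residues, ",
      length(x$chain_ids), " chain(s): ",
      paste(sprintf("%s (%d)", names(per_chain), per_chain), collapse = ", "),
      "; valid: ", sum(x$residue_mask), "\n", sep = "")
  invisible(x)
}

#' Number of residues in a backbone structure
#' @param structure A `backbone_structure`.
#' @param valid_only Count only residues with `residue_mask` set.
#' @return Integer residue count.
#' @export
n_residues <- function(structure, valid_only = FALSE) {
  if (valid_only) sum(structure$residue_mask) else length(structure$chain)
}

# three-letter residue names accepted as protein polymer residues
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Read a protein backbone from a PDB or mmCIF file
#'
#' Extracts per-residue N, Ca, C, O coordinates for all protein chains.
#' Heteroatom records, waters and non-protein polymers are skipped; alternate
#' locations are resolved to the highest-occupancy copy (ties: first in
#' file); insertion codes are preserved in the residue numbering. Residues
#' missing any of N/Ca/C are retained but flagged invalid.
#'
#' @param path Path to the structure file.
#' @param dialect `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @return A [backbone_structure()].
#' @export
read_backbone <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_backbone: no such file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (dialect == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      # read.cif announces its beta status and absent helix/sheet records
      # on every call; neither concerns backbone extraction
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) {
      stop("read_backbone: failed to parse '", path, "' as ", dialect, ": ",
           conditionMessage(e))
    }
  )
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$resid %in% .AA3 &
    at$elety %in% c("N", "CA", "C", "O")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("read_backbone: no protein residues in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  rid <- paste(at$chain, at$resno, at$insert, sep = "\r")
  # residue order: first appearance in file, per chain
  res_order <- rid[!duplicated(rid)]
  res_chain <- at$chain[!duplicated(rid)]
  res_order <- res_order[order(match(res_chain, unique(at$chain)))]
  nres <- length(res_order)
  coords <- list(N = matrix(NA_real_, nres, 3L), CA = matrix(NA_real_, nres, 3L),
                 C = matrix(NA_real_, nres, 3L), O = matrix(NA_real_, nres, 3L))
  amask <- matrix(FALSE, nres, 4L, dimnames = list(NULL, c("N", "CA", "C", "O")))
  ri <- match(rid, res_order)
  # altloc resolution: within each (residue, atom), keep highest occupancy,
  # ties broken by file order (stable sort on -occupancy).
  key <- paste(ri, at$elety)
  ord <- order(-at$o)          # stable: preserves file order among ties
  first <- ord[!duplicated(key[ord])]
  for (k in first) {
    el <- at$elety[k]
    i <- ri[k]
    coords[[el]][i, ] <- c(at$x[k], at$y[k], at$z[k])
    amask[i, el] <- TRUE
  }
  parts <- strsplit(res_order, "\r", fixed = TRUE)
  chain <- vapply(parts, `[`, "", 1L)
  resno <- vapply(parts, function(p) paste0(p[2], if (length(p) >= 3) p[3] else ""), "")
  for (el in names(coords)) coords[[el]][!amask[, el], ] <- 0
  backbone_structure(chain, resno, coords$N, coords$CA, coords$C, coords$O,
                     atom_mask = amask)
}

#' Write a backbone structure to a PDB file
#'
#' Emits one ATOM record per present backbone atom (N, CA, C, O) with
#' glycine-free placeholder residue names taken from `resid` (default `GLY`).
#' Used for synthetic fixtures and round-trip tests.
#'
#' @param structure A [backbone_structure()].
#' @param path Output file path.
#' @param resid Optional per-residue 3-letter residue names.
#' @export
write_backbone_pdb <- function(structure, path, resid = NULL) {
  nres <- n_residues(structure)
  if (is.null(resid)) resid <- rep("GLY", nres)
  atoms <- c("N", "CA", "C", "O")
  slots <- c("n", "ca", "c", "o")
  xyz <- c(); eleno <- c(); elety <- c(); a_resno <- c(); a_resid <- c()
  a_chain <- c(); a_insert <- c()
  num <- as.integer(sub("([0-9-]+).*", "\\1", structure$resno))
  ins <- sub("^[0-9-]+", "", structure$resno)
  cnt <- 0L
  for (i in seq_len(nres)) {
    for (a in seq_along(atoms)) {
      if (!structure$atom_mask[i, a]) next
      cnt <- cnt + 1L
      xyz <- c(xyz, structure[[slots[a]]][i, ])
      eleno <- c(eleno, cnt)
      elety <- c(elety, atoms[a])
      a_resno <- c(a_resno, num[i])
      a_resid <- c(a_resid, resid[i])
      a_chain <- c(a_chain, structure$chain[i])
      a_insert <- c(a_insert, if (nzchar(ins[i])) ins[i] else NA)
    }
  }
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz, resno = a_resno,
                   resid = a_resid, eleno = eleno, elety = elety,
                   chain = a_chain, insert = a_insert, verbose = FALSE)
  invisible(path)
}

#' Write design results to a FASTA file
#'
#' One record per sample. The header carries the sample index, sampling
#' temperature, average log probability, and (when a reference sequence was
#' supplied) sequence recovery. Multi-chain sequences are concatenated in the
#' record and shown joined by `/` in the description.
#'
#' @param designs A `design_result` from [sample_sequence()].
#' @param path Output FASTA path.
#' @export
write_designs <- function(designs, path) {
  stopifnot(inherits(designs, "design_result"))
  if (length(designs$samples) == 0L) stop("write_designs: no samples to write")
  seqs <- vapply(designs$samples, function(s) paste(s$chains, collapse = ""), "")
  hdr <- vapply(seq_along(designs$samples), function(i) {
    s <- designs$samples[[i]]
    h <- sprintf("sample_%d T=%g avg_log_prob=%.4f", i,
                 designs$constraints$temperature, s$avg_log_prob)
    if (!is.null(s$recovery)) h <- sprintf("%s recovery=%.4f", h, s$recovery)
    sprintf("%s seq=%s", h, paste(s$chains, collapse = "/"))
  }, "")
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
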