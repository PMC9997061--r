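#' Amino-acid vocabulary
#'
#' The 21-letter design vocabulary: the 20 standard amino acids in
#' alphabetical one-letter order, plus `X` (unknown). `X` is never sampled
#' during design but is accepted as sequence context.
#'
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
}

#' Convert a sequence string to integer tokens
#'
#' @param x Character scalar (e.g. `"ACDE"`) or character vector of single
#'   letters. Lowercase accepted.
#' @return Integer vector of 1-based token indices into [aa_alphabet()].
#' @export
seq_to_tokens <- function(x) {
  if (length(x) == 1L && nchar(x[1]) > 1L) x <- strsplit(x, "")[[1]]
  tok <- match(toupper(x), aa_alphabet())
  if (anyNA(tok)) {
    bad <- unique(toupper(x)[is.na(tok)])
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  tok
}

#' Convert integer tokens back to a sequence string
#'
#' @param tok Integer vector of token indices.
#' @return Character scalar.
#' @export
tokens_to_seq <- function(tok) {
  paste(aa_alphabet()[tok], collapse = "")
}

# Derive an independent 32-bit sub-seed from (seed, label, index).
# Splitmix-style integer mixing keeps substreams (noise / order / sampling /
# dropout / init) decorrelated while remaining reproducible from one seed.
substream_seed <- function(seed, label, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", index))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  x <- (as.numeric(seed) %% 2147483647) + h
  # two rounds of multiplicative mixing in double precision (exact < 2^53)
  x <- (x * 48271) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}

# Evaluate expr with a temporarily seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Numerically stable log-sum-exp by row of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Row-wise softmax of a matrix (stable).
row_softmax <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# Softmax of a vector (stable); -Inf entries give exact zeros.
softmax_vec <- function(v) {
  e <- exp(v - max(v[is.finite(v)]))
  e[!is.finite(v) & v < 0] <- 0
  e / sum(e)
}

# rowsum() that always returns n rows aligned 1..n even when groups are absent.
rowsum_n <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  rs <- rowsum(m, group = idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
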