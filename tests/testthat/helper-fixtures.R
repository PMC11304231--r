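# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately reimplement each check naively and stay
# independent of the package code paths they verify.

rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

random_dna_fixture <- function(n, seed, alphabet = c("A", "C", "G", "T")) {
  withr::with_seed(seed, paste(sample(alphabet, n, replace = TRUE),
                               collapse = ""))
}

# Zero-width junction GRanges from plain vectors.
junction_gr <- function(chrom, junction, strand = "+") {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = junction + 1L, width = 0L),
    strand = strand)
  gr$junction <- as.integer(junction)
  gr
}

# Brute-force TIR oracle: enumerate every terminal-anchored ungapped
# window (anchor offsets <= tol, length >= minLen), keep those with
# identity >= minIdent, and return the maximum-score one (score =
# matches - mismatches; ties -> longer, then more identical).
tir_oracle <- function(s, minLen = 10L, minIdent = 0.8, tol = 5L) {
  s <- toupper(s)
  r <- rc(s)
  L <- nchar(s)
  best <- NULL
  for (i0 in 0:tol) for (j0 in 0:tol) {
    maxl <- (L - i0 - j0) %/% 2L
    if (maxl < minLen) next
    for (len in minLen:maxl) {
      a <- substr(s, i0 + 1L, i0 + len)
      b <- substr(r, j0 + 1L, j0 + len)
      m <- sum(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])
      ident <- m / len
      if (ident < minIdent) next
      score <- 2L * m - len
      better <- is.null(best) || score > best$score ||
        (score == best$score && len > best$len) ||
        (score == best$score && len == best$len && ident > best$identity)
      if (better) best <- list(len = len, identity = ident, score = score)
    }
  }
  best
}

# Naive O(n*m) interval-stabbing oracle for the junction overlap rule:
# a junction j overlaps [start, end] (1-based closed) iff the interval
# contains base j (0-based j-1 ... 1-based j) or base j+1.
stab_oracle <- function(junction, starts, ends) {
  vapply(junction, function(j) {
    any((starts <= j & j <= ends) | (starts <= j + 1L & j + 1L <= ends))
  }, TRUE)
}

# Full hypergeometric enumeration oracle for the two-sided Fisher test
# (minimum-likelihood rule), written from choose() only.
fisher_oracle <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  lo <- max(0L, K - n2)
  hi <- min(n1, K)
  ks <- lo:hi
  probs <- choose(n1, ks) * choose(n2, K - ks) / choose(n1 + n2, K)
  obs <- probs[ks == k1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Shannon information content of a base-count column, in bits.
entropy_ic <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  2 + sum(p * log2(p))
}

# Default element consensus and its terminal sequence, shared by the
# pipeline fixtures.
default_config <- function(seed, ...) simConfig(seed = seed, ...)

consensus_end <- function(config) {
  cons <- as.character(config@elementConsensus)
  substr(cons, nchar(cons) - config@transposonEndLength + 1L, nchar(cons))
}
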