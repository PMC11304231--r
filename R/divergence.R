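# Kimura two-parameter divergence and the repeat landscape.

#' @include AllClasses.R
#' @importFrom Biostrings DNAString pairwiseAlignment nucleotideSubstitutionMatrix
#'   alignedPattern alignedSubject
#' @importFrom graphics barplot
NULL

#' Kimura two-parameter distance
#'
#' Closed-form K2P distance from transition (`P`) and transversion
#' (`Q`) mismatch proportions:
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
#' When `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the distance is saturated
#' and `NA` is returned for that element.
#'
#' @param P,Q Transition and transversion mismatch proportions
#'   (vectorized, recycled).
#' @return Numeric vector of distances in substitutions/site, `NA`
#'   where saturated.
#' @examples
#' kimura2p(0.1, 0.05)  # 0.17018...
#' @export
kimura2p <- function(P, Q) {
  if (any(P < 0 | Q < 0)) stop("P and Q must be non-negative")
  if (any(P + Q > 1)) stop("P + Q cannot exceed 1")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  K <- rep(NA_real_, length(w1))
  ok <- w1 > 0 & w2 > 0
  K[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
  K
}

## Count transitions/transversions over gap-free columns of two aligned
## (equal-length, gapped) character strings.
.pq_from_aligned <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  if (length(av) != length(bv)) stop("aligned strings differ in length")
  keep <- av %in% .DNA_ALPHABET & bv %in% .DNA_ALPHABET
  av <- av[keep]; bv <- bv[keep]
  n <- length(av)
  if (n == 0L) return(list(n = 0L, P = NA_real_, Q = NA_real_))
  mis <- av != bv
  ts <- sum(mis & .TRANSITION[av] == bv)
  tv <- sum(mis) - ts
  list(n = n, P = ts / n, Q = tv / n)
}

#' K2P divergence of one copy against a reference
#'
#' Aligns a genomic copy to the family consensus/representative (global
#' alignment with affine gaps; match +1, mismatch -1, gap open -5 and
#' -1 per extra base) and computes transition/transversion proportions
#' over the gap-free columns, then the K2P distance. Pre-aligned pairs
#' (equal-length gapped strings, gaps as `-`) may be supplied with
#' `aligned = TRUE`, in which case no alignment is performed.
#'
#' @param copy,reference Copy and reference sequences (character or
#'   [Biostrings::DNAString]); gapped when `aligned = TRUE`.
#' @param copyId Identifier stored in the estimate.
#' @param aligned Set to `TRUE` when the inputs are already aligned.
#' @return A [DivergenceEstimate]; `saturated`/`NA` flags degenerate or
#'   saturated cases (including zero gap-free columns).
#' @export
copyDivergence <- function(copy, reference, copyId = "copy",
                           aligned = FALSE) {
  if (aligned) {
    a <- toupper(as.character(copy))
    b <- toupper(as.character(reference))
  } else {
    cs <- .as_dna_chr(copy, allow_n = TRUE, what = "copy")
    rs <- .as_dna_chr(reference, allow_n = TRUE, what = "reference")
    mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                        baseOnly = FALSE)
    aln <- pairwiseAlignment(DNAString(cs), DNAString(rs), type = "global",
                             substitutionMatrix = mat,
                             gapOpening = 4, gapExtension = 1)
    a <- as.character(alignedPattern(aln))
    b <- as.character(alignedSubject(aln))
  }
  pq <- .pq_from_aligned(a, b)
  if (pq$n == 0L) {
    return(new("DivergenceEstimate", copyId = copyId, alignedBp = 0L,
               P = NA_real_, Q = NA_real_, K = NA_real_, saturated = TRUE))
  }
  K <- kimura2p(pq$P, pq$Q)
  new("DivergenceEstimate", copyId = copyId, alignedBp = pq$n,
      P = pq$P, Q = pq$Q, K = K, saturated = is.na(K))
}

#' Divergence estimates for a set of copies
#'
#' @param copies Named [Biostrings::DNAStringSet] (or character vector)
#'   of copies.
#' @param reference Family consensus or representative sequence.
#' @param ... Passed to [copyDivergence()].
#' @return List of [DivergenceEstimate] objects.
#' @export
familyDivergence <- function(copies, reference, ...) {
  cs <- as.character(copies)
  ids <- names(cs)
  if (is.null(ids)) ids <- sprintf("copy%03d", seq_along(cs))
  lapply(seq_along(cs), function(i) {
    copyDivergence(cs[[i]], reference, copyId = ids[[i]], ...)
  })
}

#' Bin copy divergences into a landscape
#'
#' Sums the gap-free aligned bp of each copy into percent-divergence
#' bins (percent divergence = 100 * K), the divergence-vs-coverage
#' landscape used to read the age structure of a repeat family.
#' Saturated or undefined copies are excluded from the bins and their
#' aligned bp reported separately, so the binned mass always equals the
#' summed aligned bp of the usable copies.
#'
#' @param estimates List of [DivergenceEstimate] objects.
#' @param binWidthPct Bin width in percent divergence (default 1).
#' @param maxPct Upper edge of the last bin; defaults to the smallest
#'   multiple of `binWidthPct` covering the data (at least one bin).
#' @return A [DivergenceLandscape].
#' @export
buildLandscape <- function(estimates, binWidthPct = 1, maxPct = NULL) {
  if (!length(estimates)) stop("estimates must be non-empty")
  K <- vapply(estimates, function(e) e@K, 1)
  bp <- vapply(estimates, function(e) as.numeric(e@alignedBp), 1)
  sat <- vapply(estimates, function(e) e@saturated, TRUE) | is.na(K)
  pct <- 100 * K[!sat]
  usable <- bp[!sat]
  if (is.null(maxPct)) {
    maxPct <- if (length(pct)) {
      max(binWidthPct, binWidthPct * ceiling(max(pct) / binWidthPct + 1e-9))
    } else binWidthPct
    # a value exactly on the top edge still needs a bin
    if (length(pct) && max(pct) >= maxPct) maxPct <- maxPct + binWidthPct
  }
  edges <- seq(0, maxPct, by = binWidthPct)
  idx <- findInterval(pct, edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  cov <- vapply(seq_len(length(edges) - 1L),
                function(i) sum(usable[idx == i]), 1)
  new("DivergenceLandscape", binEdges = edges, coverage = cov,
      saturatedBp = sum(bp[sat]), nCopies = sum(!sat))
}

#' Landscape as a data frame
#'
#' @param landscape A [DivergenceLandscape].
#' @return Data frame with `bin_lo`, `bin_hi` (percent divergence) and
#'   `coverage_bp`.
#' @export
landscapeTable <- function(landscape) {
  e <- landscape@binEdges
  data.frame(bin_lo = e[-length(e)], bin_hi = e[-1L],
             coverage_bp = landscape@coverage)
}

#' Plot a divergence landscape
#'
#' Simple barplot of coverage (bp) against percent divergence.
#'
#' @param landscape A [DivergenceLandscape].
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plotLandscape <- function(landscape, ...) {
  df <- landscapeTable(landscape)
  invisible(barplot(df$coverage_bp,
                    names.arg = sprintf("%g", df$bin_lo),
                    xlab = "K divergence (%)", ylab = "coverage (bp)", ...))
}
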