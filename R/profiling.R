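# Integration-site profiling: logos, target-motif fraction, enrichment
# against random loci, genomic-safe-harbor classification.

#' @include AllClasses.R
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   consensusMatrix countPattern
#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps seqnames strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits DataFrame
#' @importFrom stats fisher.test rnbinom
NULL

## Normalize site input to a GRanges with a 0-based `junction` column.
.site_gr <- function(sites) {
  if (is(sites, "InsertionSiteSet")) sites <- sites(sites)
  stopifnot(is(sites, "GRanges"))
  if (is.null(sites$junction))
    stop("sites must carry a 'junction' metadata column (0-based)")
  sites
}

## A junction overlaps an interval iff the interval contains either of
## the two bases flanking the between-base coordinate. Represent each
## junction by a GRanges covering those two bases (1-based j, j+1).
.junction_flanks <- function(sites) {
  gr <- .site_gr(sites)
  j <- gr$junction
  GRanges(seqnames = seqnames(gr),
          ranges = IRanges(start = pmax(1L, j), end = j + 1L),
          strand = "*")
}

#' Extract strand-oriented windows around insertion junctions
#'
#' Returns the `window`-bp genomic sequence centered on each junction
#' (half the window on each side of the between-base coordinate),
#' reverse-complemented for minus-strand sites so that all windows read
#' in element orientation. Sites too close to a contig edge are dropped
#' with a warning.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param sites [GenomicRanges::GRanges] with a `junction` column, or
#'   an [InsertionSiteSet].
#' @param window Even window width in bp (default 60).
#' @return A [Biostrings::DNAStringSet] of windows (one per retained
#'   site).
#' @export
extractWindows <- function(genome, sites, window = 60L) {
  stopifnot(is(genome, "DNAStringSet"), window %% 2L == 0L)
  gr <- .site_gr(sites)
  chroms <- as.character(seqnames(gr))
  miss <- setdiff(unique(chroms), names(genome))
  if (length(miss))
    stop("contig(s) absent from genome: ", paste(miss, collapse = ", "))
  half <- window %/% 2L
  j <- gr$junction
  lo <- j - half + 1L            # 1-based
  hi <- j + half
  lens <- vapply(chroms, function(ch) length(genome[[ch]]), 1L)
  ok <- lo >= 1L & hi <= lens
  if (any(!ok))
    warning(sum(!ok), " site(s) within ", half,
            " bp of a contig edge were dropped")
  out <- vapply(which(ok), function(i) {
    s <- as.character(Biostrings::subseq(genome[[chroms[i]]], lo[i], hi[i]))
    if (as.character(strand(gr))[i] == "-") .revcomp_chr(s) else s
  }, "")
  DNAStringSet(out)
}

#' Build a sequence-logo matrix
#'
#' Column base frequencies and per-position information content
#' `IC[j] = 2 + sum_b f[j,b] * log2 f[j,b]` (with `0 * log 0 = 0`):
#' 2 bits when every window agrees, 0 bits for uniform base usage.
#'
#' @param windows Equal-length [Biostrings::DNAStringSet] (or character
#'   vector) of windows.
#' @return A [LogoMatrix].
#' @export
buildLogo <- function(windows) {
  ws <- as.character(windows)
  if (!length(ws)) stop("at least one window is required")
  if (length(unique(nchar(ws))) != 1L)
    stop("windows must have uniform length")
  cm <- consensusMatrix(DNAStringSet(ws), baseOnly = TRUE)
  freq <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  tot <- colSums(freq)
  if (any(tot == 0)) stop("a window column contains no A/C/G/T bases")
  freq <- sweep(freq, 2L, tot, "/")
  plogp <- freq * log2(freq)
  plogp[freq == 0] <- 0
  ic <- pmin(2, pmax(0, 2 + colSums(plogp)))
  new("LogoMatrix", freq = freq, infoContent = as.numeric(ic),
      nWindows = length(ws))
}

## Expand an IUPAC pattern check: does the fixed-length context match?
.iupac_match <- function(contexts, pattern) {
  pat <- DNAString(pattern)
  vapply(contexts, function(ctx) {
    if (is.na(ctx) || nchar(ctx) != length(pat)) return(FALSE)
    countPattern(pat, DNAString(ctx), fixed = FALSE) > 0L
  }, TRUE, USE.NAMES = FALSE)
}

#' Fraction of sites at the target motif
#'
#' Tests, per site, whether the strand-oriented genomic context around
#' the junction matches an IUPAC target pattern with the junction at
#' `junctionOffset` bases into the pattern. The shipped presets are the
#' Spy target motifs `AAATTT` (junction between AAA and TTT, offset 3)
#' and the degenerate `AAWTT` (offset 3). With
#' `bothOrientations = TRUE` the opposite orientation of the context is
#' also accepted, and per-orientation counts are reported.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param sites Sites as in [extractWindows()].
#' @param pattern IUPAC pattern (default `"AAWTT"`).
#' @param junctionOffset Bases of the pattern 5' of the junction
#'   (default 3).
#' @param bothOrientations Accept a match in either orientation of the
#'   context (default `TRUE`).
#' @return List with `fraction`, `nMatch`, `nSites`, and
#'   `matchForward`/`matchReverse` logical vectors.
#' @export
targetMotifFraction <- function(genome, sites, pattern = "AAWTT",
                                junctionOffset = 3L,
                                bothOrientations = TRUE) {
  gr <- .site_gr(sites)
  plen <- nchar(pattern)
  if (junctionOffset < 0L || junctionOffset > plen)
    stop("junctionOffset must lie within the pattern")
  chroms <- as.character(seqnames(gr))
  std <- as.character(strand(gr))
  j <- gr$junction
  lens <- vapply(chroms, function(ch) length(genome[[ch]]), 1L)
  ctx <- vapply(seq_along(gr), function(i) {
    if (std[i] == "-") {
      lo <- j[i] - (plen - junctionOffset) + 1L
      hi <- j[i] + junctionOffset
    } else {
      lo <- j[i] - junctionOffset + 1L
      hi <- j[i] + (plen - junctionOffset)
    }
    if (lo < 1L || hi > lens[i]) return(NA_character_)
    s <- as.character(Biostrings::subseq(genome[[chroms[i]]], lo, hi))
    if (std[i] == "-") .revcomp_chr(s) else s
  }, "")
  fwd <- .iupac_match(ctx, pattern)
  rev <- if (bothOrientations) {
    .iupac_match(vapply(ctx, function(s) {
      if (is.na(s)) NA_character_ else .revcomp_chr(s)
    }, "", USE.NAMES = FALSE), pattern)
  } else rep(FALSE, length(ctx))
  match <- fwd | rev
  list(fraction = mean(match), nMatch = sum(match), nSites = length(match),
       matchForward = fwd, matchReverse = rev)
}

#' Draw seeded random control loci
#'
#' Uniform junctions over the supplied chromosome lengths (chromosomes
#' weighted by length), optionally excluding masked regions; the random
#' control against which insertion-site fractions are compared.
#'
#' @param chromSizes Named integer vector of chromosome lengths.
#' @param n Number of loci (the field-standard control uses 100000).
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @param exclude Optional [GenomicRanges::GRanges] of regions (e.g.
#'   assembly gaps) whose loci are redrawn.
#' @return [GenomicRanges::GRanges] of zero-width junction anchors with
#'   a `junction` column and random strand.
#' @export
randomLoci <- function(chromSizes, n, seed = NULL, exclude = NULL) {
  stopifnot(!is.null(names(chromSizes)), all(chromSizes > 1))
  draw <- function(m) {
    ch <- sample(names(chromSizes), m, replace = TRUE,
                 prob = as.numeric(chromSizes))
    j <- vapply(ch, function(c2) {
      sample.int(chromSizes[[c2]] - 1L, 1L)
    }, 1L, USE.NAMES = FALSE)
    gr <- GRanges(seqnames = ch, ranges = IRanges(start = j + 1L, width = 0L),
                  strand = sample(c("+", "-"), m, replace = TRUE))
    gr$junction <- j
    gr
  }
  .with_seed(seed, {
    gr <- draw(n)
    if (!is.null(exclude) && length(exclude)) {
      for (it in 1:100) {
        bad <- countOverlaps(.junction_flanks(gr), exclude) > 0L
        if (!any(bad)) break
        gr[bad] <- draw(sum(bad))
      }
    }
    gr
  })
}

#' Category enrichment versus random loci
#'
#' For each genomic category (an interval set), compares the fraction
#' of insertion junctions overlapping the category with the fraction of
#' seeded uniform random loci doing so; fold change 1 marks the random
#' expectation. A junction overlaps an interval iff the interval
#' contains either base flanking the between-base coordinate.
#'
#' @param sites Sites as in [extractWindows()].
#' @param categories Named list of [GenomicRanges::GRanges] interval
#'   sets (genes, TSS windows, cancer genes, ChIP peaks, ...).
#' @param chromSizes Named chromosome lengths for the random control.
#' @param nRandom Number of random loci (default 100000).
#' @param seed RNG seed for the control.
#' @return An [EnrichmentResult]; rows with a zero random fraction and
#'   non-zero observed fraction are `flagged` (fold change infinite).
#' @export
enrichment <- function(sites, categories, chromSizes, nRandom = 100000L,
                       seed = NULL) {
  gr <- .site_gr(sites)
  stopifnot(is.list(categories), !is.null(names(categories)))
  rnd <- randomLoci(chromSizes, nRandom, seed = seed)
  obsFl <- .junction_flanks(gr)
  rndFl <- .junction_flanks(rnd)
  rows <- lapply(names(categories), function(nm) {
    cat_gr <- GenomicRanges::reduce(categories[[nm]])
    obs <- mean(countOverlaps(obsFl, cat_gr) > 0L)
    rndF <- mean(countOverlaps(rndFl, cat_gr) > 0L)
    fc <- if (rndF > 0) obs / rndF else if (obs > 0) Inf else NA_real_
    data.frame(category = nm, observedFraction = obs, randomFraction = rndF,
               foldChange = fc, nSites = length(gr), nRandom = nRandom,
               flagged = rndF == 0, stringsAsFactors = FALSE)
  })
  new("EnrichmentResult", table = do.call(rbind, rows),
      nRandom = as.integer(nRandom),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

## Regions upstream of stranded TSS points, and symmetric TSS windows.
.tss_upstream <- function(tss, width) {
  std <- as.character(strand(tss))
  if (any(std == "*"))
    stop("TSS points must be stranded (upstream is undefined otherwise)")
  t0 <- GenomicRanges::start(tss)
  lo <- ifelse(std == "+", pmax(1L, t0 - width), t0 + 1L)
  hi <- ifelse(std == "+", t0 - 1L, t0 + width)
  keep <- hi >= lo
  GRanges(seqnames = seqnames(tss)[keep],
          ranges = IRanges(start = lo[keep], end = hi[keep]), strand = "*")
}

.tss_window <- function(tss, half) {
  t0 <- GenomicRanges::start(tss)
  GRanges(seqnames = seqnames(tss),
          ranges = IRanges(start = pmax(1L, t0 - half), end = t0 + half),
          strand = "*")
}

#' Five-criterion genomic-safe-harbor classification
#'
#' Flags each site for the five safe-harbor criteria -- outside gene
#' bodies; outside cancer genes; outside miRNA genes; not within 50 kb
#' upstream of any TSS (strand-aware); outside TSS +/- 5 kb -- and
#' combines them by AND.
#'
#' @param sites Sites as in [extractWindows()].
#' @param genes,cancerGenes,mirnaGenes [GenomicRanges::GRanges]
#'   interval sets.
#' @param tss Stranded [GenomicRanges::GRanges] of TSS points (width
#'   1).
#' @param upstreamWidth Upstream clearance from TSSs (default 50000).
#' @param tssHalfWindow Half-width of the symmetric TSS window
#'   (default 5000).
#' @return [S4Vectors::DataFrame] of logicals `outsideGenes`,
#'   `outsideCancerGenes`, `outsideMirnaGenes`, `outsideTssUpstream50k`,
#'   `outsideTss5k`, `combined`.
#' @export
gshClassify <- function(sites, genes, cancerGenes, mirnaGenes, tss,
                        upstreamWidth = 50000L, tssHalfWindow = 5000L) {
  gr <- .site_gr(sites)
  fl <- .junction_flanks(gr)
  outside <- function(regions) {
    if (!length(regions)) return(rep(TRUE, length(fl)))
    countOverlaps(fl, GenomicRanges::reduce(regions,
                                            ignore.strand = TRUE)) == 0L
  }
  flags <- DataFrame(
    outsideGenes = outside(genes),
    outsideCancerGenes = outside(cancerGenes),
    outsideMirnaGenes = outside(mirnaGenes),
    outsideTssUpstream50k = outside(.tss_upstream(tss, upstreamWidth)),
    outsideTss5k = outside(.tss_window(tss, tssHalfWindow))
  )
  flags$combined <- flags$outsideGenes & flags$outsideCancerGenes &
    flags$outsideMirnaGenes & flags$outsideTssUpstream50k & flags$outsideTss5k
  flags
}

#' Aggregate GSH flags into a report
#'
#' @param flags Output of [gshClassify()].
#' @return A [GshReport] with per-criterion and combined pass
#'   fractions.
#' @export
gshReport <- function(flags) {
  crit <- c("outsideGenes", "outsideCancerGenes", "outsideMirnaGenes",
            "outsideTssUpstream50k", "outsideTss5k")
  per <- vapply(crit, function(cn) mean(flags[[cn]]), 1)
  new("GshReport", perCriterion = per, combined = mean(flags$combined),
      nSites = nrow(flags), flags = flags)
}

#' Two-sided Fisher exact comparison of two site sets
#'
#' Compares pass counts between two transposon systems (e.g. safe-
#' harbor fractions) with Fisher's exact test; the two-sided p-value
#' sums all tables with fixed margins whose probability does not exceed
#' the observed table's (minimum-likelihood rule).
#'
#' @param k1,n1 Passes and total for system 1.
#' @param k2,n2 Passes and total for system 2.
#' @return Two-sided p-value.
#' @examples
#' fisherCompare(3, 4, 1, 4)  # 34/70
#' @export
fisherCompare <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("both totals must be positive")
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0)
    stop("counts must satisfy 0 <= k <= n")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L, byrow = TRUE)
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Write an enrichment table as TSV
#'
#' @param result An [EnrichmentResult].
#' @param path Output path.
#' @return Invisibly, the table.
#' @export
writeEnrichmentTable <- function(result, path) {
  write.table(enrichmentTable(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(enrichmentTable(result))
}

#' Plot per-position logo information content
#'
#' @param logo A [LogoMatrix].
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plotLogo <- function(logo, ...) {
  invisible(graphics::barplot(infoContent(logo), ylim = c(0, 2),
                              xlab = "window position",
                              ylab = "information content (bits)", ...))
}
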