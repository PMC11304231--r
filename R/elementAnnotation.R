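# Element annotation: TIR detection, boundary refinement, copy counting,
# intactness classification, flank motifs and TSD detection.

#' @include AllClasses.R AllGenerics.R
#' @importFrom GenomicRanges GRanges reduce strand seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#'   translate matchPattern
NULL

#' Detect terminal inverted repeats
#'
#' Locates the terminal inverted repeat (TIR) pair of a candidate
#' cut-and-paste transposon. The detector compares the element prefix
#' against the reverse complement of its suffix over all anchor offsets
#' up to `anchorTolerance` from either terminus, ungapped; among the
#' windows of at least `minLen` whose identity reaches `minIdentity` it
#' returns the one with maximal alignment score (match +1, mismatch
#' -1; ties broken toward the longer, then the more identical window),
#' so the reported repeat ends at the true repeat boundary instead of
#' drifting into flanking sequence. Spy-family TIRs range from 15 bp to
#' 467 bp, so no upper length bound is imposed beyond half the element.
#'
#' @param x Element sequence ([Biostrings::DNAString] or character).
#' @param minLen Minimum TIR length to report (>= 5).
#' @param minIdentity Minimum match fraction in `(0, 1]`.
#' @param anchorTolerance Maximum distance (bp) of the repeat ends from
#'   the element termini.
#' @return A [TirPair], or `NULL` when no repeat of at least `minLen`
#'   reaches `minIdentity`.
#' @examples
#' tir <- paste(rep("ACGTG", 6), collapse = "")  # 30 bp
#' el <- paste0(tir, strrep("C", 200),
#'              as.character(Biostrings::reverseComplement(
#'                Biostrings::DNAString(tir))))
#' detectTirs(el)
#' @export
detectTirs <- function(x, minLen = 10L, minIdentity = 0.8,
                       anchorTolerance = 5L) {
  s <- .as_dna_chr(x, what = "element sequence")
  if (minLen < 5L) stop("minLen must be at least 5")
  if (minIdentity <= 0 || minIdentity > 1)
    stop("minIdentity must lie in (0, 1]")
  L <- nchar(s)
  if (L < 2L * minLen) stop("element shorter than twice minLen")
  av <- strsplit(s, "")[[1L]]
  bv <- strsplit(.revcomp_chr(s), "")[[1L]]
  best <- NULL
  for (i0 in 0:anchorTolerance) {
    for (j0 in 0:anchorTolerance) {
      maxl <- (L - i0 - j0) %/% 2L  # repeats must not overlap
      if (maxl < minLen) next
      m <- cumsum(av[(i0 + 1L):(i0 + maxl)] == bv[(j0 + 1L):(j0 + maxl)])
      lens <- minLen:maxl
      ident <- m[lens] / lens
      score <- 2L * m[lens] - lens   # matches - mismatches
      ok <- which(ident >= minIdentity)
      if (!length(ok)) next
      pick <- ok[order(score[ok], lens[ok], ident[ok],
                       decreasing = TRUE)[1L]]
      len <- lens[pick]
      cand <- list(len = len, identity = m[len] / len,
                   score = score[pick], i0 = i0, j0 = j0)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$len > best$len) ||
          (cand$score == best$score && cand$len == best$len &&
           cand$identity > best$identity)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  new("TirPair",
      left = IRanges(start = best$i0 + 1L, width = best$len),
      right = IRanges(end = L - best$j0, width = best$len),
      identity = best$identity)
}

#' Refine element boundaries from a multi-copy alignment
#'
#' Given a multiple alignment of element copies extracted with flanking
#' sequence on both sides, finds the element span as the maximal
#' contiguous block of columns in which at least `consistencyThreshold`
#' of the copies agree with the column consensus. Flank columns, being
#' mutually unrelated, fall below the threshold and are excluded.
#'
#' @param alignment A [Biostrings::DNAStringSet] of equal-width aligned
#'   rows (gaps as `-`), or a character matrix of single characters.
#' @param consistencyThreshold Minimum fraction of copies matching the
#'   column consensus for a column to be inside the element. The default
#'   0.6 clears the ~0.25 agreement expected of unrelated flanks.
#' @return An [IRanges::IRanges] giving the 1-based column interval of
#'   the element within the alignment.
#' @export
refineBoundaries <- function(alignment, consistencyThreshold = 0.6) {
  if (is(alignment, "DNAStringSet") || is.character(alignment)) {
    rows <- as.character(alignment)
    if (length(unique(nchar(rows))) != 1L)
      stop("alignment rows must have equal width")
    mat <- do.call(rbind, strsplit(toupper(rows), ""))
  } else if (is.matrix(alignment)) {
    mat <- toupper(alignment)
  } else {
    stop("alignment must be a DNAStringSet, character vector or matrix")
  }
  if (nrow(mat) < 3L)
    stop("insufficient evidence: boundary refinement needs >= 3 copies")
  agree <- apply(mat, 2L, function(col) max(table(col)) / length(col))
  ok <- agree >= consistencyThreshold
  if (!any(ok)) stop("no alignment column reaches the consistency threshold")
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  i <- runs[which.max(r$lengths[runs])]
  IRanges(start = starts[i], end = ends[i])
}

#' Count genomic copies of an element under coverage/identity filters
#'
#' Retains homology hits with coverage strictly above `minCoverage` and
#' identity strictly above `minIdentity` (hits at exactly the thresholds
#' are excluded), merges retained hits that lie on the same strand with
#' a gap of at most `mergeGap` bp (fragmented alignments of one copy),
#' and counts the merged loci.
#'
#' @param hits A [GenomicRanges::GRanges] of hits with metadata columns
#'   `identity` and `coverage` (both fractions), e.g. from
#'   [readBlastHits()].
#' @param minCoverage,minIdentity Strict lower bounds on aligned-length
#'   coverage of the element and percent identity (as fractions).
#' @param mergeGap Maximum gap (bp) between same-strand hits merged into
#'   one copy.
#' @return A list with `count` (integer), `copies` (merged [GRanges]),
#'   and `retained` (the unmerged hits passing the filters).
#' @export
countCopies <- function(hits, minCoverage = 0.4, minIdentity = 0.8,
                        mergeGap = 100L) {
  if (length(hits) == 0L) {
    return(list(count = 0L, copies = GRanges(), retained = GRanges()))
  }
  mc <- S4Vectors::mcols(hits)
  if (!all(c("identity", "coverage") %in% colnames(mc)))
    stop("hits must carry 'identity' and 'coverage' metadata columns")
  if (any(mc$identity < 0 | mc$identity > 1)) stop("identity must be in [0, 1]")
  if (any(mc$coverage <= 0)) stop("coverage must be positive")
  keep <- mc$coverage > minCoverage & mc$identity > minIdentity
  retained <- hits[keep]
  copies <- reduce(retained, min.gapwidth = mergeGap + 1L)
  list(count = length(copies), copies = copies, retained = retained)
}

#' Classify element intactness
#'
#' Applies the intact-transposase rule: `"intact"` requires a transposase
#' longer than 500 amino acids carrying both a DNA-binding domain and a
#' DDE catalytic domain, on an element with both TIRs detectable;
#' `"full_length"` requires both TIRs but a failing transposase;
#' everything else is a `"fragment"`.
#'
#' @param proteinLength Transposase length in amino acids (0 for none).
#' @param hasDbd,hasDde Logical domain evidence, e.g. from
#'   [hasDomainEvidence()].
#' @param hasTirs Logical; both TIRs detected.
#' @return `"intact"`, `"full_length"` or `"fragment"`.
#' @export
classifyElement <- function(proteinLength, hasDbd, hasDde, hasTirs) {
  stopifnot(length(proteinLength) == 1L, proteinLength >= 0)
  if (isTRUE(hasTirs) && proteinLength > 500L &&
      isTRUE(hasDbd) && isTRUE(hasDde)) {
    "intact"
  } else if (isTRUE(hasTirs)) {
    "full_length"
  } else {
    "fragment"
  }
}

#' Genomic flank motifs of an element copy
#'
#' Extracts the `k` bases immediately 5' and 3' of a genomic element
#' copy, reported in element orientation: for a minus-strand copy the
#' genomic downstream flank is reverse-complemented into the 5' flank
#' and vice versa. Spy-family insertions characteristically sit between
#' an upstream `AAA` and a downstream `TTT` with no target site
#' duplication.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param hit A length-1 [GenomicRanges::GRanges] locating the copy.
#' @param k Flank length (default 3).
#' @return List with `flank5`, `flank3` (character, `NA` at contig
#'   edges) and `matchesAAATTT` (`TRUE` iff flank5 == "AAA" and
#'   flank3 == "TTT" for `k = 3`).
#' @export
flankMotifs <- function(genome, hit, k = 3L) {
  stopifnot(is(genome, "DNAStringSet"), is(hit, "GRanges"),
            length(hit) == 1L)
  chrom <- as.character(seqnames(hit))
  if (!chrom %in% names(genome))
    stop("contig '", chrom, "' not present in genome")
  chromSeq <- genome[[chrom]]
  s <- start(hit); e <- end(hit)
  up <- if (s - k >= 1L) as.character(subseq(chromSeq, s - k, s - 1L))
        else NA_character_
  dn <- if (e + k <= length(chromSeq)) as.character(subseq(chromSeq, e + 1L, e + k))
        else NA_character_
  if (as.character(strand(hit)) == "-") {
    f5 <- if (is.na(dn)) NA_character_ else .revcomp_chr(dn)
    f3 <- if (is.na(up)) NA_character_ else .revcomp_chr(up)
  } else {
    f5 <- up; f3 <- dn
  }
  matches <- !is.na(f5) && !is.na(f3) && k == 3L &&
    f5 == "AAA" && f3 == "TTT"
  list(flank5 = f5, flank3 = f3, matchesAAATTT = matches)
}

#' Target-site-duplication length at an insertion locus
#'
#' Compares the empty (pre-insertion) and occupied (post-insertion)
#' alleles of one locus, localizes the inserted segment by longest
#' common prefix/suffix, and measures the target site duplication (TSD)
#' as the longest stretch duplicated on both sides of the insert. A
#' blunt, Spy-style insertion returns 0.
#'
#' Single-event TSD inference is ambiguous when the insert's boundary
#' bases coincide with the adjacent target bases; the maximal consistent
#' duplication length is reported.
#'
#' @param preLocus,postLocus DNA sequences of the locus before and after
#'   insertion (character or [Biostrings::DNAString]).
#' @param maxTsd Longest TSD considered.
#' @return Integer TSD length (0 for a blunt insertion).
#' @export
detectTsd <- function(preLocus, postLocus, maxTsd = 20L) {
  pre <- .as_dna_chr(preLocus, what = "preLocus")
  post <- .as_dna_chr(postLocus, what = "postLocus")
  d <- nchar(post) - nchar(pre)
  if (d <= 0L)
    stop("loci not explainable by a single insertion (no length gain)")
  p <- .lcp_len(pre, post)
  s <- .lcs_len(pre, post)
  if (p + s < nchar(pre))
    stop("loci not explainable by a single insertion (flanks disagree)")
  seg <- substr(post, p + 1L, p + d)  # leftmost-placed inserted segment
  tmax <- min(maxTsd, d, p)
  tsd <- 0L
  t <- 1L
  while (t <= tmax) {
    leftFlank <- substr(post, p - t + 1L, p)
    segTail <- substr(seg, d - t + 1L, d)
    if (leftFlank == segTail) tsd <- t
    t <- t + 1L
  }
  tsd
}

#' Longest open reading frame of an element
#'
#' Scans both strands in all three frames for the longest ORF with an
#' ATG start and a stop codon (standard genetic code).
#'
#' @param x Element sequence.
#' @return List with `orf` (1-based [IRanges::IRanges] on the input, or
#'   `NULL`), `strand` (`"+"`, `"-"` or `NA`) and `proteinLength`
#'   (amino acids, excluding the stop; 0 if none found).
#' @export
findLongestOrf <- function(x) {
  s <- .as_dna_chr(x, what = "element sequence")
  L <- nchar(s)
  best <- list(orf = NULL, strand = NA_character_, proteinLength = 0L)
  stops <- c("TAA", "TAG", "TGA")
  for (std in c("+", "-")) {
    seqc <- if (std == "+") s else .revcomp_chr(s)
    for (frame in 0:2) {
      n <- (nchar(seqc) - frame) %/% 3L
      if (n < 2L) next
      starts <- frame + 3L * (seq_len(n) - 1L) + 1L
      codons <- substring(seqc, starts, starts + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% stops)
      if (!length(atg) || !length(stp)) next
      for (a in atg) {
        nxt <- stp[stp > a]
        if (!length(nxt)) next
        aa <- nxt[1L] - a  # codons incl. ATG, excl. stop
        if (aa > best$proteinLength) {
          i1 <- starts[a]; i2 <- starts[nxt[1L]] + 2L  # on seqc, incl. stop
          orf <- if (std == "+") IRanges(start = i1, end = i2)
                 else IRanges(start = L - i2 + 1L, end = L - i1 + 1L)
          best <- list(orf = orf, strand = std, proteinLength = aa)
        }
      }
    }
  }
  best
}

#' Domain evidence for a transposase
#'
#' Decides DBD/DDE presence from parsed domain-hit records (see
#' [readDomtblout()]). When no domain table is available, a
#' low-confidence fallback scans the protein for an acidic D..D..E triad
#' with transposase-like spacing (35-150 aa between the aspartates,
#' 25-140 aa to the glutamate); the fallback's provenance is flagged in
#' the result.
#'
#' @param elementId Element identifier to look up in `domains`.
#' @param domains Data frame of domain hits with columns `element_id`,
#'   `domain_name` (and optionally coordinates/score), or `NULL`.
#' @param protein Amino-acid sequence used by the fallback (character),
#'   or `NULL`.
#' @return List with `hasDbd`, `hasDde` (logical) and `source`
#'   (`"domain_table"` or `"triad_heuristic"`).
#' @export
hasDomainEvidence <- function(elementId, domains = NULL, protein = NULL) {
  if (!is.null(domains) && nrow(domains)) {
    hits <- domains[domains$element_id == elementId, , drop = FALSE]
    nm <- toupper(hits$domain_name)
    hasDbd <- any(grepl("DBD|HTH|DNA[-_ ]?BIND|PAIRED|MYB|BED", nm))
    hasDde <- any(grepl("DDE|TRANSPOSASE|INTEGRASE|RVE", nm))
    return(list(hasDbd = hasDbd, hasDde = hasDde, source = "domain_table"))
  }
  if (is.null(protein) || !nzchar(protein)) {
    return(list(hasDbd = FALSE, hasDde = FALSE, source = "triad_heuristic"))
  }
  aa <- strsplit(toupper(protein), "")[[1L]]
  dpos <- which(aa == "D"); epos <- which(aa == "E")
  hasDde <- FALSE
  for (d1 in dpos) {
    d2s <- dpos[dpos - d1 >= 35 & dpos - d1 <= 150]
    for (d2 in d2s) {
      if (any(epos - d2 >= 25 & epos - d2 <= 140)) { hasDde <- TRUE; break }
    }
    if (hasDde) break
  }
  # Heuristic cannot see a DBD; report it only through the DDE triad.
  list(hasDbd = hasDde, hasDde = hasDde, source = "triad_heuristic")
}

#' Annotate one candidate element
#'
#' Convenience driver combining [detectTirs()], [findLongestOrf()],
#' domain evidence and [classifyElement()] into a [TransposonElement].
#'
#' @param id Element identifier.
#' @param x Element sequence.
#' @param domains Optional domain-hit data frame (see
#'   [hasDomainEvidence()]).
#' @param flank5,flank3 Optional known genomic flank motifs.
#' @param ... Passed to [detectTirs()].
#' @return A [TransposonElement].
#' @export
annotateElement <- function(id, x, domains = NULL,
                            flank5 = NA_character_, flank3 = NA_character_,
                            ...) {
  s <- .as_dna_chr(x, what = "element sequence")
  tirs <- detectTirs(s, ...)
  orf <- findLongestOrf(s)
  protein <- if (!is.null(orf$orf)) {
    cds <- if (orf$strand == "+") {
      subseq(DNAString(s), IRanges::start(orf$orf), IRanges::end(orf$orf))
    } else {
      reverseComplement(subseq(DNAString(s), IRanges::start(orf$orf),
                               IRanges::end(orf$orf)))
    }
    as.character(translate(cds))
  } else NULL
  dom <- hasDomainEvidence(id, domains, protein)
  cls <- classifyElement(orf$proteinLength, dom$hasDbd, dom$hasDde,
                         !is.null(tirs))
  new("TransposonElement", id = id, sequence = DNAString(s), tirs = tirs,
      orf = orf$orf, orfStrand = orf$strand,
      proteinLength = as.integer(orf$proteinLength),
      hasDbd = dom$hasDbd, hasDde = dom$hasDde, classification = cls,
      flank5 = flank5, flank3 = flank3)
}
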