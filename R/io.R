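# Readers and writers for the external interchange formats.

#' @include AllClasses.R
#' @importFrom utils read.table write.table
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' Read a tabular BLAST hit table as copy hits
#'
#' Parses a BLAST `-outfmt 6` table (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore; element as
#' query, genome as subject) into a [GenomicRanges::GRanges] of copy
#' hits with `identity` and `coverage` metadata, ready for
#' [countCopies()]. Subject coordinates with `sstart > send` are folded
#' onto the minus strand.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @param elementLength Element length (bp) used to compute coverage =
#'   alignment length / element length.
#' @return [GenomicRanges::GRanges] with metadata columns `element_id`,
#'   `identity` (fraction) and `coverage` (fraction).
#' @export
readBlastHits <- function(path, elementLength) {
  stopifnot(elementLength > 0)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("qseqid", "sseqid", "pident", "length",
                                  "mismatch", "gapopen", "qstart", "qend",
                                  "sstart", "send", "evalue", "bitscore"),
                    stringsAsFactors = FALSE)
  minus <- tab$sstart > tab$send
  gstart <- ifelse(minus, tab$send, tab$sstart)
  gend <- ifelse(minus, tab$sstart, tab$send)
  GRanges(seqnames = tab$sseqid,
          ranges = IRanges(start = gstart, end = gend),
          strand = ifelse(minus, "-", "+"),
          element_id = tab$qseqid,
          identity = tab$pident / 100,
          coverage = tab$length / elementLength)
}

#' Read an hmmscan domain table
#'
#' Parses an `hmmscan --domtblout` file into a domain-evidence data
#' frame usable by [hasDomainEvidence()]. Only the fixed leading fields
#' are read; the free-text description is ignored.
#'
#' @param path Path to the domtblout file.
#' @return Data frame with columns `element_id` (query), `domain_name`
#'   (target model), `ali_from`, `ali_to` (alignment coordinates on the
#'   protein) and `score` (per-domain bit score).
#' @export
readDomtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(element_id = character(), domain_name = character(),
                      ali_from = integer(), ali_to = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- vapply(fields, length, 1L) < 22L
  if (any(bad)) stop("malformed domtblout line(s): ", which(bad)[1L])
  get <- function(i) vapply(fields, `[[`, "", i)
  data.frame(element_id = get(4L), domain_name = get(1L),
             ali_from = as.integer(get(18L)), ali_to = as.integer(get(19L)),
             score = as.numeric(get(14L)), stringsAsFactors = FALSE)
}

#' Export annotated elements as GFF3
#'
#' Writes one `mobile_genetic_element` feature per genomic copy with
#' its classification, TIR length and identity, and flank motifs as
#' attributes.
#'
#' @param elements List of [TransposonElement] objects.
#' @param loci [GenomicRanges::GRanges] of the corresponding genomic
#'   copies (same length/order as `elements`).
#' @param path Output GFF3 path.
#' @return Invisibly, the exported [GenomicRanges::GRanges].
#' @export
exportElementsGFF3 <- function(elements, loci, path) {
  stopifnot(length(elements) == length(loci))
  gr <- loci
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "mobile_genetic_element",
    ID = vapply(elements, function(e) e@id, ""),
    classification = vapply(elements, classification, ""),
    tir_length = vapply(elements, function(e) {
      if (is.null(e@tirs)) NA_integer_ else IRanges::width(e@tirs@left)
    }, 1L),
    tir_identity = vapply(elements, function(e) {
      if (is.null(e@tirs)) NA_real_ else e@tirs@identity
    }, 1),
    protein_length = vapply(elements, function(e) e@proteinLength, 1L),
    flank5 = vapply(elements, function(e) e@flank5, ""),
    flank3 = vapply(elements, function(e) e@flank3, "")
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(gr)
}

#' Write a divergence-estimate table
#'
#' @param estimates List of [DivergenceEstimate] objects.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
writeDivergenceTable <- function(estimates, path) {
  df <- divergenceTable(estimates)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Flatten divergence estimates to a data frame
#'
#' @param estimates List of [DivergenceEstimate] objects.
#' @return Data frame with one row per copy.
#' @export
divergenceTable <- function(estimates) {
  data.frame(
    copy_id = vapply(estimates, function(e) e@copyId, ""),
    aligned_bp = vapply(estimates, function(e) e@alignedBp, 1L),
    P = vapply(estimates, function(e) e@P, 1),
    Q = vapply(estimates, function(e) e@Q, 1),
    K = vapply(estimates, function(e) e@K, 1),
    saturated = vapply(estimates, function(e) e@saturated, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Export called insertion sites as BED6
#'
#' BED intervals are zero-width at the junction in spirit; for
#' compatibility the two flanking bases are written (0-based half-open
#' `[junction - 1, junction + 1)`), name = read support, score =
#' molecule support, capped at 1000 per the BED specification.
#'
#' @param siteSet An [InsertionSiteSet].
#' @param path Output BED path.
#' @return Invisibly, the written data frame.
#' @export
exportSitesBed <- function(siteSet, path) {
  gr <- sites(siteSet)
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = mc$junction - 1L,
    end = mc$junction + 1L,
    name = paste0("reads=", mc$supportReads),
    score = pmin(mc$supportMolecules, 1000L),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(df)
}

#' Read a BED file of insertion-site junctions
#'
#' Inverse of [exportSitesBed()]: the junction is taken as the midpoint
#' of each (two-base) interval, i.e. 0-based `start + 1` for the
#' exported convention. General BED intervals may also be supplied, in
#' which case the interval midpoint (rounded down) is used.
#'
#' @param path BED path (3-6 columns).
#' @return [GenomicRanges::GRanges] of zero-width junction anchors with
#'   a `junction` metadata column (0-based between-base coordinate).
#' @export
readSitesBed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  chrom <- tab[[1L]]
  junction <- (tab[[2L]] + tab[[3L]]) %/% 2L
  strand <- if (ncol(tab) >= 6L) tab[[6L]] else "*"
  gr <- GRanges(seqnames = chrom,
                ranges = IRanges(start = junction + 1L, width = 0L),
                strand = strand)
  gr$junction <- junction
  gr
}
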