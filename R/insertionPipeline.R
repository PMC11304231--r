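# Junction-library read processing: filter, trim, map, call sites.

#' @include AllClasses.R
#' @importFrom Biostrings DNAString DNAStringSet vmatchPattern matchPattern
#'   readDNAStringSet reverseComplement
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom Rsamtools asBam scanBam scanBamFlag ScanBamParam
NULL

## First match start of `pattern` within the first `window` bases of
## each sequence; NA when absent. maxMismatch 0 uses exact matching.
.first_match <- function(seqs, pattern, window = NULL, maxMismatch = 0L) {
  if (!is.null(window)) seqs <- substr(seqs, 1L, window)
  hits <- vmatchPattern(pattern, DNAStringSet(seqs),
                        max.mismatch = maxMismatch)
  starts <- IRanges::start(hits)
  vapply(starts, function(s) if (length(s)) s[1L] else NA_integer_, 1L)
}

#' Filter junction-library read pairs
#'
#' Applies the library-structure filters: the forward read must carry
#' the megaprimer within its first `searchWindow` bp, the reverse read
#' must carry the linker cassette within its first `searchWindow` bp,
#' and the sample barcode observed immediately after the megaprimer
#' must belong to the sample sheet. The first failing check is recorded
#' as the reason.
#'
#' @param fwd,rev Character vectors of forward/reverse read sequences.
#' @param megaprimer,linker Library construction sequences.
#' @param barcodes Character vector of valid sample barcodes (all the
#'   same length). `NULL` disables the barcode check.
#' @param searchWindow Window (bp) searched at the read start
#'   (default 100).
#' @param maxMismatch Mismatches tolerated when locating megaprimer and
#'   linker (default 0 = exact).
#' @return Data frame with `pass`, `reason` (`"megaprimer"`, `"linker"`,
#'   `"barcode"` or `NA`), `barcode` (observed) and `mpEnd` (last base
#'   of the megaprimer match on the forward read).
#' @export
filterReadPairs <- function(fwd, rev, megaprimer, linker, barcodes = NULL,
                            searchWindow = 100L, maxMismatch = 0L) {
  stopifnot(length(fwd) == length(rev), nzchar(megaprimer), nzchar(linker))
  n <- length(fwd)
  mp <- .first_match(fwd, megaprimer, searchWindow, maxMismatch)
  lk <- .first_match(rev, linker, searchWindow, maxMismatch)
  mpEnd <- mp + nchar(megaprimer) - 1L
  bc <- rep(NA_character_, n)
  if (!is.null(barcodes) && length(barcodes)) {
    bcLen <- unique(nchar(barcodes))
    if (length(bcLen) != 1L) stop("sample barcodes must share one length")
    ok <- !is.na(mpEnd)
    bc[ok] <- substr(fwd[ok], mpEnd[ok] + 1L, mpEnd[ok] + bcLen)
  }
  reason <- rep(NA_character_, n)
  reason[is.na(mp)] <- "megaprimer"
  reason[is.na(reason) & is.na(lk)] <- "linker"
  if (!is.null(barcodes) && length(barcodes)) {
    reason[is.na(reason) & !(bc %in% barcodes)] <- "barcode"
  }
  data.frame(pass = is.na(reason), reason = reason, barcode = bc,
             mpEnd = mpEnd, stringsAsFactors = FALSE)
}

#' Extract the molecular barcode from reverse reads
#'
#' The per-molecule barcode sits in the linker cassette, immediately
#' after the linker sequence on the reverse read.
#'
#' @param rev Character vector of reverse read sequences.
#' @param linker Linker cassette sequence.
#' @param length Barcode length (bp).
#' @param searchWindow,maxMismatch As in [filterReadPairs()].
#' @return Character vector of barcodes (`NA` where the linker or the
#'   full barcode is absent).
#' @export
extractMolecularBarcode <- function(rev, linker, length = 8L,
                                    searchWindow = 100L, maxMismatch = 0L) {
  lk <- .first_match(rev, linker, searchWindow, maxMismatch)
  lkEnd <- lk + nchar(linker) - 1L
  bc <- substr(rev, lkEnd + 1L, lkEnd + length)
  bc[is.na(lk) | nchar(bc) < length] <- NA_character_
  bc
}

#' Trim adapter constructs from reads
#'
#' Iteratively removes adapter matches together with everything between
#' them and the nearer read end: a match whose midpoint lies in the
#' first half of the read is treated as leading (the match and its
#' prefix are removed), otherwise as trailing (the match and its suffix
#' are removed). Reads shorter than `minLen` after trimming are
#' discarded (`NA`).
#'
#' @param seqs Character vector of read sequences.
#' @param adapters Character vector of adapter/primer/anchor sequences.
#' @param minLen Minimum retained length (default 80 bp).
#' @param maxMismatch Mismatches tolerated per adapter match.
#' @return Character vector of trimmed sequences, `NA` for discarded
#'   reads.
#' @export
trimReads <- function(seqs, adapters, minLen = 80L, maxMismatch = 0L) {
  stopifnot(length(adapters) >= 1L, all(nzchar(adapters)))
  pats <- lapply(adapters, DNAString)
  trim1 <- function(s) {
    for (iter in 1:20) {
      if (is.na(s) || !nzchar(s)) return(NA_character_)
      subj <- DNAString(s)
      found <- NULL
      for (p in pats) {
        if (length(p) > nchar(s)) next
        m <- matchPattern(p, subj, max.mismatch = maxMismatch)
        if (length(m)) {
          st <- IRanges::start(m)[1L]
          if (is.null(found) || st < found$start) {
            found <- list(start = st,
                          end = IRanges::end(m)[1L])
          }
        }
      }
      if (is.null(found)) break
      mid <- (found$start + found$end) / 2
      s <- if (mid <= nchar(s) / 2) {
        substr(s, found$end + 1L, nchar(s))
      } else {
        substr(s, 1L, found$start - 1L)
      }
    }
    if (is.na(s) || nchar(s) < minLen) NA_character_ else s
  }
  vapply(seqs, trim1, "", USE.NAMES = FALSE)
}

#' Map reads to a reference with a small exact/near-exact mapper
#'
#' Intended for synthetic references: each read (and its reverse
#' complement) is scanned against every contig, allowing the smallest
#' mismatch count up to `maxMismatch`; a read is `unique` when exactly
#' one best placement exists, `ambiguous` when several tie, `unmapped`
#' otherwise. For real genomes, supply external alignments via
#' [readSamPlacements()] instead.
#'
#' @param reads Character vector of (trimmed) read sequences; names are
#'   used as read ids.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param maxMismatch Maximum substitutions tolerated (default 2).
#' @return Data frame with `read_id`, `status`, `chrom`, `start`, `end`
#'   (1-based), `strand` and `mismatches` (placement fields `NA` unless
#'   `status == "unique"`).
#' @export
mapReads <- function(reads, genome, maxMismatch = 2L) {
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  empty <- function(id, status) {
    data.frame(read_id = id, status = status, chrom = NA_character_,
               start = NA_integer_, end = NA_integer_,
               strand = NA_character_, mismatches = NA_integer_,
               stringsAsFactors = FALSE)
  }
  res <- lapply(seq_along(reads), function(i) {
    s <- reads[[i]]
    if (is.na(s) || !nzchar(s)) return(empty(ids[[i]], "unmapped"))
    pat <- DNAString(s)
    rcp <- reverseComplement(pat)
    for (mm in 0:maxMismatch) {
      placements <- list()
      for (std in c("+", "-")) {
        p <- if (std == "+") pat else rcp
        hits <- vmatchPattern(p, genome, max.mismatch = mm)
        for (ci in seq_along(hits)) {
          h <- hits[[ci]]
          if (length(h)) {
            placements[[length(placements) + 1L]] <- data.frame(
              chrom = names(genome)[ci], start = IRanges::start(h),
              end = IRanges::end(h), strand = std,
              stringsAsFactors = FALSE)
          }
        }
      }
      if (length(placements)) {
        pl <- do.call(rbind, placements)
        if (nrow(pl) == 1L) {
          return(data.frame(read_id = ids[[i]], status = "unique",
                            chrom = pl$chrom, start = pl$start,
                            end = pl$end, strand = pl$strand,
                            mismatches = mm, stringsAsFactors = FALSE))
        }
        return(empty(ids[[i]], "ambiguous"))
      }
    }
    empty(ids[[i]], "unmapped")
  })
  do.call(rbind, res)
}

## Reference-consuming cigar width (M/D/N/=/X operations).
.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1L]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    kind <- sub("^[0-9]+", "", toks)
    sum(lens[kind %in% c("M", "D", "N", "=", "X")])
  }, 1L, USE.NAMES = FALSE)
}

#' Import placements from an external SAM alignment
#'
#' Accepts alignments produced by an external mapper (e.g. BWA, with
#' multi-hit reads already resolved by a secondary aligner). Unmapped,
#' secondary and supplementary records are dropped.
#'
#' @param samPath Path to a SAM (or BAM) file.
#' @return Data frame in the [mapReads()] layout (all retained records
#'   have `status = "unique"`).
#' @export
readSamPlacements <- function(samPath) {
  bam <- if (grepl("\\.bam$", samPath, ignore.case = TRUE)) samPath
         else asBam(samPath, tempfile(), overwrite = TRUE,
                    indexDestination = FALSE)
  param <- ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand"),
    flag = scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE))
  rec <- scanBam(bam, param = param)[[1L]]
  if (!length(rec$qname)) {
    return(data.frame(read_id = character(), status = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  width <- .cigar_ref_width(rec$cigar)
  data.frame(read_id = rec$qname, status = "unique",
             chrom = as.character(rec$rname), start = rec$pos,
             end = rec$pos + width - 1L,
             strand = as.character(rec$strand),
             mismatches = NA_integer_, stringsAsFactors = FALSE)
}

#' Junction coordinates from read placements
#'
#' The forward read runs from the transposon terminus into the flanking
#' genome, so the junction is the between-base coordinate at the
#' transposon-proximal end of the genomic alignment: `start - 1`
#' (0-based) for a plus-strand placement, `end` for a minus-strand one.
#'
#' @param placements Data frame from [mapReads()] or
#'   [readSamPlacements()].
#' @return The input with a `junction` column added (0-based
#'   between-base; `NA` for non-unique reads).
#' @export
junctionFromPlacement <- function(placements) {
  j <- ifelse(placements$strand == "+",
              placements$start - 1L, placements$end)
  j[placements$status != "unique"] <- NA_integer_
  placements$junction <- as.integer(j)
  placements
}

## Greedy UMI collapsing: distinct barcodes within Hamming distance 1
## of a more abundant barcode are treated as sequencing errors of it.
.count_molecules <- function(barcodes) {
  b <- barcodes[!is.na(barcodes)]
  if (!length(b)) return(1L)
  tab <- sort(table(b), decreasing = TRUE)
  reps <- character(0)
  ham1 <- function(x, y) {
    if (nchar(x) != nchar(y)) return(FALSE)
    sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]]) <= 1L
  }
  for (bc in names(tab)) {
    if (!any(vapply(reps, ham1, TRUE, y = bc))) reps <- c(reps, bc)
  }
  length(reps)
}

#' Call insertion sites from placed reads
#'
#' Collapses uniquely placed reads per (chrom, junction, strand) and
#' reports sites whose support reaches `minSupport`. Support is counted
#' as reads, or as distinct molecular barcodes when
#' `dedupeByMolecule = TRUE` and barcodes are available (PCR-duplicate
#' aware; barcodes within Hamming distance 1 of a more abundant barcode
#' are collapsed as sequencing errors); both counts are always
#' reported. Ambiguous or unmapped reads never contribute.
#'
#' @param placements Data frame with columns `chrom`, `junction`,
#'   `strand`, `status` and optionally `molecularBarcode`.
#' @param minSupport Minimum supporting reads (or molecules, see
#'   `dedupeByMolecule`); the field-standard threshold is 10
#'   independent reads.
#' @param dedupeByMolecule Count distinct molecular barcodes instead of
#'   reads when barcodes are present.
#' @return An [InsertionSiteSet].
#' @export
callSites <- function(placements, minSupport = 10L,
                      dedupeByMolecule = TRUE) {
  pl <- placements[placements$status == "unique" &
                     !is.na(placements$junction), , drop = FALSE]
  hasBc <- "molecularBarcode" %in% colnames(pl) &&
    any(!is.na(pl$molecularBarcode))
  if (nrow(pl)) {
    key <- paste(pl$chrom, pl$junction, pl$strand, sep = "\r")
    reads <- as.integer(table(key))
    keys <- names(table(key))
    mol <- if (hasBc) {
      vapply(keys, function(k) {
        .count_molecules(pl$molecularBarcode[key == k])
      }, 1L, USE.NAMES = FALSE)
    } else reads
    parts <- strsplit(keys, "\r", fixed = TRUE)
    chrom <- vapply(parts, `[[`, "", 1L)
    junction <- as.integer(vapply(parts, `[[`, "", 2L))
    strand <- vapply(parts, `[[`, "", 3L)
    support <- if (dedupeByMolecule && hasBc) mol else reads
    keep <- support >= minSupport
    gr <- GRanges(seqnames = chrom[keep],
                  ranges = IRanges(start = junction[keep] + 1L, width = 0L),
                  strand = strand[keep])
    gr$junction <- junction[keep]
    gr$supportReads <- reads[keep]
    gr$supportMolecules <- mol[keep]
    o <- order(as.character(GenomicRanges::seqnames(gr)), gr$junction)
    gr <- gr[o]
  } else {
    gr <- GRanges()
    gr$junction <- integer()
    gr$supportReads <- integer()
    gr$supportMolecules <- integer()
  }
  new("InsertionSiteSet", sites = gr,
      attrition = data.frame(stage = c("placed", "sites"),
                             n = c(nrow(pl), length(gr))),
      params = list(minSupport = minSupport,
                    dedupeByMolecule = dedupeByMolecule && hasBc))
}

#' Run the full junction-library pipeline
#'
#' Filter, trim, map and call in one pass: read pairs are filtered for
#' megaprimer/linker/barcode structure; molecular barcodes are taken
#' from the reverse reads; forward reads are stripped of the megaprimer
#' and transposon-end constructs (reads below `minTrimmedLen` are
#' eliminated), mapped, and collapsed into supported insertion sites.
#' Only forward reads are mapped -- the junction lives at their
#' genomic boundary; reverse reads contribute the linker check and the
#' molecular barcode.
#'
#' @param fwd,rev Forward/reverse reads: FASTQ paths,
#'   [Biostrings::DNAStringSet]s, or character vectors.
#' @param genome Named [Biostrings::DNAStringSet] reference, or `NULL`
#'   when `sam` is given.
#' @param megaprimer,linker,barcodes Library structure (see
#'   [filterReadPairs()]).
#' @param transposonEnd Element-terminus sequence carried on the
#'   forward read between barcode and genomic junction.
#' @param molecularBarcodeLength Molecular barcode length (0 disables).
#' @param sam Optional path to external SAM/BAM alignments of the
#'   trimmed forward reads (replaces the built-in mapper).
#' @param searchWindow,adapterMismatch,mapMismatch,minTrimmedLen,minSupport,dedupeByMolecule
#'   Tuning parameters; defaults follow the protocol (100-bp search
#'   window, exact adapters, 80-bp minimum trimmed length, >= 10
#'   supporting reads).
#' @return An [InsertionSiteSet] whose attrition table records the read
#'   counts surviving each stage.
#' @export
runInsertionPipeline <- function(fwd, rev, genome,
                                 megaprimer, linker, barcodes = NULL,
                                 transposonEnd = NULL,
                                 molecularBarcodeLength = 8L,
                                 sam = NULL,
                                 searchWindow = 100L, adapterMismatch = 0L,
                                 mapMismatch = 2L, minTrimmedLen = 80L,
                                 minSupport = 10L, dedupeByMolecule = TRUE) {
  asChr <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      x <- readDNAStringSet(x, format = "fastq")
    }
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- sprintf("read%06d", seq_along(out))
    out
  }
  fwd <- asChr(fwd); rev <- asChr(rev)
  nTotal <- length(fwd)
  flt <- filterReadPairs(fwd, rev, megaprimer, linker, barcodes,
                         searchWindow, adapterMismatch)
  keep <- flt$pass
  fwdK <- fwd[keep]; revK <- rev[keep]
  molBc <- if (molecularBarcodeLength > 0L) {
    extractMolecularBarcode(revK, linker, molecularBarcodeLength,
                            searchWindow, adapterMismatch)
  } else rep(NA_character_, length(revK))
  adapters <- c(megaprimer, transposonEnd)
  adapters <- adapters[!is.null(adapters) & nzchar(adapters)]
  trimmed <- trimReads(fwdK, adapters, minLen = minTrimmedLen,
                       maxMismatch = adapterMismatch)
  ok <- !is.na(trimmed)
  trimmedK <- trimmed[ok]
  names(trimmedK) <- names(fwdK)[ok]
  molBcK <- molBc[ok]
  placements <- if (!is.null(sam)) {
    pl <- readSamPlacements(sam)
    pl[pl$read_id %in% names(trimmedK), , drop = FALSE]
  } else {
    if (is.null(genome)) stop("either a genome or a SAM file is required")
    mapReads(trimmedK, genome, maxMismatch = mapMismatch)
  }
  placements$molecularBarcode <- molBcK[match(placements$read_id,
                                              names(trimmedK))]
  placements <- junctionFromPlacement(placements)
  siteSet <- callSites(placements, minSupport = minSupport,
                       dedupeByMolecule = dedupeByMolecule)
  att <- data.frame(
    stage = c("input_pairs", "pass_structure_filter", "pass_trim",
              "mapped_unique", "sites"),
    n = c(nTotal, sum(keep), sum(ok),
          sum(placements$status == "unique"), length(sites(siteSet))))
  new("InsertionSiteSet", sites = sites(siteSet), attrition = att,
      params = c(siteSet@params,
                 list(adapterMismatch = adapterMismatch,
                      mapMismatch = mapMismatch,
                      minTrimmedLen = minTrimmedLen)))
}
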