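# Synthetic-data module: seeded genomes, planted motifs and element
# copies, and junction sequencing libraries with ground truth.

#' @include AllClasses.R
#' @importFrom Biostrings DNAString DNAStringSet writeXStringSet BStringSet
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom stats rnbinom runif
NULL

## Deterministic default element consensus: 467-bp TIRs (the cgSpy TIR
## length) around an ORF encoding a >500-aa transposase-sized protein.
.default_consensus <- function() {
  .with_seed(990137L, {
    tir <- .random_dna(467L, gc = 0.45)
    # pad ends with stops in all three frames so no upstream ATG can
    # extend the designed ORF
    pad <- paste0(.random_dna(21L, gc = 0.5), "TAATAATAA")
    # TTA/CTA/TCA read as stop codons on the reverse strand, keeping
    # the antisense ORFs short so the transposase ORF is the longest
    codons <- c("GCT", "GAA", "GAT", "AAA", "CGT", "TGG", "CAT", "ATC",
                "CTG", "TTC", "GGA", "AGC", "ACC", "TAC", "GTG", "CAG",
                "CCT", "AAC", "TGC", "TTA", "CTA", "TCA", "TTA", "CTA",
                "TCA")
    orf <- paste0("ATG", paste(sample(codons, 680L, replace = TRUE),
                               collapse = ""), "TAA")
    tail <- .random_dna(90L, gc = 0.5)
    DNAString(paste0(tir, pad, orf, tail, .revcomp_chr(tir)))
  })
}

#' Build a simulation configuration
#'
#' Assembles a validated [SpySimConfig]. Defaults describe the study
#' conditions the rest of the package is exercised under: a 100-kb
#' background genome at GC 0.5 with one planted AAATTT target motif per
#' kb; an element consensus with 467-bp TIRs and a >500-aa transposase
#' ORF; copies planted in two age waves (K about 0.02 and 0.15, the
#' young/old coexistence signature); 120 insertion sites, 60% of them
#' at the target motif (the empirically observed target-motif
#' fraction); negative-binomial read depth (mean 20, dispersion 5) with
#' an Illumina-like 0.001 substitution error rate on 150-bp reads.
#' Larger site sets need a correspondingly larger genome or motif
#' density (at-motif sites draw planted motifs without replacement).
#'
#' @param seed Mandatory RNG seed.
#' @param genomeLength,gcContent,motifDensity Background genome model.
#' @param elementConsensus Element consensus sequence (defaults to a
#'   built-in deterministic 3.1-kb element).
#' @param copyDivergences Two-column matrix (or 2-vector) of per-copy
#'   true (transition, transversion) probabilities.
#' @param nSites,targetMotifFraction Insertion-site model.
#' @param readsPerSiteMean,readsPerSiteDispersion,errorRate,readLength
#'   Library depth and error model.
#' @param megaprimer,linker,sampleBarcodes,transposonEndLength,molecularBarcodeLength
#'   Library structure.
#' @return A [SpySimConfig].
#' @export
simConfig <- function(seed,
                      genomeLength = 100000L, gcContent = 0.5,
                      motifDensity = 1.0,
                      elementConsensus = NULL,
                      copyDivergences = NULL,
                      nSites = 120L, targetMotifFraction = 0.6,
                      readsPerSiteMean = 20, readsPerSiteDispersion = 5,
                      errorRate = 0.001, readLength = 150L,
                      megaprimer = "GTACGTCACAATATGATTAT",
                      linker = "CTAGGACCTTGAACGCATCG",
                      sampleBarcodes = c("ACGTCA", "TGCAGT", "GATCGA",
                                         "CTAGCT"),
                      transposonEndLength = 20L,
                      molecularBarcodeLength = 8L) {
  if (is.null(elementConsensus)) elementConsensus <- .default_consensus()
  if (is.character(elementConsensus))
    elementConsensus <- DNAString(toupper(elementConsensus))
  if (is.null(copyDivergences)) {
    copyDivergences <- rbind(
      matrix(rep(c(0.013, 0.007), 6), ncol = 2, byrow = TRUE),  # young wave
      matrix(rep(c(0.090, 0.045), 6), ncol = 2, byrow = TRUE))  # old wave
  }
  if (is.null(dim(copyDivergences)))
    copyDivergences <- matrix(copyDivergences, ncol = 2, byrow = TRUE)
  colnames(copyDivergences) <- c("P", "Q")
  new("SpySimConfig", seed = as.integer(seed),
      genomeLength = as.integer(genomeLength), gcContent = gcContent,
      motifDensity = motifDensity, elementConsensus = elementConsensus,
      copyDivergences = copyDivergences, nSites = as.integer(nSites),
      targetMotifFraction = targetMotifFraction,
      readsPerSiteMean = readsPerSiteMean,
      readsPerSiteDispersion = readsPerSiteDispersion,
      errorRate = errorRate, readLength = as.integer(readLength),
      megaprimer = megaprimer, linker = linker,
      sampleBarcodes = sampleBarcodes,
      transposonEndLength = as.integer(transposonEndLength),
      molecularBarcodeLength = as.integer(molecularBarcodeLength))
}

#' Simulate a background genome with planted target motifs
#'
#' Draws an i.i.d. background sequence at the configured GC content and
#' plants `AAATTT` target motifs at the configured density at
#' non-overlapping positions (away from the contig edges). Byte-
#' identical output under a fixed seed.
#'
#' @param config A [SpySimConfig].
#' @return List with `genome` (a [Biostrings::DNAStringSet] with one
#'   contig `chr1`) and `motifs` (a [GenomicRanges::GRanges] of the
#'   planted 6-bp motifs, with `junction` = the 0-based between-base
#'   coordinate separating AAA from TTT).
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SpySimConfig"))
  L <- config@genomeLength
  nMotif <- round(config@motifDensity * L / 1000)
  margin <- 200L
  # motifs are drawn on an 18-bp grid with 0-5 bp jitter, keeping them
  # >= 13 bp apart (non-overlapping) without rejection sampling
  capacity <- (L - 2L * margin - 6L) %/% 18L
  if (nMotif > capacity)
    stop("motif density infeasible for this genome length")
  .with_seed(config@seed, {
    g <- .random_dna(L, gc = config@gcContent)
    starts <- integer(0)
    if (nMotif > 0L) {
      slots <- sort(sample.int(capacity, nMotif))
      starts <- margin + 1L + 18L * (slots - 1L) +
        sample(0:5, nMotif, replace = TRUE)
      for (s in starts) {
        substr(g, s, s + 5L) <- "AAATTT"
      }
    }
    genome <- DNAStringSet(g)
    names(genome) <- "chr1"
    motifs <- GRanges(seqnames = rep("chr1", length(starts)),
                      ranges = IRanges(start = starts, width = 6L),
                      strand = rep("+", length(starts)))
    motifs$junction <- starts + 2L  # 0-based: after the third base (AAA|TTT)
    list(genome = genome, motifs = motifs)
  })
}

## Mutate a consensus under the K2P generative model: per site,
## transition with probability P, transversion with probability Q.
.mutate_copy <- function(consensus, P, Q) {
  v <- strsplit(consensus, "")[[1L]]
  n <- length(v)
  u <- runif(n)
  ts <- u < P
  tv <- !ts & u < P + Q
  v[ts] <- .TRANSITION[v[ts]]
  if (any(tv)) {
    tvsets <- list(A = c("C", "T"), G = c("C", "T"),
                   C = c("A", "G"), T = c("A", "G"))
    pick <- runif(sum(tv)) < 0.5
    v[tv] <- mapply(function(b, first) tvsets[[b]][if (first) 1L else 2L],
                    v[tv], pick)
  }
  paste(v, collapse = "")
}

#' Plant diverged element copies into a genome
#'
#' Each copy is the consensus mutated under the K2P generative model at
#' its own true (P*, Q*), inserted blunt (zero TSD) between the AAA and
#' TTT of a planted target motif, on a random strand. The truth table
#' records the final genomic interval and the true divergence of every
#' copy.
#'
#' @param sim Output of [simulateGenome()].
#' @param config A [SpySimConfig]; `copyDivergences` gives one (P*, Q*)
#'   row per copy to plant.
#' @return List with `genome` (copies inserted), `truth` (data frame:
#'   `copy_id`, `start`, `end` 1-based, `strand`, `P_true`, `Q_true`,
#'   `K_true`), `copies` (the mutated copy sequences, in element
#'   orientation) and `motifs` (remaining unoccupied motifs, coordinates
#'   shifted to the new genome).
#' @export
plantCopies <- function(sim, config) {
  stopifnot(is(config, "SpySimConfig"))
  div <- config@copyDivergences
  nCopy <- nrow(div)
  motifs <- sim$motifs
  if (length(motifs) < nCopy)
    stop("not enough planted motifs to host ", nCopy, " copies")
  cons <- as.character(config@elementConsensus)
  .with_seed(config@seed + 1L, {
    pick <- sort(sample(seq_along(motifs), nCopy))
    j <- motifs$junction[pick]          # 0-based insertion points
    ord <- order(j)
    g <- as.character(sim$genome[[1L]])
    copies <- character(nCopy)
    strands <- sample(c("+", "-"), nCopy, replace = TRUE)
    lens <- integer(nCopy)
    for (i in seq_len(nCopy)) {
      copies[i] <- .mutate_copy(cons, div[i, 1L], div[i, 2L])
      lens[i] <- nchar(copies[i])
    }
    # insert right-to-left so earlier coordinates stay valid
    for (i in order(j, decreasing = TRUE)) {
      ins <- if (strands[i] == "+") copies[i] else .revcomp_chr(copies[i])
      g <- paste0(substr(g, 1L, j[i]), ins,
                  substr(g, j[i] + 1L, nchar(g)))
    }
    shift <- vapply(seq_len(nCopy),
                    function(i) sum(lens[j < j[i]]), 1)
    start1 <- j + shift + 1L
    truth <- data.frame(
      copy_id = sprintf("copy%03d", seq_len(nCopy)),
      start = as.integer(start1), end = as.integer(start1 + lens - 1L),
      strand = strands, P_true = div[, 1L], Q_true = div[, 2L],
      K_true = kimura2p(div[, 1L], div[, 2L]),
      stringsAsFactors = FALSE)
    genome <- DNAStringSet(g)
    names(genome) <- names(sim$genome)
    remaining <- motifs[-pick]
    remShift <- vapply(remaining$junction,
                       function(x) sum(lens[j < x]), 1)
    remaining <- GRanges(
      seqnames = GenomicRanges::seqnames(remaining),
      ranges = IRanges(start = GenomicRanges::start(remaining) + remShift,
                       width = 6L),
      strand = "+")
    remaining$junction <- GenomicRanges::start(remaining) + 2L
    names(copies) <- truth$copy_id
    list(genome = genome, truth = truth,
         copies = DNAStringSet(copies), motifs = remaining)
  })
}

#' Plant insertion sites for library simulation
#'
#' Chooses `nSites` junctions: a `targetMotifFraction` share at planted
#' AAATTT motif centers (between AAA and TTT), the rest uniform over
#' the genome away from motifs and contig edges; strands random.
#'
#' @param sim List with `genome` and `motifs` (from [simulateGenome()]
#'   or [plantCopies()]).
#' @param config A [SpySimConfig].
#' @param nSites,targetMotifFraction Optional overrides of the config.
#' @return Data frame `site_id`, `chrom`, `junction` (0-based),
#'   `strand`, `at_motif`.
#' @export
plantInsertionSites <- function(sim, config, nSites = NULL,
                                targetMotifFraction = NULL) {
  stopifnot(is(config, "SpySimConfig"))
  n <- if (is.null(nSites)) config@nSites else as.integer(nSites)
  frac <- if (is.null(targetMotifFraction)) config@targetMotifFraction
          else targetMotifFraction
  motifs <- sim$motifs
  nAtMotif <- round(n * frac)
  if (nAtMotif > length(motifs))
    stop("not enough planted motifs for ", nAtMotif, " motif sites")
  L <- length(sim$genome[[1L]])
  .with_seed(config@seed + 2L, {
    pick <- sample(seq_along(motifs), nAtMotif)
    jm <- motifs$junction[pick]
    margin <- 200L
    forbidden <- unique(motifs$junction)
    ju <- integer(0)
    while (length(ju) < n - nAtMotif) {
      cand <- sample((margin):(L - margin), n - nAtMotif - length(ju),
                     replace = FALSE)
      cand <- setdiff(cand, c(forbidden, ju))
      ju <- c(ju, cand)
    }
    j <- c(jm, ju)
    at <- c(rep(TRUE, nAtMotif), rep(FALSE, length(ju)))
    o <- sample(seq_along(j))  # shuffle so ids don't encode truth order
    data.frame(site_id = sprintf("site%04d", seq_along(j)),
               chrom = names(sim$genome)[1L],
               junction = as.integer(j[o]),
               strand = sample(c("+", "-"), length(j), replace = TRUE),
               at_motif = at[o], stringsAsFactors = FALSE)
  })
}

#' Simulate a junction sequencing library
#'
#' Generates paired reads for each insertion site: the forward read is
#' megaprimer + sample barcode + transposon end + genomic sequence
#' running away from the junction; the reverse read is linker cassette
#' + per-molecule barcode + genomic filler. Read counts per site are
#' negative-binomial unless `readsPerSite` overrides them; uniform
#' substitution errors are applied over the whole read at the
#' configured rate. Output is byte-identical under a fixed seed.
#'
#' @param sim List with `genome` (the insertion reference).
#' @param sitesTruth Data frame from [plantInsertionSites()] (or the
#'   same columns).
#' @param config A [SpySimConfig].
#' @param readsPerSite Optional integer vector (recycled) of read
#'   counts per site, overriding the depth model.
#' @param fastqPrefix Optional path prefix; when given,
#'   `<prefix>_R1.fastq` / `<prefix>_R2.fastq` are written.
#' @return List with `fwd`, `rev` (named character vectors),
#'   `siteTruth` (per site: reads and distinct molecules) and
#'   `readTruth` (per read: site and molecule barcode).
#' @export
simulateLibrary <- function(sim, sitesTruth, config, readsPerSite = NULL,
                            fastqPrefix = NULL) {
  stopifnot(is(config, "SpySimConfig"))
  g <- as.character(sim$genome[[1L]])
  L <- nchar(g)
  cons <- as.character(config@elementConsensus)
  te <- substr(cons, nchar(cons) - config@transposonEndLength + 1L,
               nchar(cons))
  bc <- config@sampleBarcodes[1L]
  prefixLen <- nchar(config@megaprimer) + nchar(bc) + nchar(te)
  glen <- config@readLength - prefixLen
  if (glen < 80L)
    stop("read length too short for the adapter constructs plus 80 bp")
  rprefixLen <- nchar(config@linker) + config@molecularBarcodeLength
  rglen <- config@readLength - rprefixLen
  .with_seed(config@seed + 3L, {
    n <- nrow(sitesTruth)
    counts <- if (is.null(readsPerSite)) {
      pmax(1L, rnbinom(n, mu = config@readsPerSiteMean,
                       size = config@readsPerSiteDispersion))
    } else rep_len(as.integer(readsPerSite), n)
    fwd <- character(0); rev <- character(0)
    readSite <- character(0); readMol <- character(0)
    siteMol <- integer(n)
    for (i in seq_len(n)) {
      j <- sitesTruth$junction[i]
      std <- sitesTruth$strand[i]
      if (std == "+") {
        gen <- substr(g, j + 1L, j + glen)
        oth <- .revcomp_chr(substr(g, j - rglen + 1L, j))
      } else {
        gen <- .revcomp_chr(substr(g, j - glen + 1L, j))
        oth <- substr(g, j + 1L, j + rglen)
      }
      nr <- counts[i]
      nMol <- max(1L, round(nr * 0.7))
      # within-site barcodes kept pairwise Hamming >= 3 apart so that
      # error-tolerant deduplication is well-posed
      molIds <- character(0)
      while (length(molIds) < nMol) {
        cand <- paste(sample(c("A", "C", "G", "T"),
                             config@molecularBarcodeLength, replace = TRUE),
                      collapse = "")
        cv <- strsplit(cand, "")[[1L]]
        ok <- all(vapply(molIds, function(x) {
          sum(strsplit(x, "")[[1L]] != cv) >= 3L
        }, TRUE))
        if (ok) molIds <- c(molIds, cand)
      }
      assign <- c(seq_len(nMol), sample(nMol, max(0L, nr - nMol),
                                        replace = TRUE))[seq_len(nr)]
      siteMol[i] <- length(unique(assign))
      f <- paste0(config@megaprimer, bc, te, gen)
      for (r in seq_len(nr)) {
        fwd <- c(fwd, f)
        rev <- c(rev, paste0(config@linker, molIds[assign[r]], oth))
        readSite <- c(readSite, sitesTruth$site_id[i])
        readMol <- c(readMol, molIds[assign[r]])
      }
    }
    # uniform substitution errors over the whole read
    addErr <- function(s) {
      if (config@errorRate <= 0) return(s)
      v <- strsplit(s, "")[[1L]]
      hit <- runif(length(v)) < config@errorRate
      if (any(hit)) {
        v[hit] <- vapply(v[hit], function(b) {
          sample(setdiff(.DNA_ALPHABET, b), 1L)
        }, "")
        s <- paste(v, collapse = "")
      }
      s
    }
    fwd <- vapply(fwd, addErr, "", USE.NAMES = FALSE)
    rev <- vapply(rev, addErr, "", USE.NAMES = FALSE)
    ids <- sprintf("%s_r%04d", readSite, seq_along(fwd))
    names(fwd) <- ids; names(rev) <- ids
    siteTruth <- sitesTruth
    siteTruth$n_reads <- counts
    siteTruth$n_molecules <- siteMol
    readTruth <- data.frame(read_id = ids, site_id = readSite,
                            molecular_barcode = readMol,
                            stringsAsFactors = FALSE)
    if (!is.null(fastqPrefix)) {
      writeFq <- function(x, path) {
        ss <- DNAStringSet(x)
        writeXStringSet(ss, path, format = "fastq",
                        qualities = BStringSet(strrep("I", nchar(x))))
      }
      writeFq(fwd, paste0(fastqPrefix, "_R1.fastq"))
      writeFq(rev, paste0(fastqPrefix, "_R2.fastq"))
    }
    list(fwd = fwd, rev = rev, siteTruth = siteTruth,
         readTruth = readTruth)
  })
}

#' Construct a post-insertion locus with a known TSD
#'
#' Builds the occupied allele of a locus by inserting `insert` after
#' 1-based position `position` of `preLocus`, duplicating the `tsd`
#' bases immediately 5' of the insertion point on the 3' side of the
#' insert (the target site duplication). `tsd = 0` gives a blunt,
#' Spy-style insertion. The inverse of [detectTsd()].
#'
#' @param preLocus Pre-insertion sequence (character or
#'   [Biostrings::DNAString]).
#' @param insert Inserted element sequence.
#' @param position 1-based position after which the insert is placed
#'   (must be >= `tsd`).
#' @param tsd TSD length.
#' @return Post-insertion sequence (character).
#' @export
syntheticInsertion <- function(preLocus, insert, position, tsd = 0L) {
  pre <- .as_dna_chr(preLocus, what = "preLocus")
  ins <- .as_dna_chr(insert, what = "insert")
  stopifnot(position >= tsd, position <= nchar(pre), nchar(ins) > 0L)
  dup <- if (tsd > 0L) substr(pre, position - tsd + 1L, position) else ""
  paste0(substr(pre, 1L, position), ins, dup,
         substr(pre, position + 1L, nchar(pre)))
}
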