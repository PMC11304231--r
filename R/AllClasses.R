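# S4 classes for the core data objects.

#' @import methods
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors DataFrame mcols mcols<-
NULL

setClassUnion("IRangesOrNULL", c("IRanges", "NULL"))

#' Terminal inverted repeat pair
#'
#' A pair of reverse-complementary repeats at the two termini of a DNA
#' transposon, as located by [detectTirs()]. Coordinates are 1-based
#' closed intervals on the element sequence.
#'
#' @slot left,right [IRanges::IRanges] of the left and right repeat copy.
#' @slot identity Fraction of matching positions between the left repeat
#'   and the reverse complement of the right repeat.
#' @seealso [detectTirs()]
#' @exportClass TirPair
setClass("TirPair",
  representation(left = "IRanges", right = "IRanges", identity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@left) != 1L || length(object@right) != 1L)
      msg <- c(msg, "left and right must each be a single range")
    if (IRanges::width(object@left) != IRanges::width(object@right))
      msg <- c(msg, "left and right TIR must have equal length")
    if (object@identity < 0 || object@identity > 1)
      msg <- c(msg, "identity must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

setClassUnion("TirPairOrNULL", c("TirPair", "NULL"))

#' Annotated candidate transposon element
#'
#' Bundle of annotations for one candidate element: its sequence, TIR
#' pair (if detected), longest open reading frame, transposase domain
#' evidence and the resulting intactness classification.
#'
#' Classification follows the intact-transposase rule: an element is
#' `"intact"` only if its transposase exceeds 500 amino acids, carries
#' both a DNA-binding domain and a DDE catalytic domain, and both TIRs
#' are present; `"full_length"` requires both TIRs; anything else is a
#' `"fragment"`.
#'
#' @slot id Element identifier.
#' @slot sequence Element [Biostrings::DNAString].
#' @slot tirs A [TirPair] or `NULL` when no TIRs were detected.
#' @slot orf 1-based interval of the longest ORF on the element, or
#'   `NULL`; `orfStrand` gives its strand.
#' @slot proteinLength Transposase length in amino acids (0 if no ORF).
#' @slot hasDbd,hasDde Domain evidence flags.
#' @slot classification One of `"intact"`, `"full_length"`, `"fragment"`.
#' @slot flank5,flank3 Genomic flank motifs in element orientation
#'   (`NA` when unknown).
#' @seealso [annotateElement()], [classifyElement()]
#' @exportClass TransposonElement
setClass("TransposonElement",
  representation(
    id = "character", sequence = "DNAString", tirs = "TirPairOrNULL",
    orf = "IRangesOrNULL", orfStrand = "character",
    proteinLength = "integer", hasDbd = "logical", hasDde = "logical",
    classification = "character", flank5 = "character", flank3 = "character"
  ),
  prototype(
    orfStrand = NA_character_, proteinLength = 0L,
    hasDbd = FALSE, hasDde = FALSE, classification = "fragment",
    flank5 = NA_character_, flank3 = NA_character_
  ),
  validity = function(object) {
    msg <- character()
    cls <- object@classification
    if (!cls %in% c("intact", "full_length", "fragment"))
      msg <- c(msg, "classification must be intact, full_length or fragment")
    if (cls %in% c("intact", "full_length") && is.null(object@tirs))
      msg <- c(msg, "intact/full_length elements must carry a TIR pair")
    if (cls == "intact" &&
        !(object@proteinLength > 500L && object@hasDbd && object@hasDde))
      msg <- c(msg, "intact requires >500 aa transposase with DBD and DDE")
    if (length(msg)) msg else TRUE
  }
)

#' Kimura two-parameter divergence of one element copy
#'
#' Transition/transversion mismatch proportions and the resulting K2P
#' distance of one copy aligned against a family reference, counted over
#' gap-free alignment columns only.
#'
#' @slot copyId Copy identifier.
#' @slot alignedBp Number of gap-free aligned columns.
#' @slot P,Q Transition and transversion mismatch proportions.
#' @slot K K2P distance in substitutions/site (`NA` when saturated or
#'   undefined).
#' @slot saturated `TRUE` when the K2P logarithm argument is
#'   non-positive (distance undefined).
#' @seealso [copyDivergence()], [kimura2p()]
#' @exportClass DivergenceEstimate
setClass("DivergenceEstimate",
  representation(copyId = "character", alignedBp = "integer",
                 P = "numeric", Q = "numeric", K = "numeric",
                 saturated = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@P) == 1L && length(object@Q) == 1L &&
        !is.na(object@P) && !is.na(object@Q)) {
      if (object@P < 0 || object@Q < 0 || object@P + object@Q > 1)
        msg <- c(msg, "P and Q must be non-negative with P + Q <= 1")
    }
    if (!object@saturated && !is.na(object@K) && object@K < 0)
      msg <- c(msg, "K must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Divergence-versus-coverage landscape
#'
#' Genome coverage (bp) of an element family binned by percent K2P
#' divergence, the classic repeat-landscape summary: mass near 0%
#' indicates recent activity, multiple modes indicate repeated invasion
#' waves.
#'
#' @slot binEdges Bin edges in percent divergence (length `nbins + 1`).
#' @slot coverage Summed gap-free aligned bp per bin.
#' @slot saturatedBp Aligned bp of copies excluded as saturated.
#' @slot nCopies Number of copies contributing to `coverage`.
#' @seealso [buildLandscape()]
#' @exportClass DivergenceLandscape
setClass("DivergenceLandscape",
  representation(binEdges = "numeric", coverage = "numeric",
                 saturatedBp = "numeric", nCopies = "integer"),
  validity = function(object) {
    if (length(object@coverage) != length(object@binEdges) - 1L)
      return("coverage must have one entry per bin")
    if (any(object@coverage < 0)) return("coverage must be non-negative")
    TRUE
  }
)

#' Called insertion-site set
#'
#' Unique integration sites called from a junction library, stored as
#' zero-width anchors at the between-base junction coordinate, together
#' with the read-level attrition log of the pipeline run.
#'
#' @slot sites [GenomicRanges::GRanges] of zero-width junction anchors
#'   (1-based start `j + 1` for 0-based between-base junction `j`) with
#'   metadata columns `junction` (0-based), `supportReads` and
#'   `supportMolecules`.
#' @slot attrition Data frame of per-stage read counts.
#' @slot params Pipeline parameters in force (support threshold,
#'   deduplication mode, adapter mismatch allowance).
#' @seealso [callSites()], [runInsertionPipeline()]
#' @exportClass InsertionSiteSet
setClass("InsertionSiteSet",
  representation(sites = "GRanges", attrition = "data.frame",
                 params = "list"),
  validity = function(object) {
    mc <- mcols(object@sites)
    need <- c("junction", "supportReads", "supportMolecules")
    if (!all(need %in% colnames(mc)))
      return(paste("sites must carry metadata columns:",
                   paste(need, collapse = ", ")))
    if (length(object@sites) &&
        any(mc$supportReads < mc$supportMolecules))
      return("supportReads must be >= supportMolecules")
    if (length(object@sites) && any(mc$supportMolecules < 1L))
      return("supportMolecules must be >= 1")
    TRUE
  }
)

#' Sequence logo matrix
#'
#' Per-position base frequencies and information content (bits) for a
#' set of equal-length windows centered on insertion junctions. The
#' ceiling of 2 bits (log2 4) is reached only when every window carries
#' the same base at that position.
#'
#' @slot freq 4 x W base-frequency matrix (rows A, C, G, T; columns sum
#'   to 1).
#' @slot infoContent Per-position information content in `[0, 2]` bits.
#' @slot nWindows Number of windows summarized.
#' @seealso [buildLogo()]
#' @exportClass LogoMatrix
setClass("LogoMatrix",
  representation(freq = "matrix", infoContent = "numeric",
                 nWindows = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@freq) != 4L)
      msg <- c(msg, "freq must have 4 rows (A, C, G, T)")
    if (ncol(object@freq) != length(object@infoContent))
      msg <- c(msg, "infoContent must match the number of positions")
    cs <- colSums(object@freq)
    if (any(abs(cs - 1) > 1e-9))
      msg <- c(msg, "freq columns must sum to 1")
    if (any(object@infoContent < -1e-12 | object@infoContent > 2 + 1e-12))
      msg <- c(msg, "infoContent must lie in [0, 2] bits")
    if (length(msg)) msg else TRUE
  }
)

#' Category enrichment of an insertion-site set
#'
#' Observed versus random-control overlap fractions and fold change per
#' genomic category, with the random control drawn as seeded uniform
#' loci over the supplied chromosome lengths (fold change 1 = random
#' expectation).
#'
#' @slot table Data frame with columns `category`, `observedFraction`,
#'   `randomFraction`, `foldChange`, `nSites`, `nRandom`, `flagged`
#'   (`TRUE` when the fold change is undefined or infinite).
#' @slot nRandom Number of random control loci drawn.
#' @slot seed Seed used for the random control (`NA` if none given).
#' @seealso [enrichment()]
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(table = "data.frame", nRandom = "integer",
                 seed = "integer"),
  validity = function(object) {
    need <- c("category", "observedFraction", "randomFraction",
              "foldChange", "nSites", "nRandom", "flagged")
    if (!all(need %in% colnames(object@table)))
      return(paste("table must have columns:", paste(need, collapse = ", ")))
    fr <- c(object@table$observedFraction, object@table$randomFraction)
    if (any(fr < 0 | fr > 1, na.rm = TRUE))
      return("fractions must lie in [0, 1]")
    TRUE
  }
)

#' Genomic-safe-harbor report
#'
#' Per-criterion and combined pass fractions for the five-criterion
#' genomic-safe-harbor (GSH) definition: a site must fall outside gene
#' bodies, cancer genes and miRNA genes, not within 50 kb upstream of
#' any TSS, and outside TSS +/- 5 kb, simultaneously.
#'
#' @slot perCriterion Named pass fractions for the five criteria.
#' @slot combined Fraction of sites passing all five criteria.
#' @slot nSites Number of sites classified.
#' @slot flags Per-site logical [S4Vectors::DataFrame] of criterion flags.
#' @seealso [gshClassify()], [gshReport()]
#' @exportClass GshReport
setClass("GshReport",
  representation(perCriterion = "numeric", combined = "numeric",
                 nSites = "integer", flags = "DataFrame"),
  validity = function(object) {
    msg <- character()
    if (length(object@perCriterion) != 5L)
      msg <- c(msg, "perCriterion must hold the five GSH criteria")
    if (length(object@perCriterion) &&
        object@combined > min(object@perCriterion) + 1e-12)
      msg <- c(msg, "combined fraction cannot exceed any single criterion")
    if (length(msg)) msg else TRUE
  }
)

#' Simulation configuration
#'
#' Parameters for the synthetic-data module: background genome, planted
#' AAATTT target motifs, diverged element copies, and the junction
#' sequencing library (megaprimer / sample barcode / transposon end on
#' the forward read, linker cassette / molecular barcode on the reverse
#' read). All randomness flows from `seed`.
#'
#' @slot seed Mandatory RNG seed.
#' @slot genomeLength Background genome length (bp).
#' @slot gcContent Background GC fraction.
#' @slot motifDensity Planted AAATTT motifs per kb.
#' @slot elementConsensus Element consensus [Biostrings::DNAString]
#'   (carries the TIRs).
#' @slot copyDivergences Two-column matrix of per-copy true
#'   (transition, transversion) substitution probabilities.
#' @slot nSites Number of insertion sites to plant.
#' @slot targetMotifFraction Fraction of sites planted between the AAA
#'   and TTT of a target motif.
#' @slot readsPerSiteMean,readsPerSiteDispersion Negative-binomial read
#'   depth model per site.
#' @slot errorRate Uniform per-base substitution error rate of reads.
#' @slot readLength Read length (bp).
#' @slot megaprimer,linker Library construction sequences.
#' @slot sampleBarcodes Sample barcode whitelist.
#' @slot transposonEndLength Length of element terminus carried on the
#'   forward read.
#' @slot molecularBarcodeLength Length of the per-molecule barcode in
#'   the linker cassette.
#' @seealso [simConfig()], [simulateGenome()], [simulateLibrary()]
#' @exportClass SpySimConfig
setClass("SpySimConfig",
  representation(
    seed = "integer", genomeLength = "integer", gcContent = "numeric",
    motifDensity = "numeric", elementConsensus = "DNAString",
    copyDivergences = "matrix", nSites = "integer",
    targetMotifFraction = "numeric", readsPerSiteMean = "numeric",
    readsPerSiteDispersion = "numeric", errorRate = "numeric",
    readLength = "integer", megaprimer = "character", linker = "character",
    sampleBarcodes = "character", transposonEndLength = "integer",
    molecularBarcodeLength = "integer"
  ),
  validity = function(object) {
    msg <- character()
    fr <- c(gc = object@gcContent, motif = object@targetMotifFraction,
            err = object@errorRate)
    if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
    if (length(object@seed) != 1L || is.na(object@seed))
      msg <- c(msg, "seed is mandatory")
    if (object@genomeLength < 1000L)
      msg <- c(msg, "genomeLength must be at least 1 kb")
    if (length(msg)) msg else TRUE
  }
)
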