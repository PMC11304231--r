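---
title: "Methods: annotating and profiling Spy-family transposons"
author: "SpyTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and profiling Spy-family transposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpyTools)
```

# Scope

Spy-family elements are cut-and-paste DNA transposons with an unusual
integration chemistry: they insert blunt between an upstream `AAA` and a
downstream `TTT` and leave no target site duplication (TSD). cgSpy, the
family member from the Pacific oyster *Crassostrea gigas*, is active in
human cells, which makes the family a candidate delivery vehicle for
gene therapy and motivates careful computational characterization: how
intact and how old are the genomic copies, where exactly does the
element integrate, and how often does it land in genomic safe harbors.

SpyTools implements that characterization as a set of testable
operations: element annotation, divergence dating, insertion-site
calling from junction libraries, integration profiling, the two assay
calculators, and a seeded synthetic-data module that provides ground
truth for every stage.

# Element annotation

## TIR detection

`detectTirs()` compares the element prefix against the reverse
complement of its suffix over all anchor offsets up to
`anchorTolerance` (default 5 bp) from either terminus. The comparison
is ungapped: among candidate windows of at least `minLen` (default
10 bp) whose identity reaches `minIdentity` (default 0.8), the window
with the maximal match-minus-mismatch score is reported, with ties
broken toward the longer and then the more identical window.

We chose an ungapped scan over a gapped local alignment deliberately.
The pair invariant that both repeat copies have equal length is only
well-defined without gaps; the termini of a blunt-cutting transposon
are not expected to differ by indels between the two TIR copies of one
element; and the maximal-score rule keeps the reported repeat from
drifting into flanking sequence, which a pure "longest window above
the identity floor" rule does (random flanks match at about 25% and can
sustain 80% cumulative identity for surprisingly long). The scan is
exactly reproducible and brute-force verifiable, which the test suite
exploits with an independent enumeration oracle.

The identity floor 0.8 must clear the 0.25 expectation of unrelated
sequence; `minLen` 5 is rejected as below the shortest reported
Spy-family TIR (15 bp) would be meaningless to anchor.

## Boundary refinement

`refineBoundaries()` takes a multiple alignment of copies extracted
with flanking sequence and returns the maximal contiguous column block
in which at least `consistencyThreshold` (default 0.6) of rows match
the column consensus. Flanks of independent copies are mutually
unrelated, so their agreement hovers near 0.25 for four-letter columns;
0.6 clears that with margin while tolerating polymorphic element
columns. At least three copies are required — with two, every column
trivially reaches agreement 0.5 or 1.0 and the statistic is
uninformative.

## Copy counting

`countCopies()` retains homology hits with coverage strictly greater
than 0.4 and identity strictly greater than 0.8 — strict because the
filter thresholds are printed as strict inequalities, and boundary
hits (exactly 40% or 80%) are excluded. Retained same-strand hits
separated by at most 100 bp are merged before counting, since a single
degraded copy is routinely reported as several alignment fragments;
100 bp is small against the multi-kilobase element length, so distinct
neighboring copies do not merge.

## Intactness classification

`classifyElement()` applies the intact-transposase rule: *intact*
requires a transposase longer than 500 amino acids carrying both a
DNA-binding domain and a DDE catalytic domain on an element with both
TIRs detectable; *full-length* requires both TIRs; everything else is a
*fragment*. 500 aa is a strict lower bound (a 500-aa protein is not
intact). Domain evidence is consumed from a parsed hmmscan-style
domain table; when none is available, a low-confidence fallback scans
the protein for an acidic D..D..E triad at transposase-like spacings
(35-150 aa between the aspartates, 25-140 aa to the glutamate). The
fallback result is flagged with its provenance and cannot claim a
DNA-binding domain independently; real analyses should supply domain
hits.

ORF scanning follows the standard rule: both strands, three frames,
ATG start, stop codon, longest wins.

## Flank motifs and TSD detection

`flankMotifs()` reports the `k` bases on each side of a genomic copy in
element orientation (minus-strand copies have their flanks swapped and
complemented), so the Spy signature reads `AAA` / `TTT` regardless of
strand. `detectTsd()` compares the empty and occupied alleles of a
locus, places the inserted segment at the leftmost position consistent
with the longest common prefix/suffix, and reports the longest
duplication of the left flank at the insert's 3' end. Single-event TSD
inference is inherently ambiguous when the insert's boundary bases
coincide with adjacent target bases; the maximal consistent duplication
is reported, and the synthetic inserter used in testing plants inserts
with informative boundaries so round trips are exact for TSD lengths
0-20.

# Divergence dating

`kimura2p()` implements the two-parameter distance
$K = -\tfrac12 \ln\left((1-2P-Q)\sqrt{1-2Q}\right)$ from transition
(P) and transversion (Q) mismatch proportions. When $1-2P-Q \le 0$ or
$1-2Q \le 0$ the logarithm saturates and the estimate is flagged rather
than extrapolated. `copyDivergence()` counts P and Q over gap-free
columns only; alignment, where needed, is global with affine gaps
(match +1, mismatch −1, gap open −5, −1 per additional base). On
substitution-only input (as produced by the default simulator) the
alignment is the identity, and the estimator-recovery study therefore
uses the pre-aligned input path at 10 kb; the alignment path is
exercised separately on indel-bearing fixtures.

`buildLandscape()` bins each copy's aligned bp by percent divergence
(100·K, 1% bins), the classic repeat-landscape view: coverage mass
near zero marks recent activity, several modes mark repeated invasion
waves. Saturated copies are excluded from bins and reported separately,
so the binned mass exactly equals the aligned bp of usable copies.
Divergence is computed per copy, not per alignment fragment; CpG-aware
corrections are not applied.

# Insertion-site calling

The junction-library protocol filters read pairs on structure: the
forward read must carry the megaprimer within its first 100 bp, the
reverse read the linker cassette within its first 100 bp, and the
sample barcode (read immediately after the megaprimer) must be on the
sample sheet. Adapter constructs are then trimmed — a match with its
midpoint in the first half of the read removes the prefix through the
match, otherwise the suffix from the match — and reads shorter than
80 bp after trimming are eliminated. Matching is exact by default, with
an optional one-mismatch mode for libraries carrying realistic
sequencing error.

Only forward reads are mapped: the junction lies at the
transposon-proximal end of their genomic portion (0-based between-base
coordinate, `start − 1` on the plus strand, `end` on the minus strand).
Reverse reads contribute the linker check and the per-molecule barcode.
The built-in mapper is an exact/near-exact scanner suitable for
synthetic references; reads with tied best placements are dropped as
ambiguous and never contribute support. Alignments from an external
mapper (with multi-mappers already resolved) can be supplied as
SAM/BAM instead.

`callSites()` collapses placements per (chromosome, junction, strand)
and reports sites with support of at least 10 reads, the field-standard
threshold for "independent reads". Because the library attaches
molecular barcodes, both counts are always reported: raw reads and
distinct molecules, with barcodes within Hamming distance 1 of a more
abundant barcode collapsed as sequencing errors. Whether the threshold
applies to reads or molecules is a configuration switch
(`dedupeByMolecule`), recorded in the result's parameters; molecule
counting is exact only when every molecule retains at least one intact
read, so lossless comparisons are made on error-free libraries.

# Integration profiling

`extractWindows()` returns strand-oriented 60-bp windows centered on
each junction; `buildLogo()` converts them to base frequencies and
per-position information content $2 + \sum_b f_b \log_2 f_b$, which
reaches 2 bits exactly when all windows agree and 0 for uniform base
usage. `targetMotifFraction()` tests the strand-normalized junction
context against an IUPAC pattern; both the degenerate `AAWTT` and the
strict `AAATTT` presets place the junction after the third base. Both
orientations of the context are accepted by default (the motif is its
own reverse complement, but the junction offset is asymmetric for
`AAWTT`), and per-orientation counts are reported so either convention
can be read off.

`enrichment()` compares the fraction of junctions overlapping each
category against seeded uniform random loci (100000 by default) drawn
over the supplied chromosome lengths, optionally redrawing loci inside
an exclusion mask. A between-base junction overlaps an interval iff the
interval contains either flanking base; this rule, rather than a
zero-width point test, makes abutting intervals count and is invariant
to splitting an interval into adjacent pieces. Fold change 1 is the
random expectation; a zero random fraction with non-zero observed
fraction is flagged rather than reported as infinity.

`gshClassify()` applies the five genomic-safe-harbor criteria —
outside gene bodies, outside cancer genes, outside miRNA genes, not
within 50 kb upstream of any TSS (strand-aware, hence the requirement
that TSS points be stranded), outside TSS ± 5 kb — and combines them
by conjunction, so the combined fraction can never exceed any single
criterion. The "5' ends of genes" enrichment category, where needed,
is operationalized as a fixed ±2.5 kb window around the TSS.

`fisherCompare()` delegates the two-sided exact test to
`stats::fisher.test`, whose two-sided rule is the minimum-likelihood
summation over tables with fixed margins; the test suite verifies it
against a from-scratch hypergeometric enumeration.

# Assay calculators

`ddpcrLambda()` uses the standard single-volume Poisson estimator
$\lambda = -\ln(1 - k/n)$ from the negative-droplet fraction, with no
droplet-volume variance correction; saturated wells (all droplets
positive) are errors, not estimates. `copiesPerGenome()` is the
target/reference concentration ratio against a single-copy reference
gene (RPP30 by convention); whether "per genome" means per haploid or
per diploid equivalent is a stated convention
(`referenceCopiesPerGenome`), not a guess. `cytotoxicityPct()` is the
LDH release formula
$100\,(A_{treated}-A_{control})/(A_{max}-A_{control})$, affine-
invariant under a common absorbance offset.

# The synthetic-data module

The simulator emulates the statistical structure the analyses assume:
an i.i.d. background genome at configurable GC content; `AAATTT`
target motifs planted at a configurable density on an 18-bp grid with
random jitter (non-overlapping by construction); element copies
mutated from the consensus with independent per-site transition and
transversion probabilities (the K2P generative model, no indels by
default) and inserted blunt between `AAA|TTT` on random strands; and
junction libraries whose forward reads read megaprimer, sample
barcode, transposon end and genomic junction sequence, and whose
reverse reads read linker and molecular barcode, with
negative-binomial per-site depth and uniform substitution errors over
the whole read.

Defaults are the study conditions the tests run under: 100-kb genome
at GC 0.5, one motif per kb, a deterministic 3.1-kb consensus with
467-bp TIRs (the cgSpy TIR length) and a 681-aa transposase ORF, two
six-copy age waves near K 0.02 and 0.15 (the young/old coexistence
signature), 60% of insertion sites at the target motif (the observed
target-motif fraction for cgSpy), negative-binomial depth with mean 20
and dispersion 5, and a 0.001 per-base substitution error rate
(Illumina-like). Within-site molecular barcodes are drawn pairwise at
Hamming distance ≥ 3 so that error-tolerant deduplication is
well-posed. All outputs are byte-identical under a fixed seed.

What the simulator does **not** emulate — and hence what passing tests
cannot show about real data — includes repetitive and low-complexity
genomic context (multi-mapping is exercised only through planted
duplications), indels and quality-dependent error profiles, PCR
chimeras and jackpot amplification, chromatin-driven insertion bias,
and real genome annotation geometry. Results on real libraries depend
on an external mapper for genome-scale alignment; the built-in mapper
is deliberately small.

# Problem sizes and numerical choices

The shipped verification runs use: a 1776-point (P, Q) grid at
tolerance 1e-12 for the closed form; 200 replicates of 10-kb copies at
(P*, Q*) = (0.05, 0.02) for estimator recovery (|K − K*| < 0.01 in at
least 95%); a 100-kb genome with 50 supported (15-20 reads) and 20
decoy (3-9 reads) sites for end-to-end recovery; 2000 sites at a 60%
planted motif fraction judged against the binomial 95% interval; 1000
random sites against the safe-harbor oracle; and exhaustive Fisher
enumeration for small tables plus sampled tables with margins up to 30.
These sizes were chosen so each property is tested at a scale where its
statistical guarantee is meaningful.

Ties and degenerate inputs are resolved explicitly throughout: strict
filter inequalities; TIR ties by score, then length, then identity;
ambiguous mappings dropped; saturated K2P estimates flagged;
zero-insert TSD comparisons rejected; unstranded TSS inputs rejected
(upstream would be undefined); empty hit lists count zero copies
without error.

# Known limitations

The TIR detector is ungapped by design and will under-report repeat
pairs whose two copies differ by indels. The domain-evidence fallback
is a heuristic and says so. The built-in mapper does not scale to real
genomes. Molecule counts are lower bounds in the presence of read
loss. The safe-harbor definition is the five-criterion conjunction
only; it does not incorporate expression or chromatin data, which are
consumed, if at all, as pre-computed interval sets.
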