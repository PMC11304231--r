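# Element annotation: TIR detection, boundary refinement, copy
# counting, classification, flank motifs, TSD detection.

test_that("detectTirs finds a planted perfect 467-bp TIR exactly", {
  tir <- random_dna_fixture(467, seed = 101)
  insert <- random_dna_fixture(2000, seed = 102)
  el <- paste0(tir, insert, rc(tir))
  res <- detectTirs(el)
  expect_s4_class(res, "TirPair")
  expect_identical(IRanges::width(tirLeft(res)), 467L)
  expect_identical(IRanges::width(tirRight(res)), 467L)
  expect_equal(tirIdentity(res), 1.0)
  expect_identical(IRanges::start(tirLeft(res)), 1L)
  expect_identical(IRanges::end(tirRight(res)), nchar(el))
})

test_that("detectTirs returns NULL for sequence without terminal repeats", {
  rnd <- random_dna_fixture(2000, seed = 103)
  expect_null(detectTirs(rnd, minLen = 10L))
})

test_that("detectTirs matches the brute-force oracle on a degraded TIR", {
  # 30-bp TIR carrying 3 mismatches on the right copy; poly-A insert is
  # maximally uninformative against its own reverse complement.
  t30 <- paste(rep("ACGTG", 6), collapse = "")
  t30m <- t30
  substr(t30m, 5, 5) <- "T"    # G -> T
  substr(t30m, 14, 14) <- "A"  # T -> A
  substr(t30m, 22, 22) <- "G"  # C -> G
  el <- paste0(t30, strrep("A", 300), rc(t30m))
  res <- detectTirs(el, minIdentity = 0.8)
  expect_identical(IRanges::width(tirLeft(res)), 30L)
  expect_equal(tirIdentity(res), 27 / 30)
  oracle <- tir_oracle(el, minLen = 10L, minIdent = 0.8, tol = 5L)
  expect_identical(IRanges::width(tirLeft(res)), as.integer(oracle$len))
  expect_equal(tirIdentity(res), oracle$identity)
})

test_that("TIR detection is strand-symmetric", {
  for (seed in c(201, 202, 203)) {
    tir <- random_dna_fixture(60, seed = seed)
    insert <- random_dna_fixture(500, seed = seed + 50)
    el <- paste0(tir, insert, rc(tir))
    fwd <- detectTirs(el)
    rev <- detectTirs(rc(el))
    expect_identical(IRanges::width(tirLeft(fwd)),
                     IRanges::width(tirLeft(rev)))
    expect_equal(tirIdentity(fwd), tirIdentity(rev))
  }
})

test_that("detectTirs rejects invalid inputs", {
  expect_error(detectTirs("ACGTNXQ"), "non-DNA")
  expect_error(detectTirs(random_dna_fixture(100, 1), minLen = 4L),
               "at least 5")
  expect_error(detectTirs("ACGTACGTAC", minLen = 10L), "twice")
})

test_that("refineBoundaries recovers a planted element core", {
  # mutually dissimilar flanks: per column the 5 rows cycle through the
  # alphabet, capping column agreement at 2/5 < 0.6
  core <- random_dna_fixture(400, seed = 301)
  bases <- c("A", "C", "G", "T")
  flank <- function(row, n, phase) {
    paste(bases[((seq_len(n) + row + phase) %% 4) + 1], collapse = "")
  }
  rows <- vapply(1:5, function(i) {
    paste0(flank(i, 100, 0), core, flank(i, 100, 2))
  }, "")
  iv <- refineBoundaries(rows)
  expect_identical(IRanges::start(iv), 101L)
  expect_identical(IRanges::end(iv), 500L)
})

test_that("refineBoundaries returns the whole alignment when all rows agree", {
  row <- random_dna_fixture(300, seed = 331)
  iv <- refineBoundaries(rep(row, 4))
  expect_identical(IRanges::start(iv), 1L)
  expect_identical(IRanges::end(iv), 300L)
})

test_that("refineBoundaries separates controlled agreement levels", {
  # Per-column agreement planted directly: flanks 0.3 (3 of 10 rows
  # match consensus), core 0.95 on average; threshold 0.6 must recover
  # the core within +/- 2 columns.
  n_rows <- 10L; flank <- 80L; core_len <- 300L
  cons <- strsplit(random_dna_fixture(flank * 2L + core_len, seed = 341),
                   "")[[1L]]
  withr::with_seed(342, {
    mat <- vapply(seq_len(n_rows), function(r) {
      v <- cons
      for (j in seq_along(v)) {
        inside <- j > flank && j <= flank + core_len
        keep_p <- if (inside) 0.95 else 0.3
        if (runif(1) > keep_p) {
          v[j] <- sample(setdiff(c("A", "C", "G", "T"), cons[j]), 1L)
        }
      }
      paste(v, collapse = "")
    }, "")
    iv <- refineBoundaries(mat, consistencyThreshold = 0.6)
    expect_lte(abs(IRanges::start(iv) - (flank + 1L)), 2L)
    expect_lte(abs(IRanges::end(iv) - (flank + core_len)), 2L)
  })
})

test_that("refineBoundaries needs at least three copies", {
  expect_error(refineBoundaries(c("ACGT", "ACGT")), "3 copies")
})

make_hits <- function(starts, identity, coverage, strand = "+",
                      width = 3000L) {
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = starts, width = width),
    strand = strand)
  gr$identity <- identity
  gr$coverage <- coverage
  gr
}

test_that("countCopies applies strict coverage/identity filters", {
  # boundary hits sit exactly at or below the printed cutoffs
  hits <- make_hits(c(1000, 20000, 40000, 60000),
                    identity = c(0.95, 0.79, 0.95, 0.80),
                    coverage = c(0.39, 0.95, 0.41, 0.41))
  res <- countCopies(hits)
  expect_identical(res$count, 1L)
  expect_identical(GenomicRanges::start(res$copies), 40000L)
})

test_that("countCopies counts planted non-overlapping copies exactly", {
  starts <- seq(1000, by = 10000, length.out = 12)
  hits <- make_hits(starts, identity = 0.9, coverage = 1.0)
  expect_identical(countCopies(hits)$count, 12L)
  # permutation invariance
  perm <- withr::with_seed(1, sample(length(hits)))
  expect_identical(countCopies(hits[perm])$count, 12L)
  # merging is idempotent: re-counting the merged copies changes nothing
  merged <- countCopies(hits)$copies
  merged$identity <- 0.9; merged$coverage <- 1.0
  expect_identical(countCopies(merged)$count, 12L)
})

test_that("countCopies merges same-strand fragments within the gap", {
  hits <- make_hits(c(1000, 4050, 20000), identity = 0.9, coverage = 0.5,
                    width = 3000L)
  # gap between hit 1 (ends 3999) and hit 2 (starts 4050) is 50 <= 100
  expect_identical(countCopies(hits)$count, 2L)
  # opposite strands never merge
  hits2 <- make_hits(c(1000, 4050), identity = 0.9, coverage = 0.5,
                     strand = c("+", "-"), width = 3000L)
  expect_identical(countCopies(hits2)$count, 2L)
  expect_identical(countCopies(GenomicRanges::GRanges())$count, 0L)
})

test_that("classifyElement applies the intact-transposase rule", {
  expect_identical(classifyElement(700L, TRUE, TRUE, TRUE), "intact")
  expect_identical(classifyElement(499L, TRUE, TRUE, TRUE), "full_length")
  expect_identical(classifyElement(500L, TRUE, TRUE, TRUE), "full_length")
  expect_identical(classifyElement(700L, TRUE, FALSE, TRUE), "full_length")
  expect_identical(classifyElement(700L, TRUE, TRUE, FALSE), "fragment")
})

test_that("flankMotifs reports flanks in element orientation", {
  el <- random_dna_fixture(500, seed = 401)
  g <- Biostrings::DNAStringSet(paste0(
    random_dna_fixture(200, seed = 402), "AAA", el, "TTT",
    random_dna_fixture(200, seed = 403)))
  names(g) <- "chr1"
  hit <- GenomicRanges::GRanges("chr1", IRanges::IRanges(204, 703),
                                strand = "+")
  res <- flankMotifs(g, hit)
  expect_identical(res$flank5, "AAA")
  expect_identical(res$flank3, "TTT")
  expect_true(res$matchesAAATTT)

  # minus-strand copy: genomic ...AAA[revcomp(el)]TTT... must still
  # report AAA/TTT after orientation normalization
  g2 <- Biostrings::DNAStringSet(paste0(
    random_dna_fixture(200, seed = 404), "AAA", rc(el), "TTT",
    random_dna_fixture(200, seed = 405)))
  names(g2) <- "chr1"
  hit2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(204, 703),
                                 strand = "-")
  res2 <- flankMotifs(g2, hit2)
  expect_identical(res2$flank5, "AAA")
  expect_identical(res2$flank3, "TTT")
  expect_true(res2$matchesAAATTT)

  # non-target context
  g3 <- Biostrings::DNAStringSet(paste0(
    random_dna_fixture(50, seed = 406), "GGG", el, "CCC",
    random_dna_fixture(50, seed = 407)))
  names(g3) <- "chr1"
  hit3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(54, 553),
                                 strand = "+")
  res3 <- flankMotifs(g3, hit3)
  expect_identical(res3$flank5, "GGG")
  expect_false(res3$matchesAAATTT)

  # contig edge: absent flank, no match
  g4 <- Biostrings::DNAStringSet(paste0(el, "TTT"))
  names(g4) <- "chr1"
  hit4 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500),
                                 strand = "+")
  res4 <- flankMotifs(g4, hit4)
  expect_true(is.na(res4$flank5))
  expect_false(res4$matchesAAATTT)
})

test_that("detectTsd measures blunt and duplicating insertions", {
  pre <- paste0(random_dna_fixture(80, seed = 501), "AAATTT",
                random_dna_fixture(80, seed = 502))
  insert <- paste0("G", random_dna_fixture(198, seed = 503), "C")
  # blunt insertion between AAA and TTT
  post <- syntheticInsertion(pre, insert, position = 83L, tsd = 0L)
  expect_identical(detectTsd(pre, post), 0L)
  # TTAA-duplicating insertion
  pre2 <- paste0(random_dna_fixture(60, seed = 504), "TTAA",
                 random_dna_fixture(60, seed = 505))
  post2 <- syntheticInsertion(pre2, insert, position = 64L, tsd = 4L)
  expect_identical(detectTsd(pre2, post2), 4L)
  # degenerate inputs
  expect_error(detectTsd(pre, pre), "single insertion")
  expect_error(detectTsd(pre, substr(pre, 1, 100)), "single insertion")
})

test_that("detectTsd round-trips all planted TSD lengths 0-20", {
  withr::with_seed(510, {
    for (tsd in 0:20) {
      pre <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
      pos <- sample(50:250, 1)
      # informative boundaries: insert must not extend the duplication
      # (last base != base left of the duplicated block) nor shift the
      # insertion point (first base != base right of it)
      leftBase <- substr(pre, pos - tsd, pos - tsd)
      rightBase <- substr(pre, pos + 1, pos + 1)
      first <- sample(setdiff(c("A", "C", "G", "T"), rightBase), 1)
      last <- sample(setdiff(c("A", "C", "G", "T"), leftBase), 1)
      insert <- paste0(first,
                       paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                             collapse = ""), last)
      post <- syntheticInsertion(pre, insert, position = pos, tsd = tsd)
      expect_identical(detectTsd(pre, post), as.integer(tsd))
    }
  })
})

test_that("findLongestOrf scans both strands and annotateElement combines", {
  cfg <- default_config(1)
  cons <- as.character(cfg@elementConsensus)
  orf <- findLongestOrf(cons)
  expect_identical(orf$proteinLength, 681L)  # ATG + 680 codons
  expect_identical(orf$strand, "+")
  # the same ORF must be found on the reverse complement, minus strand
  orf_rc <- findLongestOrf(rc(cons))
  expect_identical(orf_rc$proteinLength, 681L)
  expect_identical(orf_rc$strand, "-")

  dom <- data.frame(element_id = "el1",
                    domain_name = c("HTH_Tnp_1", "DDE_Tnp_1"),
                    stringsAsFactors = FALSE)
  el <- annotateElement("el1", cons, domains = dom)
  expect_identical(classification(el), "intact")
  # a domain table without DBD/DDE hits for this element -> full_length
  dom2 <- data.frame(element_id = "el2", domain_name = "zf-CCHC",
                     stringsAsFactors = FALSE)
  el2 <- annotateElement("el2", cons, domains = dom2)
  expect_identical(classification(el2), "full_length")
})

test_that("BLAST and domtblout tables parse into the expected shapes", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "el1\tchr1\t95.00\t3000\t150\t2\t1\t3000\t10001\t13000\t0.0\t5000",
    "el1\tchr1\t90.00\t1500\t150\t2\t1\t1500\t45000\t43501\t0.0\t2500"),
    tsv)
  hits <- readBlastHits(tsv, elementLength = 3000)
  expect_identical(length(hits), 2L)
  expect_equal(hits$identity, c(0.95, 0.90))
  expect_equal(hits$coverage, c(1.0, 0.5))
  expect_identical(as.character(GenomicRanges::strand(hits)), c("+", "-"))
  expect_identical(GenomicRanges::start(hits), c(10001L, 43501L))

  dt <- tempfile(fileext = ".domtblout")
  writeLines(c(
    "# hmmscan --domtblout output",
    paste("DDE_Tnp_1 PF01609.21 300 el1 - 700 1e-50 170.0 0.1 1 1",
          "1e-48 1e-45 165.0 0.1 5 290 310 600 300 610 0.95 desc text"),
    ""), dt)
  dom <- readDomtblout(dt)
  expect_identical(nrow(dom), 1L)
  expect_identical(dom$element_id, "el1")
  expect_identical(dom$domain_name, "DDE_Tnp_1")
  expect_identical(dom$ali_from, 310L)
  expect_equal(dom$score, 165.0)
})
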