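# Integration-site profiling: windows, logos, motif fraction,
# enrichment, safe harbors, Fisher comparisons.

test_that("extractWindows centers on the junction and honors strand", {
  left <- random_dna_fixture(30, seed = 801)
  right <- random_dna_fixture(30, seed = 802)
  g <- Biostrings::DNAStringSet(paste0(
    random_dna_fixture(100, seed = 803), left, right,
    random_dna_fixture(100, seed = 804)))
  names(g) <- "chr1"
  j <- 130L  # junction between the two planted 30-mers
  w <- extractWindows(g, junction_gr("chr1", j, "+"), window = 60L)
  expect_identical(as.character(w[[1]]), paste0(left, right))
  # minus strand returns the reverse complement of the plus window
  wm <- extractWindows(g, junction_gr("chr1", j, "-"), window = 60L)
  expect_identical(as.character(wm[[1]]), rc(paste0(left, right)))
  # edge sites are dropped with a warning
  expect_warning(
    we <- extractWindows(g, junction_gr("chr1", c(10L, j), "+")),
    "edge")
  expect_identical(length(we), 1L)
  expect_error(extractWindows(g, junction_gr("chrX", j)), "chrX")
})

test_that("buildLogo reaches the 2-bit ceiling on identical windows", {
  w <- rep(random_dna_fixture(60, seed = 811), 25)
  logo <- buildLogo(w)
  expect_equal(infoContent(logo), rep(2, 60))
  expect_equal(colSums(baseFreq(logo)), rep(1, 60), ignore_attr = TRUE)
})

test_that("buildLogo information content matches direct entropy values", {
  # uniform column -> 0 bits; half/half column -> 1 bit
  w <- c("AA", "CA", "GC", "TC")
  logo <- buildLogo(w)
  expect_equal(infoContent(logo)[1], 0)
  expect_equal(infoContent(logo)[2], 1)
  expect_equal(infoContent(logo)[2], entropy_ic(c(2, 2, 0, 0)))
  expect_error(buildLogo(c("ACGT", "ACG")), "uniform length")
})

test_that("logo of shuffled windows decays toward 0 bits", {
  withr::with_seed(812, {
    w <- vapply(1:400, function(i) {
      paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    }, "")
    logo <- buildLogo(w)
    expect_true(all(infoContent(logo) >= 0 & infoContent(logo) <= 2))
    expect_lt(mean(infoContent(logo)), 0.05)
  })
})

test_that("targetMotifFraction matches planted AAATTT junctions", {
  g <- Biostrings::DNAStringSet(paste0(
    random_dna_fixture(100, seed = 821), "AAATTT",
    strrep("GC", 50), random_dna_fixture(94, seed = 822)))
  names(g) <- "chr1"
  jm <- 103L  # between AAA and TTT
  jgc <- 160L  # inside the GC-only block
  res <- targetMotifFraction(g, junction_gr("chr1", c(jm, jgc), "+"),
                             pattern = "AAATTT", junctionOffset = 3L)
  expect_identical(res$matchForward, c(TRUE, FALSE))
  expect_equal(res$fraction, 0.5)
  # the degenerate AAWTT preset also matches the planted site
  res2 <- targetMotifFraction(g, junction_gr("chr1", jm, "+"),
                              pattern = "AAWTT", junctionOffset = 3L)
  expect_equal(res2$fraction, 1)
  # a minus-strand site at the same motif still matches
  res3 <- targetMotifFraction(g, junction_gr("chr1", jm, "-"),
                              pattern = "AAATTT", junctionOffset = 3L)
  expect_equal(res3$fraction, 1)
})

test_that("planted motif fraction is recovered across a simulated set", {
  cfg <- default_config(82, genomeLength = 150000, motifDensity = 3,
                        nSites = 500, targetMotifFraction = 0.6)
  sg <- simulateGenome(cfg)
  st <- plantInsertionSites(sg, cfg)
  res <- targetMotifFraction(
    sg$genome, junction_gr(st$chrom, st$junction, st$strand),
    pattern = "AAATTT", junctionOffset = 3L)
  ci <- 1.96 * sqrt(0.6 * 0.4 / 500)
  expect_lt(abs(res$fraction - 0.6), ci)
  # every site the truth table marks at-motif must match
  expect_true(all((res$matchForward | res$matchReverse)[st$at_motif]))
})

test_that("enrichment fold change is calibrated against uniform sites", {
  cs <- c(chr1 = 100000L)
  sitesU <- randomLoci(cs, 2000, seed = 901)
  cats <- list(
    whole = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000)),
    tenth = GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, 30000)),
    empty = GenomicRanges::GRanges())
  er <- enrichment(sitesU, cats, cs, nRandom = 20000, seed = 902)
  tab <- enrichmentTable(er)
  expect_equal(tab$foldChange[tab$category == "whole"], 1)
  expect_true(tab$flagged[tab$category == "empty"])
  expect_lt(abs(tab$foldChange[tab$category == "tenth"] - 1), 0.15)
  # interval order / splitting invariance
  split_tenth <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(25001, 20001), c(30000, 25000)))
  er2 <- enrichment(sitesU, list(tenth = split_tenth), cs,
                    nRandom = 20000, seed = 902)
  expect_equal(enrichmentTable(er2)$foldChange,
               tab$foldChange[tab$category == "tenth"])
})

test_that("the junction overlap rule counts abutting intervals", {
  cat_gr <- list(iv = GenomicRanges::GRanges("chr1",
                                             IRanges::IRanges(1001, 2000)))
  cs <- c(chr1 = 10000L)
  # junctions: inside (1500), left-abutting (1000: right flank base is
  # base 1001), right-abutting (2000), and clear outside (3000)
  sites <- junction_gr("chr1", c(1500L, 1000L, 2000L, 3000L))
  er <- enrichment(sites, cat_gr, cs, nRandom = 100, seed = 1)
  expect_equal(enrichmentTable(er)$observedFraction, 0.75)
})

test_that("gshClassify flags the five criteria and their conjunction", {
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(100000, 150000))
  cancer <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(400000, 420000))
  mirna <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(500000, 501000))
  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100000, width = 1),
                                strand = "+")
  # inside the gene body -> genes criterion fails, combined fails
  f1 <- gshClassify(junction_gr("chr1", 120000L), genes, cancer, mirna, tss)
  expect_false(f1$outsideGenes)
  expect_false(f1$combined)
  # 60 kb upstream of the only TSS, clear of everything -> all pass
  f2 <- gshClassify(junction_gr("chr1", 40000L), genes, cancer, mirna, tss)
  expect_true(all(unlist(as.data.frame(f2)[1, 1:5])))
  expect_true(f2$combined)
  # 30 kb upstream -> inside the 50-kb upstream window only
  f3 <- gshClassify(junction_gr("chr1", 70000L), genes, cancer, mirna, tss)
  expect_true(f3$outsideGenes)
  expect_false(f3$outsideTssUpstream50k)
  expect_false(f3$combined)
  # 3 kb INTO the gene from the TSS -> within TSS +/- 5 kb
  f4 <- gshClassify(junction_gr("chr1", 103000L), genes, cancer, mirna, tss)
  expect_false(f4$outsideTss5k)
  # unstranded TSS is an error
  tss_un <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100000, width = 1))
  expect_error(gshClassify(junction_gr("chr1", 1000L), genes, cancer,
                           mirna, tss_un), "stranded")
})

test_that("gshClassify equals the naive interval-stabbing oracle", {
  withr::with_seed(911, {
    L <- 1000000L
    mkiv <- function(n, w) {
      s <- sort(sample.int(L - w, n))
      GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + w - 1L))
    }
    genes <- mkiv(40, 20000); cancer <- mkiv(10, 15000)
    mirna <- mkiv(15, 500)
    tpos <- sample.int(L, 30)
    tss <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(tpos, width = 1),
      strand = sample(c("+", "-"), 30, TRUE))
    sites <- junction_gr("chr1", sample.int(L - 1L, 1000))
    flags <- gshClassify(sites, genes, cancer, mirna, tss)

    j <- sites$junction
    stab <- function(gr) {
      stab_oracle(j, GenomicRanges::start(gr), GenomicRanges::end(gr))
    }
    up_lo <- ifelse(as.character(GenomicRanges::strand(tss)) == "+",
                    tpos - 50000L, tpos + 1L)
    up_hi <- ifelse(as.character(GenomicRanges::strand(tss)) == "+",
                    tpos - 1L, tpos + 50000L)
    oracle <- !stab(genes) & !stab(cancer) & !stab(mirna) &
      !stab_oracle(j, pmax(1L, up_lo), up_hi) &
      !stab_oracle(j, pmax(1L, tpos - 5000L), tpos + 5000L)
    expect_identical(as.logical(flags$combined), as.logical(oracle))

    # combined <= each per-criterion fraction (subset monotonicity)
    rep <- gshReport(flags)
    expect_true(all(combinedFraction(rep) <=
                      criterionFractions(rep) + 1e-12))
  })
})

test_that("fisherCompare equals the hypergeometric enumeration oracle", {
  expect_equal(fisherCompare(3, 4, 1, 4), 34 / 70, tolerance = 1e-12)
  expect_equal(fisherCompare(0, 10, 10, 10), 2 / choose(20, 10),
               tolerance = 1e-9)
  # identical proportions with equal n -> p = 1
  expect_equal(fisherCompare(5, 12, 5, 12), 1)
  # exhaustive over all tables with group sizes up to 12
  for (n1 in 1:12) for (n2 in 1:12) for (k1 in 0:n1) for (k2 in 0:n2) {
    expect_equal(fisherCompare(k1, n1, k2, n2),
                 fisher_oracle(k1, n1, k2, n2), tolerance = 1e-9)
  }
  # sampled larger tables with margins up to 30
  withr::with_seed(921, {
    for (i in 1:200) {
      n1 <- sample.int(30, 1); n2 <- sample.int(min(30, 60 - n1), 1)
      k1 <- sample.int(n1 + 1, 1) - 1L; k2 <- sample.int(n2 + 1, 1) - 1L
      if (k1 + k2 > 30 || (n1 - k1) + (n2 - k2) > 30) next
      expect_equal(fisherCompare(k1, n1, k2, n2),
                   fisher_oracle(k1, n1, k2, n2), tolerance = 1e-9)
    }
  })
  expect_error(fisherCompare(0, 0, 1, 2), "positive")
})
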