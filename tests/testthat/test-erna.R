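test_that("segmentation finds dense runs, merges close ones and drops short ones", {
  L <- 20000
  ## no tags -> no calls
  none <- callNascentTranscripts(mkTags(integer()), mkTags(integer()))
  expect_length(none, 0)

  ## one dense 400-bp run (1 tag/bp each condition, normFactor 1:
  ## smoothed pooled coverage ~1 tag/bp at the core)
  wt <- mkTags(runTags(5000, 5400), chromSizes = c(chrA = L))
  dko <- mkTags(runTags(5000, 5400), chromSizes = c(chrA = L))
  wt@normFactor <- 10; dko@normFactor <- 10
  calls <- callNascentTranscripts(wt, dko, minCoverage = 5,
                                  maxGap = 250, minLength = 200)
  expect_length(calls, 1)
  ## spans the run, within the smoothing tolerance
  expect_lt(abs(start(calls) - 1 - 5000), 150)
  expect_lt(abs(end(calls) - 5400), 150)
  ## counts: all 400 tags of each library, normalized
  expect_equal(mcols(calls)$wtCount, 4000)
  expect_equal(mcols(calls)$foldChange, 1)

  ## two runs separated by less than maxGap merge into one call
  two <- mkTags(c(runTags(5000, 5300), runTags(5450, 5750)),
                chromSizes = c(chrA = L))
  two@normFactor <- 10
  merged <- callNascentTranscripts(two, two, minCoverage = 5,
                                   maxGap = 250, minLength = 200)
  expect_length(merged, 1)
  ## and stay separate when the gap exceeds maxGap
  apart <- mkTags(c(runTags(3000, 3300), runTags(5000, 5300)),
                  chromSizes = c(chrA = L))
  apart@normFactor <- 10
  expect_length(callNascentTranscripts(apart, apart, minCoverage = 5,
                                       maxGap = 250, minLength = 200), 2)
})

test_that("segmentation equals the per-base brute-force reference on small instances", {
  set.seed(61)
  L <- 3000
  for (i in 1:4) {
    nW <- sample(50:150, 1); nD <- sample(50:150, 1)
    posW <- c(sample(0:(L - 1), nW, replace = TRUE),
              runTags(800, 1000), runTags(1900, 2100))
    posD <- c(sample(0:(L - 1), nD, replace = TRUE),
              runTags(820, 1050))
    nfW <- 25; nfD <- 30
    wt <- mkTags(posW, chromSizes = c(chrA = L), normFactor = nfW)
    dko <- mkTags(posD, chromSizes = c(chrA = L), normFactor = nfD)
    got <- callNascentTranscripts(wt, dko, minCoverage = 4,
                                  maxGap = 100, minLength = 120,
                                  smoothWindow = 50)
    oracle <- bruteSegment(posW, posD, L, nfW, nfD, minCoverage = 4,
                           maxGap = 100, minLength = 120,
                           smoothWindow = 50)
    expect_equal(start(got) - 1, oracle$start)
    expect_equal(end(got), oracle$end)
  }
})

test_that("gene-body exclusion is half-open, strand-blind and matches the pairwise oracle", {
  calls <- GRanges("chrA", IRanges(c(101, 501, 901), c(200, 600, 1000)))
  mcols(calls) <- DataFrame(id = c("a", "b", "c"), wtCount = 1,
                            dkoCount = 1, foldChange = 1)
  genes <- GRanges("chrA", IRanges(c(150, 601), c(170, 700)),
                   strand = c("+", "-"))
  kept <- excludeGenic(calls, genes)
  ## 'a' overlaps a gene; 'b' abuts one (half-open in BED terms) and stays
  expect_equal(mcols(kept)$id, c("b", "c"))
  expect_equal(metadata(kept)$genicExcluded, 1)
  expect_error(excludeGenic(calls, GRanges()), "empty")

  set.seed(62)
  dfC <- randomIntervals(300); dfG <- randomIntervals(40)
  calls <- GRanges(dfC$chrom, IRanges(dfC$start + 1, dfC$end))
  mcols(calls)$id <- paste0("c", seq_along(calls))
  genes <- GRanges(dfG$chrom, IRanges(dfG$start + 1, dfG$end))
  kept <- excludeGenic(calls, genes)
  oracle <- bruteSurvivors(dfC, dfG)
  expect_equal(length(kept), nrow(oracle))
})

test_that("the de-repression filter is boundary-inclusive with its pseudocount", {
  gr <- GRanges("chrA", IRanges(c(1, 101, 201), width = 50))
  mcols(gr) <- DataFrame(id = c("x", "y", "z"),
                         wtCount = c(10, 10, 0),
                         dkoCount = c(15, 14, 100),
                         foldChange = 1)
  kept <- filterDerepressed(gr, fold = 1.5, pseudocount = 0)
  expect_equal(mcols(kept)$id, c("x", "z"))       # 1.5 kept, 1.4 dropped
  expect_equal(mcols(kept)$foldChange[1], 1.5)
  ## closed form: fold 1+eps, pc 0 keeps exactly dko > wt... and
  ## fold exactly 1 is rejected by the precondition
  expect_error(filterDerepressed(gr, fold = 1), "> 1")
  keptAll <- filterDerepressed(gr, fold = 1 + 1e-12, pseudocount = 0)
  expect_equal(mcols(keptAll)$id,
               mcols(gr)$id[mcols(gr)$dkoCount / mcols(gr)$wtCount >=
                              1 + 1e-12])
})

test_that("PU.1 adjacency respects the distance window exactly", {
  calls <- GRanges("chrA", IRanges(1001, 1400))   # 0-based [1000, 1400)
  mcols(calls) <- DataFrame(id = "e1", wtCount = 1, dkoCount = 9,
                            foldChange = 9)
  inside <- mkPeaks("chrA", 1100, 1200, name = "in")
  expect_length(intersectPu1(calls, inside, 0), 1)
  ## extended interval is [500, 1900): a peak reaching its last base is
  ## adjacent, one starting at the (half-open) edge is not
  atEdge <- mkPeaks("chrA", 1899, 2000)
  expect_length(intersectPu1(calls, atEdge, 500), 1)
  beyond <- mkPeaks("chrA", 1900, 2000)
  expect_length(intersectPu1(calls, beyond, 500), 0)

  set.seed(63)
  dfC <- randomIntervals(200); dfP <- randomIntervals(100)
  calls <- GRanges(dfC$chrom, IRanges(dfC$start + 1, dfC$end))
  mcols(calls) <- DataFrame(id = paste0("c", seq_along(calls)),
                            wtCount = 1, dkoCount = 2, foldChange = 2)
  for (d in c(0, 120)) {
    got <- intersectPu1(calls, dfToPeaks(dfP), d)
    ext <- dfC; ext$start <- ext$start - d; ext$end <- ext$end + d
    expect_length(got, bruteOverlapCount(ext, dfP))
  }
})

test_that("the full cascade recovers planted de-repressed PU.1 enhancers on synthetic data", {
  cfg <- smallConfig()
  genome <- generateGenome(cfg)
  pu1 <- enhancerPeaks(genome, "pu1Bound", "PU.1")
  wt <- generateGroseq(genome, "WT", cfg)
  dko <- generateGroseq(genome, "DKO", cfg)
  cas <- ernaCascade(wt, dko, geneBodies(genome), pu1)

  ## monotone narrowing, every stage
  expect_true(all(diff(unname(cas$counts)) <= 0))

  truth <- enhancers(genome)
  want <- truth[mcols(truth)$ernaDerepressed & mcols(truth)$pu1Bound]
  expect_gte(mean(overlapsAny(want, cas$pu1Adjacent,
                              ignore.strand = TRUE)), 0.85)
  expect_lte(mean(!overlapsAny(cas$pu1Adjacent, want,
                               ignore.strand = TRUE)), 0.10)

  ## gene bodies never make it into the surviving set
  expect_false(any(overlapsAny(cas$pu1Adjacent, geneBodies(genome),
                               ignore.strand = TRUE)))

  ## H3K27ac around the surviving enhancers: knockout above WT at baseline
  h0 <- generateChipTags(genome, "H3K27ac", "WT", 0, cfg)
  k0 <- generateChipTags(genome, "H3K27ac", "KO", 0, cfg)
  prof <- compareH3k27acAtErnaEnhancers(cas$pu1Adjacent, pu1, h0, k0)
  expect_gt(centralDensity(prof$KO), centralDensity(prof$WT))
  ## identical libraries give identical profiles
  same <- compareH3k27acAtErnaEnhancers(cas$pu1Adjacent, pu1, h0, h0)
  expect_equal(profileDensity(same$WT), profileDensity(same$KO))
  ## consistency with a direct metaprofile over the matched anchors
  matched <- unique(unlist(strsplit(mcols(cas$pu1Adjacent)$pu1Ids, ",")))
  direct <- metaProfile(h0, macEnhancers:::subsetPeakSet(
    pu1, peakIds(pu1) %in% matched))
  expect_equal(profileDensity(prof$WT), profileDensity(direct))
  expect_error(compareH3k27acAtErnaEnhancers(cas$pu1Adjacent[0], pu1,
                                             h0, k0), "0 calls")
})

test_that("a null planting (erna fold 1) is recovered no better than the empirical null", {
  cfgNull <- smallConfig(seed = 77L, ernaFold = 1)
  genome <- generateGenome(cfgNull)
  pu1 <- enhancerPeaks(genome, "pu1Bound", "PU.1")
  cas <- ernaCascade(generateGroseq(genome, "WT", cfgNull),
                     generateGroseq(genome, "DKO", cfgNull),
                     geneBodies(genome), pu1)
  truth <- enhancers(genome)
  flagged <- mcols(truth)$ernaDerepressed
  hit <- overlapsAny(truth, cas$derepressed, ignore.strand = TRUE)
  ## planted "positives" pass the 1.5-fold filter at the same (low) rate
  ## as unflagged enhancers
  expect_lte(mean(hit[flagged]), mean(hit[!flagged]) + 0.05)
  expect_lte(mean(hit), 0.1)
})
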