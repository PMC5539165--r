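test_that("readBed parses dialects, preserves coordinates and rejects bad lines", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tpk1\t25\t+", tf)
  ps <- readBed(tf, "BED6")
  tab <- peakTable(ps)
  expect_equal(tab$start, 100)
  expect_equal(tab$end, 200)
  expect_equal(tab$score, 25)
  expect_equal(tab$id, "pk1")
  expect_equal(as.character(strand(peakRanges(ps))), "+")

  ## round trip through the peak dialect is lossless
  out <- withr::local_tempfile(fileext = ".bed")
  writeBed(ps, out)
  expect_equal(peakTable(readBed(out, "peak"))[1:5], tab[1:5])

  ## empty file -> empty set; BED3 gets default ids and zero scores
  writeLines(character(), tf)
  expect_length(readBed(tf), 0)
  writeLines(c("chr1\t0\t10", "chr2\t5\t6"), tf)
  ps3 <- readBed(tf, "BED3")
  expect_equal(peakScores(ps3), c(0, 0))
  expect_equal(as.character(strand(peakRanges(ps3))), c("*", "*"))

  ## malformed input names the offending line
  writeLines(c("chr1\t0\t10", "chr1\t200\t100"), tf)
  expect_error(readBed(tf), "line 2")
  writeLines(c("chr1\t0\t10", "chr1\tx\t100"), tf)
  expect_error(readBed(tf), "line 2")
  writeLines(c("chr1\t0\t10\ta\t1", "chr1\t0"), tf)
  expect_error(readBed(tf), "malformed")
})

test_that("PeakSet enforces unique ids, sorting and non-negative scores", {
  expect_error(PeakSet(GRanges("chr1", IRanges(c(1, 5), c(3, 9)),
                               id = c("a", "a"), score = c(1, 1))),
               "unique")
  expect_error(PeakSet(GRanges("chr1", IRanges(1, 3), id = "a",
                               score = -1)),
               "non-negative")
  ps <- mkPeaks("chr1", c(500, 10), c(600, 20))
  expect_equal(peakTable(ps)$start, c(10, 500))
})

test_that("filterByScore is boundary-inclusive and matches a linear scan", {
  ps <- mkPeaks("chr1", c(0, 100, 200), c(50, 150, 250),
                score = c(19.9, 20, 25))
  expect_length(filterByScore(ps, 20), 2)
  expect_length(filterByScore(ps, 0), 3)
  set.seed(101)
  df <- randomIntervals(1000)
  ps <- dfToPeaks(df)
  for (cut in c(5, 20, 47.3))
    expect_length(filterByScore(ps, cut), sum(df$score >= cut))
})

test_that("subtractOverlapping uses half-open >=1 bp overlap and matches the all-pairs oracle", {
  pk <- mkPeaks("chr1", 100, 200)
  expect_length(subtractOverlapping(pk, mkPeaks("chr1", 199, 300)), 0)
  expect_length(subtractOverlapping(pk, mkPeaks("chr1", 200, 300)), 1)
  set.seed(202)
  for (i in 1:5) {
    A <- randomIntervals(500)
    B <- randomIntervals(50)
    surv <- subtractOverlapping(dfToPeaks(A), dfToPeaks(B, "bl"))
    oracle <- bruteSurvivors(A, B)
    got <- peakTable(surv)
    expect_equal(nrow(got), nrow(oracle))
    expect_setequal(paste(got$chrom, got$start, got$end),
                    paste(oracle$chrom, oracle$start, oracle$end))
  }
})

test_that("poolPeakSets merges by overlap/gap, keeps max score and matches the sweep oracle", {
  a <- mkPeaks("chr1", 100, 200, score = 5, name = "a")
  b <- mkPeaks("chr1", 150, 250, score = 9, name = "b")
  pooled <- poolPeakSets(list(a, b))
  expect_equal(peakTable(pooled)[, c("start", "end", "score")],
               data.frame(start = 100, end = 250, score = 9))
  expect_match(mcols(peakRanges(pooled))$members, "a:.*,b:")

  ## disjoint sets stay separate; abutting half-open intervals do too
  expect_length(poolPeakSets(list(mkPeaks("chr1", 0, 10),
                                  mkPeaks("chr1", 100, 110))), 2)
  expect_length(poolPeakSets(list(mkPeaks("chr1", 0, 10),
                                  mkPeaks("chr1", 10, 20))), 2)

  set.seed(303)
  for (gap in c(0, 25)) {
    sets <- lapply(1:3, function(i) dfToPeaks(randomIntervals(150),
                                              paste0("s", i)))
    pooled <- peakTable(poolPeakSets(sets, mergeDistance = gap))
    oracle <- bruteSweep(do.call(rbind, lapply(sets, peakTable)), gap)
    expect_equal(pooled[, c("chrom", "start", "end")], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("pooling is idempotent after blacklist subtraction", {
  set.seed(404)
  sets <- lapply(1:2, function(i) dfToPeaks(randomIntervals(200),
                                            paste0("s", i)))
  bl <- dfToPeaks(randomIntervals(30), "bl")
  once <- poolPeakSets(list(subtractOverlapping(
    poolPeakSets(sets), bl)))
  twice <- poolPeakSets(list(once))
  expect_equal(peakTable(twice)[, c("chrom", "start", "end")],
               peakTable(once)[, c("chrom", "start", "end")])
})

test_that("vennCounts reproduces reference-anchored counts and inclusion-exclusion", {
  ## disjoint case
  A <- mkPeaks("chr1", c(0, 1000), c(100, 1100), name = "A")
  B <- mkPeaks("chr1", 5000, 5100, name = "B")
  v <- vennCounts(A, B, B)
  expect_equal(c(v@nAB, v@nAC, v@nABC, v@nAUnionBC), c(0L, 0L, 0L, 0L))

  ## random instances against the exhaustive classification oracle
  set.seed(505)
  for (i in 1:5) {
    dA <- randomIntervals(200); dB <- randomIntervals(200)
    dC <- randomIntervals(200)
    v <- vennCounts(dfToPeaks(dA, "A"), dfToPeaks(dB, "B"),
                    dfToPeaks(dC, "C"))
    inB <- vapply(seq_len(nrow(dA)), function(j)
      ovAny0(dA$chrom[j], dA$start[j], dA$end[j], dB), logical(1))
    inC <- vapply(seq_len(nrow(dA)), function(j)
      ovAny0(dA$chrom[j], dA$start[j], dA$end[j], dC), logical(1))
    expect_equal(v@nAB, sum(inB))
    expect_equal(v@nAC, sum(inC))
    expect_equal(v@nABC, sum(inB & inC))
    expect_equal(v@nBC, bruteOverlapCount(dB, dC))
    expect_equal(v@nAUnionBC, sum(inB | inC))
    expect_equal(v@nAUnionBC, v@nAB + v@nAC - v@nABC)
  }
})

test_that("a reference peak overlapping several partner peaks counts once", {
  A <- mkPeaks("chr1", 100, 500, name = "A")
  B <- mkPeaks("chr1", c(120, 300), c(180, 400), name = "B")
  v <- vennCounts(A, B, B)
  expect_equal(v@nAB, 1L)
})

test_that("overlapPercentage rounds to reporting precision and guards the ratio", {
  expect_equal(overlapPercentage(1040, 2026), 51)
  expect_equal(overlapPercentage(729, 2026), 36)
  expect_equal(overlapPercentage(611, 2026), 30)
  expect_equal(overlapPercentage(0, 100), 0)
  expect_equal(overlapPercentage(1, 18, digits = 1), 5.6)
  expect_error(overlapPercentage(1, 0), "undefined")
  expect_error(overlapPercentage(5, 4))
})

test_that("sharedFraction is the reference-anchored percentage at one decimal", {
  A <- dfToPeaks(randomIntervals(400), "A")
  expect_equal(sharedFraction(A, A), 100.0)
  far <- mkPeaks("chrZ", 0, 10, name = "far")
  expect_equal(sharedFraction(A, far), 0.0)
  set.seed(606)
  dA <- randomIntervals(400); dB <- randomIntervals(300)
  expect_equal(sharedFraction(dfToPeaks(dA, "A"), dfToPeaks(dB, "B")),
               round(100 * bruteOverlapCount(dA, dB) / 400, 1))
  expect_error(sharedFraction(mkPeaks("chr1", integer(), integer()), A),
               "empty")
})

test_that("half-open semantics hold across random coordinate pairs", {
  set.seed(707)
  for (i in 1:50) {
    a <- sort(sample(1e6, 2)); b <- a[2] + sample(0:50, 1)
    touching <- mkPeaks("chr1", a[2], b + 1)      # starts at a's end
    inside <- mkPeaks("chr1", a[2] - 1, b + 1)    # one shared base
    peak <- mkPeaks("chr1", a[1], a[2])
    expect_length(subtractOverlapping(peak, touching), 1)
    expect_length(subtractOverlapping(peak, inside), 0)
  }
})
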