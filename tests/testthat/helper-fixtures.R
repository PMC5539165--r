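## Fixture builders and independent brute-force oracles.  Oracles work on
## plain 0-based half-open interval tables and never touch GenomicRanges,
## so they check the implementation from the outside.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## PeakSet from 0-based half-open coordinates
mkPeaks <- function(chrom, start0, end0, score = 0, id = NULL,
                    name = "test") {
  n <- length(start0)
  if (!n) return(PeakSet(GRanges(), name = name))
  gr <- GRanges(rep_len(chrom, n), IRanges(start0 + 1, end0),
                id = id %||% paste0(name, "_", seq_len(n)),
                score = rep_len(score, n))
  PeakSet(gr, name = name)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## 0-based half-open interval table of a PeakSet, in input order by id
peakTable <- function(ps) {
  gr <- peakRanges(ps)
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1,
             end = end(gr), id = peakIds(ps), score = peakScores(ps),
             stringsAsFactors = FALSE)
}

randomIntervals <- function(n, chroms = c("chrA", "chrB"),
                            span = 10000, maxLen = 120) {
  start <- floor(runif(n, 0, span - maxLen))
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + ceiling(runif(n, 1, maxLen)),
             score = round(runif(n, 0, 50), 2),
             stringsAsFactors = FALSE)
}

dfToPeaks <- function(df, name = "rand")
  mkPeaks(df$chrom, df$start, df$end, df$score, name = name)

## oracle: does 0-based half-open interval a overlap any row of df?
ovAny0 <- function(chrom, start, end, df) {
  any(df$chrom == chrom & df$start < end & start < df$end)
}

## oracle: count of rows of A overlapping >= 1 row of B (all pairs scan)
bruteOverlapCount <- function(A, B) {
  sum(vapply(seq_len(nrow(A)), function(i)
    ovAny0(A$chrom[i], A$start[i], A$end[i], B), logical(1)))
}

## oracle: rows of A surviving subtraction of B
bruteSurvivors <- function(A, B) {
  keep <- !vapply(seq_len(nrow(A)), function(i)
    ovAny0(A$chrom[i], A$start[i], A$end[i], B), logical(1))
  A[keep, , drop = FALSE]
}

## oracle: sweep-line merge of 0-based half-open intervals; gap <
## mergeDist (or overlap) merges
bruteSweep <- function(df, mergeDist = 0) {
  out <- list()
  for (cn in sort(unique(df$chrom))) {
    d <- df[df$chrom == cn, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cs <- d$start[1]; ce <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] - ce < mergeDist || d$start[i] < ce) {
        ce <- max(ce, d$end[i])
      } else {
        out[[length(out) + 1]] <- data.frame(chrom = cn, start = cs,
                                             end = ce)
        cs <- d$start[i]; ce <- d$end[i]
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = cn, start = cs, end = ce)
  }
  d <- do.call(rbind, out)
  d[order(d$chrom, d$start), , drop = FALSE]
}

## oracle: tags (0-based positions) in [center-hw, center+hw)
bruteWindowCount <- function(pos, center, hw)
  sum(pos >= center - hw & pos < center + hw)

## tag library on one chromosome from 0-based positions
mkTags <- function(pos, chrom = "chrA", strand = "*", name = "lib",
                   normFactor = 1, chromSizes = NULL) {
  TagLibrary(pos, chrom, strand = strand, name = name,
             normFactor = normFactor, chromSizes = chromSizes)
}

## oracle: per-base threshold segmentation of pooled smoothed coverage on
## a single chromosome of length L (0-based bases 0..L-1).  Mirrors the
## definition: per-base smoothed coverage = (count of tags within the
## centered window) * normFactor / smoothWindow, conditions averaged.
bruteSegment <- function(posW, posD, L, nfW, nfD, minCoverage, maxGap,
                         minLength, smoothWindow) {
  half <- smoothWindow %/% 2
  left <- half
  right <- smoothWindow - half - 1
  covAt <- function(pos, b, nf)
    sum(pos >= b - right & pos <= b + left) * nf / smoothWindow
  pooled <- vapply(0:(L - 1), function(b)
    (covAt(posW, b, nfW) + covAt(posD, b, nfD)) / 2, numeric(1))
  above <- pooled >= minCoverage
  ## maximal runs
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values] - 1, end = ends[r$values])
  if (!nrow(runs)) return(runs)
  ## merge gaps < maxGap, then drop short runs
  m <- bruteSweep(cbind(chrom = "c", runs), mergeDist = maxGap)
  m <- m[m$end - m$start >= minLength, c("start", "end"), drop = FALSE]
  rownames(m) <- NULL
  m
}

## dense tag run covering 0-based [from, to), perBase tags at every base
runTags <- function(from, to, perBase = 1)
  rep(seq(from, to - 1), each = perBase)

## quick synthetic fixture shared by several files (small, fast)
smallConfig <- function(seed = 42L, nGenes = 120L, nEnhancers = 60L, ...)
  simulationConfig(seed = seed, chromSizes = c(chr1 = 4e5, chr2 = 4e5),
                   nGenes = nGenes, nEnhancers = nEnhancers, ...)
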