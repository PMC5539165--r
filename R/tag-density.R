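#' @include simulate.R
NULL

#' Normalized tag count in windows around centers
#'
#' Counts tags whose 0-based 5' position lies in
#' `[center - halfwidth, center + halfwidth)` (half-open on the right, so a
#' tag exactly `halfwidth` bp downstream is excluded) and multiplies by the
#' library's normalization factor.  Strand-blind.  Vectorized over centers;
#' windows on chromosomes unknown to the library count 0 with a warning.
#'
#' @param library a [TagLibrary-class].
#' @param chrom chromosome of each window center.
#' @param center 0-based center position(s).
#' @param halfwidth window half-width (bp, > 0).
#' @return numeric vector of normalized counts.
#' @export
countTagsInWindow <- function(library, chrom, center, halfwidth) {
  stopifnot(is(library, "TagLibrary"), halfwidth > 0)
  if (!tagTotal(library)) return(numeric(length(center)))
  chrom <- rep_len(as.character(chrom), length(center))
  known <- chrom %in% seqlevels(tagRanges(library))
  if (!all(known))
    warning("window(s) on chromosome(s) absent from the library: ",
            paste(unique(chrom[!known]), collapse = ", "))
  out <- numeric(length(center))
  if (any(known)) {
    win <- GRanges(chrom[known],
                   IRanges(center[known] - halfwidth + 1L,
                           center[known] + halfwidth))
    out[known] <- countOverlaps(win, tagRanges(library),
                                ignore.strand = TRUE) *
      normFactor(library)
  }
  out
}

## Per-site binned window counts: rows = peaks, cols = bins; values are
## normFactor-scaled tag counts.  The workhorse behind metaProfile() and
## densityMatrix().
.binnedCounts <- function(library, peaks, halfwidth, binsize) {
  if (!length(peaks)) stop("empty peak set")
  if ((2 * halfwidth) %% binsize != 0)
    stop("binsize must divide 2*halfwidth")
  nbin <- as.integer(2 * halfwidth / binsize)
  centers <- peakCenters(peaks)
  gr <- peakRanges(peaks)
  tags <- tagRanges(library)
  sl <- seqlengths(tags)
  if (length(sl) && !all(is.na(sl))) {
    low <- centers - halfwidth < 0
    high <- !is.na(sl[as.character(seqnames(gr))]) &
      centers + halfwidth > sl[as.character(seqnames(gr))]
    if (any(low | high, na.rm = TRUE))
      message(sum(low | high, na.rm = TRUE),
              " window(s) extend beyond chromosome ends; ",
              "missing bins count zero")
  }
  win <- GRanges(seqnames(gr),
                 IRanges(centers - halfwidth + 1L, centers + halfwidth))
  hits <- findOverlaps(win, tags, ignore.strand = TRUE)
  mat <- matrix(0, length(peaks), nbin,
                dimnames = list(peakIds(peaks),
                                seq(-halfwidth, halfwidth - binsize,
                                    by = binsize)))
  if (length(hits)) {
    offset <- start(tags)[subjectHits(hits)] - 1L -
      centers[queryHits(hits)]                      # in [-hw, hw-1]
    bin <- (offset + halfwidth) %/% binsize + 1L
    tab <- table(factor(queryHits(hits), levels = seq_along(peaks)),
                 factor(bin, levels = seq_len(nbin)))
    mat <- mat + as.matrix(tab) * 1
    dimnames(mat) <- list(peakIds(peaks),
                          seq(-halfwidth, halfwidth - binsize, by = binsize))
  }
  mat * normFactor(library)
}

#' Average tag-density metaprofile around peak centers
#'
#' Bins every tag by its offset from each peak center and averages the
#' depth-normalized per-bin counts over all peaks — the "average read
#' density in the vicinity of binding sites" display.  Units are
#' normalized tags per bin per site; offsets label the left edge of each
#' bin.  Windows running past a chromosome end simply contribute zero
#' counts in the missing bins (reported as a message).
#'
#' @param library a [TagLibrary-class].
#' @param peaks a non-empty [PeakSet-class] of anchors.
#' @param halfwidth window half-width (bp); default 2 kb.
#' @param binsize bin width (bp); must divide `2*halfwidth`.
#' @return a [MetaProfile-class].
#' @export
metaProfile <- function(library, peaks, halfwidth = 2000, binsize = 100) {
  mat <- .binnedCounts(library, peaks, halfwidth, binsize)
  new("MetaProfile", reference = setName(peaks), library = library@name,
      halfwidth = as.numeric(halfwidth), binsize = as.numeric(binsize),
      offsets = seq(-halfwidth, halfwidth - binsize, by = binsize),
      density = colMeans(mat), nSites = length(peaks))
}

#' @rdname MetaProfile-accessors
#' @name MetaProfile-accessors
#' @param x a `MetaProfile`.
#' @aliases profileOffsets profileDensity
#' @export
setMethod("profileOffsets", "MetaProfile", function(x) x@offsets)

#' @rdname MetaProfile-accessors
#' @export
setMethod("profileDensity", "MetaProfile", function(x) x@density)

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile of '", object@library, "' around ", object@nSites,
      " '", object@reference, "' sites: +/-", object@halfwidth, " bp in ",
      length(object@offsets), " bins of ", object@binsize, " bp\n",
      sep = "")
})

#' Density of the central bins of a metaprofile
#'
#' Mean density over the innermost `2*n` bins — a convenient scalar for
#' comparing conditions at the anchor point itself.
#'
#' @param x a `MetaProfile`.
#' @param n bins on each side of the center to average (default 2).
#' @return mean central density.
#' @export
centralDensity <- function(x, n = 2L) {
  nbin <- length(x@offsets)
  mid <- nbin / 2
  mean(x@density[(mid - n + 1L):(mid + n)])
}

#' Per-site density matrix across libraries
#'
#' One row per anchor peak and one column block per library, each block
#' holding the binned normalized tag counts of that peak's window — the
#' matrix behind tag-density heatmaps.  Column means equal the
#' corresponding [metaProfile()] densities by construction.
#'
#' @param libraries named list of [TagLibrary-class] objects.
#' @param peaks a non-empty [PeakSet-class].
#' @param halfwidth,binsize window geometry; defaults 2 kb and 25 bp (the
#'   finer heatmap binning).
#' @return a [DensityMatrix-class] (unclustered; see [kmeansRows()]).
#' @export
densityMatrix <- function(libraries, peaks, halfwidth = 2000,
                          binsize = 25) {
  stopifnot(length(libraries) >= 1L)
  if (is.null(names(libraries)))
    names(libraries) <- vapply(libraries, function(l) l@name, "")
  blocks <- lapply(libraries, .binnedCounts, peaks = peaks,
                   halfwidth = halfwidth, binsize = binsize)
  values <- do.call(cbind, blocks)
  offsets <- seq(-halfwidth, halfwidth - binsize, by = binsize)
  colnames(values) <- paste(rep(names(libraries), each = length(offsets)),
                            rep(offsets, length(libraries)), sep = ":")
  new("DensityMatrix", values = values, libraries = names(libraries),
      offsets = offsets, halfwidth = as.numeric(halfwidth),
      binsize = as.numeric(binsize),
      rowClusters = rep(NA_integer_, nrow(values)),
      rowOrder = seq_len(nrow(values)))
}

#' @rdname DensityMatrix-accessors
#' @name DensityMatrix-accessors
#' @param x a `DensityMatrix`.
#' @aliases densityValues rowClusters
#' @export
setMethod("densityValues", "DensityMatrix", function(x) x@values)

#' @rdname DensityMatrix-accessors
#' @export
setMethod("rowClusters", "DensityMatrix", function(x) x@rowClusters)

setMethod("show", "DensityMatrix", function(object) {
  cat("DensityMatrix: ", nrow(object@values), " sites x ",
      length(object@offsets), " bins x ", length(object@libraries),
      " libraries (", paste(object@libraries, collapse = ", "), ")",
      if (!anyNA(object@rowClusters))
        paste0("; ", length(unique(object@rowClusters)), " row clusters"),
      "\n", sep = "")
})

#' Top-scoring peaks
#'
#' The `n` highest-score peaks of a set (e.g. the top 500 binding sites at
#' baseline); ties are broken by genomic order, which is reported when it
#' decides the cut.  Asking for more peaks than exist returns the whole
#' set with a warning.
#'
#' @param peaks a [PeakSet-class].
#' @param n number of peaks to keep (>= 1).
#' @return the selected `PeakSet` (sorted genomically, like any PeakSet).
#' @export
topNByScore <- function(peaks, n = 500L) {
  stopifnot(n >= 1L)
  if (length(peaks) <= n) {
    if (length(peaks) < n)
      warning("requested ", n, " peaks but the set has only ",
              length(peaks), "; returning all")
    return(subsetPeakSet(peaks, seq_len(length(peaks)),
                         note = paste0("top ", n, " by score")))
  }
  sc <- peakScores(peaks)
  o <- order(-sc, as.character(seqnames(peakRanges(peaks))),
             start(peakRanges(peaks)))
  cut <- sc[o][n]
  if (sum(sc == cut) > 1L && sc[o][n + 1L] == cut)
    message("score tie at the cutoff (", cut,
            ") broken by genomic order")
  subsetPeakSet(peaks, sort(o[seq_len(n)]),
                note = paste0("top ", n, " by score"))
}

#' K-means clustering of density-matrix rows
#'
#' Groups the per-site density rows into `k` clusters with standard
#' K-means (best of `restarts` seeded starts by within-cluster sum of
#' squares) and orders rows for display: cluster blocks sorted by
#' decreasing mean central intensity, rows within a block likewise.
#' Deterministic given `seed`.
#'
#' @param x a [DensityMatrix-class].
#' @param k number of clusters (>= 2, fewer than rows).
#' @param seed RNG seed.
#' @param restarts independent K-means starts.
#' @return `x` with `rowClusters` and `rowOrder` filled.
#' @export
kmeansRows <- function(x, k = 5L, seed = 1L, restarts = 10L) {
  v <- x@values
  stopifnot(k >= 2L, nrow(v) >= k)
  km <- withSeed(seed,
                 kmeans(v, centers = k, nstart = restarts, iter.max = 100L))
  ## central intensity: innermost two bins of each library block
  nbin <- length(x@offsets)
  mid <- c(nbin / 2, nbin / 2 + 1L)
  centralCols <- as.vector(outer(mid, (seq_along(x@libraries) - 1L) * nbin,
                                 `+`))
  central <- rowMeans(v[, centralCols, drop = FALSE])
  clMean <- tapply(central, km$cluster, mean)
  clRank <- rank(-clMean, ties.method = "first")[as.character(km$cluster)]
  x@rowClusters <- as.integer(km$cluster)
  x@rowOrder <- order(clRank, -central)
  validObject(x)
  x
}
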