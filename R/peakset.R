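#' @include AllGenerics.R
NULL

#' Construct a PeakSet
#'
#' Builds a [PeakSet-class] from a `GRanges`, filling in missing `id`
#' (`"<name>_peak_<i>"`) and `score` (0) columns and sorting by
#' (chromosome, start).  Strand is preserved but ignored by every overlap
#' operation: TF and histone peaks are unstranded.
#'
#' @param ranges a `GRanges`; optional metadata columns `id` and `score`.
#' @param name label for the cistrome.
#' @param provenance character vector of free-text provenance records.
#' @return a `PeakSet`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(150, 11), width = 50))
#' PeakSet(gr, name = "demo")
#' @export
PeakSet <- function(ranges, name = "peaks", provenance = character()) {
  if (!is(ranges, "GRanges"))
    stop("'ranges' must be a GRanges")
  if (is.null(mcols(ranges)$id))
    mcols(ranges)$id <- if (length(ranges))
      paste0(name, "_peak_", seq_along(ranges)) else character()
  mcols(ranges)$id <- as.character(mcols(ranges)$id)
  if (is.null(mcols(ranges)$score))
    mcols(ranges)$score <- numeric(length(ranges))
  mcols(ranges)$score <- as.numeric(mcols(ranges)$score)
  o <- order(as.character(seqnames(ranges)), start(ranges))
  new("PeakSet", name = name, ranges = ranges[o],
      provenance = as.character(provenance))
}

#' PeakSet accessors
#'
#' @param x a `PeakSet`.
#' @name PeakSet-accessors
#' @aliases peakRanges peakIds peakScores setName provenance
NULL

#' @rdname PeakSet-accessors
#' @export
setMethod("peakRanges", "PeakSet", function(x) x@ranges)

#' @rdname PeakSet-accessors
#' @export
setMethod("peakIds", "PeakSet", function(x) mcols(x@ranges)$id)

#' @rdname PeakSet-accessors
#' @export
setMethod("peakScores", "PeakSet", function(x) mcols(x@ranges)$score)

#' @rdname PeakSet-accessors
#' @export
setMethod("setName", "PeakSet", function(x) x@name)

#' @rdname PeakSet-accessors
#' @export
setMethod("provenance", "PeakSet", function(x) x@provenance)

#' @export
setMethod("length", "PeakSet", function(x) length(x@ranges))

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet '", object@name, "': ", length(object), " peaks on ",
      length(unique(as.character(seqnames(object@ranges)))),
      " chromosome(s)\n", sep = "")
  if (length(object@provenance))
    cat("  provenance: ", paste(object@provenance, collapse = "; "),
        "\n", sep = "")
})

## subset while preserving class and provenance
subsetPeakSet <- function(x, i, note = NULL) {
  prov <- x@provenance
  if (!is.null(note)) prov <- c(prov, note)
  new("PeakSet", name = x@name, ranges = x@ranges[i], provenance = prov)
}

#' Peak centers
#'
#' Midpoints of the peak intervals in 0-based coordinates,
#' `floor((start0 + end0) / 2)`; even-length intervals take the floor
#' midpoint.  All window anchoring in the package uses these centers.
#'
#' @param x a `PeakSet` or `GRanges`.
#' @return integer vector of 0-based center positions.
#' @export
peakCenters <- function(x) {
  gr <- if (is(x, "PeakSet")) peakRanges(x) else x
  as.integer(floor((start(gr) - 1 + end(gr)) / 2))
}

#' Read a BED-like peak file
#'
#' Parses tab-separated, headerless BED dialects into a [PeakSet-class]:
#' BED3 (`chrom start end`), BED6 (`chrom start end name score strand`) and
#' a 5-column peak dialect (`chrom start end id score`) as emitted by peak
#' callers.  Coordinates are 0-based half-open on disk and converted to the
#' 1-based closed convention in memory, preserving the half-open overlap
#' semantics.  Missing strand becomes `*`, missing score becomes 0.
#'
#' @param path file path.
#' @param dialect `"auto"` (by column count), `"BED3"`, `"BED6"` or
#'   `"peak"`.
#' @param name label for the resulting set; defaults to the file name.
#' @return a `PeakSet` (empty for an empty file).
#' @export
readBed <- function(path, dialect = c("auto", "BED3", "BED6", "peak"),
                    name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(PeakSet(GRanges(), name = name, provenance = paste0("read ", path)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- switch(dialect, BED3 = 3L, BED6 = 6L, peak = 5L,
                 auto = nf[1L])
  bad <- which(nf < min(want, 3L) | nf != nf[1L])
  if (length(bad))
    stop("malformed BED line ", bad[1L], " in ", path,
         " (expected ", nf[1L], " fields, found ", nf[bad[1L]], ")")
  if (dialect == "auto")
    dialect <- if (want >= 6L) "BED6" else if (want == 5L) "peak" else "BED3"
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.numeric(m[, 2L]))
  end0 <- suppressWarnings(as.numeric(m[, 3L]))
  badc <- which(!is.finite(start0) | !is.finite(end0))
  if (length(badc))
    stop("non-numeric coordinates at line ", badc[1L], " in ", path)
  badv <- which(start0 < 0 | start0 >= end0)
  if (length(badv))
    stop("invalid interval (need 0 <= start < end) at line ", badv[1L],
         " in ", path)
  ids <- if (dialect %in% c("BED6", "peak")) m[, 4L] else
    paste0(name, "_peak_", seq_len(nrow(m)))
  scores <- if (dialect %in% c("BED6", "peak"))
    suppressWarnings(as.numeric(m[, 5L])) else numeric(nrow(m))
  scores[!is.finite(scores)] <- 0
  strand <- if (dialect == "BED6" && ncol(m) >= 6L) m[, 6L] else
    rep("*", nrow(m))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(m[, 1L], IRanges(start0 + 1, end0), strand = strand,
                id = ids, score = scores)
  PeakSet(gr, name = name,
          provenance = paste0("read ", path, " as ", dialect))
}

#' Write a PeakSet as a BED file
#'
#' Emits the 5-column peak dialect (`chrom start end id score`), or BED6
#' with strand, using 0-based half-open coordinates.
#'
#' @param x a `PeakSet`.
#' @param path output file path.
#' @param dialect `"peak"` or `"BED6"`.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path, dialect = c("peak", "BED6")) {
  dialect <- match.arg(dialect)
  gr <- peakRanges(x)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   id = peakIds(x), score = peakScores(x))
  if (dialect == "BED6") df$strand <- as.character(strand(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep high-confidence peaks by score
#'
#' Retains peaks whose score is at least `minScore` (boundary inclusive, as
#' in the conventional "score >= 20" high-confidence cut for HOMER peaks);
#' order is preserved and the filter is recorded in provenance.
#'
#' @param x a `PeakSet`.
#' @param minScore non-negative threshold.
#' @return the filtered `PeakSet`.
#' @export
filterByScore <- function(x, minScore = 20) {
  stopifnot(is(x, "PeakSet"), minScore >= 0)
  subsetPeakSet(x, peakScores(x) >= minScore,
                note = paste0("score filter >= ", minScore))
}

#' Remove peaks overlapping an exclusion set
#'
#' Drops every peak sharing at least one base with any exclusion interval
#' (blacklist or simple-repeat regions); surviving peaks are untouched.
#' Overlap is strand-blind and half-open: an abutting exclusion interval
#' does not remove a peak.
#'
#' @param x a `PeakSet`.
#' @param exclusion a `PeakSet` or `GRanges` of regions to subtract.
#' @return the surviving `PeakSet`.
#' @export
subtractOverlapping <- function(x, exclusion) {
  stopifnot(is(x, "PeakSet"))
  excl <- if (is(exclusion, "PeakSet")) peakRanges(exclusion) else exclusion
  hit <- .ovAny(peakRanges(x), excl)
  subsetPeakSet(x, !hit,
                note = paste0("removed ", sum(hit),
                              " peaks overlapping exclusion set"))
}

#' Pool peak sets across conditions
#'
#' Unions several cistromes (e.g. Bmal1 peaks from the 0, 4 and 24 h KLA
#' conditions) into one: intervals that overlap, or lie within
#' `mergeDistance` bp of one another, are merged into a single interval
#' spanning them, scored with the maximum constituent score.  With the
#' default `mergeDistance = 0` only genuinely overlapping intervals merge,
#' so abutting half-open intervals stay separate.  Constituent peak ids are
#' recorded in an `members` metadata column and in provenance.
#'
#' @param sets list of `PeakSet` objects (at least one).
#' @param mergeDistance maximum gap (bp) still merged.
#' @param name label for the pooled set.
#' @return the pooled `PeakSet`.
#' @export
poolPeakSets <- function(sets, mergeDistance = 0, name = "pooled") {
  stopifnot(length(sets) >= 1L, all(vapply(sets, is, TRUE, "PeakSet")))
  grl <- lapply(sets, function(s) {
    gr <- peakRanges(s)
    mcols(gr) <- DataFrame(id = paste0(setName(s), ":", peakIds(s)),
                           score = peakScores(s))
    strand(gr) <- "*"
    gr
  })
  all <- sort(do.call(c, unname(grl)))
  if (!length(all))
    return(PeakSet(GRanges(), name = name, provenance = "pooled 0 peaks"))
  merged <- reduce(all, min.gapwidth = mergeDistance, with.revmap = TRUE)
  rev <- mcols(merged)$revmap
  score <- vapply(rev, function(i) max(mcols(all)$score[i]), numeric(1))
  members <- vapply(rev, function(i)
    paste(mcols(all)$id[i], collapse = ","), character(1))
  mcols(merged) <- DataFrame(id = paste0(name, "_", seq_along(merged)),
                             score = score, members = members)
  PeakSet(merged, name = name,
          provenance = paste0("pooled ", length(sets), " sets (",
                              length(all), " peaks) into ", length(merged),
                              " merged peaks, mergeDistance=", mergeDistance))
}

#' Three-way reference-anchored overlap counts
#'
#' Classifies every peak of the reference set `A` by whether it overlaps
#' (>= 1 bp, strand-blind) at least one peak of `B` and/or `C` — the
#' counting used for TF co-occupancy Venn diagrams, where e.g. more than
#' half of the Bmal1 cistrome overlaps PU.1 and/or p65.  A reference peak
#' overlapping several partner peaks counts once.  The union count obeys
#' inclusion-exclusion: `nAUnionBC = nAB + nAC - nABC`.
#'
#' @param A reference `PeakSet` (the anchored cistrome).
#' @param B,C partner `PeakSet`s.
#' @return a [VennSummary-class].
#' @export
vennCounts <- function(A, B, C) {
  stopifnot(is(A, "PeakSet"), is(B, "PeakSet"), is(C, "PeakSet"))
  inB <- .ovAny(peakRanges(A), peakRanges(B))
  inC <- .ovAny(peakRanges(A), peakRanges(C))
  bInC <- .ovAny(peakRanges(B), peakRanges(C))
  vennSummary(nA = length(A), nB = length(B), nC = length(C),
              nAB = sum(inB), nAC = sum(inC), nBC = sum(bInC),
              nABC = sum(inB & inC),
              setNames = c(setName(A), setName(B), setName(C)))
}

#' Assemble a VennSummary from counts
#'
#' Useful when only the subset counts are known (e.g. counts read off a
#' published Venn diagram); the A-anchored union count is derived by
#' inclusion-exclusion.
#'
#' @param nA,nB,nC set sizes.
#' @param nAB,nAC A peaks overlapping B, resp. C.
#' @param nBC B peaks overlapping C.
#' @param nABC A peaks overlapping both B and C.
#' @param setNames labels for sets A, B, C.
#' @return a [VennSummary-class].
#' @examples
#' ## Bmal1 anchored on its 2,026 peaks: 1,040 share PU.1, 729 share p65,
#' ## 611 share both -> 1,158 peaks in the union
#' vennSummary(2026, 32000, 9000, nAB = 1040, nAC = 729, nBC = 0, nABC = 611)
#' @export
vennSummary <- function(nA, nB, nC, nAB, nAC, nBC, nABC,
                        setNames = c("A", "B", "C")) {
  new("VennSummary", setNames = as.character(setNames),
      nA = as.integer(nA), nB = as.integer(nB), nC = as.integer(nC),
      nAB = as.integer(nAB), nAC = as.integer(nAC), nBC = as.integer(nBC),
      nABC = as.integer(nABC),
      nAUnionBC = as.integer(nAB) + as.integer(nAC) - as.integer(nABC))
}

setMethod("show", "VennSummary", function(object) {
  sn <- object@setNames
  cat("VennSummary (anchored on ", sn[1L], ")\n", sep = "")
  cat(sprintf("  |%s|=%d  |%s|=%d  |%s|=%d\n", sn[1L], object@nA,
              sn[2L], object@nB, sn[3L], object@nC))
  cat(sprintf("  %s peaks overlapping %s: %d; %s: %d; both: %d; union: %d\n",
              sn[1L], sn[2L], object@nAB, sn[3L], object@nAC,
              object@nABC, object@nAUnionBC))
})

#' Convert a VennSummary to a plain list
#'
#' Keys match the slot names, ready for JSON serialization.
#'
#' @param x a `VennSummary`.
#' @param ... ignored.
#' @return named list of counts.
#' @export
as.list.VennSummary <- function(x, ...) {
  list(setNames = x@setNames, n_A = x@nA, n_B = x@nB, n_C = x@nC,
       n_AB = x@nAB, n_AC = x@nAC, n_BC = x@nBC, n_ABC = x@nABC,
       n_A_union_BC = x@nAUnionBC)
}

#' Overlap percentage at reporting precision
#'
#' `100 * nSubset / nTotal`, rounded to the reporting precision (nearest
#' integer by default, one decimal on request) — the form in which cistrome
#' co-occupancy is usually quoted (e.g. 1,040 of 2,026 peaks -> 51\%).
#'
#' @param nSubset,nTotal counts with `0 <= nSubset <= nTotal`, `nTotal > 0`.
#' @param digits decimal places to keep.
#' @return the rounded percentage.
#' @export
overlapPercentage <- function(nSubset, nTotal, digits = 0) {
  if (any(nTotal <= 0)) stop("undefined ratio: nTotal must be > 0")
  if (any(nSubset < 0) || any(nSubset > nTotal))
    stop("need 0 <= nSubset <= nTotal")
  round(100 * nSubset / nTotal, digits)
}

#' Fraction of a reference cistrome shared with another
#'
#' Percentage of `A` peaks overlapping at least one `B` peak, at one
#' decimal — the statistic behind cross-tissue comparisons such as the
#' small macrophage/liver sharing of Bmal1 binding sites.
#'
#' @param A reference `PeakSet` (denominator).
#' @param B comparison `PeakSet`.
#' @return percentage of `A` shared with `B`, one decimal.
#' @export
sharedFraction <- function(A, B) {
  stopifnot(is(A, "PeakSet"), is(B, "PeakSet"))
  if (!length(A)) stop("undefined ratio: reference set is empty")
  hits <- sum(.ovAny(peakRanges(A), peakRanges(B)))
  overlapPercentage(hits, length(A), digits = 1)
}
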