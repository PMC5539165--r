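#' @include tag-density.R
NULL

#' Call KLA-activated enhancers by H3K27ac fold change
#'
#' For every PU.1 peak, quantifies depth-normalized H3K27ac in a window
#' around the peak center at steady state and after stimulation, and calls
#' the enhancer activated when
#' `(treated + pseudocount) / (baseline + pseudocount) >= fold`
#' (boundary inclusive, the conventional ">= 2-fold over steady state at
#' 4 h" cut).  The activation set is defined once, on the libraries given
#' here, and is meant to be profiled afterwards in both genotypes.
#'
#' @param pu1 non-empty [PeakSet-class] of PU.1 binding sites.
#' @param baseline,treated [TagLibrary-class] of H3K27ac at steady state
#'   and after stimulation.
#' @param halfwidth quantification half-window (bp); the 500 bp default is
#'   narrower than display windows, capturing the acetylation flanking the
#'   nucleosome-depleted site itself.
#' @param fold activation threshold (> 1).
#' @param pseudocount added to both normalized counts (stabilizes
#'   low-count folds).
#' @return `GRanges` of all PU.1 peaks with metadata columns `id`,
#'   `baseline`, `treated`, `foldChange`, `activated`; call parameters in
#'   `metadata()`.
#' @export
callActivatedEnhancers <- function(pu1, baseline, treated,
                                   halfwidth = 500, fold = 2,
                                   pseudocount = 1) {
  stopifnot(is(pu1, "PeakSet"))
  if (!length(pu1)) stop("empty PU.1 peak set")
  if (fold <= 1) stop("activation fold must be > 1")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  gr <- granges(peakRanges(pu1))
  centers <- peakCenters(pu1)
  chrom <- as.character(seqnames(gr))
  b <- countTagsInWindow(baseline, chrom, centers, halfwidth)
  t <- countTagsInWindow(treated, chrom, centers, halfwidth)
  fc <- (t + pseudocount) / (b + pseudocount)
  mcols(gr) <- DataFrame(id = peakIds(pu1), baseline = b, treated = t,
                         foldChange = fc, activated = fc >= fold)
  metadata(gr) <- list(halfwidth = halfwidth, fold = fold,
                       pseudocount = pseudocount,
                       baselineLibrary = baseline@name,
                       treatedLibrary = treated@name)
  gr
}

#' Activated subset of enhancer calls as a PeakSet
#'
#' @param calls output of [callActivatedEnhancers()].
#' @param name label for the resulting set.
#' @return a [PeakSet-class] of the activated enhancers.
#' @export
activatedEnhancers <- function(calls, name = "activated_enhancers") {
  act <- calls[mcols(calls)$activated]
  gr <- granges(act)
  mcols(gr) <- DataFrame(id = mcols(act)$id,
                         score = mcols(act)$foldChange)
  PeakSet(gr, name = name,
          provenance = paste0(length(act), " of ", length(calls),
                              " peaks activated at fold >= ",
                              metadata(calls)$fold))
}

#' Temporal H3K27ac metaprofiles over a fixed activated set
#'
#' Profiles each supplied condition library over the activated enhancer
#' set — the set stays fixed (defined by the reference genotype's call)
#' so genotypes and timepoints are directly comparable.
#'
#' @param calls output of [callActivatedEnhancers()] with a non-empty
#'   activated subset.
#' @param libraries named list of [TagLibrary-class], names like
#'   `"WT_0"`.
#' @param conditions condition names to profile; defaults to all supplied.
#' @param halfwidth,binsize profile geometry (display window).
#' @return named list of [MetaProfile-class], one per condition.
#' @export
temporalH3k27acProfiles <- function(calls, libraries,
                                    conditions = names(libraries),
                                    halfwidth = 2000, binsize = 100) {
  act <- activatedEnhancers(calls)
  if (!length(act)) stop("activated enhancer subset is empty")
  missing <- setdiff(conditions, names(libraries))
  if (length(missing))
    stop("missing librar(ies) for requested condition(s): ",
         paste(missing, collapse = ", "))
  profs <- lapply(conditions, function(cn)
    metaProfile(libraries[[cn]], act, halfwidth, binsize))
  names(profs) <- conditions
  profs
}

#' Write enhancer-activation calls as TSV
#'
#' @param calls output of [callActivatedEnhancers()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeEnhancerCalls <- function(calls, path) {
  df <- data.frame(id = mcols(calls)$id,
                   chrom = as.character(seqnames(calls)),
                   start = start(calls) - 1L, end = end(calls),
                   baseline = mcols(calls)$baseline,
                   treated = mcols(calls)$treated,
                   foldChange = mcols(calls)$foldChange,
                   activated = mcols(calls)$activated)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
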