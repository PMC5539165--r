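#' @include macEnhancers-package.R
NULL

#' PeakSet: a named, sorted set of ChIP-seq peaks
#'
#' Thin S4 wrapper around a [GenomicRanges::GRanges] holding peak intervals
#' with mandatory `id` and `score` metadata columns.  Coordinates follow the
#' usual Bioconductor 1-based closed convention internally; BED input/output
#' converts from/to 0-based half-open, so two peaks that abut in BED space
#' never overlap.  Peaks are kept sorted by (chromosome, start) and ids must
#' be unique within a set.
#'
#' @slot name single label for the cistrome (e.g. `"Bmal1"`).
#' @slot ranges `GRanges` with metadata columns `id` (character, unique) and
#'   `score` (non-negative numeric, the peak-caller confidence).
#' @slot provenance character vector of free-text annotations recording the
#'   source files and filters applied.
#' @exportClass PeakSet
setClass("PeakSet",
  representation(name = "character", ranges = "GRanges",
                 provenance = "character"))

setValidity("PeakSet", function(object) {
  gr <- object@ranges
  msg <- character()
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  if (!all(c("id", "score") %in% names(mcols(gr))))
    msg <- c(msg, "ranges must carry 'id' and 'score' metadata columns")
  else {
    if (anyDuplicated(mcols(gr)$id))
      msg <- c(msg, "peak ids must be unique within a set")
    if (length(gr) && any(mcols(gr)$score < 0))
      msg <- c(msg, "peak scores must be non-negative")
  }
  if (length(gr) > 1L) {
    o <- order(as.character(seqnames(gr)), start(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "peaks must be sorted by (chrom, start)")
  }
  if (length(msg)) msg else TRUE
})

#' TagLibrary: a sequencing library as single-base 5' tag positions
#'
#' Aligned tags reduced to their 5'-end base, the unit of all density
#' computation.  The normalization factor scales raw window counts to a
#' common depth; the default used throughout the package is tags-per-ten-
#' million (`1e7 / total`).
#'
#' @slot name library label, conventionally `"factor_genotype_timepoint"`.
#' @slot tags width-1 `GRanges` of 5' tag positions; strand is retained
#'   (GRO-seq) but ignored by strand-blind density operations.
#' @slot total number of tags (always `length(tags)`).
#' @slot normFactor positive scaling applied to every count derived from
#'   this library.
#' @exportClass TagLibrary
setClass("TagLibrary",
  representation(name = "character", tags = "GRanges",
                 total = "integer", normFactor = "numeric"))

setValidity("TagLibrary", function(object) {
  msg <- character()
  if (object@total != length(object@tags))
    msg <- c(msg, "'total' must equal the number of tags")
  if (length(object@normFactor) != 1L || !is.finite(object@normFactor) ||
      object@normFactor <= 0)
    msg <- c(msg, "'normFactor' must be a single positive number")
  if (length(object@tags) && !all(width(object@tags) == 1L))
    msg <- c(msg, "tags must be single-base positions")
  if (length(msg)) msg else TRUE
})

#' VennSummary: reference-anchored three-way overlap counts
#'
#' Counts for a three-cistrome Venn comparison anchored on set A: `nAB` is
#' the number of A peaks overlapping at least one B peak (one A peak
#' overlapping several B peaks counts once), and `nAUnionBC` is the number
#' of A peaks overlapping B or C, computed by inclusion-exclusion
#' `nAB + nAC - nABC`.
#'
#' @slot setNames labels of sets A, B, C.
#' @slot nA,nB,nC set sizes.
#' @slot nAB,nAC,nBC A peaks overlapping B / A overlapping C / B overlapping C.
#' @slot nABC A peaks overlapping both B and C.
#' @slot nAUnionBC A peaks overlapping B or C.
#' @exportClass VennSummary
setClass("VennSummary",
  representation(setNames = "character",
                 nA = "integer", nB = "integer", nC = "integer",
                 nAB = "integer", nAC = "integer", nBC = "integer",
                 nABC = "integer", nAUnionBC = "integer"))

setValidity("VennSummary", function(object) {
  msg <- character()
  if (object@nAB > object@nA || object@nAC > object@nA)
    msg <- c(msg, "pairwise counts cannot exceed the reference set size")
  if (object@nABC > min(object@nAB, object@nAC))
    msg <- c(msg, "triple overlap cannot exceed either pairwise count")
  if (object@nAUnionBC != object@nAB + object@nAC - object@nABC)
    msg <- c(msg, "union count must satisfy inclusion-exclusion")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic study
#'
#' All knobs of the seeded simulator.  Defaults describe the study design the
#' package emulates: a miniature two-chromosome genome, a KLA stimulation
#' time course sampled at 0/6/24/48 h (RNA) and 0/4/8/12/24 h (ChIP), five
#' temporal expression templates with a knockout-delayed cluster-1 profile,
#' Poisson tag background with Gaussian peak-shaped enrichment, and
#' bidirectional eRNA signals de-repressed in a RevErb double-knockout.
#'
#' @slot seed master seed; every generator derives its stream from it.
#' @slot chromSizes named chromosome lengths (bp).
#' @slot nGenes,nEnhancers numbers of gene bodies and intergenic enhancers.
#' @slot flagProbs named probabilities for the planted enhancer attributes
#'   `bmal1Bound`, `pu1Bound`, `p65Bound`, `klaActivated`, `ernaDerepressed`.
#' @slot clusterTemplates 5 x 4 matrix of positive temporal shapes (rows =
#'   templates, columns = RNA timepoints) defining the WT expression programs.
#' @slot genotypeEffects same shape, the knockout version of each template.
#' @slot rnaTimepoints,chipTimepoints sampling times in hours.
#' @slot fracLowExpressed fraction of genes planted below the expression floor.
#' @slot noiseSd additive noise on mean-one template shapes.
#' @slot backgroundRate ChIP background, tags per bp.
#' @slot enrichment expected tags per enhancer per condition at multiplier 1.
#' @slot peakSd SD (bp) of the Gaussian tag scatter around enhancer centers.
#' @slot klaFold planted H3K27ac fold rise at 4 h at KLA-activated sites (WT).
#' @slot koBaseline planted knockout H3K27ac baseline elevation factor.
#' @slot groGenicRate gene-body nascent transcription, tags per bp.
#' @slot groBackgroundRate GRO-seq background per strand, tags per bp.
#' @slot ernaLevel expected eRNA tags per enhancer per strand (WT).
#' @slot ernaFold planted DKO/WT eRNA ratio at de-repressed enhancers (>= 1).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(seed = "integer", chromSizes = "numeric",
                 nGenes = "integer", nEnhancers = "integer",
                 flagProbs = "numeric",
                 clusterTemplates = "matrix", genotypeEffects = "matrix",
                 rnaTimepoints = "numeric", chipTimepoints = "numeric",
                 fracLowExpressed = "numeric", noiseSd = "numeric",
                 backgroundRate = "numeric", enrichment = "numeric",
                 peakSd = "numeric", klaFold = "numeric",
                 koBaseline = "numeric", groGenicRate = "numeric",
                 groBackgroundRate = "numeric", ernaLevel = "numeric",
                 ernaFold = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  rates <- c(object@backgroundRate, object@enrichment, object@peakSd,
             object@groGenicRate, object@groBackgroundRate, object@ernaLevel)
  if (any(rates <= 0)) msg <- c(msg, "all rates must be > 0")
  if (object@ernaFold < 1) msg <- c(msg, "'ernaFold' must be >= 1")
  flags <- c("bmal1Bound", "pu1Bound", "p65Bound", "klaActivated",
             "ernaDerepressed")
  if (!all(flags %in% names(object@flagProbs)))
    msg <- c(msg, "'flagProbs' must name all five planted attributes")
  if (ncol(object@clusterTemplates) != length(object@rnaTimepoints))
    msg <- c(msg, "each template needs one value per RNA timepoint")
  if (!identical(dim(object@clusterTemplates), dim(object@genotypeEffects)))
    msg <- c(msg, "'genotypeEffects' must match 'clusterTemplates' in shape")
  if (any(object@clusterTemplates <= 0) || any(object@genotypeEffects <= 0))
    msg <- c(msg, "template shapes must be positive")
  if (object@fracLowExpressed < 0 || object@fracLowExpressed >= 1)
    msg <- c(msg, "'fracLowExpressed' must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' GenomeModel: a miniature genome with planted ground truth
#'
#' @slot chromSizes named chromosome lengths (bp).
#' @slot genes stranded `GRanges` of gene bodies with an `id` column.
#' @slot enhancers unstranded `GRanges` of intergenic enhancers with `id`,
#'   `score` and the five logical planted-attribute columns.  Enhancers are
#'   placed far enough from gene bodies that gene-body exclusion can never
#'   remove a planted eRNA-de-repressed enhancer.
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(chromSizes = "numeric", genes = "GRanges",
                 enhancers = "GRanges"))

setValidity("GenomeModel", function(object) {
  msg <- character()
  flags <- c("bmal1Bound", "pu1Bound", "p65Bound", "klaActivated",
             "ernaDerepressed")
  if (length(object@enhancers) &&
      !all(c("id", "score", flags) %in% names(mcols(object@enhancers))))
    msg <- c(msg, "enhancers must carry id, score and the planted flags")
  within <- function(gr) {
    !length(gr) || all(as.character(seqnames(gr)) %in%
                         names(object@chromSizes) &
                       end(gr) <= object@chromSizes[
                         as.character(seqnames(gr))])
  }
  if (!within(object@genes) || !within(object@enhancers))
    msg <- c(msg, "features must lie within chromSizes")
  if (length(msg)) msg else TRUE
})

#' FuzzyClusterResult: fuzzy c-means output with thresholded assignments
#'
#' @slot membership genes x c matrix, rows summing to one.
#' @slot centers c x timepoints matrix of cluster centroids (Z units).
#' @slot m fuzziness exponent used (> 1).
#' @slot objective per-iteration fuzzy objective of the best restart
#'   (non-increasing).
#' @slot converged whether the center shift fell below `tol`.
#' @slot seed seed of the best restart's initialization.
#' @slot threshold membership threshold used by [assignMembers()] (`NA`
#'   until assignment).
#' @slot assignments data.frame with columns `gene`, `cluster`,
#'   `membership` for genes whose maximal membership reached the threshold.
#' @exportClass FuzzyClusterResult
setClass("FuzzyClusterResult",
  representation(membership = "matrix", centers = "matrix", m = "numeric",
                 objective = "numeric", converged = "logical",
                 seed = "integer", threshold = "numeric",
                 assignments = "data.frame"))

setValidity("FuzzyClusterResult", function(object) {
  msg <- character()
  if (nrow(object@membership) &&
      max(abs(rowSums(object@membership) - 1)) > 1e-9)
    msg <- c(msg, "membership rows must sum to 1 (within 1e-9)")
  if (object@m <= 1) msg <- c(msg, "fuzziness exponent must be > 1")
  if (nrow(object@assignments) && !is.na(object@threshold) &&
      any(object@assignments$membership < object@threshold))
    msg <- c(msg, "assigned genes must meet the membership threshold")
  if (length(msg)) msg else TRUE
})

#' MetaProfile: average tag density around a set of anchors
#'
#' Per-bin mean of depth-normalized tag counts over all anchor windows.
#' Units are normalized tags per bin per site.
#'
#' @slot reference name of the anchoring peak set.
#' @slot library name of the tag library profiled.
#' @slot halfwidth,binsize window geometry (bp); `2*halfwidth/binsize` bins.
#' @slot offsets left edge of each bin relative to the anchor center (bp).
#' @slot density mean normalized tags per bin per site.
#' @slot nSites number of anchor windows averaged.
#' @exportClass MetaProfile
setClass("MetaProfile",
  representation(reference = "character", library = "character",
                 halfwidth = "numeric", binsize = "numeric",
                 offsets = "numeric", density = "numeric",
                 nSites = "integer"))

setValidity("MetaProfile", function(object) {
  msg <- character()
  nbin <- 2 * object@halfwidth / object@binsize
  if (length(object@offsets) != nbin || length(object@density) != nbin)
    msg <- c(msg, "profile must have 2*halfwidth/binsize bins")
  if (length(object@density) && any(object@density < 0))
    msg <- c(msg, "densities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DensityMatrix: per-site binned tag densities, optionally row-clustered
#'
#' One row per anchor peak; columns are bin offsets, concatenated across the
#' profiled libraries.  Column means over all rows reproduce the
#' corresponding [MetaProfile] densities exactly.
#'
#' @slot values numeric matrix of normalized per-site bin counts.
#' @slot libraries library names in column-block order.
#' @slot offsets bin offsets of one library block.
#' @slot halfwidth,binsize window geometry (bp).
#' @slot rowClusters integer cluster label per row (`NA` before clustering).
#' @slot rowOrder display permutation (cluster blocks, then central
#'   intensity).
#' @exportClass DensityMatrix
setClass("DensityMatrix",
  representation(values = "matrix", libraries = "character",
                 offsets = "numeric", halfwidth = "numeric",
                 binsize = "numeric", rowClusters = "integer",
                 rowOrder = "integer"))

setValidity("DensityMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) !=
      length(object@offsets) * length(object@libraries))
    msg <- c(msg, "columns must be offsets x libraries")
  if (length(object@rowOrder) &&
      !setequal(object@rowOrder, seq_len(nrow(object@values))))
    msg <- c(msg, "'rowOrder' must be a permutation of the rows")
  if (length(msg)) msg else TRUE
})

#' TimecourseCounts: a genotype x timepoint expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `normcounts`
#' assay and `colData` columns `genotype` and `timepoint`.  Synthetic
#' matrices additionally carry the planted `template` and `lowExpressed`
#' ground truth in `rowData`.
#'
#' @exportClass TimecourseCounts
setClass("TimecourseCounts", contains = "SummarizedExperiment")

setValidity("TimecourseCounts", function(object) {
  msg <- character()
  if (!all(c("genotype", "timepoint") %in% names(colData(object))))
    msg <- c(msg, "colData must contain 'genotype' and 'timepoint'")
  if (!"normcounts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'normcounts' is required")
  else if (any(assay(object, "normcounts") < 0))
    msg <- c(msg, "normalized counts must be non-negative")
  cn <- paste(colData(object)$genotype, colData(object)$timepoint, sep = "_")
  if (anyDuplicated(cn))
    msg <- c(msg, "(genotype, timepoint) labels must be unique")
  if (length(msg)) msg else TRUE
})
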