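#' @include erna.R enhancer-dynamics.R clustering.R
NULL

#' Pipeline run configuration
#'
#' Bundles every stage threshold with its conventional default — peak
#' score >= 20, expression floor >= 100, membership >= 0.3, five expression
#' clusters, five heatmap row clusters, top 500 sites, activation fold
#' >= 2, eRNA de-repression fold >= 1.5 — plus the master seed and the
#' simulation configuration used for synthetic runs.
#'
#' @param masterSeed seed from which every stochastic stage derives its
#'   own stream.
#' @param simulation a [SimulationConfig-class]; its seed is set from
#'   `masterSeed`.
#' @param scoreMin high-confidence peak score cut.
#' @param minCount expression floor in the reference genotype.
#' @param membershipThreshold fuzzy membership cut in (0, 1].
#' @param clusters fuzzy cluster count.
#' @param kmeansK heatmap row-cluster count.
#' @param topN sites kept for the density heatmap.
#' @param activationFold,activationHalfwidth H3K27ac activation call.
#' @param ernaFold,ernaMaxDistance eRNA cascade thresholds.
#' @param profileHalfwidth,profileBinsize metaprofile geometry.
#' @param outputDir directory for stage artifacts (`NULL`: keep results in
#'   memory only).
#' @return a `RunConfig` list.
#' @export
runConfig <- function(masterSeed = 1L,
                      simulation = simulationConfig(seed = masterSeed),
                      scoreMin = 20, minCount = 100,
                      membershipThreshold = 0.3, clusters = 5L,
                      kmeansK = 5L, topN = 500L,
                      activationFold = 2, activationHalfwidth = 500,
                      ernaFold = 1.5, ernaMaxDistance = 500L,
                      profileHalfwidth = 2000, profileBinsize = 100,
                      outputDir = NULL) {
  structure(list(masterSeed = as.integer(masterSeed),
                 simulation = simulation, scoreMin = scoreMin,
                 minCount = minCount,
                 membershipThreshold = membershipThreshold,
                 clusters = as.integer(clusters),
                 kmeansK = as.integer(kmeansK), topN = as.integer(topN),
                 activationFold = activationFold,
                 activationHalfwidth = activationHalfwidth,
                 ernaFold = ernaFold,
                 ernaMaxDistance = as.integer(ernaMaxDistance),
                 profileHalfwidth = profileHalfwidth,
                 profileBinsize = profileBinsize,
                 outputDir = outputDir),
            class = "RunConfig")
}

#' Validate a pipeline configuration
#'
#' Returns every violation as a message naming the offending field and its
#' admissible range, without executing anything; an empty return means the
#' configuration is runnable.
#'
#' @param config a `RunConfig`.
#' @return character vector of findings (empty when valid).
#' @export
validateConfig <- function(config) {
  findings <- character()
  chk <- function(ok, msg) if (!ok) findings <<- c(findings, msg)
  chk(config$scoreMin >= 0, "scoreMin: must be >= 0")
  chk(config$minCount >= 0, "minCount: must be >= 0")
  chk(config$membershipThreshold > 0 && config$membershipThreshold <= 1,
      "membershipThreshold: must be in (0, 1]")
  chk(config$clusters >= 2L, "clusters: must be >= 2")
  chk(config$kmeansK >= 2L, "kmeansK: must be >= 2")
  chk(config$topN >= 1L, "topN: must be >= 1")
  chk(config$activationFold > 1, "activationFold: must be > 1")
  chk(config$activationHalfwidth > 0,
      "activationHalfwidth: must be > 0")
  chk(config$ernaFold > 1, "ernaFold: must be > 1")
  chk(config$ernaMaxDistance >= 0, "ernaMaxDistance: must be >= 0")
  chk(config$profileHalfwidth > 0 && config$profileBinsize > 0 &&
        (2 * config$profileHalfwidth) %% config$profileBinsize == 0,
      "profile geometry: binsize must divide 2*halfwidth")
  v <- validObject(config$simulation, test = TRUE)
  if (is.character(v)) findings <- c(findings, paste0("simulation: ", v))
  if (is(config$simulation, "SimulationConfig") &&
      config$clusters > config$simulation@nGenes)
    findings <- c(findings, "clusters: exceeds the number of genes")
  findings
}

#' Run the full synthetic-data pipeline
#'
#' Generates a seeded synthetic study and executes every stage in
#' dependency order: time-course clustering of the expression matrix
#' (filter, standardize on WT, fuzzy c-means, membership threshold,
#' knockout projection), TF co-occupancy of the planted Bmal1/PU.1/p65
#' cistromes, tag-density matrix with K-means row grouping over the top
#' co-binding sites, H3K27ac activation calling, and the GRO-seq eRNA
#' de-repression cascade.  Because the inputs are synthetic, every stage
#' is scored against the planted ground truth (adjusted Rand index,
#' recall/precision, cascade recovery) and the scores are part of the
#' report.  Fully deterministic given the master seed.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @return a `RunReport` list: `parameters`, per-stage `counts`,
#'   `recovery` scores, and the stage objects themselves under `stages`.
#' @export
runPipeline <- function(config = runConfig()) {
  findings <- validateConfig(config)
  if (length(findings))
    stop("invalid configuration:\n  ", paste(findings, collapse = "\n  "))
  sim <- config$simulation
  genome <- generateGenome(sim)
  truth <- as.data.frame(mcols(enhancers(genome)))

  ## --- clustering stage -------------------------------------------------
  counts <- generateCounts(genome, sim)
  expressed <- filterExpressed(counts, "WT", config$minCount)
  zWT <- standardizeCounts(expressed, "WT")
  zKO <- standardizeCounts(expressed, "KO")
  fcm <- fuzzyCMeans(zWT, c = config$clusters,
                     seed = seedFanout(config$masterSeed, "fcm"))
  fcm <- assignMembers(fcm, config$membershipThreshold)
  assigned <- clusterAssignments(fcm)
  planted <- rowData(expressed)$template
  names(planted) <- rownames(expressed)
  ari <- mclust::adjustedRandIndex(assigned$cluster,
                                   planted[assigned$gene])
  projection <- projectGenotype(fcm, zWT, zKO)

  ## --- co-occupancy stage ----------------------------------------------
  bmal1 <- enhancerPeaks(genome, "bmal1Bound", "Bmal1")
  pu1 <- enhancerPeaks(genome, "pu1Bound", "PU.1")
  p65 <- enhancerPeaks(genome, "p65Bound", "p65")
  venn <- vennCounts(bmal1, pu1, p65)

  ## --- tag density stage ------------------------------------------------
  cobound <- subsetPeakSet(bmal1,
                           .ovAny(peakRanges(bmal1), peakRanges(pu1)),
                           note = "Bmal1 peaks co-bound by PU.1")
  top <- suppressWarnings(topNByScore(cobound, config$topN))
  libs0 <- list(
    Bmal1 = generateChipTags(genome, "Bmal1", "WT", 0, sim),
    PU.1 = generateChipTags(genome, "PU.1", "WT", 0, sim),
    p65 = generateChipTags(genome, "p65", "WT", 0, sim),
    H3K27ac = generateChipTags(genome, "H3K27ac", "WT", 0, sim))
  dm <- densityMatrix(libs0, top, config$profileHalfwidth, 25)
  dm <- kmeansRows(dm, config$kmeansK,
                   seed = seedFanout(config$masterSeed, "kmeans"))

  ## --- activation stage -------------------------------------------------
  h3k0 <- libs0$H3K27ac
  h3k4 <- generateChipTags(genome, "H3K27ac", "WT", 4, sim)
  actCalls <- callActivatedEnhancers(pu1, h3k0, h3k4,
                                     config$activationHalfwidth,
                                     config$activationFold)
  actIds <- mcols(actCalls)$id[mcols(actCalls)$activated]
  actTruth <- truth$id[truth$pu1Bound & truth$klaActivated]
  actRecall <- if (length(actTruth))
    mean(actTruth %in% actIds) else NA_real_
  actPrecision <- if (length(actIds))
    mean(actIds %in% actTruth) else NA_real_

  ## --- eRNA stage -------------------------------------------------------
  gro <- list(WT = generateGroseq(genome, "WT", sim),
              DKO = generateGroseq(genome, "DKO", sim))
  cascade <- ernaCascade(gro$WT, gro$DKO, geneBodies(genome), pu1,
                         fold = config$ernaFold,
                         maxDistance = config$ernaMaxDistance)
  ernaTruthIds <- truth$id[truth$ernaDerepressed & truth$pu1Bound]
  ernaTruth <- enhancers(genome)[mcols(enhancers(genome))$id %in%
                                   ernaTruthIds]
  recovered <- .ovAny(ernaTruth, cascade$pu1Adjacent)
  contaminant <- !.ovAny(cascade$pu1Adjacent, ernaTruth)
  ernaRecall <- if (length(ernaTruth)) mean(recovered) else NA_real_
  ernaContamination <- if (length(cascade$pu1Adjacent))
    mean(contaminant) else NA_real_

  report <- structure(list(
    parameters = config[setdiff(names(config), "simulation")],
    seeds = c(master = config$masterSeed,
              fcm = seedFanout(config$masterSeed, "fcm"),
              kmeans = seedFanout(config$masterSeed, "kmeans")),
    counts = list(
      genes = nrow(counts), expressed = nrow(expressed),
      assigned = nrow(assigned),
      venn = as.list.VennSummary(venn),
      topSites = length(top),
      activated = sum(mcols(actCalls)$activated),
      erna = as.list(cascade$counts)),
    recovery = list(clusteringARI = ari,
                    fuzzinessM = fcm@m,
                    fcmConverged = fcm@converged,
                    activationRecall = actRecall,
                    activationPrecision = actPrecision,
                    ernaRecall = ernaRecall,
                    ernaContamination = ernaContamination),
    stages = list(genome = genome, counts = counts, clustering = fcm,
                  projection = projection, venn = venn,
                  densityMatrix = dm, activationCalls = actCalls,
                  ernaCascade = cascade)),
    class = "RunReport")
  if (!is.null(config$outputDir))
    writeRunReport(report, config$outputDir)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Pipeline run (master seed ", x$seeds[["master"]], ")\n", sep = "")
  cat("  genes: ", x$counts$genes, " -> expressed: ", x$counts$expressed,
      " -> assigned: ", x$counts$assigned,
      " (ARI vs planted templates: ",
      round(x$recovery$clusteringARI, 3), ")\n", sep = "")
  v <- x$counts$venn
  cat("  co-occupancy (", paste(v$setNames, collapse = "/"), "): ",
      v$n_A_union_BC, " of ", v$n_A, " reference peaks in the union\n",
      sep = "")
  cat("  activation: ", x$counts$activated, " enhancers (recall ",
      round(x$recovery$activationRecall, 3), ", precision ",
      round(x$recovery$activationPrecision, 3), ")\n", sep = "")
  e <- x$counts$erna
  cat("  eRNA cascade: ", e$candidates, " -> ", e$intergenic, " -> ",
      e$derepressed, " -> ", e$pu1Adjacent, " (recall ",
      round(x$recovery$ernaRecall, 3), ", contamination ",
      round(x$recovery$ernaContamination, 3), ")\n", sep = "")
  invisible(x)
}

#' Write pipeline artifacts to disk
#'
#' Emits the plain-text external outputs of a run: cluster membership TSV,
#' activated-enhancer BED and call TSV, surviving eRNA BED, and the
#' structured report (counts, parameters, seeds, recovery) as JSON.
#'
#' @param report a `RunReport`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(clusterAssignments(report$stages$clustering),
              file.path(dir, "cluster_membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeEnhancerCalls(report$stages$activationCalls,
                     file.path(dir, "activation_calls.tsv"))
  writeBed(activatedEnhancers(report$stages$activationCalls),
           file.path(dir, "activated_enhancers.bed"))
  surv <- report$stages$ernaCascade$pu1Adjacent
  write.table(data.frame(chrom = as.character(seqnames(surv)),
                         start = start(surv) - 1L, end = end(surv),
                         id = mcols(surv)$id,
                         wtCount = mcols(surv)$wtCount,
                         dkoCount = mcols(surv)$dkoCount,
                         foldChange = mcols(surv)$foldChange,
                         pu1Ids = mcols(surv)$pu1Ids),
              file.path(dir, "erna_enhancers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report[c("parameters", "seeds", "counts",
                                "recovery")],
                       file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
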