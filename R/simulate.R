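#' @include utils.R peakset.R
NULL

## Layout constants of the miniature genome.  Features are laid out on a
## fixed grid of blocks so that every enhancer is guaranteed a wide margin
## from every gene body (>= ~1.4 kb), which keeps gene-body exclusion from
## ever removing a planted intergenic enhancer.
.BLOCK <- 3200L      # bp per feature block
.GENE_PAD <- 700L    # gene offset inside its block
.CHIP_TIMEPOINTS <- c(0, 4, 8, 12, 24)

## Planted temporal multiplier tables (rows: ChIP timepoints above).
## H3K27ac at KLA-activated sites: WT rises at 4 h then decays; the
## Arntl-null (KO) genotype starts elevated and persists — the qualitative
## enhancer phenotype the simulator emulates.  p65 recruitment peaks at
## 4-8 h in both genotypes; Bmal1 is absent from the KO.
.h3k27acMultiplier <- function(genotype, klaFold, koBaseline) {
  wt <- c(1, klaFold, 3, 2, 1.2)
  ko <- c(koBaseline, klaFold, klaFold, 3.5, 3)
  if (genotype == "KO") ko else wt
}

.conditionMultiplier <- function(factor, genotype, timepoint, flags,
                                 klaFold, koBaseline) {
  ti <- match(timepoint, .CHIP_TIMEPOINTS)
  if (is.na(ti))
    stop("ChIP timepoint must be one of ",
         paste(.CHIP_TIMEPOINTS, collapse = "/"), " h")
  n <- nrow(flags)
  switch(factor,
    H3K27ac = {
      act <- .h3k27acMultiplier(genotype, klaFold, koBaseline)[ti]
      base <- rep(1, n)
      ## the knockout's constitutive hyperacetylation is planted both at
      ## KLA-activated and at eRNA-de-repressed enhancers
      if (genotype == "KO")
        base[flags$ernaDerepressed] <- koBaseline
      ifelse(flags$klaActivated, act, base)
    },
    p65 = {
      prof <- c(0.3, 1, 1, 0.6, 0.3)
      ifelse(flags$p65Bound, prof[ti], 0)
    },
    PU.1 = ifelse(flags$pu1Bound, 1, 0),
    Bmal1 = if (genotype == "KO") numeric(n)
            else ifelse(flags$bmal1Bound, 1, 0),
    stop("unknown ChIP factor '", factor,
         "' (expected Bmal1, PU.1, p65 or H3K27ac)"))
}

#' Simulation configuration
#'
#' Builds a [SimulationConfig-class] with the package's default study
#' conditions: a 2 x 2 Mb genome carrying 1,000 genes and 200 intergenic
#' enhancers; five temporal expression templates over 0/6/24/48 h with the
#' first (early-induction) template delayed to 24 h in the knockout; 20% of
#' genes planted below the 100-count expression floor; background-dominated
#' ChIP libraries (Poisson background at 0.01 tags/bp, ~200 expected tags
#' per bound enhancer);
#' a four-fold planted H3K27ac rise at KLA-activated sites; and eRNA
#' signals de-repressed three-fold in the RevErb double-knockout at a
#' quarter of enhancers.
#'
#' @param seed master seed for all generators.
#' @param chromSizes,nGenes,nEnhancers genome geometry.
#' @param flagProbs planted attribute probabilities (see
#'   [SimulationConfig-class]).
#' @param clusterTemplates,genotypeEffects positive temporal shape matrices
#'   (templates x RNA timepoints) for WT and knockout.
#' @param rnaTimepoints,chipTimepoints sampling times (h).
#' @param fracLowExpressed,noiseSd count-matrix parameters.
#' @param backgroundRate,enrichment,peakSd ChIP tag model.
#' @param klaFold,koBaseline planted H3K27ac condition table scalars.
#' @param groGenicRate,groBackgroundRate,ernaLevel,ernaFold GRO-seq model.
#' @return a `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             chromSizes = c(chr1 = 2e6, chr2 = 2e6),
                             nGenes = 1000L, nEnhancers = 200L,
                             flagProbs = c(bmal1Bound = 0.4,
                                           pu1Bound = 0.6,
                                           p65Bound = 0.4,
                                           klaActivated = 0.35,
                                           ernaDerepressed = 0.25),
                             clusterTemplates = rbind(
                               c(1, 8, 3, 1.5),   # early induction (6 h)
                               c(1, 2, 6, 8),     # late induction
                               c(8, 3, 1, 1),     # early repression
                               c(3, 1, 2, 6),     # transient repression
                               c(6, 5, 3, 1)),    # slow decline
                             genotypeEffects = rbind(
                               c(1, 2, 8, 3),     # induction delayed to 24 h
                               c(1, 2, 6, 8),
                               c(8, 3, 1, 1),
                               c(3, 1, 2, 6),
                               c(6, 5, 3, 1)),
                             rnaTimepoints = c(0, 6, 24, 48),
                             chipTimepoints = .CHIP_TIMEPOINTS,
                             fracLowExpressed = 0.2, noiseSd = 0.3,
                             backgroundRate = 0.01, enrichment = 200,
                             peakSd = 75, klaFold = 4, koBaseline = 2,
                             groGenicRate = 0.04,
                             groBackgroundRate = 5e-4,
                             ernaLevel = 60, ernaFold = 3) {
  new("SimulationConfig", seed = as.integer(seed),
      chromSizes = chromSizes, nGenes = as.integer(nGenes),
      nEnhancers = as.integer(nEnhancers), flagProbs = flagProbs,
      clusterTemplates = clusterTemplates,
      genotypeEffects = genotypeEffects,
      rnaTimepoints = rnaTimepoints, chipTimepoints = chipTimepoints,
      fracLowExpressed = fracLowExpressed, noiseSd = noiseSd,
      backgroundRate = backgroundRate, enrichment = enrichment,
      peakSd = peakSd, klaFold = klaFold, koBaseline = koBaseline,
      groGenicRate = groGenicRate, groBackgroundRate = groBackgroundRate,
      ernaLevel = ernaLevel, ernaFold = ernaFold)
}

#' Generate a miniature genome with planted ground truth
#'
#' Lays genes and intergenic enhancers onto a fixed block grid (one feature
#' per 3.2 kb block, shuffled across the genome) and draws the planted
#' attribute flags with the configured probabilities.  The grid guarantees
#' every enhancer at least ~1.4 kb of clearance from every gene body, so
#' downstream gene-body exclusion can never discard a planted
#' eRNA-de-repressed enhancer.  Fully reproducible from the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GenomeModel-class].
#' @export
generateGenome <- function(config) {
  validObject(config)
  nBlocks <- sum(floor(config@chromSizes / .BLOCK))
  nFeat <- config@nGenes + config@nEnhancers
  if (nFeat > nBlocks)
    stop("capacity error: ", nFeat, " features do not fit into ",
         nBlocks, " blocks; enlarge chromSizes or reduce features")
  withSeed(seedFanout(config@seed, "genome"), {
    ## assign features to random blocks
    kind <- sample(rep(c("gene", "enh"),
                       c(config@nGenes, config@nEnhancers)))
    blocks <- sort(sample(nBlocks, nFeat))
    perChrom <- floor(config@chromSizes / .BLOCK)
    chromOf <- rep(names(config@chromSizes), perChrom)
    offset <- rep(c(0, cumsum(perChrom))[seq_along(perChrom)], perChrom)
    blockStart <- (blocks - offset[blocks] - 1L) * .BLOCK
    isGene <- kind == "gene"
    geneLen <- as.integer(round(runif(sum(isGene), 500, 1800)))
    geneStart0 <- blockStart[isGene] + .GENE_PAD
    genes <- GRanges(chromOf[blocks][isGene],
                     IRanges(geneStart0 + 1L, geneStart0 + geneLen),
                     strand = sample(c("+", "-"), sum(isGene),
                                     replace = TRUE),
                     id = sprintf("gene_%04d", seq_len(sum(isGene))))
    enhWidth <- as.integer(round(runif(sum(!isGene), 400, 600)))
    enhCenter0 <- blockStart[!isGene] + .BLOCK %/% 2L
    enh <- GRanges(chromOf[blocks][!isGene],
                   IRanges(enhCenter0 - enhWidth %/% 2L + 1L,
                           enhCenter0 + enhWidth - enhWidth %/% 2L),
                   id = sprintf("enh_%04d", seq_len(sum(!isGene))),
                   score = round(runif(sum(!isGene), 10, 100), 1))
    for (fl in names(config@flagProbs))
      mcols(enh)[[fl]] <- as.logical(
        rbinom(length(enh), 1L, config@flagProbs[[fl]]))
    new("GenomeModel", chromSizes = config@chromSizes,
        genes = sort(genes), enhancers = sort(enh))
  })
}

#' GenomeModel accessors
#'
#' @param x a `GenomeModel`.
#' @name GenomeModel-accessors
#' @aliases chromSizes geneBodies enhancers
NULL

#' @rdname GenomeModel-accessors
#' @export
setMethod("chromSizes", "GenomeModel", function(x) x@chromSizes)

#' @rdname GenomeModel-accessors
#' @export
setMethod("geneBodies", "GenomeModel", function(x) x@genes)

#' @rdname GenomeModel-accessors
#' @export
setMethod("enhancers", "GenomeModel", function(x) x@enhancers)

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel: ", length(object@chromSizes), " chromosome(s), ",
      sum(object@chromSizes) / 1e6, " Mb; ", length(object@genes),
      " genes; ", length(object@enhancers), " enhancers\n", sep = "")
  fl <- c("bmal1Bound", "pu1Bound", "p65Bound", "klaActivated",
          "ernaDerepressed")
  if (length(object@enhancers)) {
    cnt <- vapply(fl, function(f) sum(mcols(object@enhancers)[[f]]), 0L)
    cat("  planted flags:", paste(fl, cnt, sep = "=", collapse = " "), "\n")
  }
})

#' Ground-truth peak set for a planted attribute
#'
#' Extracts the enhancers carrying a planted flag (or all enhancers) as a
#' [PeakSet-class], the form downstream co-occupancy/density operations
#' consume.
#'
#' @param genome a `GenomeModel`.
#' @param flag one of `"bmal1Bound"`, `"pu1Bound"`, `"p65Bound"`,
#'   `"klaActivated"`, `"ernaDerepressed"`, or `NULL` for all enhancers.
#' @param name label for the set; defaults to the flag name.
#' @return a `PeakSet`.
#' @export
enhancerPeaks <- function(genome, flag = NULL, name = NULL) {
  gr <- enhancers(genome)
  if (!is.null(flag)) {
    if (!flag %in% names(mcols(gr)))
      stop("unknown planted flag '", flag, "'")
    gr <- gr[mcols(gr)[[flag]]]
  }
  if (is.null(name)) name <- if (is.null(flag)) "enhancers" else flag
  keep <- mcols(gr)[, c("id", "score")]
  mcols(gr) <- keep
  PeakSet(gr, name = name, provenance = paste0("ground truth: ",
                                               flag %||% "all enhancers"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a TagLibrary
#'
#' @param positions0 integer vector of 0-based 5' tag positions.
#' @param chrom chromosome of each tag (recycled if length one).
#' @param strand strand of each tag (`"*"` for unstranded ChIP).
#' @param name library label.
#' @param normFactor depth normalization; default tags-per-ten-million.
#' @param chromSizes optional named lengths attached as `seqlengths`.
#' @return a [TagLibrary-class].
#' @export
TagLibrary <- function(positions0, chrom, strand = "*", name = "tags",
                       normFactor = NULL, chromSizes = NULL) {
  chrom <- rep_len(as.character(chrom), length(positions0))
  strand <- rep_len(as.character(strand), length(positions0))
  gr <- GRanges(chrom, IRanges(as.integer(positions0) + 1L, width = 1L),
                strand = strand)
  if (!is.null(chromSizes))
    seqlengths(gr) <- chromSizes[seqlevels(gr)]
  gr <- sort(gr)
  if (is.null(normFactor))
    normFactor <- if (length(gr)) 1e7 / length(gr) else 1
  new("TagLibrary", name = name, tags = gr, total = length(gr),
      normFactor = normFactor)
}

#' TagLibrary accessors
#'
#' @param x a `TagLibrary`.
#' @name TagLibrary-accessors
#' @aliases tagRanges tagTotal normFactor
NULL

#' @rdname TagLibrary-accessors
#' @export
setMethod("tagRanges", "TagLibrary", function(x) x@tags)

#' @rdname TagLibrary-accessors
#' @export
setMethod("tagTotal", "TagLibrary", function(x) x@total)

#' @rdname TagLibrary-accessors
#' @export
setMethod("normFactor", "TagLibrary", function(x) x@normFactor)

setMethod("show", "TagLibrary", function(object) {
  cat("TagLibrary '", object@name, "': ", object@total,
      " tags, normFactor ", signif(object@normFactor, 4), "\n", sep = "")
})

## Draw peak-shaped tags around enhancer centers: Poisson tag numbers with
## Gaussian positional scatter, clamped to the chromosome.
.peakTags <- function(centers0, chrom, lambda, peakSd, chromSizes) {
  n <- rpois(length(centers0), lambda)
  if (!sum(n)) return(list(pos = integer(), chrom = character()))
  pos <- rep(centers0, n) + as.integer(round(rnorm(sum(n), 0, peakSd)))
  ch <- rep(chrom, n)
  pos <- pmax(0L, pmin(pos, as.integer(chromSizes[ch] - 1L)))
  list(pos = pos, chrom = ch)
}

## Uniform Poisson background over the genome, one draw per chromosome.
.backgroundTags <- function(chromSizes, rate) {
  pos <- integer(); ch <- character()
  for (cn in names(chromSizes)) {
    n <- rpois(1L, chromSizes[[cn]] * rate)
    if (n) {
      pos <- c(pos, as.integer(floor(runif(n, 0, chromSizes[[cn]]))))
      ch <- c(ch, rep(cn, n))
    }
  }
  list(pos = pos, chrom = ch)
}

#' Simulate a ChIP-seq tag library
#'
#' Poisson background over the whole genome plus Gaussian-shaped enrichment
#' around the enhancers bound by the requested factor, with expected peak
#' heights following the planted condition table: H3K27ac rises
#' `klaFold`-fold at 4 h at KLA-activated sites in WT and is elevated at
#' baseline (and persistent) in the knockout; p65 recruitment peaks at
#' 4-8 h in both genotypes; Bmal1 tags are absent from the knockout.
#' Deterministic given the config seed, independent of the order in which
#' libraries are generated.
#'
#' @param genome a [GenomeModel-class].
#' @param factor one of `"Bmal1"`, `"PU.1"`, `"p65"`, `"H3K27ac"`.
#' @param genotype `"WT"` or `"KO"` (the *Arntl*-null genotype).
#' @param timepoint hours after KLA among the config's ChIP timepoints.
#' @param config the [SimulationConfig-class] used to build `genome`.
#' @return a [TagLibrary-class] named `"factor_genotype_timepoint"`.
#' @export
generateChipTags <- function(genome, factor, genotype = c("WT", "KO"),
                             timepoint = 0, config) {
  genotype <- match.arg(genotype)
  flags <- as.data.frame(mcols(enhancers(genome)))
  mult <- .conditionMultiplier(factor, genotype, timepoint, flags,
                               config@klaFold, config@koBaseline)
  name <- paste(factor, genotype, timepoint, sep = "_")
  withSeed(seedFanout(config@seed, paste0("chip:", name)), {
    bg <- .backgroundTags(chromSizes(genome), config@backgroundRate)
    pk <- .peakTags(peakCenters(enhancers(genome)),
                    as.character(seqnames(enhancers(genome))),
                    config@enrichment * mult, config@peakSd,
                    chromSizes(genome))
    TagLibrary(c(bg$pos, pk$pos), c(bg$chrom, pk$chrom), name = name,
               chromSizes = chromSizes(genome))
  })
}

#' Simulate a GRO-seq tag library
#'
#' Genic nascent transcription on the annotated strand over gene bodies,
#' strand-specific Poisson background, and short bidirectional (divergent)
#' eRNA signals around enhancer centers: plus-strand tags downstream and
#' minus-strand tags upstream of the center.  At planted de-repressed
#' enhancers the expected tag level in the `"DKO"` (RevErb double-knockout)
#' condition is `ernaFold` times the WT level; all other enhancers have
#' equal expectation in both conditions.
#'
#' @param genome a [GenomeModel-class].
#' @param condition `"WT"` or `"DKO"`.
#' @param config the matching [SimulationConfig-class].
#' @return a stranded [TagLibrary-class].
#' @export
generateGroseq <- function(genome, condition = c("WT", "DKO"), config) {
  condition <- match.arg(condition)
  name <- paste0("groseq_", condition)
  withSeed(seedFanout(config@seed, paste0("gro:", name)), {
    genes <- geneBodies(genome)
    pos <- integer(); ch <- character(); str <- character()
    if (length(genes)) {
      n <- rpois(length(genes), width(genes) * config@groGenicRate)
      if (sum(n)) {
        gs <- rep(start(genes) - 1L, n)
        gw <- rep(width(genes), n)
        pos <- c(pos, gs + as.integer(floor(runif(sum(n)) * gw)))
        ch <- c(ch, rep(as.character(seqnames(genes)), n))
        str <- c(str, rep(as.character(strand(genes)), n))
      }
    }
    enh <- enhancers(genome)
    if (length(enh)) {
      lev <- rep(config@ernaLevel, length(enh))
      if (condition == "DKO")
        lev[mcols(enh)$ernaDerepressed] <- lev[mcols(enh)$ernaDerepressed] *
          config@ernaFold
      centers <- peakCenters(enh)
      for (sgn in c(1L, -1L)) {
        n <- rpois(length(enh), lev)
        if (sum(n)) {
          off <- pmin(abs(as.integer(round(rnorm(sum(n), 0, 150)))), 450L)
          pos <- c(pos, rep(centers, n) + sgn * off)
          ch <- c(ch, rep(as.character(seqnames(enh)), n))
          str <- c(str, rep(if (sgn > 0) "+" else "-", sum(n)))
        }
      }
    }
    for (s in c("+", "-")) {
      bg <- .backgroundTags(chromSizes(genome), config@groBackgroundRate)
      pos <- c(pos, bg$pos); ch <- c(ch, bg$chrom)
      str <- c(str, rep(s, length(bg$pos)))
    }
    pos <- pmax(0L, pmin(pos, as.integer(chromSizes(genome)[ch] - 1L)))
    TagLibrary(pos, ch, strand = str, name = name,
               chromSizes = chromSizes(genome))
  })
}

#' Simulate a genotype x timepoint expression matrix
#'
#' Assigns each gene one of the temporal templates (recorded as ground
#' truth in `rowData`), builds its WT profile as the mean-one template
#' shape plus additive Gaussian noise, and its knockout profile from the
#' corresponding `genotypeEffects` shape — by default, the early-induction
#' template's peak is delayed from 6 h to 24 h in the knockout.  Each gene's
#' row is rescaled so that its maximal WT count hits a planted target:
#' below 100 for the configured low-expressed fraction, above it otherwise,
#' so the expression floor separates the two groups exactly.
#'
#' @param genome a [GenomeModel-class] (its genes name the rows).
#' @param config the matching [SimulationConfig-class].
#' @return a [TimecourseCounts-class] with planted `template` and
#'   `lowExpressed` in `rowData`.
#' @export
generateCounts <- function(genome, config) {
  genes <- mcols(geneBodies(genome))$id
  nG <- length(genes)
  tpl <- config@clusterTemplates
  nT <- ncol(tpl)
  withSeed(seedFanout(config@seed, "counts"), {
    template <- sample(nrow(tpl), nG, replace = TRUE)
    low <- as.logical(rbinom(nG, 1L, config@fracLowExpressed))
    targetMax <- ifelse(low, runif(nG, 20, 90), runif(nG, 120, 1500))
    wt <- ko <- matrix(0, nG, nT)
    for (k in seq_len(nrow(tpl))) {
      idx <- which(template == k)
      if (!length(idx)) next
      shapeW <- tpl[k, ] / mean(tpl[k, ])
      shapeK <- config@genotypeEffects[k, ] / mean(tpl[k, ])
      wt[idx, ] <- pmax(matrix(shapeW, length(idx), nT, byrow = TRUE) +
                          matrix(rnorm(length(idx) * nT, 0, config@noiseSd),
                                 length(idx)), 0.01)
      ko[idx, ] <- pmax(matrix(shapeK, length(idx), nT, byrow = TRUE) +
                          matrix(rnorm(length(idx) * nT, 0, config@noiseSd),
                                 length(idx)), 0.01)
    }
    scale <- targetMax / apply(wt, 1, max)
    wt <- wt * scale
    ko <- ko * scale
    mat <- cbind(wt, ko)
    geno <- rep(c("WT", "KO"), each = nT)
    tp <- rep(config@rnaTimepoints, 2L)
    rownames(mat) <- genes
    colnames(mat) <- paste(geno, tp, sep = "_")
    TimecourseCounts(mat, genotype = geno, timepoint = tp,
                     template = template, lowExpressed = low)
  })
}

#' Write a simulated run to disk
#'
#' Emits the plain-text external representation of a synthetic dataset
#' under `dir`: gene annotation and enhancer BED files, BED6 tag files for
#' the supplied libraries, the count matrix TSV, and a JSON ground-truth
#' manifest (planted flags, template assignments, configuration echo).
#'
#' @param genome a `GenomeModel`.
#' @param config the matching `SimulationConfig`.
#' @param dir output directory (created if needed).
#' @param libraries optional named list of [TagLibrary-class] to write.
#' @param counts optional [TimecourseCounts-class] to write.
#' @return `dir`, invisibly.
#' @export
exportSimulation <- function(genome, config, dir, libraries = list(),
                             counts = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- geneBodies(genome)
  write.table(data.frame(as.character(seqnames(genes)), start(genes) - 1L,
                         end(genes), mcols(genes)$id, 0,
                         as.character(strand(genes))),
              file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeBed(enhancerPeaks(genome), file.path(dir, "enhancers.bed"))
  for (nm in names(libraries)) {
    lib <- libraries[[nm]]
    gr <- tagRanges(lib)
    write.table(data.frame(as.character(seqnames(gr)), start(gr) - 1L,
                           end(gr), ".", 0, as.character(strand(gr))),
                file.path(dir, paste0(nm, ".tags.bed")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(counts))
    write.table(data.frame(gene = rownames(assay(counts, "normcounts")),
                           assay(counts, "normcounts"),
                           check.names = FALSE),
                file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  enh <- enhancers(genome)
  manifest <- list(
    seed = config@seed,
    chromSizes = as.list(chromSizes(genome)),
    enhancers = as.data.frame(mcols(enh)),
    geneTemplates = if (!is.null(counts))
      data.frame(gene = rownames(counts),
                 template = rowData(counts)$template,
                 lowExpressed = rowData(counts)$lowExpressed) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
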