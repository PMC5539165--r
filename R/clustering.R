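#' @include utils.R
NULL

#' Construct a TimecourseCounts container
#'
#' Wraps a genes x (genotype, timepoint) matrix of normalized counts in a
#' [TimecourseCounts-class].  The matrix is accepted as already normalized;
#' [normalizeTotalCount()] offers total-count scaling when no external
#' normalization is available.
#'
#' @param counts numeric matrix, genes in rows; `rownames` are gene ids.
#' @param genotype,timepoint per-column condition labels.
#' @param template,lowExpressed optional planted ground truth (synthetic
#'   data), stored in `rowData`.
#' @return a `TimecourseCounts`.
#' @export
TimecourseCounts <- function(counts, genotype, timepoint,
                             template = NULL, lowExpressed = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  cd <- DataFrame(genotype = as.character(genotype),
                  timepoint = as.numeric(timepoint))
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(template)) rd$template <- template
  if (!is.null(lowExpressed)) rd$lowExpressed <- lowExpressed
  colnames(counts) <- paste(cd$genotype, cd$timepoint, sep = "_")
  se <- SummarizedExperiment(assays = list(normcounts = counts),
                             colData = cd, rowData = rd)
  new("TimecourseCounts", se)
}

#' Read a count matrix TSV
#'
#' Expects a header row of `genotype_timepoint` labels (e.g. `WT_0`) and a
#' first column of gene ids.
#'
#' @param path TSV file path.
#' @return a [TimecourseCounts-class].
#' @export
readCountMatrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                   check.names = FALSE)
  lab <- strsplit(colnames(df), "_", fixed = TRUE)
  TimecourseCounts(as.matrix(df),
                   genotype = vapply(lab, `[`, "", 1L),
                   timepoint = as.numeric(vapply(lab, `[`, "", 2L)))
}

#' Total-count normalization to a common library size
#'
#' Scales every column to the mean column sum.  Provided for raw matrices;
#' clustering itself is agnostic to the normalization used.
#'
#' @param x a `TimecourseCounts`.
#' @return a rescaled `TimecourseCounts`.
#' @export
normalizeTotalCount <- function(x) {
  m <- assay(x, "normcounts")
  f <- mean(colSums(m)) / colSums(m)
  SummarizedExperiment::assay(x, "normcounts") <-
    sweep(m, 2L, f, `*`)
  x
}

#' Filter genes by an expression floor in a reference genotype
#'
#' Retains genes whose normalized count reaches `minCount` at one or more
#' timepoint of the reference genotype (boundary inclusive, mirroring the
#' conventional ">= 100 normalized counts in WT" floor); all conditions of
#' retained genes are kept.
#'
#' @param x a `TimecourseCounts`.
#' @param genotype reference genotype label.
#' @param minCount expression floor.
#' @return the filtered `TimecourseCounts`.
#' @export
filterExpressed <- function(x, genotype = "WT", minCount = 100) {
  if (!genotype %in% colData(x)$genotype)
    stop("unknown genotype '", genotype, "'")
  ref <- assay(x, "normcounts")[, colData(x)$genotype == genotype,
                                drop = FALSE]
  x[apply(ref, 1L, max) >= minCount, ]
}

#' Row-wise standardization over one genotype's time course
#'
#' Z-scores each gene over the selected genotype's timepoints so that the
#' per-gene mean is zero and the standard deviation one, using the
#' population (divisor n) standard deviation.  Genes with zero variance
#' cannot be standardized and are dropped with a warning.
#'
#' @param x a `TimecourseCounts`.
#' @param genotype genotype whose timepoints are standardized.
#' @return numeric matrix (genes x timepoints) with the timepoints as an
#'   `"timepoints"` attribute.
#' @export
standardizeCounts <- function(x, genotype = "WT") {
  sel <- colData(x)$genotype == genotype
  if (!any(sel)) stop("unknown genotype '", genotype, "'")
  if (sum(sel) < 2L) stop("need at least two timepoints")
  m <- assay(x, "normcounts")[, sel, drop = FALSE]
  tp <- colData(x)$timepoint[sel]
  o <- order(tp)
  m <- m[, o, drop = FALSE]
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))
  zero <- sdp == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) excluded from ",
            "standardization")
    m <- m[!zero, , drop = FALSE]
    mu <- mu[!zero]; sdp <- sdp[!zero]
  }
  z <- (m - mu) / sdp
  colnames(z) <- paste0("t", tp[o])
  attr(z, "timepoints") <- tp[o]
  attr(z, "genotype") <- genotype
  z
}

#' Mfuzz-style fuzziness estimate
#'
#' Estimates the fuzzy c-means exponent `m` from the data dimensions
#' (N genes, D timepoints) with the standard minimum-fuzziness formula used
#' for time-course expression clustering:
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#'
#' @param z standardized matrix (genes x timepoints).
#' @return the estimated exponent (> 1).
#' @export
mEstimate <- function(z) {
  N <- nrow(z); D <- ncol(z)
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

## One seeded fuzzy c-means run from a random membership initialization.
.fcmRun <- function(z, c, m, tol, maxIter, seed) {
  withSeed(seed, {
    u <- matrix(runif(nrow(z) * c), nrow(z), c)
    u <- u / rowSums(u)
    centers <- matrix(0, c, ncol(z))
    obj <- numeric(0)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      um <- u^m
      newCenters <- (t(um) %*% z) / colSums(um)
      ## squared Euclidean distances genes x centers
      d2 <- outer(rowSums(z^2), rep(1, c)) -
        2 * z %*% t(newCenters) + outer(rep(1, nrow(z)), rowSums(newCenters^2))
      d2 <- pmax(d2, 0)
      exact <- d2 < 1e-12
      inv <- (1 / pmax(d2, 1e-12))^(1 / (m - 1))
      u <- inv / rowSums(inv)
      hitRow <- rowSums(exact) > 0
      if (any(hitRow)) {
        u[hitRow, ] <- exact[hitRow, , drop = FALSE] /
          rowSums(exact[hitRow, , drop = FALSE])
      }
      obj <- c(obj, sum(u^m * d2))
      shift <- max(abs(newCenters - centers))
      centers <- newCenters
      if (it > 1L && shift < tol) { converged <- TRUE; break }
    }
    list(u = u, centers = centers, obj = obj, converged = converged)
  })
}

#' Fuzzy c-means clustering of standardized time courses
#'
#' Classic fuzzy c-means: alternate membership^m-weighted center updates
#' and inverse-squared-distance membership updates with exponent
#' `2/(m-1)`, until the maximal center shift falls below `tol` or
#' `maxIter` is reached.  Memberships are initialized from a seeded uniform
#' draw (row-normalized); `restarts` independent initializations are run,
#' with seeds derived from `seed`, and the solution with the lowest fuzzy
#' objective is kept.  The per-iteration objective trajectory of the
#' winning run is returned and is non-increasing.
#'
#' @param z standardized matrix from [standardizeCounts()].
#' @param c number of clusters (>= 2; default 5, the number of temporal
#'   response classes distinguished in TLR4 time courses).
#' @param m fuzziness exponent (> 1); `NULL` uses [mEstimate()].
#' @param tol convergence tolerance on the center shift.
#' @param maxIter iteration cap; non-convergence is reported via the
#'   `converged` slot, not an error.
#' @param seed master seed for the restarts.
#' @param restarts number of seeded initializations.
#' @return a [FuzzyClusterResult-class] (no assignments yet; see
#'   [assignMembers()]).
#' @export
fuzzyCMeans <- function(z, c = 5L, m = NULL, tol = 1e-6, maxIter = 200L,
                        seed = 1L, restarts = 5L) {
  z <- as.matrix(z)
  if (c < 2L) stop("need at least 2 clusters")
  if (nrow(z) < c) stop("need at least as many genes as clusters")
  if (is.null(m)) m <- mEstimate(z)
  if (m <= 1) stop("fuzziness exponent must be > 1")
  best <- NULL; bestSeed <- NA_integer_
  for (r in seq_len(restarts)) {
    rs <- seedFanout(seed, paste0("fcm_restart_", r))
    run <- .fcmRun(z, c, m, tol, maxIter, rs)
    if (is.null(best) || min(run$obj) < min(best$obj)) {
      best <- run; bestSeed <- rs
    }
  }
  u <- best$u
  rownames(u) <- rownames(z)
  colnames(u) <- paste0("cluster_", seq_len(c))
  centers <- best$centers
  dimnames(centers) <- list(colnames(u), colnames(z))
  new("FuzzyClusterResult", membership = u, centers = centers, m = m,
      objective = best$obj, converged = best$converged, seed = bestSeed,
      threshold = NA_real_,
      assignments = data.frame(gene = character(), cluster = integer(),
                               membership = numeric()))
}

#' FuzzyClusterResult accessors
#'
#' @param x a `FuzzyClusterResult`.
#' @name FuzzyClusterResult-accessors
#' @aliases membershipMatrix clusterCenters clusterAssignments
NULL

#' @rdname FuzzyClusterResult-accessors
#' @export
setMethod("membershipMatrix", "FuzzyClusterResult",
          function(x) x@membership)

#' @rdname FuzzyClusterResult-accessors
#' @export
setMethod("clusterCenters", "FuzzyClusterResult", function(x) x@centers)

#' @rdname FuzzyClusterResult-accessors
#' @export
setMethod("clusterAssignments", "FuzzyClusterResult",
          function(x) x@assignments)

setMethod("show", "FuzzyClusterResult", function(object) {
  cat("FuzzyClusterResult: ", nrow(object@membership), " genes, ",
      ncol(object@membership), " clusters, m = ",
      round(object@m, 3), ", ", if (object@converged) "converged"
      else "NOT converged", " in ", length(object@objective),
      " iteration(s)\n", sep = "")
  if (nrow(object@assignments))
    cat("  ", nrow(object@assignments), " genes assigned at membership >= ",
        object@threshold, "\n", sep = "")
})

#' Threshold fuzzy memberships into hard cluster members
#'
#' A gene joins its argmax cluster if and only if its maximal membership
#' reaches `threshold` (boundary inclusive; the conventional cut is 0.3).
#' Ties go to the lowest cluster index and are reported.
#'
#' @param x a [FuzzyClusterResult-class].
#' @param threshold membership cut in (0, 1].
#' @return `x` with the `assignments` slot filled.
#' @export
assignMembers <- function(x, threshold = 0.3) {
  stopifnot(threshold > 0, threshold <= 1)
  u <- x@membership
  top <- apply(u, 1L, max)
  cl <- apply(u, 1L, which.max)
  ties <- rowSums(u == top) > 1L
  if (any(ties & top >= threshold))
    message(sum(ties & top >= threshold),
            " membership tie(s) broken toward the lowest cluster index")
  keep <- top >= threshold
  x@threshold <- threshold
  x@assignments <- data.frame(gene = rownames(u)[keep],
                              cluster = as.integer(cl[keep]),
                              membership = top[keep],
                              row.names = NULL)
  validObject(x)
  x
}

#' Project clusters onto another genotype's standardized profiles
#'
#' Clusters are defined on the reference genotype only and never re-fit;
#' this returns, for each cluster, the member genes' Z-profiles in a
#' second genotype (e.g. the knockout), plus per-cluster mean profiles for
#' both genotypes.  Genes missing from `other` are dropped with a warning.
#'
#' @param x an assigned [FuzzyClusterResult-class].
#' @param reference the standardized matrix the clusters were fit on.
#' @param other standardized matrix of the second genotype.
#' @return list with `profiles` (per-cluster matrices from `other`),
#'   `referenceMean` and `projectedMean` (cluster x timepoint matrices).
#' @export
projectGenotype <- function(x, reference, other) {
  a <- clusterAssignments(x)
  if (!nrow(a)) stop("no assigned genes; run assignMembers() first")
  missing <- setdiff(a$gene, rownames(other))
  if (length(missing)) {
    warning(length(missing), " assigned gene(s) missing from the ",
            "projection matrix were dropped")
    a <- a[!a$gene %in% missing, ]
  }
  nc <- ncol(membershipMatrix(x))
  profiles <- lapply(seq_len(nc), function(k) {
    g <- a$gene[a$cluster == k]
    other[g, , drop = FALSE]
  })
  names(profiles) <- colnames(membershipMatrix(x))
  meanOf <- function(mat) t(vapply(seq_len(nc), function(k) {
    g <- intersect(a$gene[a$cluster == k], rownames(mat))
    if (!length(g)) rep(NA_real_, ncol(mat))
    else colMeans(mat[g, , drop = FALSE])
  }, numeric(ncol(other))))
  list(profiles = profiles,
       referenceMean = meanOf(reference),
       projectedMean = meanOf(other))
}

#' Two-timepoint scatter report with fold-change guides
#'
#' For a gene list (typically one cluster's members), reports
#' `log2(count + pseudocount)` at two timepoints of one genotype and
#' classifies each gene against fold-change guide lines: `"up"` when
#' `count(t2)/count(t1) >= foldGuides`, `"down"` when the ratio is
#' `<= 1/foldGuides`, `"within"` otherwise (classification uses the raw
#' ratio; the pseudocount only stabilizes the log coordinates).
#'
#' @param x a `TimecourseCounts`.
#' @param genes gene ids to include.
#' @param t1,t2 timepoints to compare.
#' @param genotype genotype to read counts from.
#' @param foldGuides guide fold change (> 1).
#' @param pseudocount added inside the log2.
#' @return list with `points` (per-gene data.frame: gene, x, y, region)
#'   and `summary` (region counts).
#' @export
timepointScatter <- function(x, genes, t1, t2, genotype = "WT",
                             foldGuides = 1.5, pseudocount = 1) {
  cd <- colData(x)
  i1 <- which(cd$genotype == genotype & cd$timepoint == t1)
  i2 <- which(cd$genotype == genotype & cd$timepoint == t2)
  if (!length(i1) || !length(i2))
    stop("both timepoints must be present for genotype '", genotype, "'")
  m <- assay(x, "normcounts")[genes, c(i1[1L], i2[1L]), drop = FALSE]
  ratio <- ifelse(m[, 1L] > 0, m[, 2L] / m[, 1L],
                  ifelse(m[, 2L] > 0, Inf, 1))
  region <- ifelse(ratio >= foldGuides, "up",
                   ifelse(ratio <= 1 / foldGuides, "down", "within"))
  pts <- data.frame(gene = genes,
                    x = log2(m[, 1L] + pseudocount),
                    y = log2(m[, 2L] + pseudocount),
                    ratio = ratio, region = region, row.names = NULL)
  list(points = pts,
       summary = c(up = sum(region == "up"),
                   within = sum(region == "within"),
                   down = sum(region == "down")))
}
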