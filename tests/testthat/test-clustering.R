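## shared expression fixture; template recovery needs a few hundred genes
## to be meaningful, so this one is mid-sized
cfg <- simulationConfig(seed = 42L, chromSizes = c(chr1 = 1e6, chr2 = 1e6),
                        nGenes = 500L, nEnhancers = 50L)
genome <- generateGenome(cfg)
counts <- generateCounts(genome, cfg)
expressed <- filterExpressed(counts, "WT", 100)
zWT <- standardizeCounts(expressed, "WT")

test_that("filterExpressed keeps genes reaching the floor at any reference timepoint", {
  m <- rbind(g1 = c(99, 99, 99, 99, 5, 5, 5, 5),
             g2 = c(99, 100, 0, 0, 5, 5, 5, 5),
             g3 = c(500, 2, 2, 2, 5, 5, 5, 5))
  tc <- TimecourseCounts(m, genotype = rep(c("WT", "KO"), each = 4),
                         timepoint = rep(c(0, 6, 24, 48), 2))
  kept <- filterExpressed(tc, "WT", 100)
  expect_setequal(rownames(kept), c("g2", "g3"))
  ## all conditions of retained genes are kept
  expect_equal(ncol(kept), 8)
})

test_that("standardizeCounts yields exact population Z-scores and drops flat genes", {
  m <- rbind(gA = c(1, 2, 3, 4), gB = c(7, 7, 7, 7))
  tc <- TimecourseCounts(m, genotype = rep("WT", 4),
                         timepoint = c(0, 6, 24, 48))
  expect_warning(z <- standardizeCounts(tc, "WT"), "zero-variance")
  expect_equal(unname(z["gA", ]),
               c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
  expect_false("gB" %in% rownames(z))

  ## every row has mean 0 and population sd 1; idempotence
  expect_lt(max(abs(rowMeans(zWT))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(zWT^2)) - 1)), 1e-9)
  tc2 <- TimecourseCounts(zWT - min(zWT), genotype = rep("WT", ncol(zWT)),
                          timepoint = attr(zWT, "timepoints"))
  z2 <- standardizeCounts(tc2, "WT")
  expect_equal(unname(z2), unname(zWT + 0), tolerance = 1e-9)
})

test_that("fuzzy c-means separates well-separated clouds and matches hard k-means as m -> 1", {
  set.seed(11)
  cloud <- rbind(matrix(rnorm(150, 0, 0.2), ncol = 3) +
                   matrix(c(2, 0, -2), 50, 3, byrow = TRUE),
                 matrix(rnorm(150, 0, 0.2), ncol = 3) +
                   matrix(c(-2, 0, 2), 50, 3, byrow = TRUE))
  rownames(cloud) <- paste0("p", 1:100)
  res <- fuzzyCMeans(cloud, c = 2, m = 1.25, seed = 5L)
  u <- membershipMatrix(res)
  expect_true(all(apply(u, 1, max) > 0.95))
  hard <- apply(u, 1, which.max)
  expect_true(length(unique(hard[1:50])) == 1 &&
                length(unique(hard[51:100])) == 1 &&
                hard[1] != hard[100])

  ## near-hard fuzziness reproduces k-means partitioning
  resH <- fuzzyCMeans(cloud, c = 2, m = 1.05, seed = 5L)
  km <- kmeans(cloud, centers = clusterCenters(resH), iter.max = 50)
  expect_gte(mclust::adjustedRandIndex(
    apply(membershipMatrix(resH), 1, which.max), km$cluster), 1)
})

test_that("fuzzy c-means memberships are simplex-valued and the objective never increases", {
  res <- fuzzyCMeans(zWT, c = 5, seed = 7L)
  u <- membershipMatrix(res)
  expect_lt(max(abs(rowSums(u) - 1)), 1e-9)
  expect_true(all(u >= 0 & u <= 1))
  expect_true(all(diff(res@objective) <= 1e-8))
  expect_true(res@converged)
  ## preconditions
  expect_error(fuzzyCMeans(zWT, c = 1), "clusters")
  expect_error(fuzzyCMeans(zWT[1:3, ], c = 5), "as many genes")
  expect_error(fuzzyCMeans(zWT, c = 5, m = 1), "> 1")
})

test_that("fuzzy c-means agrees with an independent fuzzy clustering implementation", {
  skip_if_not_installed("e1071")
  ## seed the reference implementation with our converged centers: both
  ## must sit in the same optimum, with matching memberships
  res <- fuzzyCMeans(zWT, c = 5, m = 1.5, seed = 3L)
  ref <- e1071::cmeans(zWT, centers = clusterCenters(res), m = 1.5,
                       iter.max = 300)
  expect_equal(unname(ref$membership), unname(membershipMatrix(res)),
               tolerance = 1e-3)
  expect_equal(unname(ref$centers), unname(clusterCenters(res)),
               tolerance = 1e-3)
})

test_that("assignMembers applies an inclusive threshold with lowest-index ties", {
  u <- rbind(a = c(0.31, 0.29, 0.2, 0.1, 0.1),
             b = c(0.2, 0.2, 0.2, 0.2, 0.2),
             c = c(0.4, 0.4, 0.1, 0.05, 0.05))
  res <- new("FuzzyClusterResult", membership = u,
             centers = matrix(0, 5, 4), m = 2, objective = 1,
             converged = TRUE, seed = 1L, threshold = NA_real_,
             assignments = data.frame(gene = character(),
                                      cluster = integer(),
                                      membership = numeric()))
  expect_message(res <- assignMembers(res, 0.3), "tie")
  a <- clusterAssignments(res)
  expect_equal(a$gene, c("a", "c"))
  expect_equal(a$cluster, c(1L, 1L))
  expect_equal(a$membership[1], 0.31)
  expect_error(assignMembers(res, 0), "threshold")
})

test_that("assigned-gene count is monotone non-increasing in the threshold", {
  res <- fuzzyCMeans(zWT, c = 5, seed = 7L)
  sizes <- vapply(c(0.2, 0.3, 0.5, 0.7),
                  function(th) nrow(clusterAssignments(
                    assignMembers(res, th))), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("template recovery on planted five-template data reaches ARI >= 0.8", {
  res <- assignMembers(fuzzyCMeans(zWT, c = 5, seed = 7L), 0.3)
  a <- clusterAssignments(res)
  planted <- setNames(rowData(expressed)$template, rownames(expressed))
  expect_gte(mclust::adjustedRandIndex(a$cluster, planted[a$gene]), 0.8)
})

test_that("projection onto the knockout shifts the delayed cluster's peak from 6 to 24 h", {
  zKO <- standardizeCounts(expressed, "KO")
  res <- assignMembers(fuzzyCMeans(zWT, c = 5, seed = 7L), 0.3)
  proj <- projectGenotype(res, zWT, zKO)
  planted <- setNames(rowData(expressed)$template, rownames(expressed))
  a <- clusterAssignments(res)
  ## find the fitted cluster dominated by planted template 1
  dom <- vapply(seq_len(5), function(k) {
    g <- a$gene[a$cluster == k]
    mean(planted[g] == 1)
  }, numeric(1))
  k1 <- which.max(dom)
  expect_gt(dom[k1], 0.8)
  tp <- attr(zWT, "timepoints")
  expect_equal(tp[which.max(proj$referenceMean[k1, ])], 6)
  expect_equal(tp[which.max(proj$projectedMean[k1, ])], 24)

  ## projecting the reference onto itself is the identity
  projSelf <- projectGenotype(res, zWT, zWT)
  expect_equal(projSelf$projectedMean, projSelf$referenceMean)

  ## missing genes are dropped with a warning
  expect_warning(projectGenotype(res, zWT, zKO[-(1:3), ]), "missing")
})

test_that("timepointScatter classifies against fold guides exactly as a direct scan", {
  m <- rbind(gOn = c(100, 150), gFlat = c(100, 100), gUp = c(10, 100),
             gDown = c(100, 10))
  tc <- TimecourseCounts(m, genotype = c("WT", "WT"), timepoint = c(0, 6))
  sc <- timepointScatter(tc, rownames(m), 0, 6, foldGuides = 1.5)
  expect_equal(sc$points$region,
               c("up", "within", "up", "down"))  # 1.5-fold line inclusive
  expect_equal(sc$points$x[1], log2(101))
  expect_equal(sc$summary, c(up = 2, within = 1, down = 1))

  set.seed(21)
  mat <- matrix(rpois(400, 120), ncol = 2)
  rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  tc <- TimecourseCounts(mat, genotype = c("WT", "WT"),
                         timepoint = c(0, 6))
  sc <- timepointScatter(tc, rownames(mat), 0, 6, foldGuides = 1.2)
  ratio <- mat[, 2] / mat[, 1]
  expect_equal(unname(sc$summary["up"]), sum(ratio >= 1.2))
  expect_equal(unname(sc$summary["down"]), sum(ratio <= 1 / 1.2))
  expect_error(timepointScatter(tc, rownames(mat), 0, 99), "timepoints")
})
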