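# small planted cell population generator: disjoint 30-gene marker blocks
makePopulations <- function(n_pop = 3, n_cells = 100, n_genes = 300,
                            seed = 61) {
  set.seed(seed)
  prof <- sapply(seq_len(n_pop), function(k) {
    p <- rep(10, n_genes)
    p[((k - 1) * 30 + 1):(k * 30)] <- 80
    p / sum(p)
  })
  pop <- rep(seq_len(n_pop), each = n_cells)
  libs <- round(rlnorm(length(pop), log(2000), 0.2))
  cnt <- sapply(seq_along(pop), function(i) rmultinom(1, libs[i], prof[, pop[i]]))
  dimnames(cnt) <- list(paste0("g", seq_len(n_genes)),
                        paste0("c", seq_along(pop)))
  list(counts = cnt, pop = pop)
}

test_that("QC filtering removes exactly the failing cells", {
  cnt <- cbind(good1 = c(5L, 3L, 2L), good2 = c(8L, 0L, 4L),
               empty = c(0L, 0L, 0L), tiny = c(1L, 0L, 0L))
  rownames(cnt) <- paste0("g", 1:3)
  sce <- makeCellExperiment(cnt)
  f <- qcFilterCells(sce, min_counts = 1)
  expect_setequal(colnames(f), c("good1", "good2", "tiny"))
  expect_equal(S4Vectors::metadata(f)$qc$removed_barcodes, "empty")
  ## wide-open thresholds are the identity
  f2 <- qcFilterCells(sce, min_genes = 0, max_genes = Inf, min_counts = 0)
  expect_identical(colnames(f2), colnames(sce))
  expect_error(qcFilterCells(sce, min_counts = 100), "all cells")

  ## the synthetic seed's planted empty barcodes are exactly the removals
  cells <- fixtureCells()
  filt <- qcFilterCells(cells$sce, min_counts = 100)
  planted <- names(cells$truth$true_labels)[
    cells$truth$true_labels == "empty"]
  expect_setequal(S4Vectors::metadata(filt)$qc$removed_barcodes, planted)
})

test_that("normalization is median-library log1p with scale invariance", {
  cnt <- cbind(a = c(0L, 10L, 30L), b = c(5L, 15L, 20L), c = c(2L, 8L, 30L))
  rownames(cnt) <- paste0("g", 1:3)
  sce <- normalizeCells(makeCellExperiment(cnt))
  norm <- SummarizedExperiment::assay(sce, "logcounts")
  expect_equal(norm["g1", "a"], 0)   # zeros stay zero
  ## doubling one cell's counts leaves its normalized vector unchanged
  cnt2 <- cnt; cnt2[, "a"] <- cnt2[, "a"] * 2L
  norm2 <- SummarizedExperiment::assay(normalizeCells(makeCellExperiment(cnt2)),
                                       "logcounts")
  expect_equal(as.numeric(norm2[, "a"]), as.numeric(norm[, "a"]),
               tolerance = 1e-12)
  ## equal libraries: value = log1p(count)
  eq <- cbind(a = c(1L, 3L), b = c(2L, 2L), d = c(0L, 4L))
  rownames(eq) <- c("g1", "g2")
  ne <- SummarizedExperiment::assay(normalizeCells(makeCellExperiment(eq)),
                                    "logcounts")
  expect_equal(as.matrix(ne), log1p(as.matrix(eq) * 1.0), ignore_attr = TRUE)
  ## zero-library cell rejected
  z <- cbind(a = c(1L, 1L), b = c(0L, 0L))
  rownames(z) <- c("g1", "g2")
  expect_error(normalizeCells(makeCellExperiment(z)), "zero-library")
})

test_that("graph clustering recovers planted populations deterministically", {
  pops <- makePopulations()
  sce <- normalizeCells(makeCellExperiment(pops$counts))
  sce <- clusterCells(sce, n_pcs = 20, resolution = 1.0, seed = 7)
  lab <- SummarizedExperiment::colData(sce)$cluster
  expect_gte(ari(pops$pop, lab), 0.95)
  expect_equal(length(unique(lab)), 3)
  ## identical rerun with the same seed
  sce2 <- clusterCells(sce, n_pcs = 20, resolution = 1.0, seed = 7)
  expect_identical(lab, SummarizedExperiment::colData(sce2)$cluster)
  ## parameters are recorded
  p <- S4Vectors::metadata(sce)$clustering
  expect_equal(p$n_pcs, 20)
  expect_equal(p$seed, 7)
  expect_error(clusterCells(sce[, 1:15], n_pcs = 20), "more cells")
})

test_that("identical cells collapse into a single cluster", {
  cnt <- matrix(rep(c(5L, 3L, 8L, 0L, 2L), 100), 5, 100)
  dimnames(cnt) <- list(paste0("g", 1:5), paste0("c", 1:100))
  sce <- normalizeCells(makeCellExperiment(cnt))
  sce <- clusterCells(sce, n_pcs = 2, n_hvg = 5, seed = 1)
  expect_equal(length(unique(SummarizedExperiment::colData(sce)$cluster)), 1)
})

test_that("subclustering divides planted subtypes and nothing else", {
  pops <- makePopulations()
  sce <- normalizeCells(makeCellExperiment(pops$counts))
  sce <- clusterCells(sce, n_pcs = 20, seed = 7)
  ## force populations 1+2 into one cluster labeled "5"
  lab <- ifelse(pops$pop <= 2, "5", "9")
  SummarizedExperiment::colData(sce)$cluster <- lab
  sub <- subclusterCells(sce, "5", resolution = 0.5, seed = 7)
  labSub <- SummarizedExperiment::colData(sub)$cluster
  expect_setequal(unique(labSub[pops$pop <= 2]), c("5a", "5b"))
  expect_gte(ari(pops$pop[pops$pop <= 2], labSub[pops$pop <= 2]), 0.95)
  ## labels outside the target cluster are untouched
  expect_identical(labSub[pops$pop == 3], lab[pops$pop == 3])
  ## a homogeneous cluster at low resolution comes back unchanged
  sub2 <- subclusterCells(sub, "9", resolution = 0.1, seed = 7)
  expect_identical(SummarizedExperiment::colData(sub2)$cluster, labSub)
  expect_error(subclusterCells(sce, "nope"), "unknown cluster")
})

test_that("marker detection applies the test and all three filters", {
  ## perfect separation: 50 in-cluster cells express, 450 do not
  set.seed(62)
  n <- 500
  cnt <- matrix(rpois(20 * n, 3), 20, n,
                dimnames = list(paste0("g", 1:20), paste0("c", 1:n)))
  cnt["g1", ] <- 0L
  cnt["g1", 1:50] <- rpois(50, 8) + 1L
  lab <- rep(c("A", "B"), c(50, 450))
  sce <- normalizeCells(makeCellExperiment(cnt))
  SummarizedExperiment::colData(sce)$cluster <- lab
  mk <- findMarkers(sce)
  row <- mk[mk$gene == "g1" & mk$cluster == "A", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$pct_in, 1.0)
  expect_equal(row$pct_out, 0.0)
  ## uniform genes yield no marker record
  expect_false(any(mk$gene != "g1"))
  ## every emitted row satisfies the filters
  expect_true(all(mk$log2FC >= 1 & mk$adj_p < 0.05 & mk$pct_in >= 0.25))
})

test_that("marker p-values equal exact rank-sum enumeration for 4v4", {
  vals <- c(5.2, 3.1, 4.8, 6.0, 1.2, 0.4, 2.2, 0.9)
  cnt <- rbind(g1 = as.integer(round(vals * 10)), g2 = rep(3L, 8))
  colnames(cnt) <- paste0("c", 1:8)
  sce <- normalizeCells(makeCellExperiment(cnt))
  SummarizedExperiment::colData(sce)$cluster <- rep(c("A", "B"), each = 4)
  norm <- SummarizedExperiment::assay(sce, "logcounts")
  mk <- findMarkers(sce, lfc_min = 0, alpha = 1.1)
  row <- mk[mk$gene == "g1" & mk$cluster == "A", ]
  expect_equal(row$p, rankSumOracle(as.numeric(norm["g1", 1:4]),
                                    as.numeric(norm["g1", 5:8])))
  ## fold convention: de-logged means with unit pseudocount
  expIn <- mean(expm1(norm["g1", 1:4])); expOut <- mean(expm1(norm["g1", 5:8]))
  expect_equal(row$log2FC, log2((expIn + 1) / (expOut + 1)))
})

test_that("planted markers in the synthetic seed are recovered", {
  mk <- fixtureMarkers()
  expect_true(all(mk$log2FC >= 1 & mk$adj_p < 0.05 & mk$pct_in >= 0.25))
  truth <- fixtureCells()$truth
  cmap <- fixtureClusterMap()
  prec <- rec <- plantedRec <- c()
  for (cl in names(cmap)) {
    if (cmap[[cl]] == "ambiguous") {
      expect_equal(sum(mk$cluster == cl), 0)
      next
    }
    got <- mk$gene[mk$cluster == cl]
    expected <- truth$expected_markers[[cmap[[cl]]]]
    prec <- c(prec, mean(got %in% expected))
    rec <- c(rec, mean(expected %in% got))
    plantedRec <- c(plantedRec,
                    mean(truth$planted_markers[[cmap[[cl]]]] %in% got))
  }
  expect_gte(min(plantedRec), 0.9)
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})

test_that("pseudobulk sums counts and conserves totals", {
  cnt <- cbind(c1 = c(1L, 2L), c2 = c(3L, 4L))
  rownames(cnt) <- c("g1", "g2")
  sce <- makeCellExperiment(cnt)
  pb <- pseudobulk(sce)
  expect_equal(as.numeric(pb), c(4, 6))
  SummarizedExperiment::colData(sce)$cluster <- c("A", "B")
  per <- pseudobulk(sce, by_cluster = TRUE)
  expect_equal(rowSums(per), pb[, 1])
  expect_warning(z <- pseudobulk(sce, by_cluster = TRUE,
                                 clusters = c("A", "B", "C")),
                 "empty cluster")
  expect_equal(unname(z[, "C"]), c(0, 0))
})
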