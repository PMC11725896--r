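## Single-nucleus workflow: QC, median-library log normalization, PCA/SNN
## graph clustering with Leiden community detection, subclustering, marker
## detection, pseudobulk.

#' Build a SingleCellExperiment from a cell count matrix
#'
#' @param counts gene x cell count matrix (barcodes as colnames).
#' @return `SingleCellExperiment` with assay `counts`.
#' @export
makeCellExperiment <- function(counts) {
  .checkCounts(counts)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
}

#' Filter cells on detected-gene and total-count thresholds
#'
#' Removes cells whose number of detected genes lies outside
#' `[min_genes, max_genes]` or whose total count falls below `min_counts`.
#'
#' @param sce `SingleCellExperiment` with assay `counts`.
#' @param min_genes,max_genes detected-gene bounds (defaults 1, Inf).
#' @param min_counts total-count lower bound (default 1).
#' @return filtered `SingleCellExperiment`; the removal report is in
#'   `metadata(sce)$qc`.
#' @export
qcFilterCells <- function(sce, min_genes = 1, max_genes = Inf, min_counts = 1) {
  stopifnot(min_genes >= 0, max_genes >= min_genes, min_counts >= 0)
  counts <- SummarizedExperiment::assay(sce, "counts")
  nGenes <- Matrix::colSums(counts > 0)
  nCounts <- Matrix::colSums(counts)
  keep <- nGenes >= min_genes & nGenes <= max_genes & nCounts >= min_counts
  if (!any(keep)) stop("all cells removed by QC thresholds")
  out <- sce[, keep]
  S4Vectors::metadata(out)$qc <- list(
    n_removed = sum(!keep), removed_barcodes = colnames(sce)[!keep],
    thresholds = c(min_genes = min_genes, max_genes = max_genes,
                   min_counts = min_counts))
  out
}

#' Median-library log normalization
#'
#' `log1p(count / cell_library_size * median_library_size)`: cells are
#' scaled to the median library size before the log transform, so doubling
#' a cell's counts leaves its normalized vector unchanged. Zeros stay zero.
#'
#' @param sce `SingleCellExperiment` with assay `counts`; no zero-library
#'   cells (QC first).
#' @return `sce` with an added `logcounts` assay.
#' @export
normalizeCells <- function(sce) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  lib <- Matrix::colSums(counts)
  if (any(lib == 0))
    stop("zero-library cell(s): ",
         paste(head(colnames(counts)[lib == 0], 5), collapse = ", "),
         " (run qcFilterCells first)")
  sf <- median(lib) / lib
  norm <- counts %*% Matrix::Diagonal(x = sf)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  sce
}

## top variable genes by mean-binned standardized dispersion (var/mean of
## the normalized values, z-scored within 20 mean bins)
.variableGenes <- function(norm, n = 2000) {
  m <- Matrix::rowMeans(norm)
  v <- Matrix::rowMeans(norm^2) - m^2
  disp <- ifelse(m > 0, v / m, 0)
  bins <- cut(rank(m, ties.method = "first"), 20)
  z <- unsplit(lapply(split(disp, bins), function(d) {
    s <- sd(d)
    if (is.na(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
  }), bins)
  rownames(norm)[order(-z)][seq_len(min(n, sum(m > 0)))]
}

## shared-nearest-neighbor graph: k nearest neighbors (self included, as in
## the usual SNN construction), Jaccard weights, pruned below `prune`
.snnGraph <- function(scores, k = 20, prune = 1 / 15) {
  n <- nrow(scores)
  if (n <= k) stop("fewer cells than k neighbors")
  d <- as.matrix(dist(scores))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared / (2 * k - shared)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Cluster cells on a PCA embedding with SNN + Leiden
#'
#' Standardizes the top `n_hvg` variable genes over cells, takes the top
#' `n_pcs` principal components, builds a shared-nearest-neighbor graph
#' (k = 20, Jaccard weights, pruned at 1/15) and partitions it with Leiden
#' modularity optimization at the given resolution. Deterministic for a
#' fixed seed.
#'
#' @param sce normalized `SingleCellExperiment` (see [normalizeCells()]).
#' @param n_pcs number of principal components (default 30).
#' @param resolution Leiden resolution (default 1.0).
#' @param seed RNG seed recorded with the labeling.
#' @param n_hvg number of highly variable genes for the embedding.
#' @param k neighbors for the SNN graph.
#' @return `sce` with `colData$cluster` (character ids `"0"`, `"1"`, ... in
#'   decreasing size order), the embedding in `reducedDim(sce, "PCA")`, and
#'   parameters in `metadata(sce)$clustering`.
#' @export
clusterCells <- function(sce, n_pcs = 30, resolution = 1.0, seed = 0,
                         n_hvg = 2000, k = 20) {
  norm <- SummarizedExperiment::assay(sce, "logcounts")
  if (ncol(norm) < n_pcs + 1) stop("need more cells than principal components")
  hvg <- .variableGenes(norm, n_hvg)
  mat <- t(as.matrix(norm[hvg, , drop = FALSE]))
  mat <- scale(mat)
  mat[is.na(mat)] <- 0
  attr(mat, "scaled:center") <- attr(mat, "scaled:scale") <- NULL
  mat[mat > 10] <- 10
  pca <- prcomp(mat, center = FALSE, rank. = n_pcs)
  scores <- pca$x
  g <- .snnGraph(scores, k = k)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  mem <- igraph::membership(cl)
  ord <- order(-table(mem))
  relab <- setNames(as.character(seq_along(ord) - 1L), names(table(mem))[ord])
  labels <- relab[as.character(mem)]
  SummarizedExperiment::colData(sce)$cluster <- unname(labels)
  SingleCellExperiment::reducedDim(sce, "PCA") <- scores
  S4Vectors::metadata(sce)$clustering <- list(
    n_pcs = n_pcs, resolution = resolution, seed = seed, k = k,
    n_hvg = length(hvg))
  sce
}

#' Subcluster one cluster on the existing embedding
#'
#' Re-clusters only the cells of `cluster_id`, reusing the stored PCA
#' embedding; resulting children are labeled `"<id>a"`, `"<id>b"`, ... in
#' decreasing size order. All other labels are untouched. When the cells
#' form a single community at the given resolution the labeling is returned
#' unchanged.
#'
#' @param sce clustered `SingleCellExperiment` from [clusterCells()].
#' @param cluster_id cluster to divide.
#' @param resolution Leiden resolution for the subdivision.
#' @param seed RNG seed.
#' @return `sce` with updated `colData$cluster`.
#' @export
subclusterCells <- function(sce, cluster_id, resolution = 1.0, seed = 0) {
  labels <- SummarizedExperiment::colData(sce)$cluster
  idx <- which(labels == cluster_id)
  if (!length(idx)) stop("unknown cluster_id: ", cluster_id)
  scores <- SingleCellExperiment::reducedDim(sce, "PCA")[idx, , drop = FALSE]
  k <- min(20, length(idx) - 1L)
  g <- .snnGraph(scores, k = k)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  mem <- igraph::membership(cl)
  if (length(unique(mem)) > 1L) {
    ord <- order(-table(mem))
    relab <- setNames(letters[seq_along(ord)], names(table(mem))[ord])
    labels[idx] <- paste0(cluster_id, relab[as.character(mem)])
    SummarizedExperiment::colData(sce)$cluster <- labels
  }
  sce
}

#' Detect positive cluster markers (one-vs-rest Wilcoxon)
#'
#' Per cluster, genes expressed in at least `min_pct` of in-cluster cells
#' *or* `min_pct` of out-cluster cells are tested with a two-sided Wilcoxon
#' rank-sum test on normalized values; p-values are BH-adjusted over the
#' tested genes of that cluster. Reported markers are positive and satisfy
#' `log2_fold_change >= lfc_min`, `adj_p < alpha` and `pct_in >= min_pct`.
#' The fold change is computed on the de-logged scale:
#' `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`.
#'
#' @param sce clustered, normalized `SingleCellExperiment`.
#' @param min_pct expression-fraction gate (default 0.25).
#' @param lfc_min minimum log2 fold change (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return `data.frame`: cluster, gene, log2FC, pct_in, pct_out, p, adj_p.
#' @export
findMarkers <- function(sce, min_pct = 0.25, lfc_min = 1, alpha = 0.05) {
  labels <- SummarizedExperiment::colData(sce)$cluster
  norm <- SummarizedExperiment::assay(sce, "logcounts")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stop("need >= 2 clusters")
  out <- list()
  for (cl in clusters) {
    inIdx <- labels == cl
    if (sum(inIdx) < 3L) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    inMat <- as.matrix(norm[, inIdx, drop = FALSE])
    outMat <- as.matrix(norm[, !inIdx, drop = FALSE])
    pctIn <- rowMeans(inMat > 0)
    pctOut <- rowMeans(outMat > 0)
    test <- which(pctIn >= min_pct | pctOut >= min_pct)
    if (!length(test)) next
    lfc <- log2((rowMeans(expm1(inMat[test, , drop = FALSE])) + 1) /
                (rowMeans(expm1(outMat[test, , drop = FALSE])) + 1))
    p <- vapply(test, function(i)
      suppressWarnings(wilcox.test(inMat[i, ], outMat[i, ])$p.value),
      numeric(1))
    adj <- p.adjust(p, "BH")
    keep <- lfc >= lfc_min & adj < alpha & pctIn[test] >= min_pct
    if (!any(keep)) next
    out[[cl]] <- data.frame(
      cluster = cl, gene = rownames(norm)[test][keep],
      log2FC = lfc[keep], pct_in = pctIn[test][keep],
      pct_out = pctOut[test][keep], p = p[keep], adj_p = adj[keep],
      row.names = NULL)
  }
  if (!length(out))
    return(data.frame(cluster = character(), gene = character(),
                      log2FC = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p = numeric(), adj_p = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pseudobulk raw-count profiles
#'
#' Sums raw counts over all cells (single column `pseudobulk`) or over the
#' cells of each cluster when labels are given. Empty clusters yield a zero
#' column with a warning.
#'
#' @param sce `SingleCellExperiment` with assay `counts`.
#' @param by_cluster sum per cluster (`colData$cluster`) instead of overall.
#' @param clusters optional explicit cluster ids (may include clusters with
#'   no cells).
#' @return gene x column matrix of summed counts.
#' @export
pseudobulk <- function(sce, by_cluster = FALSE, clusters = NULL) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (!by_cluster) {
    out <- matrix(Matrix::rowSums(counts), ncol = 1,
                  dimnames = list(rownames(counts), "pseudobulk"))
    return(out)
  }
  labels <- SummarizedExperiment::colData(sce)$cluster
  if (is.null(clusters)) clusters <- sort(unique(labels))
  out <- vapply(clusters, function(cl) {
    idx <- labels == cl
    if (!any(idx)) {
      warning("empty cluster ", cl)
      return(numeric(nrow(counts)))
    }
    Matrix::rowSums(counts[, idx, drop = FALSE])
  }, numeric(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}
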