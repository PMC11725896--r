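## Bulk / single-nucleus integration: hypergeometric overlap enrichment,
## cluster-to-subregion assignment, module projection onto clusters, and
## rank-correlation comparisons.

#' Hypergeometric overlap enrichment of two gene sets
#'
#' One-sided enrichment p-value `P(X >= overlap)` for drawing `|A|` genes
#' from a finite background containing `|B|` successes, plus the odds ratio
#' of the 2x2 table (Haldane 0.5 correction when any cell is zero).
#'
#' @param set_a,set_b character vectors of gene ids, subsets of
#'   `background`.
#' @param background character vector: the explicit finite gene universe.
#' @return list with set sizes, background_size, overlap, odds_ratio,
#'   p_value.
#' @export
overlapEnrichment <- function(set_a, set_b, background) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  background <- unique(background)
  out <- setdiff(c(set_a, set_b), background)
  if (length(out))
    stop("gene(s) outside background: ", paste(head(out, 5), collapse = ", "))
  N <- length(background)
  a <- length(set_a); b <- length(set_b)
  ov <- length(intersect(set_a, set_b))
  p <- phyper(ov - 1, b, N - b, a, lower.tail = FALSE)
  tab <- c(ov, a - ov, b - ov, N - a - b + ov)
  if (any(tab == 0)) tab <- tab + 0.5
  orr <- (tab[1] * tab[4]) / (tab[2] * tab[3])
  list(set_a_size = a, set_b_size = b, background_size = N, overlap = ov,
       odds_ratio = orr, p_value = p)
}

#' Assign single-nucleus clusters to seed subregions
#'
#' Each cluster's marker genes are tested for overlap enrichment against
#' every subregion's specific mRNA set over an explicit background
#' (conventionally the intersection of bulk-detected and single-nucleus-
#' expressed genes). q-values are BH over subregions within a cluster; the
#' assigned subregion is the argmax of -log10 q among subregions with
#' `q < q_threshold` (ties broken by odds ratio, then lexicographic id), or
#' `NA` when none qualify. All other subregions with `q < q_threshold` are
#' listed as secondary assignments.
#'
#' @param marker_sets named list: cluster -> character vector of marker
#'   genes.
#' @param specific_sets named list: subregion -> character vector of
#'   specific genes.
#' @param background explicit gene universe; marker and specific genes
#'   outside it are dropped before testing.
#' @param q_threshold assignment threshold (default 0.05).
#' @return list with `assignments` (data.frame: cluster,
#'   assigned_subregion, q, odds_ratio, confidence, secondary, reason) and
#'   `enrichment` (long data.frame of every cluster x subregion test).
#' @export
assignClusters <- function(marker_sets, specific_sets, background,
                           q_threshold = 0.05) {
  background <- unique(background)
  specific_sets <- lapply(specific_sets, intersect, background)
  rows <- list(); asg <- list()
  for (cl in names(marker_sets)) {
    mk <- intersect(unique(marker_sets[[cl]]), background)
    if (!length(mk)) {
      asg[[cl]] <- data.frame(cluster = cl, assigned_subregion = NA_character_,
                              q = NA_real_, odds_ratio = NA_real_,
                              confidence = NA_real_, secondary = "",
                              reason = "empty marker set")
      next
    }
    st <- lapply(names(specific_sets), function(s) {
      o <- overlapEnrichment(mk, specific_sets[[s]], background)
      data.frame(cluster = cl, subregion = s, overlap = o$overlap,
                 set_a_size = o$set_a_size, set_b_size = o$set_b_size,
                 odds_ratio = o$odds_ratio, p = o$p_value)
    })
    st <- do.call(rbind, st)
    st$q <- p.adjust(st$p, "BH")
    rows[[cl]] <- st
    score <- -log10(st$q)
    ord <- order(-score, -st$odds_ratio, st$subregion)
    best <- ord[1]; second <- if (nrow(st) > 1) ord[2] else NA
    if (st$q[best] < q_threshold) {
      conf <- if (!is.na(second)) {
        if (score[second] == 0) Inf else score[best] / score[second]
      } else Inf
      sec <- setdiff(st$subregion[st$q < q_threshold], st$subregion[best])
      asg[[cl]] <- data.frame(cluster = cl,
                              assigned_subregion = st$subregion[best],
                              q = st$q[best], odds_ratio = st$odds_ratio[best],
                              confidence = conf,
                              secondary = paste(sec, collapse = ","),
                              reason = "")
    } else {
      asg[[cl]] <- data.frame(cluster = cl, assigned_subregion = NA_character_,
                              q = st$q[best], odds_ratio = st$odds_ratio[best],
                              confidence = NA_real_, secondary = "",
                              reason = "no subregion with q below threshold")
    }
  }
  list(assignments = do.call(rbind, c(asg, list(make.row.names = FALSE))),
       enrichment = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Project a coexpression module onto single-nucleus clusters
#'
#' The per-cell module score is the mean normalized expression over the
#' module genes present in the cell matrix; cluster-level z-scores are
#' `(cluster mean - overall mean) / overall sd` of the per-cell scores.
#' Clusters with `z >= z_enriched` are called enriched.
#'
#' @param sce clustered, normalized `SingleCellExperiment`.
#' @param members module gene ids (absent genes dropped with a warning).
#' @param z_enriched enrichment threshold on the cluster z-score.
#' @return list with `per_cell_score`, `per_cluster_mean`, `per_cluster_z`,
#'   `enriched_clusters`, `n_genes_used`.
#' @export
projectModule <- function(sce, members, z_enriched = 1.5) {
  norm <- SummarizedExperiment::assay(sce, "logcounts")
  present <- intersect(unique(members), rownames(norm))
  if (!length(present)) stop("no module gene present in the cell matrix")
  if (length(present) < length(unique(members)))
    warning(length(unique(members)) - length(present),
            " module gene(s) absent from the cell matrix")
  score <- Matrix::colMeans(norm[present, , drop = FALSE])
  labels <- SummarizedExperiment::colData(sce)$cluster
  clMean <- tapply(score, labels, mean)
  z <- (clMean - mean(score)) / sd(score)
  list(per_cell_score = score,
       per_cluster_mean = clMean,
       per_cluster_z = z,
       enriched_clusters = names(z)[z >= z_enriched],
       n_genes_used = length(present))
}

#' Spearman correlation of cluster pseudobulk against subregion profiles
#'
#' Computed on the shared genes of both matrices after CPM and log2(x+1)
#' transformation; genes zero in both members of a pair are excluded from
#' that pair.
#'
#' @param cluster_pseudobulk gene x cluster summed-count matrix
#'   ([pseudobulk()]).
#' @param subregion_profiles gene x group CPM matrix
#'   ([expressionProfile()]).
#' @param shared_genes optional explicit gene universe; defaults to the
#'   rowname intersection (>= 10 genes required).
#' @return numeric clusters x subregions matrix of Spearman rho.
#' @export
clusterSubregionCorrelation <- function(cluster_pseudobulk, subregion_profiles,
                                        shared_genes = NULL) {
  if (is.null(shared_genes))
    shared_genes <- intersect(rownames(cluster_pseudobulk),
                              rownames(subregion_profiles))
  if (length(shared_genes) < 10) stop("fewer than 10 shared genes")
  pb <- log2(countsPerMillion(cluster_pseudobulk[shared_genes, , drop = FALSE]) + 1)
  pr <- log2(subregion_profiles[shared_genes, , drop = FALSE] + 1)
  rho <- matrix(NA_real_, ncol(pb), ncol(pr),
                dimnames = list(colnames(pb), colnames(pr)))
  for (i in seq_len(ncol(pb))) for (j in seq_len(ncol(pr))) {
    keep <- pb[, i] > 0 | pr[, j] > 0
    rho[i, j] <- cor(pb[keep, i], pr[keep, j], method = "spearman")
  }
  rho
}

#' Global pseudobulk vs whole-seed bulk comparison
#'
#' Spearman rho over shared genes of log2(CPM + 1) values, plus the
#' per-gene table behind the scatter plot.
#'
#' @param pb single-column pseudobulk count matrix ([pseudobulk()]).
#' @param bulk single-column (or vector) whole-seed count profile.
#' @param min_shared minimum number of shared genes (default 100).
#' @return list with `rho` and `table` (gene, log2cpm_bulk,
#'   log2cpm_pseudobulk).
#' @export
pseudobulkVsBulk <- function(pb, bulk, min_shared = 100) {
  if (is.null(dim(bulk))) bulk <- matrix(bulk, ncol = 1,
                                         dimnames = list(names(bulk), "bulk"))
  shared <- intersect(rownames(pb), rownames(bulk))
  if (length(shared) < min_shared)
    stop("fewer than ", min_shared, " shared genes")
  x <- log2(countsPerMillion(bulk[shared, , drop = FALSE])[, 1] + 1)
  y <- log2(countsPerMillion(pb[shared, , drop = FALSE])[, 1] + 1)
  list(rho = cor(x, y, method = "spearman"),
       table = data.frame(gene = shared, log2cpm_bulk = x,
                          log2cpm_pseudobulk = y, row.names = NULL))
}
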