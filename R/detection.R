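#' Counts per million
#'
#' Library-size normalization: each column is scaled to sum to one million.
#' Columns with zero library size are an error (named in the message).
#'
#' @param counts gene x column count matrix.
#' @return dense numeric matrix of CPM values.
#' @examples
#' countsPerMillion(matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "s")))
#' @export
countsPerMillion <- function(counts) {
  lib <- Matrix::colSums(counts)
  if (any(lib == 0))
    stop("zero library size in column(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  out <- as.matrix(sweep(as.matrix(counts), 2, lib, "/")) * 1e6
  dimnames(out) <- dimnames(counts)
  out
}

#' Call detected genes per subregion x stage group
#'
#' Two detection rules are provided. `all_replicates_nonzero` (used for LCM
#' subregion libraries) calls a gene detected in a group when every
#' biological replicate has at least one raw count. `cpm_threshold` (used for
#' whole-seed libraries) calls a gene detected when its replicate-averaged
#' CPM exceeds `threshold`; the default 0.0978 is the average CPM equivalent
#' of one raw count in the subregion libraries.
#'
#' @param se `SummarizedExperiment` from [makeBulkExperiment()].
#' @param rule `"all_replicates_nonzero"` or `"cpm_threshold"`.
#' @param threshold CPM threshold for the `cpm_threshold` rule.
#' @return logical gene x group matrix with attribute `rule`.
#' @export
detectGenes <- function(se, rule = c("all_replicates_nonzero", "cpm_threshold"),
                        threshold = 0.0978) {
  rule <- match.arg(rule)
  counts <- SummarizedExperiment::assay(se, "counts")
  groups <- .groupIds(SummarizedExperiment::colData(se))
  if (any(table(groups) < 1L)) stop("group without replicates")
  gs <- sort(unique(groups))
  if (rule == "all_replicates_nonzero") {
    det <- vapply(gs, function(g) {
      sub <- counts[, groups == g, drop = FALSE]
      apply(as.matrix(sub) >= 1, 1, all)
    }, logical(nrow(counts)))
  } else {
    cpm <- countsPerMillion(counts)
    det <- .groupMeans(cpm, groups) > threshold
  }
  dimnames(det) <- list(rownames(counts), gs)
  attr(det, "rule") <- rule
  det
}

#' Summarize detection calls across groups
#'
#' @param detected logical gene x group matrix from [detectGenes()].
#' @return list with `per_group_count`, `mean_over_groups`, `union_count`
#'   (genes detected in >= 1 group) and `intersection_count` (genes detected
#'   in all groups).
#' @export
detectionSummary <- function(detected) {
  if (ncol(detected) < 1L) stop("need at least one group")
  per <- colSums(detected)
  list(per_group_count = per,
       mean_over_groups = mean(per),
       union_count = sum(rowSums(detected) >= 1L),
       intersection_count = sum(rowSums(detected) == ncol(detected)))
}

#' Replicate-averaged CPM expression profile per group
#'
#' Group-level prevalence is the arithmetic mean of per-replicate CPM values
#' (`average_cpm`), or alternatively the CPM of replicate-summed counts
#' (`cpm_of_sums`); the two differ when library sizes vary between
#' replicates.
#'
#' @param se `SummarizedExperiment` with bulk counts.
#' @param method averaging convention, see above.
#' @return numeric gene x group matrix of CPM.
#' @export
expressionProfile <- function(se, method = c("average_cpm", "cpm_of_sums")) {
  method <- match.arg(method)
  counts <- SummarizedExperiment::assay(se, "counts")
  groups <- .groupIds(SummarizedExperiment::colData(se))
  if (method == "average_cpm") {
    .groupMeans(countsPerMillion(counts), groups)
  } else {
    gs <- sort(unique(groups))
    summed <- vapply(gs, function(g)
      Matrix::rowSums(counts[, groups == g, drop = FALSE]),
      numeric(nrow(counts)))
    countsPerMillion(summed)
  }
}

#' Compare prevalence of a gene subset against all other detected genes
#'
#' Within one group, restricts to detected genes, then compares CPM of the
#' subset (e.g. transcription-factor mRNAs) against the complement with a
#' two-sided Mann-Whitney rank test.
#'
#' @param profile gene x group CPM matrix from [expressionProfile()].
#' @param subset character vector of gene ids.
#' @param group group id (a `profile` column).
#' @param detected optional logical gene x group matrix; when given, only
#'   genes detected in `group` enter the comparison.
#' @return list with `median_subset`, `median_all` (complement median) and
#'   `p`.
#' @export
comparePrevalence <- function(profile, subset, group, detected = NULL) {
  vals <- profile[, group]
  if (!is.null(detected)) vals <- vals[detected[names(vals), group]]
  inset <- names(vals) %in% subset
  if (!any(inset)) stop("subset empty after detection filter")
  if (all(inset)) stop("complement empty")
  wt <- wilcox.test(vals[inset], vals[!inset], alternative = "two.sided")
  list(median_subset = median(vals[inset]),
       median_all = median(vals[!inset]),
       p = wt$p.value)
}
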