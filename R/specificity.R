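## Negative-binomial machinery for subregion-specificity calls.
## Counts are first placed on a common library scale ("pseudodata"), group
## sums are compared with a conditional NB exact test, and dispersions come
## from a moment estimator shrunk toward a mean-dispersion trend.

.pseudoCounts <- function(counts, lib = Matrix::colSums(counts)) {
  ref <- exp(mean(log(lib)))
  round(sweep(as.matrix(counts), 2, ref / lib, "*"))
}

## per-gene conditional log-likelihood of a common dispersion given the
## group sums (equal-library replicates): free of the group means, so it
## stays well calibrated at 2-3 replicates where plug-in moment estimators
## bias low. Single-replicate groups contribute nothing and drop out.
.condLogLik <- function(phi, counts, groups) {
  r <- 1 / phi
  tot <- numeric(nrow(counts))
  for (g in unique(groups)) {
    sub <- counts[, groups == g, drop = FALSE]
    n <- ncol(sub)
    if (n < 2L) next
    z <- rowSums(sub)
    tot <- tot + rowSums(lgamma(sub + r)) - n * lgamma(r) +
      lgamma(n * r) - lgamma(z + n * r)
  }
  tot
}

#' Estimate per-gene negative-binomial dispersion
#'
#' Conditional maximum likelihood on equal-library pseudodata: the
#' likelihood of the replicates given their group sum does not involve the
#' group mean, which keeps the estimator calibrated at 2-3 replicates.
#' A trend is fit by maximizing the pooled conditional likelihood within
#' `n_bins` abundance bins; per-gene estimates are shrunk toward the trend
#' with prior weight `prior_df` against the gene's residual degrees of
#' freedom, and floored at `floor`. Genes without within-group variation sit
#' at the floor.
#'
#' @param counts gene x sample count matrix.
#' @param groups character/factor of group membership per column.
#' @param prior_df prior degrees of freedom of the trend (shrinkage
#'   strength); the per-gene estimate keeps weight equal to its residual df.
#' @param floor lower bound on any dispersion estimate.
#' @param n_bins abundance bins for the dispersion trend.
#' @return numeric vector of dispersions, one per gene.
#' @export
estimateDispersion <- function(counts, groups, prior_df = 10, floor = 1e-4,
                               n_bins = 10) {
  groups <- as.character(groups)
  nrep <- table(groups)
  if (all(nrep < 2L))
    stop("all groups have a single replicate; supply a fixed dispersion instead")
  pc <- .pseudoCounts(counts)
  df <- sum(pmax(nrep - 1L, 0L))
  upper <- 20

  ## zero within-group variance carries no dispersion information
  novar <- rep(TRUE, nrow(pc))
  for (g in names(nrep)[nrep >= 2L]) {
    sub <- pc[, groups == g, drop = FALSE]
    novar <- novar & (apply(sub, 1, var) == 0)
  }
  if (all(novar))
    return(setNames(rep(floor, nrow(pc)), rownames(counts)))

  ## trend: pooled conditional ML within abundance bins
  ab <- rowMeans(pc)
  bins <- cut(rank(ab, ties.method = "first"),
              min(n_bins, max(1, floor(nrow(pc) / 20))))
  trend <- rep(floor, nrow(pc))
  for (b in levels(bins)) {
    idx <- which(bins == b & !novar)
    if (length(idx) < 2) next
    sub <- pc[idx, , drop = FALSE]
    trend[bins == b] <- max(floor, stats::optimize(function(p)
      sum(.condLogLik(p, sub, groups)), c(floor, upper),
      maximum = TRUE)$maximum)
  }

  ## per-gene conditional ML, shrunk toward the trend
  perGene <- vapply(seq_len(nrow(pc)), function(i) {
    if (novar[i]) return(floor)
    stats::optimize(function(p)
      .condLogLik(p, pc[i, , drop = FALSE], groups),
      c(floor, upper), maximum = TRUE)$maximum
  }, numeric(1))
  shrunk <- (df * perGene + prior_df * trend) / (df + prior_df)
  setNames(pmax(shrunk, floor), rownames(counts))
}

## conditional double-tail exact p for one gene: group sums ya, yb of na, nb
## equal-library NB replicates with common dispersion phi
.nbExactP <- function(ya, yb, na, nb, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  mu0 <- t / (na + nb)
  x <- 0:t
  pa <- dnbinom(x, size = na / phi, mu = na * mu0)
  pb <- dnbinom(t - x, size = nb / phi, mu = nb * mu0)
  pr <- pa * pb
  tot <- sum(pr)
  if (tot == 0) return(1)
  obs <- pr[ya + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]) / tot)
}

#' Pairwise differential expression between two groups
#'
#' Two-sided negative-binomial exact test on library-size-adjusted summed
#' counts (equal-library pseudodata), conditioning on the two-group total:
#' the p-value sums the conditional probabilities of all splits at most as
#' likely as the observed one. Log2 fold changes come from replicate-mean
#' CPM with a pseudocount; FDR is Benjamini-Hochberg across all genes of
#' this comparison.
#'
#' @param se `SummarizedExperiment` with bulk counts.
#' @param group_a,group_b group ids (`subregion.stage`); both need >= 2
#'   replicates and must not overlap.
#' @param dispersion per-gene dispersions, see [estimateDispersion()].
#' @param pseudocount CPM pseudocount bounding fold changes (default 0.25).
#' @return `data.frame` with gene_id, log2_fold_change (a over b), p_value,
#'   fdr.
#' @export
pairwiseDE <- function(se, group_a, group_b, dispersion, pseudocount = 0.25) {
  counts <- SummarizedExperiment::assay(se, "counts")
  groups <- .groupIds(SummarizedExperiment::colData(se))
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(intersect(ia, ib))) stop("overlapping group membership")
  if (length(ia) < 2L || length(ib) < 2L) stop("both groups need >= 2 replicates")
  sel <- c(ia, ib)
  pc <- .pseudoCounts(counts[, sel, drop = FALSE],
                      lib = Matrix::colSums(counts)[sel])
  na <- length(ia); nb <- length(ib)
  sa <- rowSums(pc[, seq_len(na), drop = FALSE])
  sb <- rowSums(pc[, na + seq_len(nb), drop = FALSE])
  phi <- rep_len(dispersion, nrow(counts))
  p <- vapply(seq_len(nrow(counts)), function(i)
    .nbExactP(sa[i], sb[i], na, nb, phi[i]), numeric(1))
  cpm <- countsPerMillion(counts)
  ma <- rowMeans(cpm[, ia, drop = FALSE])
  mb <- rowMeans(cpm[, ib, drop = FALSE])
  lfc <- log2((ma + pseudocount) / (mb + pseudocount))
  data.frame(gene_id = rownames(counts),
             group_a = group_a, group_b = group_b,
             log2_fold_change = lfc,
             p_value = p,
             fdr = p.adjust(p, "BH"),
             row.names = NULL)
}

#' Call subregion- or regional-specific mRNAs at one stage
#'
#' A gene is called specific for focal subregion S when, against *every*
#' subregion of the comparison set at the same stage, it accumulates at
#' `fold`-fold or higher (CPM scale) with FDR below `fdr_max`. The
#' comparison set is all other same-stage subregions (`scope =
#' "subregion"`) or only same-stage subregions in *other* seed regions
#' (`scope = "regional"`); subregion-scope calls are therefore a subset of
#' regional-scope calls. A pooled one-vs-all-others contrast is available
#' via `pooled = TRUE`.
#'
#' @param se `SummarizedExperiment` with bulk counts.
#' @param stage one of glob/hrt/cot/em present in the data.
#' @param scope `"subregion"` or `"regional"`.
#' @param fold minimum linear fold change against every comparison
#'   subregion (default 5).
#' @param fdr_max maximum BH FDR in every comparison (default 0.001).
#' @param pooled compare against the pooled complement instead of each
#'   subregion separately.
#' @param dispersion optional per-gene dispersions; estimated from the
#'   stage's groups when missing.
#' @return `data.frame` of calls: gene_id, stage, focal_subregion, scope,
#'   min_fold_change, max_fdr.
#' @export
callSpecific <- function(se, stage, scope = c("subregion", "regional"),
                         fold = 5, fdr_max = 0.001, pooled = FALSE,
                         dispersion = NULL) {
  scope <- match.arg(scope)
  cd <- SummarizedExperiment::colData(se)
  sel <- cd$stage == stage
  if (!any(sel)) stop("stage not present: ", stage)
  sse <- se[, sel]
  cd <- SummarizedExperiment::colData(sse)
  subs <- sort(unique(cd$subregion))
  if (length(subs) < 2L) stop("need >= 2 subregions at stage ", stage)
  regionOf <- setNames(as.character(cd$region), cd$subregion)[subs]
  if (scope == "regional" && length(unique(regionOf)) < 2L)
    stop("regional scope needs >= 2 regions at stage ", stage)
  groups <- .groupIds(cd)
  counts <- SummarizedExperiment::assay(sse, "counts")
  if (is.null(dispersion))
    dispersion <- estimateDispersion(counts, groups)

  if (pooled) {
    ## one-vs-rest: relabel the complement as a single pseudo-group
    res <- lapply(subs, function(s) {
      cmp <- if (scope == "subregion") setdiff(subs, s)
             else subs[regionOf != regionOf[s]]
      if (!length(cmp)) stop("empty comparison set for ", s)
      keep <- cd$subregion %in% c(s, cmp)
      cd2 <- cd[keep, ]
      cd2$subregion <- ifelse(cd2$subregion == s, s, ".rest")
      se2 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts[, keep, drop = FALSE]),
        colData = cd2)
      de <- pairwiseDE(se2, paste(s, stage, sep = "."),
                       paste(".rest", stage, sep = "."), dispersion)
      hit <- de$log2_fold_change >= log2(fold) & de$fdr < fdr_max
      if (!any(hit)) return(NULL)
      data.frame(gene_id = de$gene_id[hit], stage = stage,
                 focal_subregion = s, scope = scope,
                 min_fold_change = 2^de$log2_fold_change[hit],
                 max_fdr = de$fdr[hit], row.names = NULL)
    })
    return(do.call(rbind, c(res, list(make.row.names = FALSE))))
  }

  ## cache each unordered pair once; fold sign gives both directions
  pairRes <- list()
  getDE <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "|")
    if (is.null(pairRes[[key]])) {
      ab <- sort(c(a, b))
      pairRes[[key]] <<- pairwiseDE(sse, paste(ab[1], stage, sep = "."),
                                    paste(ab[2], stage, sep = "."), dispersion)
    }
    de <- pairRes[[key]]
    if (de$group_a[1] == paste(a, stage, sep = ".")) de
    else transform(de, log2_fold_change = -log2_fold_change)
  }
  res <- lapply(subs, function(s) {
    cmp <- if (scope == "subregion") setdiff(subs, s)
           else subs[regionOf != regionOf[s]]
    if (!length(cmp)) stop("empty comparison set for ", s)
    minF <- rep(Inf, nrow(counts)); maxQ <- rep(0, nrow(counts))
    ok <- rep(TRUE, nrow(counts))
    for (cs in cmp) {
      de <- getDE(s, cs)
      f <- 2^de$log2_fold_change
      ok <- ok & f >= fold & de$fdr < fdr_max
      minF <- pmin(minF, f)
      maxQ <- pmax(maxQ, de$fdr)
    }
    if (!any(ok)) return(NULL)
    data.frame(gene_id = rownames(counts)[ok], stage = stage,
               focal_subregion = s, scope = scope,
               min_fold_change = minF[ok], max_fdr = maxQ[ok],
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(), stage = character(),
                      focal_subregion = character(), scope = character(),
                      min_fold_change = numeric(), max_fdr = numeric())
  out
}

#' Conserved regional-specific transcription factors across two species
#'
#' Pairs species-A regional-specific TFs with orthologous species-B
#' regional-specific TFs from the paired region, ranked by the species-A
#' gene's prevalence (maximum mean CPM in its focal subregion); the top `k`
#' pairs per region are returned.
#'
#' @param calls_a,calls_b specificity-call tables (regional scope), see
#'   [callSpecific()].
#' @param orthologs an [OrthologMap-class] (species A in column 1).
#' @param tf_a,tf_b character vectors of TF gene ids per species.
#' @param region_pairing named character vector mapping species-A regions to
#'   species-B regions.
#' @param region_of_a,region_of_b named character vectors mapping subregion
#'   -> region per species.
#' @param profile_a gene x group CPM matrix for species A, used for ranking.
#' @param k number of pairs reported per region (default 5).
#' @return `data.frame`: region_a, gene_a, gene_b, prevalence_a, rank.
#' @export
conservedRegionalTFs <- function(calls_a, calls_b, orthologs, tf_a, tf_b,
                                 region_pairing, region_of_a, region_of_b,
                                 profile_a, k = 5) {
  pairs <- orthologPairs(orthologs)
  if (!nrow(pairs)) stop("empty ortholog map")
  ca <- calls_a[calls_a$gene_id %in% tf_a, , drop = FALSE]
  cb <- calls_b[calls_b$gene_id %in% tf_b, , drop = FALSE]
  ca$region <- region_of_a[ca$focal_subregion]
  cb$region <- region_of_b[cb$focal_subregion]
  out <- lapply(names(region_pairing), function(ra) {
    rb <- region_pairing[[ra]]
    ga <- unique(ca$gene_id[ca$region == ra])
    gb <- unique(cb$gene_id[cb$region == rb])
    hit <- pairs[pairs[, 1] %in% ga & pairs[, 2] %in% gb, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    prev <- vapply(hit[, 1], function(g) {
      subs <- unique(ca$focal_subregion[ca$gene_id == g & ca$region == ra])
      cols <- colnames(profile_a)[sub("\\.[^.]+$", "", colnames(profile_a)) %in% subs]
      max(profile_a[g, cols])
    }, numeric(1))
    ord <- order(-prev, hit[, 1], hit[, 2])
    n <- min(k, nrow(hit))
    data.frame(region_a = ra, gene_a = hit[ord, 1][seq_len(n)],
               gene_b = hit[ord, 2][seq_len(n)],
               prevalence_a = prev[ord][seq_len(n)],
               rank = seq_len(n), row.names = NULL)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(region_a = character(), gene_a = character(),
                      gene_b = character(), prevalence_a = numeric(),
                      rank = integer())
  out
}
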