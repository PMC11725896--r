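## Weighted coexpression core: soft threshold, adjacency, topological
## overlap, deterministic module detection, eigengenes, merging and spatial
## classification. Input is a log2(CPM + 1) gene x sample matrix, usually of
## subregion x stage group means.

#' Choose a soft-thresholding power by the scale-free fit criterion
#'
#' For each candidate power, computes the weighted connectivity k of every
#' gene and regresses log10 p(k) on log10 k over `n_bins` occupied bins. The
#' chosen power is the smallest whose signed R^2 (sign flipped when the
#' slope is positive) reaches `r2_target`; when no power qualifies, the
#' power maximizing signed R^2 is returned with `reached_target = FALSE`.
#'
#' @param expr numeric gene x sample matrix (log scale); >= 8 samples.
#' @param powers integer grid of candidate powers (default 1:20).
#' @param r2_target scale-free fit target (default 0.8).
#' @param network_type `"unsigned"` or `"signed_hybrid"`.
#' @param n_bins histogram bins for the p(k) fit (default 10).
#' @return list with `power`, `reached_target`, and `fit_table`
#'   (power, r_squared, slope, mean_k).
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, r2_target = 0.8,
                              network_type = c("unsigned", "signed_hybrid"),
                              n_bins = 10) {
  network_type <- match.arg(network_type)
  if (ncol(expr) < 8L) stop("scale-free fit needs >= 8 samples")
  stopifnot(all(powers >= 1), r2_target > 0, r2_target <= 1)
  cc <- cor(t(expr))
  base <- if (network_type == "unsigned") abs(cc) else pmax(cc, 0)
  diag(base) <- 0
  fits <- lapply(powers, function(p) {
    k <- rowSums(base^p)
    ## homogeneous connectivity (all genes share one profile): nothing to
    ## fit -- every node is equivalent, accept trivially
    if ((max(k) - min(k)) / max(k, 1e-300) < 0.01)
      return(data.frame(power = p, r_squared = 1, slope = 0, mean_k = mean(k)))
    brk <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, breaks = unique(brk), include.lowest = TRUE)
    pk <- tabulate(bin, nbins = nlevels(bin)) / length(k)
    mid <- (head(brk, -1) + brk[-1]) / 2
    keep <- pk > 0 & mid > 0
    if (sum(keep) < 3)
      return(data.frame(power = p, r_squared = 0, slope = NA_real_,
                        mean_k = mean(k)))
    f <- stats::lm(log10(pk[keep]) ~ log10(mid[keep]))
    r2 <- summary(f)$r.squared
    sl <- coef(f)[2]
    data.frame(power = p, r_squared = ifelse(sl < 0, r2, -r2),
               slope = sl, mean_k = mean(k))
  })
  tab <- do.call(rbind, fits)
  ok <- which(tab$r_squared >= r2_target)
  if (length(ok)) {
    list(power = tab$power[ok[1]], reached_target = TRUE, fit_table = tab)
  } else {
    list(power = tab$power[which.max(tab$r_squared)],
         reached_target = FALSE, fit_table = tab)
  }
}

#' Coexpression adjacency matrix
#'
#' Unsigned: `|cor|^power`; signed hybrid: `cor^power` for positive
#' correlations and 0 otherwise. Diagonal is set to 1.
#'
#' @param expr gene x sample matrix; every gene needs nonzero variance.
#' @param power soft-thresholding power.
#' @param network_type `"unsigned"` or `"signed_hybrid"`.
#' @return symmetric gene x gene adjacency matrix in \[0, 1\].
#' @export
adjacencyMatrix <- function(expr, power = 6,
                            network_type = c("unsigned", "signed_hybrid")) {
  network_type <- match.arg(network_type)
  v <- apply(expr, 1, var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(expr)[v == 0], 5), collapse = ", "))
  cc <- cor(t(expr))
  a <- if (network_type == "unsigned") abs(cc)^power else ifelse(cc > 0, cc^power, 0)
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over u distinct from i and j, and connectivity
#' `k_i = sum_u a_iu` over u distinct from i; `TOM_ii = 1`. Neighbors shared
#' between two genes raise their similarity beyond the direct adjacency.
#'
#' @param A symmetric adjacency matrix with unit diagonal, entries in
#'   \[0, 1\].
#' @return TOM matrix; `1 - tomSimilarity(A)` is the dissimilarity used for
#'   clustering.
#' @export
tomSimilarity <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(A < 0) || any(A > 1)) stop("adjacency entries must lie in [0, 1]")
  if (any(abs(diag(A) - 1) > 1e-10)) stop("adjacency diagonal must be 1")
  A0 <- A
  diag(A0) <- 0
  L <- A0 %*% A0            # l_ij plus nothing: diagonal-free products
  k <- rowSums(A0)
  denom <- outer(k, k, pmin) + 1 - A0
  tom <- (L + A0) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect modules on a TOM dissimilarity by deterministic tree cutting
#'
#' Average-linkage hierarchical clustering on the dissimilarity, followed by
#' a static cut just below the top of the dendrogram (at the maximum merge
#' height minus `cut_gap`): branches that remain intact below the cut and
#' reach `min_module_size` become candidate modules. On unstructured data
#' merge heights concentrate within `cut_gap` of the top, so the cut yields
#' only singletons and small fragments and no module is emitted. When the
#' expression matrix is supplied, candidate branches are additionally pruned
#' by module-membership correlation (kME): members whose signed correlation
#' with the branch eigengene falls below `kme_min` are released to
#' `"unassigned"`, which strips weakly attached genes (e.g. profiles merely
#' anticorrelated with the module through compositional coupling) off the
#' branch; pruned branches below `min_module_size` are dissolved.
#'
#' @param dissTOM square symmetric dissimilarity with zero diagonal.
#' @param min_module_size smallest reported module (default 30).
#' @param cut_gap height margin below the dendrogram top for the static cut
#'   (default 0.05).
#' @param expr optional gene x sample matrix (rows matching `dissTOM`)
#'   enabling kME pruning.
#' @param kme_min minimum signed gene-eigengene correlation to stay in a
#'   module (default 0.5).
#' @return named character vector gene -> module id (`"M1"`, `"M2"`, ... in
#'   decreasing size order, or `"unassigned"`).
#' @export
cutModules <- function(dissTOM, min_module_size = 30, cut_gap = 0.05,
                       expr = NULL, kme_min = 0.5) {
  n <- nrow(dissTOM)
  genes <- rownames(dissTOM)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (min_module_size > n) {
    warning("min_module_size exceeds number of genes; all unassigned")
    return(setNames(rep("unassigned", n), genes))
  }
  hc <- hclust(as.dist(dissTOM), method = "average")
  cl <- cutree(hc, h = max(hc$height) - cut_gap)
  labels <- setNames(rep("unassigned", n), genes)
  sizes <- table(cl)
  keep <- list()
  for (cid in names(sizes)[sizes >= min_module_size]) {
    leaves <- which(cl == as.integer(cid))
    if (!is.null(expr)) {
      eg <- moduleEigengene(expr, genes[leaves])
      kme <- as.numeric(cor(eg, t(expr[genes[leaves], , drop = FALSE])))
      leaves <- leaves[kme >= kme_min]
      if (length(leaves) < min_module_size) next
    }
    keep[[cid]] <- leaves
  }
  if (length(keep)) {
    ord <- order(-lengths(keep))
    for (i in seq_along(ord))
      labels[keep[[ord[i]]]] <- paste0("M", i)
  }
  labels
}

#' Module eigengene
#'
#' First principal component of the gene-standardized member submatrix,
#' giving one score per sample, scaled to unit variance and sign-oriented so
#' that its mean correlation with member profiles is non-negative.
#'
#' @param expr gene x sample expression matrix.
#' @param members character vector of member gene ids (>= 2 usable members;
#'   zero-variance members are dropped with a warning).
#' @return numeric vector over samples (unit variance).
#' @export
moduleEigengene <- function(expr, members) {
  sub <- expr[members, , drop = FALSE]
  v <- apply(sub, 1, var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance member(s)")
    sub <- sub[v > 0, , drop = FALSE]
  }
  if (nrow(sub) < 2L) stop("need >= 2 usable members")
  z <- t(scale(t(sub)))
  sv <- svd(z, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  eg <- eg / sd(eg)
  if (mean(cor(eg, t(sub))) < 0) eg <- -eg
  setNames(eg, colnames(expr))
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the globally most-correlated module pair whose
#' eigengene correlation reaches `1 - merge_cut_height`, recomputing
#' eigengenes after each merge; the greedy best-pair-first order makes the
#' result independent of module ordering.
#'
#' @param expr gene x sample matrix the modules were built on.
#' @param labels gene -> module labels from [cutModules()].
#' @param merge_cut_height eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. correlation >= 0.75).
#' @return updated label vector (merged modules renumbered by size).
#' @export
mergeModules <- function(expr, labels, merge_cut_height = 0.25) {
  thr <- 1 - merge_cut_height
  repeat {
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods) < 2L) break
    egs <- vapply(mods, function(m)
      moduleEigengene(expr, names(labels)[labels == m]), numeric(ncol(expr)))
    cc <- cor(egs)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] < thr) break
    a <- mods[best[1]]; b <- mods[best[2]]
    labels[labels == b] <- a
  }
  ## renumber by size, largest first
  mods <- setdiff(unique(labels), "unassigned")
  if (length(mods)) {
    sz <- vapply(mods, function(m) sum(labels == m), integer(1))
    newId <- setNames(paste0("M", seq_along(mods)), mods[order(-sz)])
    labels[labels != "unassigned"] <- newId[labels[labels != "unassigned"]]
  }
  labels
}

#' Classify a module's spatial behavior from member specificity
#'
#' A module is `subregion_specific` when at least `min_fraction` of its
#' members carry a subregion-specific call for one common subregion *and*
#' the mean eigengene value over that subregion's samples is the maximum
#' across subregions; `regional` when the same criterion holds only at
#' regional scope; otherwise `shared`.
#'
#' @param members character vector of module gene ids.
#' @param eigengene named eigengene vector over samples (names
#'   `subregion.stage`).
#' @param calls_subregion,calls_regional specificity-call tables from
#'   [callSpecific()] at the two scopes (any stage).
#' @param min_fraction member-specificity threshold (default 0.5).
#' @return list with `spatial_class`, `focal_subregion` (NA when shared) and
#'   `fraction_members_specific`.
#' @export
classifyModuleSpatial <- function(members, eigengene, calls_subregion,
                                  calls_regional, min_fraction = 0.5) {
  subOf <- sub("\\.[^.]+$", "", names(eigengene))
  egBySub <- tapply(eigengene, subOf, mean)
  tryScope <- function(calls) {
    calls <- calls[calls$gene_id %in% members, , drop = FALSE]
    if (!nrow(calls)) return(NULL)
    frac <- vapply(split(calls$gene_id, calls$focal_subregion),
                   function(g) length(unique(g)) / length(members), numeric(1))
    s <- names(frac)[which.max(frac)]
    if (frac[s] >= min_fraction && s %in% names(egBySub) &&
        egBySub[s] == max(egBySub))
      list(sub = s, frac = unname(frac[s]))
    else NULL
  }
  hit <- tryScope(calls_subregion)
  if (!is.null(hit))
    return(list(spatial_class = "subregion_specific",
                focal_subregion = hit$sub,
                fraction_members_specific = hit$frac))
  hit <- tryScope(calls_regional)
  if (!is.null(hit))
    return(list(spatial_class = "regional", focal_subregion = hit$sub,
                fraction_members_specific = hit$frac))
  ## shared: still report the best subregion-scope fraction
  calls <- calls_subregion[calls_subregion$gene_id %in% members, , drop = FALSE]
  frac <- if (nrow(calls))
    max(vapply(split(calls$gene_id, calls$focal_subregion),
               function(g) length(unique(g)) / length(members), numeric(1)))
  else 0
  list(spatial_class = "shared", focal_subregion = NA_character_,
       fraction_members_specific = frac)
}

#' Full coexpression workflow
#'
#' Soft-threshold selection, adjacency, TOM, module detection, merging,
#' eigengenes and (when specificity calls are given) spatial classification,
#' bundled into a [CoexpressionModules-class] object. Deterministic: no
#' randomized step.
#'
#' @param expr log2(CPM + 1) gene x sample matrix (typically subregion-stage
#'   group means over detected genes).
#' @param powers,r2_target,network_type see [pickSoftThreshold()].
#' @param min_module_size,cut_gap see [cutModules()].
#' @param merge_cut_height see [mergeModules()].
#' @param calls_subregion,calls_regional optional specificity calls for
#'   spatial classification.
#' @return a [CoexpressionModules-class].
#' @export
buildCoexpressionModules <- function(expr, powers = 1:20, r2_target = 0.8,
                                     network_type = "unsigned",
                                     min_module_size = 30, cut_gap = 0.05,
                                     merge_cut_height = 0.25,
                                     calls_subregion = NULL,
                                     calls_regional = NULL) {
  v <- apply(expr, 1, var)
  expr <- expr[v > 0, , drop = FALSE]
  sft <- pickSoftThreshold(expr, powers, r2_target, network_type)
  A <- adjacencyMatrix(expr, sft$power, network_type)
  diss <- 1 - tomSimilarity(A)
  diag(diss) <- 0
  labels <- cutModules(diss, min_module_size, cut_gap, expr = expr)
  labels <- mergeModules(expr, labels, merge_cut_height)
  mods <- setdiff(unique(labels), "unassigned")
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  egs <- if (length(mods))
    vapply(mods, function(m) moduleEigengene(expr, names(labels)[labels == m]),
           numeric(ncol(expr)))
  else matrix(0, ncol(expr), 0)
  rownames(egs) <- colnames(expr)
  cls <- S4Vectors::DataFrame(
    module_id = mods,
    n_members = vapply(mods, function(m) sum(labels == m), integer(1)),
    spatial_class = rep(NA_character_, length(mods)),
    focal_subregion = rep(NA_character_, length(mods)),
    fraction_members_specific = rep(NA_real_, length(mods)))
  if (!is.null(calls_subregion) && length(mods)) {
    for (i in seq_along(mods)) {
      cl <- classifyModuleSpatial(names(labels)[labels == mods[i]],
                                  egs[, mods[i]], calls_subregion,
                                  calls_regional)
      cls$spatial_class[i] <- cl$spatial_class
      cls$focal_subregion[i] <- cl$focal_subregion
      cls$fraction_members_specific[i] <- cl$fraction_members_specific
    }
  }
  new("CoexpressionModules", labels = labels, eigengenes = egs,
      classification = cls,
      parameters = list(power = sft$power,
                        reached_target = sft$reached_target,
                        network_type = network_type,
                        min_module_size = min_module_size,
                        cut_gap = cut_gap,
                        merge_cut_height = merge_cut_height))
}
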