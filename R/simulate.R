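## Synthetic seed generator with planted ground truth. The generated
## miniature seed mirrors the structure of the real atlas: negative-binomial
## bulk counts over subregion x stage x replicate with planted fold-specific
## genes, coexpression modules whose correlation arises from a shared
## subregion-localized pattern, and multinomial single-nucleus counts drawn
## from cluster identities tied to subregion profiles plus cluster-exclusive
## marker boosts. All generators are pure functions of (config, seed).

#' Configuration of the synthetic seed
#'
#' Defaults define the standard fixture: 2,000 genes over 8 subregions in 3
#' regions, 2 stages, 3 replicates, NB dispersion 0.1, planted 8-fold
#' specific genes (the 8 per-subregion specific sets double as the 8 planted
#' modules, sizes 40-80), 6 identity clusters of 150 cells plus an ambiguous
#' mixture cluster, and seed 7.
#'
#' @param n_genes total genes.
#' @param subregions data.frame with columns subregion, region.
#' @param stages character vector of stages (subset of glob/hrt/cot/em).
#' @param replicates biological replicates per subregion x stage.
#' @param dispersion NB dispersion of bulk counts (0 = Poisson).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   per-replicate mean counts (spanning several orders of magnitude).
#' @param specific_fold planted linear fold of specific genes in their focal
#'   subregion.
#' @param n_specific planted subregion-specific genes per subregion
#'   (recycled over subregions); these sets are also the planted modules.
#' @param specific_meanlog,specific_sdlog baseline distribution of planted
#'   specific genes (drawn high: specific mRNAs are prevalent).
#' @param n_regional_per_region genes planted fold-high in *all* subregions
#'   of one region (regional- but not subregion-specific).
#' @param n_universal genes planted at a high flat baseline, detected
#'   everywhere.
#' @param universal_meanlog,universal_sdlog their baseline distribution.
#' @param module_cor target within-module correlation of log expression; 1
#'   means no per-gene noise beyond the shared spatial pattern.
#' @param cluster_subregions subregions represented by identity clusters.
#' @param cells_per_cluster nuclei per cluster.
#' @param ambiguous_cluster add a cluster drawn from the mixture of all
#'   identity profiles (assignable to no single subregion)?
#' @param n_markers,marker_log2fc planted cluster-exclusive markers per
#'   cluster and their log2 boost.
#' @param lib_meanlog,lib_sdlog log-normal cell library sizes.
#' @param empty_fraction fraction of near-empty barcodes appended (removed
#'   by QC).
#' @param n_tf_background extra non-specific genes labeled TF.
#' @param conserved_fraction fraction of regional-specific TFs given a
#'   regional-specific ortholog in the pseudo-species.
#' @param n_decoy_terms random annotation terms.
#' @param seed RNG seed (mandatory; all generators derive from it).
#' @return list of class `seed_sim_config`.
#' @export
seedSimConfig <- function(n_genes = 2000,
                          subregions = data.frame(
                            subregion = c("EP", "SUS", "ES-MCE", "ES-PEN",
                                          "ES-CZE", "SC-EPD", "SC-OI", "SC-HIL"),
                            region = c("embryo", "embryo", "endosperm",
                                       "endosperm", "endosperm", "seed_coat",
                                       "seed_coat", "seed_coat")),
                          stages = c("glob", "cot"),
                          replicates = 3,
                          dispersion = 0.1,
                          baseline_meanlog = log(20), baseline_sdlog = 1.5,
                          specific_fold = 8,
                          n_specific = c(40, 40, 40, 50, 50, 60, 70, 80),
                          specific_meanlog = log(30), specific_sdlog = 0.5,
                          n_regional_per_region = 10,
                          n_universal = 150,
                          universal_meanlog = log(50), universal_sdlog = 0.3,
                          module_cor = 1,
                          cluster_subregions = c("EP", "SUS", "ES-PEN",
                                                 "SC-EPD", "SC-OI", "SC-HIL"),
                          cells_per_cluster = 150,
                          ambiguous_cluster = TRUE,
                          n_markers = 20, marker_log2fc = 2,
                          lib_meanlog = log(5000), lib_sdlog = 0.3,
                          empty_fraction = 0.05,
                          n_tf_background = 70,
                          conserved_fraction = 0.5,
                          n_decoy_terms = 50,
                          seed = 7) {
  cfg <- as.list(environment())
  stopifnot(n_genes > 0, replicates >= 1, dispersion >= 0,
            specific_fold > 0, is.numeric(seed))
  cfg$n_specific <- rep_len(n_specific, nrow(subregions))
  if (sum(cfg$n_specific) + n_regional_per_region * length(unique(subregions$region)) +
      n_universal > n_genes)
    stop("more planted genes than n_genes")
  stopifnot(all(cluster_subregions %in% subregions$subregion))
  class(cfg) <- "seed_sim_config"
  cfg
}

## expected mean-count matrix (genes x groups) and the planted truth
.bulkMeans <- function(cfg) {
  n <- cfg$n_genes
  genes <- sprintf("Gene%04d", seq_len(n))
  subs <- cfg$subregions$subregion
  regions <- cfg$subregions$region
  groups <- as.vector(outer(subs, cfg$stages, paste, sep = "."))

  idx <- seq_len(n)
  take <- function(k) { out <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; out }
  specIdx <- lapply(cfg$n_specific, take)
  names(specIdx) <- subs
  regIdx <- lapply(unique(regions), function(r) take(cfg$n_regional_per_region))
  names(regIdx) <- unique(regions)
  uniIdx <- take(cfg$n_universal)

  mu0 <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  for (s in subs)
    mu0[specIdx[[s]]] <- rlnorm(length(specIdx[[s]]), cfg$specific_meanlog,
                                cfg$specific_sdlog)
  for (r in names(regIdx))
    mu0[regIdx[[r]]] <- rlnorm(length(regIdx[[r]]), cfg$specific_meanlog,
                               cfg$specific_sdlog)
  mu0[uniIdx] <- rlnorm(length(uniIdx), cfg$universal_meanlog,
                        cfg$universal_sdlog)

  mu <- matrix(mu0, n, length(groups), dimnames = list(genes, groups))
  subOf <- sub("\\.[^.]+$", "", groups)
  for (s in subs)
    mu[specIdx[[s]], subOf == s] <- mu[specIdx[[s]], subOf == s] * cfg$specific_fold
  for (r in names(regIdx)) {
    inR <- subOf %in% subs[regions == r]
    mu[regIdx[[r]], inR] <- mu[regIdx[[r]], inR] * cfg$specific_fold
  }

  ## optional dilution of within-module correlation by per-gene group noise
  if (cfg$module_cor < 1) {
    pat <- log2(cfg$specific_fold)^2 *
      (length(cfg$stages) / length(groups)) *
      (1 - length(cfg$stages) / length(groups))
    extra_sd <- sqrt(pat * (1 / cfg$module_cor - 1))
    for (s in subs) {
      gi <- specIdx[[s]]
      mu[gi, ] <- mu[gi, ] *
        2^matrix(rnorm(length(gi) * length(groups), 0, extra_sd),
                 length(gi), length(groups))
    }
  }

  modules <- setNames(lapply(subs, function(s) genes[specIdx[[s]]]),
                      paste0("mod_", subs))
  truth <- list(
    genes = genes,
    specific = data.frame(
      gene_id = genes[unlist(specIdx)] %||% character(0),
      focal_subregion = rep(subs, lengths(specIdx)),
      fold = rep(cfg$specific_fold, length(unlist(specIdx))),
      row.names = NULL),
    regional = data.frame(
      gene_id = genes[unlist(regIdx)],
      focal_region = rep(names(regIdx), lengths(regIdx)), row.names = NULL),
    universal_genes = genes[uniIdx],
    module_members = modules,
    module_subregion = setNames(subs, names(modules)),
    background_genes = genes[idx],
    region_of = setNames(regions, subs))
  list(mu = mu, truth = truth)
}

#' Generate synthetic bulk subregion counts with planted truth
#'
#' See [seedSimConfig()] for the planted structure. Counts are drawn
#' negative-binomially (Poisson when `dispersion = 0`) per replicate around
#' the planted group means.
#'
#' @param cfg a [seedSimConfig()] configuration.
#' @return list with `se` (`SummarizedExperiment`), `samples` (sample
#'   table), `mu` (expected mean counts, genes x groups) and `truth`
#'   (planted specific/regional/universal/module assignments).
#' @export
simulateBulk <- function(cfg) {
  stopifnot(inherits(cfg, "seed_sim_config"))
  set.seed(cfg$seed)
  bm <- .bulkMeans(cfg)
  mu <- bm$mu
  groups <- colnames(mu)
  reps <- cfg$replicates
  cols <- as.vector(t(outer(groups, seq_len(reps), paste, sep = "_r")))
  counts <- matrix(0L, nrow(mu), length(cols),
                   dimnames = list(rownames(mu), cols))
  for (j in seq_along(groups)) {
    for (r in seq_len(reps)) {
      cidx <- (j - 1) * reps + r
      counts[, cidx] <- if (cfg$dispersion > 0)
        rnbinom(nrow(mu), mu = mu[, j], size = 1 / cfg$dispersion)
      else rpois(nrow(mu), mu[, j])
    }
  }
  subOf <- sub("\\.[^.]+$", "", groups)
  stageOf <- sub("^.*\\.", "", groups)
  samples <- data.frame(
    column_id = cols,
    region = rep(bm$truth$region_of[subOf], each = reps),
    subregion = rep(subOf, each = reps),
    stage = rep(stageOf, each = reps),
    replicate = rep(seq_len(reps), length(groups)),
    row.names = NULL)
  se <- makeBulkExperiment(.autoSparse(counts), samples)
  list(se = se, samples = samples, mu = mu, truth = bm$truth)
}

#' Generate synthetic single-nucleus counts tied to the bulk truth
#'
#' Each identity cluster draws cells multinomially from its subregion's
#' expected cot-stage profile with planted cluster-exclusive marker genes
#' boosted by `2^marker_log2fc`; the optional ambiguous cluster draws from
#' the unboosted mixture of all identity profiles. A fraction of near-empty
#' barcodes is appended (to be removed by QC).
#'
#' @param cfg a [seedSimConfig()] configuration.
#' @param bulk result of [simulateBulk()] with the same config.
#' @return list with `sce` (counts assay, true labels in
#'   `colData$true_cluster`), and `truth`: cluster -> subregion map, planted
#'   marker genes, expected marker sets (genes whose planted profiles give
#'   log2 fold >= 1 and expression fraction >= 0.25 in the cluster), and the
#'   whole-seed expected profile.
#' @export
simulateCells <- function(cfg, bulk) {
  stopifnot(inherits(cfg, "seed_sim_config"))
  set.seed(cfg$seed + 1L)
  stage <- if ("cot" %in% cfg$stages) "cot" else cfg$stages[length(cfg$stages)]
  mu <- bulk$mu
  genes <- rownames(mu)
  clSubs <- cfg$cluster_subregions
  stopifnot(all(paste(clSubs, stage, sep = ".") %in% colnames(mu)))
  base <- mu[, paste(clSubs, stage, sep = "."), drop = FALSE]
  colnames(base) <- clSubs

  ## cluster-exclusive markers: background genes at a workable baseline
  pool <- intersect(bulk$truth$background_genes,
                    genes[mu[, paste(clSubs[1], stage, sep = ".")] >= 30 &
                          mu[, paste(clSubs[1], stage, sep = ".")] <= 500])
  need <- cfg$n_markers * length(clSubs)
  if (length(pool) < need) stop("too few background genes for planted markers")
  mk <- sample(pool, need)
  markers <- split(mk, rep(seq_along(clSubs), each = cfg$n_markers))
  names(markers) <- paste0("k", seq_along(clSubs))

  prof <- base
  for (i in seq_along(clSubs))
    prof[markers[[i]], i] <- prof[markers[[i]], i] * 2^cfg$marker_log2fc
  cluster_ids <- names(markers)
  if (cfg$ambiguous_cluster) {
    prof <- cbind(prof, ambiguous = rowMeans(base))
    cluster_ids <- c(cluster_ids, "ambiguous")
  }
  colnames(prof) <- cluster_ids
  probs <- sweep(prof, 2, colSums(prof), "/")

  nPer <- cfg$cells_per_cluster
  nReal <- nPer * length(cluster_ids)
  libs <- round(rlnorm(nReal, cfg$lib_meanlog, cfg$lib_sdlog))
  cellCl <- rep(cluster_ids, each = nPer)
  counts <- matrix(0L, length(genes), nReal)
  for (i in seq_len(nReal))
    counts[, i] <- rmultinom(1, libs[i], probs[, cellCl[i]])
  nEmpty <- round(cfg$empty_fraction * nReal)
  if (nEmpty > 0) {
    eLibs <- rpois(nEmpty, 3)
    empty <- vapply(eLibs, function(L)
      as.integer(rmultinom(1, L, rowMeans(probs))), integer(length(genes)))
    counts <- cbind(counts, empty)
    cellCl <- c(cellCl, rep("empty", nEmpty))
  }
  rownames(counts) <- genes
  colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  sce <- makeCellExperiment(.autoSparse(counts))
  SummarizedExperiment::colData(sce)$true_cluster <- cellCl

  ## expected markers under the caller's own fold convention: per-cell
  ## expected scaled count v = p * L, out-mean over the other clusters
  L <- exp(cfg$lib_meanlog)
  v <- probs * L
  expMarkers <- lapply(seq_along(cluster_ids), function(i) {
    vin <- v[, i]
    vout <- rowMeans(v[, -i, drop = FALSE])
    lfc <- log2((vin + 1) / (vout + 1))
    pct <- 1 - exp(-vin)
    genes[lfc >= 1 & pct >= 0.25]
  })
  names(expMarkers) <- cluster_ids

  truth <- list(
    cluster_subregion = setNames(clSubs, paste0("k", seq_along(clSubs))),
    planted_markers = markers,
    expected_markers = expMarkers,
    true_labels = setNames(cellCl, colnames(counts)),
    stage = stage)
  list(sce = sce, truth = truth)
}

#' Generate synthetic annotation, TF list and ortholog map
#'
#' One true term per planted module and per planted cluster-marker set,
#' plus random decoy terms; a TF list containing the planted
#' regional-specific genes; and an ortholog map pairing a fraction of the
#' regional TFs with regional-specific counterparts of a pseudo-species
#' (gene ids prefixed `AT_`), together with that species' call table and
#' region pairing.
#'
#' @param cfg a [seedSimConfig()] configuration.
#' @param bulk result of [simulateBulk()].
#' @param cells optional result of [simulateCells()] (adds marker terms).
#' @return list with `annotation` ([GeneSetCollection-class]), `tf_genes`,
#'   `orthologs` ([OrthologMap-class]), `calls_b`, `tf_b`,
#'   `region_pairing`, `region_of_b`, and `truth` (conserved pairs, true
#'   term ids).
#' @export
simulateAnnotation <- function(cfg, bulk, cells = NULL) {
  stopifnot(inherits(cfg, "seed_sim_config"))
  set.seed(cfg$seed + 2L)
  truth <- bulk$truth
  genes <- truth$genes
  sets <- lapply(truth$module_members, identity)
  names(sets) <- paste0("TERM:", names(truth$module_members))
  if (!is.null(cells)) {
    mk <- cells$truth$planted_markers
    names(mk) <- paste0("TERM:markers_", names(mk))
    sets <- c(sets, mk)
  }
  for (i in seq_len(cfg$n_decoy_terms)) {
    sz <- sample(10:50, 1)
    sets[[sprintf("DECOY:%03d", i)]] <- sample(genes, sz)
  }
  annotation <- GeneSetCollection(sets)

  regional <- truth$regional
  tf_genes <- unique(c(regional$gene_id,
                       sample(truth$background_genes, cfg$n_tf_background)))
  nCons <- ceiling(cfg$conserved_fraction * nrow(regional))
  consIdx <- sort(sample(seq_len(nrow(regional)), nCons))
  consA <- regional$gene_id[consIdx]
  consB <- paste0("AT_", consA)
  ## extra non-TF pairs so the map is not trivially the conserved set
  extraA <- sample(truth$background_genes, 100)
  orth <- OrthologMap(c(consA, extraA),
                      c(consB, paste0("AT_", extraA)))

  regions <- unique(cfg$subregions$region)
  region_pairing <- setNames(paste0("at_", regions), regions)
  subsB <- paste0("AT.", cfg$subregions$subregion)
  region_of_b <- setNames(paste0("at_", cfg$subregions$region), subsB)
  focalB <- paste0("AT.",
                   vapply(regional$focal_region[consIdx], function(r)
                     cfg$subregions$subregion[cfg$subregions$region == r][1],
                     character(1)))
  calls_b <- data.frame(gene_id = consB, stage = cfg$stages[1],
                        focal_subregion = focalB, scope = "regional",
                        min_fold_change = cfg$specific_fold, max_fdr = 0,
                        row.names = NULL)
  list(annotation = annotation, tf_genes = tf_genes, orthologs = orth,
       calls_b = calls_b, tf_b = consB, region_pairing = region_pairing,
       region_of_b = region_of_b,
       truth = list(conserved_pairs = data.frame(gene_a = consA,
                                                 gene_b = consB,
                                                 row.names = NULL),
                    true_terms = paste0("TERM:", names(truth$module_members))))
}
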