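## End-to-end orchestration: detection -> specificity -> coexpression ->
## single-nucleus clustering -> markers -> assignment -> projection ->
## enrichment, with a machine-readable JSON report.

#' Run the full seed-atlas analysis
#'
#' Executes the whole pipeline on either a synthetic seed (when `config`
#' carries a [seedSimConfig()] under `$simulate`) or on files (when
#' `config$inputs` gives `counts`, `samples` and optionally `cells_mtx`,
#' `gmt` paths). Stage failures are recorded with the stage name and
#' downstream stages are skipped. The returned report carries per-stage
#' status, summary statistics, the config hash, seeds and package version;
#' with planted truth available, recovery metrics are included.
#'
#' @param config list; see Details. `config$thresholds` may override
#'   `fold` (5), `fdr` (0.001), marker filters (`min_pct` 0.25, `lfc_min`
#'   1, `alpha` 0.05), assignment/enrichment `q` (0.05).
#' @param stages character vector of stages to run (default: all, in
#'   order).
#' @param out_dir optional directory; when given, the report is written to
#'   `report.json` and key tables to provenance-headed TSVs.
#' @param state result of a previous partial run to resume from.
#' @return list with `report` (written as JSON) and `state` (intermediate
#'   objects, for resumption or inspection).
#' @export
runPipeline <- function(config = list(simulate = seedSimConfig()),
                        stages = c("simulate", "detect", "specificity",
                                   "coexpress", "cluster", "markers",
                                   "assign", "project", "enrich"),
                        out_dir = NULL, state = NULL) {
  thr <- utils::modifyList(list(fold = 5, fdr = 0.001, min_pct = 0.25,
                                lfc_min = 1, alpha = 0.05, q = 0.05,
                                seed = 0), config$thresholds %||% list())
  st <- state %||% list()
  report <- list(package_version = as.character(utils::packageVersion("seedatlas")),
                 config_hash = .configHash(config),
                 seed = if (!is.null(config$simulate)) config$simulate$seed else thr$seed,
                 stages = list())
  failed <- FALSE
  runStage <- function(name, fun) {
    if (!(name %in% stages) || failed) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      message("stage ", name, " failed: ", conditionMessage(res))
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
    } else {
      report$stages[[name]] <<- c(list(status = "ok",
                                       seconds = round(proc.time()[["elapsed"]] - t0, 2)),
                                  res)
    }
    invisible(NULL)
  }

  runStage("simulate", function() {
    if (is.null(config$simulate)) {
      inp <- config$inputs
      if (is.null(inp$counts) || is.null(inp$samples))
        stop("config$inputs needs counts and samples paths")
      counts <- readCounts(inp$counts,
                           format = if (dir.exists(inp$counts)) "mtx" else "tsv")
      st$bulk <<- list(se = makeBulkExperiment(counts, readSampleTable(inp$samples)),
                       truth = NULL)
      if (!is.null(inp$cells_mtx))
        st$cells <<- list(sce = makeCellExperiment(readCounts(inp$cells_mtx, "mtx")),
                          truth = NULL)
      if (!is.null(inp$gmt)) st$annotation <<- list(annotation = readGeneSets(inp$gmt))
      list(mode = "files")
    } else {
      st$bulk <<- simulateBulk(config$simulate)
      st$cells <<- simulateCells(config$simulate, st$bulk)
      st$annotation <<- simulateAnnotation(config$simulate, st$bulk, st$cells)
      list(mode = "synthetic", n_genes = config$simulate$n_genes)
    }
  })

  runStage("detect", function() {
    det <- detectGenes(st$bulk$se, rule = "all_replicates_nonzero")
    st$detected <<- det
    st$profile <<- expressionProfile(st$bulk$se)
    detectionSummary(det)[c("mean_over_groups", "union_count",
                            "intersection_count")]
  })

  runStage("specificity", function() {
    cd <- SummarizedExperiment::colData(st$bulk$se)
    stgs <- unique(as.character(cd$stage))
    callsS <- do.call(rbind, lapply(stgs, function(s)
      callSpecific(st$bulk$se, s, "subregion", thr$fold, thr$fdr)))
    callsR <- do.call(rbind, lapply(stgs, function(s)
      callSpecific(st$bulk$se, s, "regional", thr$fold, thr$fdr)))
    st$calls_subregion <<- callsS
    st$calls_regional <<- callsR
    out <- list(n_subregion_calls = nrow(callsS),
                n_regional_calls = nrow(callsR))
    truth <- st$bulk$truth
    if (!is.null(truth)) {
      rec <- specificityRecovery(callsS, truth)
      out <- c(out, rec)
    }
    out
  })

  runStage("coexpress", function() {
    keep <- rowSums(st$detected) >= 1
    expr <- log2(st$profile[keep, , drop = FALSE] + 1)
    mods <- buildCoexpressionModules(expr,
                                     calls_subregion = st$calls_subregion,
                                     calls_regional = st$calls_regional)
    st$modules <<- mods
    cls <- moduleClassification(mods)
    list(n_modules = length(moduleMembers(mods)),
         power = mods@parameters$power,
         n_subregion_specific_modules =
           sum(cls$spatial_class == "subregion_specific", na.rm = TRUE))
  })

  runStage("cluster", function() {
    sce <- qcFilterCells(st$cells$sce, min_counts = 100)
    sce <- normalizeCells(sce)
    sce <- clusterCells(sce, n_pcs = 30, resolution = 1.0, seed = thr$seed)
    st$sce <<- sce
    list(n_cells = ncol(sce),
         n_clusters = length(unique(SummarizedExperiment::colData(sce)$cluster)),
         n_removed = S4Vectors::metadata(sce)$qc$n_removed)
  })

  runStage("markers", function() {
    mk <- findMarkers(st$sce, min_pct = thr$min_pct, lfc_min = thr$lfc_min,
                      alpha = thr$alpha)
    st$markers <<- mk
    list(n_marker_records = nrow(mk))
  })

  runStage("assign", function() {
    if (is.null(st$markers) || !nrow(st$markers)) stop("no marker records")
    markerSets <- split(st$markers$gene, st$markers$cluster)
    snGenes <- rownames(st$sce)[Matrix::rowSums(
      SummarizedExperiment::assay(st$sce, "counts")) > 0]
    background <- intersect(rownames(st$detected)[rowSums(st$detected) >= 1],
                            snGenes)
    cd <- SummarizedExperiment::colData(st$bulk$se)
    stage <- if (!is.null(st$cells$truth)) st$cells$truth$stage
             else utils::tail(unique(as.character(cd$stage)), 1)
    callsS <- st$calls_subregion[st$calls_subregion$stage == stage, ]
    specSets <- split(callsS$gene_id, callsS$focal_subregion)
    specSets <- lapply(specSets, intersect, background)
    markerSets <- lapply(markerSets, intersect, background)
    asg <- assignClusters(markerSets, specSets, background, thr$q)
    st$assignments <<- asg
    out <- list(n_assigned = sum(!is.na(asg$assignments$assigned_subregion)))
    if (!is.null(st$cells$truth))
      out <- c(out, assignmentRecovery(asg$assignments, st$sce,
                                       st$cells$truth))
    out
  })

  runStage("project", function() {
    mem <- moduleMembers(st$modules)
    proj <- lapply(mem, function(g) projectModule(st$sce, g))
    st$projections <<- proj
    top <- vapply(proj, function(p)
      names(p$per_cluster_z)[which.max(p$per_cluster_z)], character(1))
    list(top_cluster = as.list(top))
  })

  runStage("enrich", function() {
    ann <- st$annotation$annotation
    if (is.null(ann)) stop("no annotation available")
    background <- rownames(st$detected)
    mem <- moduleMembers(st$modules)
    enr <- lapply(mem, function(g)
      topTerms(enrichTerms(intersect(g, background), ann, background), 5))
    st$enrichment <<- enr
    list(n_modules_enriched = sum(vapply(enr, nrow, integer(1)) > 0))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(st$calls_subregion))
      writeProvenancedTable(st$calls_subregion,
                            file.path(out_dir, "specific_calls.tsv"),
                            list(config = report$config_hash,
                                 seed = report$seed))
    if (!is.null(st$markers))
      writeProvenancedTable(st$markers, file.path(out_dir, "markers.tsv"),
                            list(config = report$config_hash,
                                 seed = report$seed))
  }
  list(report = report, state = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recovery of planted specific genes by the specificity caller
#'
#' A planted gene counts as recovered when it is called subregion-specific
#' for its focal subregion at at least one profiled stage (calls are per
#' stage; the planted identity is per gene). The false-call rate is the
#' fraction of non-planted genes carrying any subregion-specific call.
#'
#' @param calls subregion-scope call table ([callSpecific()], all stages).
#' @param truth `truth` element of [simulateBulk()].
#' @return list with `sensitivity` and `false_call_rate`.
#' @export
specificityRecovery <- function(calls, truth) {
  key <- paste(calls$gene_id, calls$focal_subregion)
  planted <- paste(truth$specific$gene_id, truth$specific$focal_subregion)
  sens <- mean(planted %in% key)
  nonPlanted <- setdiff(truth$genes, truth$specific$gene_id)
  fcr <- mean(nonPlanted %in% calls$gene_id)
  list(sensitivity = sens, false_call_rate = fcr)
}

#' Recovery of planted cluster-to-subregion identities
#'
#' Matches inferred clusters to planted identities by majority true label,
#' then checks assignments: an identity cluster is recovered when its
#' majority-matched inferred cluster is assigned to the planted subregion;
#' the ambiguous planted cluster must stay unassigned.
#'
#' @param assignments assignment table from [assignClusters()].
#' @param sce clustered `SingleCellExperiment` (with `colData$cluster`).
#' @param truth `truth` element of [simulateCells()].
#' @return list with `assignment_accuracy`, `n_identity_clusters`, and
#'   `ambiguous_unassigned`.
#' @export
assignmentRecovery <- function(assignments, sce, truth) {
  cd <- SummarizedExperiment::colData(sce)
  lab <- cd$cluster
  tru <- truth$true_labels[colnames(sce)]
  majority <- vapply(split(tru, lab), function(x)
    names(sort(table(x), decreasing = TRUE))[1], character(1))
  asg <- setNames(assignments$assigned_subregion, assignments$cluster)
  ids <- names(truth$cluster_subregion)
  okPer <- vapply(ids, function(k) {
    infCl <- names(majority)[majority == k]
    length(infCl) >= 1 &&
      all(!is.na(asg[infCl])) &&
      all(asg[infCl] == truth$cluster_subregion[[k]])
  }, logical(1))
  ambCl <- names(majority)[majority == "ambiguous"]
  ambOk <- if (!length(ambCl)) NA else all(is.na(asg[ambCl]))
  list(assignment_accuracy = mean(okPer),
       n_identity_clusters = length(ids),
       ambiguous_unassigned = isTRUE(ambOk))
}
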