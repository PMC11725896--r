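## Shared fixtures. The standard synthetic seed is expensive (about a
## minute end to end), so each component is generated once per session and
## cached.

.fx <- new.env(parent = emptyenv())

fixtureConfig <- function() seedSimConfig()  # the standard seed: seed 7

fixtureBulk <- function() {
  if (is.null(.fx$bulk)) .fx$bulk <- simulateBulk(fixtureConfig())
  .fx$bulk
}

fixtureDetected <- function() {
  if (is.null(.fx$det))
    .fx$det <- detectGenes(fixtureBulk()$se, "all_replicates_nonzero")
  .fx$det
}

fixtureProfile <- function() {
  if (is.null(.fx$prof)) .fx$prof <- expressionProfile(fixtureBulk()$se)
  .fx$prof
}

fixtureCalls <- function(scope = "subregion") {
  key <- paste0("calls_", scope)
  if (is.null(.fx[[key]])) {
    se <- fixtureBulk()$se
    .fx[[key]] <- rbind(callSpecific(se, "glob", scope),
                        callSpecific(se, "cot", scope))
  }
  .fx[[key]]
}

fixtureModules <- function() {
  if (is.null(.fx$mods)) {
    expr <- log2(fixtureProfile()[rowSums(fixtureDetected()) >= 1, ] + 1)
    .fx$mods <- buildCoexpressionModules(
      expr, calls_subregion = fixtureCalls("subregion"),
      calls_regional = fixtureCalls("regional"))
  }
  .fx$mods
}

fixtureCells <- function() {
  if (is.null(.fx$cells))
    .fx$cells <- simulateCells(fixtureConfig(), fixtureBulk())
  .fx$cells
}

fixtureSCE <- function() {
  if (is.null(.fx$sce)) {
    sce <- qcFilterCells(fixtureCells()$sce, min_counts = 100)
    sce <- normalizeCells(sce)
    .fx$sce <- clusterCells(sce, n_pcs = 30, resolution = 1.0, seed = 7)
  }
  .fx$sce
}

fixtureMarkers <- function() {
  if (is.null(.fx$markers)) .fx$markers <- findMarkers(fixtureSCE())
  .fx$markers
}

fixtureAnnotation <- function() {
  if (is.null(.fx$ann))
    .fx$ann <- simulateAnnotation(fixtureConfig(), fixtureBulk(),
                                  fixtureCells())
  .fx$ann
}

## majority-vote map from inferred cluster ids to planted identities
fixtureClusterMap <- function() {
  sce <- fixtureSCE()
  tru <- fixtureCells()$truth$true_labels[colnames(sce)]
  lab <- SummarizedExperiment::colData(sce)$cluster
  vapply(split(tru, lab), function(x)
    names(sort(table(x), decreasing = TRUE))[1], character(1))
}

## small hand-made bulk experiment builder
makeTinySE <- function(counts, subregions, regions, stage = "cot",
                       reps = ncol(counts) / length(subregions)) {
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  samples <- data.frame(
    column_id = colnames(counts),
    region = rep(regions, each = reps),
    subregion = rep(subregions, each = reps),
    stage = stage,
    replicate = rep(seq_len(reps), length(subregions)))
  makeBulkExperiment(counts, samples)
}
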