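#' Read a pipeline run configuration from YAML
#'
#' The YAML may carry `inputs` (paths: counts, samples, cells_mtx, gmt),
#' `thresholds` (fold, fdr, min_pct, lfc_min, alpha, q, seed) and
#' `simulate` (arguments to [seedSimConfig()]); defaults equal the atlas
#' thresholds (fivefold, FDR 0.001, marker filters log2FC >= 1 / adjusted
#' p < 0.05 / expressed fraction 0.25, assignment q < 0.05).
#'
#' @param path YAML file path.
#' @return config list for [runPipeline()].
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulate))
    cfg$simulate <- do.call(seedSimConfig, cfg$simulate)
  cfg
}
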