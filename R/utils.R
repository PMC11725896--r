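#' @importFrom stats setNames quantile median cor prcomp hclust cutree as.dist
#'   dnbinom p.adjust phyper fisher.test wilcox.test rnbinom rmultinom rlnorm
#'   rnorm runif rpois sd var lowess approx aggregate
#' @importFrom utils read.delim write.table head packageVersion
NULL

## shared internal helpers: group handling, matrix checks, provenance

.checkCounts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have gene (row) and column names")
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated column ids")
  v <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(v) && (any(v < 0) || any(v != floor(v))))
    stop("counts must be non-negative integers")
  invisible(counts)
}

## store sparse when density < 50%, dense otherwise; results must not depend
## on the representation
.autoSparse <- function(counts) {
  dens <- if (methods::is(counts, "sparseMatrix")) {
    length(counts@x) / prod(dim(counts))
  } else {
    mean(counts != 0)
  }
  if (dens < 0.5) methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  else as.matrix(counts)
}

.groupIds <- function(samples) paste(samples$subregion, samples$stage, sep = ".")

.stopifnotSamples <- function(samples) {
  need <- c("column_id", "region", "subregion", "stage", "replicate")
  miss <- setdiff(need, colnames(samples))
  if (length(miss)) stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(as.character(samples$stage)), c("glob", "hrt", "cot", "em"))
  if (length(bad)) stop("unknown stage value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(samples$column_id)) stop("duplicated column_id in sample table")
  invisible(samples)
}

## per-group arithmetic mean of columns (genes x groups)
.groupMeans <- function(mat, groups) {
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  out <- vapply(gs, function(g) {
    Matrix::rowMeans(mat[, groups == g, drop = FALSE])
  }, numeric(nrow(mat)))
  dimnames(out) <- list(rownames(mat), gs)
  out
}

.provenanceHeader <- function(extra = NULL) {
  paste0("# seedatlas ", as.character(utils::packageVersion("seedatlas")),
         if (length(extra)) paste0(" ", paste(names(extra), unlist(extra),
                                              sep = "=", collapse = " ")))
}

#' Write a TSV table with a provenance comment line
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param provenance named list appended to the provenance header
#'   (e.g. rule, seed, config hash).
#' @return `path`, invisibly.
#' @export
writeProvenancedTable <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(provenance), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## stable short hash of an R object (configs, for provenance)
.configHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(raw, tf)
  unname(tools::md5sum(tf))
}
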