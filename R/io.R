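#' Read a gene x column count matrix
#'
#' Two dialects are supported. `format = "mtx"` reads a 10x-style
#' MatrixMarket triplet directory: `matrix.mtx` plus `features.tsv` (gene ids
#' in the first column) and `barcodes.tsv` companions, all optionally
#' gzip-compressed. `format = "tsv"` reads a dense table whose first column
#' holds gene ids and whose header row holds column ids.
#'
#' Entries must be non-negative integers; duplicated gene or column ids are
#' rejected. Row order is preserved exactly as stored. Matrices denser than
#' 50% are returned dense, sparser ones as a `dgCMatrix`; all downstream
#' operations give identical results on either representation.
#'
#' @param path directory (for `mtx`) or file (for `tsv`).
#' @param format `"mtx"` or `"tsv"`.
#' @return integer count matrix (base matrix or `dgCMatrix`) with gene ids as
#'   rownames and sample/cell ids as colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeCounts(matrix(0:5, 3, dimnames = list(paste0("g", 1:3), c("s1", "s2"))), tf)
#' readCounts(tf, format = "tsv")
#' @export
readCounts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    find <- function(stem) {
      hits <- list.files(path, paste0("^", stem, "(\\.tsv|\\.txt|\\.mtx)?(\\.gz)?$"),
                         full.names = TRUE)
      if (!length(hits))
        stop("missing companion file '", stem, "' in ", path)
      hits[[1]]
    }
    m <- Matrix::readMM(find("matrix"))
    feats <- read.delim(find("features"), header = FALSE)
    bcs <- read.delim(find("barcodes"), header = FALSE)
    if (nrow(feats) != nrow(m) || nrow(bcs) != ncol(m))
      stop("features/barcodes dimensions do not match the matrix")
    rownames(m) <- as.character(feats[[1]])
    colnames(m) <- as.character(bcs[[1]])
    counts <- m
  } else {
    tab <- read.delim(path, header = TRUE, check.names = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- as.character(tab[[1]])
    storage.mode(counts) <- "double"
  }
  .checkCounts(counts)
  .autoSparse(counts)
}

#' Write a count matrix
#'
#' Inverse of [readCounts()]: `tsv` writes a dense table with a `gene_id`
#' first column; `mtx` writes `matrix.mtx` + `features.tsv` + `barcodes.tsv`
#' into a directory. Round-tripping is the identity.
#'
#' @param counts gene x column matrix with dimnames.
#' @param path output file (`tsv`) or directory (`mtx`).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  .checkCounts(counts)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(counts),
                      as.matrix(counts), check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    write.table(data.frame(rownames(counts), rownames(counts)),
                file.path(path, "features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(data.frame(colnames(counts)),
                file.path(path, "barcodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a bulk sample table
#'
#' TSV with required columns `column_id`, `region`, `subregion`, `stage`
#' (one of glob/hrt/cot/em), `replicate`. `column_id` must be unique; whether
#' every id matches a count column is checked when the two are joined in
#' [makeBulkExperiment()], not here.
#'
#' @param path TSV file path.
#' @return validated `data.frame`.
#' @export
readSampleTable <- function(path) {
  samples <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  .stopifnotSamples(samples)
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1))
    stop("replicate must be a positive integer")
  samples
}

#' Assemble counts and sample metadata into a SummarizedExperiment
#'
#' Joins a count matrix with its sample table (by `column_id`), keeping the
#' count-column order, and stores the result as a `SummarizedExperiment`
#' with assay `counts`.
#'
#' @param counts gene x sample count matrix (see [readCounts()]).
#' @param samples sample table (see [readSampleTable()]).
#' @return `SummarizedExperiment` with colData columns region, subregion,
#'   stage, replicate.
#' @export
makeBulkExperiment <- function(counts, samples) {
  .checkCounts(counts)
  .stopifnotSamples(samples)
  miss <- setdiff(colnames(counts), samples$column_id)
  if (length(miss))
    stop("count columns absent from sample table: ", paste(miss, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$column_id), ]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(samples, row.names = samples$column_id))
  se
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Lines without at least one gene are a validation error.
#'
#' @param path GMT file path.
#' @return a [GeneSetCollection-class].
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("GMT line(s) without genes: ", paste(bad, collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  GeneSetCollection(sets, setNames(desc, ids))
}

#' Write gene sets in GMT format
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(gsc, path) {
  lines <- mapply(function(id, d, genes) {
    paste(c(id, d, genes), collapse = "\t")
  }, names(gsc), setDescriptions(gsc), geneSets(gsc))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' TSV with species-A gene ids in the first column and species-B ids in the
#' second; duplicated pairs are stored once.
#'
#' @param path TSV file path (header optional via `header`).
#' @param header does the file carry a header row?
#' @return an [OrthologMap-class].
#' @export
readOrthologMap <- function(path, header = FALSE) {
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("ortholog map needs two columns")
  OrthologMap(tab[[1]], tab[[2]])
}
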