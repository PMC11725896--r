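#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Collection of named gene sets
#'
#' A lightweight container for gene-set annotation (GO-style terms, TF lists,
#' module memberships). Each set has an identifier, a free-text description
#' and a character vector of gene identifiers. Gene identifiers are opaque
#' strings; they need not all occur in any particular count matrix.
#'
#' @slot sets named list of character vectors (gene ids per set)
#' @slot descriptions named character vector, parallel to `sets`
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- NULL
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "set ids must be unique and non-NULL")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "empty gene sets are not allowed")
  if (!all(vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "gene ids must be character vectors")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must be parallel to sets")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set ids).
#' @return A [GeneSetCollection-class] object.
#' @examples
#' gsc <- GeneSetCollection(list(meristem = c("g1", "g2")))
#' geneSets(gsc)
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- names(sets)
  descriptions <- stats::setNames(as.character(descriptions), names(sets))
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn GeneSetCollection-class the named list of gene sets
#' @param x,object a `GeneSetCollection`
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection-class set descriptions
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets;",
      "sizes", paste(range(lengths(object@sets)), collapse = "-"), "\n")
})

#' Many-to-many ortholog relation between two species
#'
#' Stores unique (species A gene, species B gene) pairs, e.g. soybean
#' "Glyma." ids against Arabidopsis "AT" ids. Many-to-many mappings are
#' allowed; duplicated pairs are collapsed.
#'
#' @slot pairs two-column character matrix (species_a, species_b)
#' @export
setClass("OrthologMap", representation(pairs = "matrix"))

setValidity("OrthologMap", function(object) {
  p <- object@pairs
  if (!is.character(p) || ncol(p) != 2L)
    return("pairs must be a two-column character matrix")
  if (anyDuplicated(paste(p[, 1], p[, 2], sep = "\r")))
    return("duplicated ortholog pairs")
  TRUE
})

#' Construct an OrthologMap
#'
#' @param a,b character vectors of equal length: gene ids in species A and B.
#' @return An [OrthologMap-class] object with deduplicated pairs.
#' @examples
#' om <- OrthologMap(c("g1", "g1"), c("AT1", "AT1"))
#' nrow(orthologPairs(om))  # 1
#' @export
OrthologMap <- function(a, b) {
  stopifnot(length(a) == length(b))
  p <- cbind(species_a = as.character(a), species_b = as.character(b))
  p <- p[!duplicated(paste(p[, 1], p[, 2], sep = "\r")), , drop = FALSE]
  new("OrthologMap", pairs = p)
}

#' @describeIn OrthologMap-class two-column character matrix of pairs
#' @param x a `OrthologMap`
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))

#' @export
setMethod("orthologPairs", "OrthologMap", function(x) x@pairs)

setMethod("show", "OrthologMap", function(object) {
  cat("OrthologMap with", nrow(object@pairs), "pairs\n")
})

#' Coexpression modules with eigengenes and spatial classes
#'
#' Result container for the weighted coexpression workflow: per-gene module
#' labels (reserved label `"unassigned"` for genes in no module), module
#' eigengenes (samples x modules, unit variance, sign-oriented), member
#' lists, and a per-module spatial classification table.
#'
#' @slot labels named character vector, gene -> module id
#' @slot eigengenes numeric matrix, samples x modules
#' @slot classification DataFrame with one row per module
#'   (spatial_class, focal_subregion, fraction_members_specific)
#' @slot parameters list of the parameters used
#' @export
setClass("CoexpressionModules",
  representation(labels = "character", eigengenes = "matrix",
                 classification = "DataFrame", parameters = "list"))

setValidity("CoexpressionModules", function(object) {
  mods <- setdiff(unique(object@labels), "unassigned")
  if (!all(colnames(object@eigengenes) %in% c(mods, character())))
    return("eigengene columns must match module ids")
  TRUE
})

#' @describeIn CoexpressionModules-class gene -> module labels
#' @param x,object a `CoexpressionModules`
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @export
setMethod("moduleLabels", "CoexpressionModules", function(x) x@labels)

#' @describeIn CoexpressionModules-class samples x modules eigengene matrix
#' @export
setGeneric("moduleEigengenes", function(x) standardGeneric("moduleEigengenes"))

#' @export
setMethod("moduleEigengenes", "CoexpressionModules", function(x) x@eigengenes)

#' @describeIn CoexpressionModules-class list of member gene ids per module
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' @export
setMethod("moduleMembers", "CoexpressionModules", function(x) {
  mods <- setdiff(unique(x@labels), "unassigned")
  stats::setNames(lapply(mods, function(m) names(x@labels)[x@labels == m]), mods)
})

#' @describeIn CoexpressionModules-class spatial classification table
#' @export
setGeneric("moduleClassification", function(x) standardGeneric("moduleClassification"))

#' @export
setMethod("moduleClassification", "CoexpressionModules", function(x) x@classification)

setMethod("show", "CoexpressionModules", function(object) {
  mods <- setdiff(unique(object@labels), "unassigned")
  cat("CoexpressionModules:", length(mods), "modules over",
      length(object@labels), "genes (",
      sum(object@labels == "unassigned"), "unassigned )\n")
  if (nrow(object@classification))
    print(table(object@classification$spatial_class))
})
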