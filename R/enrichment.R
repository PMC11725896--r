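## GO-style term enrichment for arbitrary gene lists (subregion-specific
## sets, cluster markers, module members). Terms are tested as given; no
## ontology-graph propagation.

#' Hypergeometric term enrichment of a gene list
#'
#' Each annotation set is intersected with the background and tested with a
#' hypergeometric upper-tail p; q-values are BH over all tested terms.
#' Terms with zero overlap are not reported. Rows with `q < q_max` are
#' returned sorted by q, then p, then term id.
#'
#' @param query character vector of gene ids (subset of `background`).
#' @param annotation a [GeneSetCollection-class].
#' @param background explicit gene universe.
#' @param q_max reporting threshold on the BH q-value (default 0.05; use 1
#'   to keep all tested terms).
#' @return `data.frame`: term_id, term_description, overlap, set_size,
#'   term_size, background_size, p, q.
#' @export
enrichTerms <- function(query, annotation, background, q_max = 0.05) {
  background <- unique(background)
  query <- intersect(unique(query), background)
  if (!length(query)) stop("query empty after background intersection")
  sets <- lapply(geneSets(annotation), intersect, background)
  sets <- sets[lengths(sets) > 0]
  if (!length(sets))
    return(data.frame(term_id = character(), term_description = character(),
                      overlap = integer(), set_size = integer(),
                      term_size = integer(), background_size = integer(),
                      p = numeric(), q = numeric()))
  N <- length(background)
  ov <- vapply(sets, function(s) length(intersect(query, s)), integer(1))
  ts <- lengths(sets)
  p <- phyper(ov - 1, ts, N - ts, length(query), lower.tail = FALSE)
  q <- p.adjust(p, "BH")
  res <- data.frame(term_id = names(sets),
                    term_description = setDescriptions(annotation)[names(sets)],
                    overlap = ov, set_size = length(query), term_size = ts,
                    background_size = N, p = p, q = q, row.names = NULL)
  res <- res[res$overlap > 0 & res$q < q_max, , drop = FALSE]
  res[order(res$q, res$p, res$term_id), , drop = FALSE]
}

#' Top enriched terms
#'
#' First `k` rows of a sorted enrichment table (ties in q broken by p then
#' term id, as guaranteed by [enrichTerms()]); fewer rows when fewer pass.
#'
#' @param rows sorted enrichment table from [enrichTerms()].
#' @param k number of rows to keep (default 5).
#' @return the first `k` rows.
#' @export
topTerms <- function(rows, k = 5) {
  head(rows, k)
}

#' Fraction of one term set present in another
#'
#' `|A intersect B| / |A|`, the fraction of the first list's terms that
#' also occur in the second; 0 (with a warning) when A is empty.
#'
#' @param terms_a,terms_b character vectors of term ids.
#' @return numeric fraction in \[0, 1\].
#' @export
sharedTermFraction <- function(terms_a, terms_b) {
  terms_a <- unique(terms_a)
  if (!length(terms_a)) {
    warning("empty first term set")
    return(0)
  }
  length(intersect(terms_a, unique(terms_b))) / length(terms_a)
}
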