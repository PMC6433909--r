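#' EASE-score enrichment test for one gene set
#'
#' The EASE score is the conservative "modified Fisher exact" test:
#' the one-sided hypergeometric tail probability computed after
#' removing one gene from the query-term overlap. With a background of
#' `N` genes, a term of `K` genes, a query of `n` genes and an overlap
#' of `k` genes, the p-value is `P(X >= k - 1)` for
#' `X ~ Hypergeometric(N, K, n)`. An overlap of one therefore never
#' scores (p = 1), and an overlap of zero is p = 1 by convention.
#'
#' @param query Character vector of query gene ids (must lie in the
#'   background).
#' @param term_genes Character vector of the term's member gene ids.
#' @param background Character vector: the gene universe.
#' @return A list with `p`, `gene_count` (the raw, undecremented
#'   overlap) and `overlap_genes`.
#' @export
ease_test <- function(query, term_genes, background) {
  query <- unique(query); term_genes <- unique(term_genes)
  background <- unique(background)
  if (!all(query %in% background)) {
    rlang::abort("ease_test: query genes must be a subset of the background")
  }
  term_genes <- intersect(term_genes, background)
  overlap <- intersect(query, term_genes)
  k <- length(overlap)
  if (k == 0L) return(list(p = 1, gene_count = 0L, overlap_genes = character(0)))
  p <- stats::phyper(k - 2, length(term_genes),
                     length(background) - length(term_genes),
                     length(query), lower.tail = FALSE)
  list(p = min(1, p), gene_count = k, overlap_genes = overlap)
}

#' Enrich a gene list against a gene-set collection
#'
#' Applies [ease_test()] to every term of a collection (e.g. read with
#' [read_gmt()]) and returns the terms ranked by ascending p-value.
#'
#' @param query Character vector of query gene ids.
#' @param collection Tibble with `term_id`, `term_name` and a `genes`
#'   list-column (see [read_gmt()]).
#' @param background Gene universe; defaults to the union of all
#'   collection members and the query.
#' @param alpha Significance threshold reported in the `significant`
#'   column.
#' @return A tibble `term_id`, `term_name`, `gene_count`, `p`,
#'   `significant`, `genes` (comma-joined overlap), sorted by `p`.
#' @export
enrich_all <- function(query, collection, background = NULL, alpha = 0.05) {
  if (is.null(background)) {
    background <- unique(c(unlist(collection$genes), query))
  }
  res <- purrr::pmap_dfr(
    list(collection$term_id, collection$term_name, collection$genes),
    function(id, nm, members) {
      r <- ease_test(query, members, background)
      tibble::tibble(term_id = id, term_name = nm,
                     gene_count = r$gene_count, p = r$p,
                     genes = paste(sort(r$overlap_genes), collapse = ","))
    })
  res |>
    dplyr::mutate(significant = .data$p < alpha) |>
    dplyr::arrange(.data$p, .data$term_id) |>
    dplyr::select("term_id", "term_name", "gene_count", "p",
                  "significant", "genes")
}
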