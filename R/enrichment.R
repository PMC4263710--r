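#' Gene-set over-representation test
#'
#' One-sided hypergeometric test per annotation term: the probability of
#' drawing at least the observed number of term members when sampling the
#' gene set from the universe, P(X >= k | N, K, n). Terms with no hit in
#' the gene set are not tested (this sets the multiple-testing family
#' size); false discovery rates are Benjamini-Hochberg over the tested
#' terms.
#'
#' @param gene_set character vector of gene ids (must be a subset of
#'   `universe`)
#' @param universe character vector of all considered gene ids
#' @param term_map data frame with columns `gene_id`, `term_id` (a flat
#'   gene-to-term annotation; entries outside the universe are ignored)
#' @param min_hits minimum hits in the gene set for a term to be tested
#'   (default 1)
#' @return data frame sorted by `fdr` then `term_id` with columns
#'   `term_id`, `hits_in_set`, `set_size`, `hits_in_universe`,
#'   `universe_size`, `p_raw`, `fdr`
#' @export
enrich <- function(gene_set, universe, term_map, min_hits = 1) {
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  outside <- setdiff(gene_set, universe)
  if (length(outside) > 0) {
    stop("enrich: gene set members outside the universe: ",
         paste(head(outside, 10), collapse = ", "))
  }
  stopifnot(all(c("gene_id", "term_id") %in% names(term_map)))
  term_map <- unique(term_map[term_map$gene_id %in% universe,
                              c("gene_id", "term_id")])
  N <- length(universe)
  n <- length(gene_set)
  empty <- data.frame(term_id = character(0), hits_in_set = integer(0),
                      set_size = integer(0), hits_in_universe = integer(0),
                      universe_size = integer(0), p_raw = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE)
  if (n == 0 || nrow(term_map) == 0) return(empty)
  K_tab <- table(term_map$term_id)
  in_set <- term_map[term_map$gene_id %in% gene_set, , drop = FALSE]
  if (nrow(in_set) == 0) return(empty)
  k_tab <- table(in_set$term_id)
  terms <- names(k_tab)[k_tab >= min_hits]
  if (length(terms) == 0) return(empty)
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    term_id = terms, hits_in_set = k, set_size = n,
    hits_in_universe = K, universe_size = N,
    p_raw = p, fdr = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$fdr, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
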