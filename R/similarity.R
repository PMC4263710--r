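#' Inter-age similarity matrix
#'
#' Pearson correlation between the age-mean expression vectors of every pair
#' of ages, computed on log2(FPKM + 1) so a handful of very highly expressed
#' genes cannot dominate the correlation. Restricting `subset` to coding or
#' lncRNA genes compares the temporal coherence of the two gene classes.
#'
#' @param es an [expression_set()]
#' @param subset optional character vector of gene ids to restrict to
#'   (default: all genes)
#' @return symmetric ages x ages correlation matrix with unit diagonal,
#'   dimnames the age days
#' @export
age_similarity <- function(es, subset = NULL) {
  stopifnot(inherits(es, "expr_set"))
  am <- age_means(es)
  if (!is.null(subset)) {
    missing_ids <- setdiff(subset, rownames(am))
    if (length(missing_ids) > 0) {
      stop("age_similarity: unknown gene ids: ",
           paste(head(missing_ids, 5), collapse = ", "))
    }
    am <- am[subset, , drop = FALSE]
  }
  if (nrow(am) < 2) stop("age_similarity: need at least 2 genes")
  x <- log2(am + 1)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("age_similarity: zero-variance expression vector at age(s) ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  r <- cor(x)
  diag(r) <- 1
  r
}
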