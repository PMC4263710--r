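#' One-way ANOVA across ages, per gene
#'
#' Fixed-effects one-way ANOVA with age as the grouping factor, computed on
#' log2(FPKM + 1) (the package's working scale for expression comparisons).
#' The F statistic uses (a - 1, N - a) degrees of freedom, with a the number
#' of ages and N the number of samples. Genes whose values are all identical
#' get F = 0 and p = 1 by convention; genes with zero within-age variance
#' but real between-age differences get p = 0.
#'
#' @param es an [expression_set()]; needs at least two ages, each with at
#'   least two replicates
#' @param log_transform apply log2(FPKM + 1) before testing (default TRUE)
#' @return data frame with columns `gene_id`, `f_stat`, `p_raw`
#' @export
anova_across_ages <- function(es, log_transform = TRUE) {
  stopifnot(inherits(es, "expr_set"))
  age <- es$samples$age_day
  tab <- table(age)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("anova_across_ages: need >= 2 ages with >= 2 replicates each")
  }
  x <- es$values
  if (log_transform) x <- log2(x + 1)
  n_tot <- ncol(x)
  a <- length(tab)
  grand <- rowMeans(x)
  ss_tot <- rowSums((x - grand)^2)
  ss_between <- numeric(nrow(x))
  for (ag in names(tab)) {
    cols <- which(age == as.integer(ag))
    gm <- rowMeans(x[, cols, drop = FALSE])
    ss_between <- ss_between + length(cols) * (gm - grand)^2
  }
  ss_within <- ss_tot - ss_between
  df_b <- a - 1L
  df_w <- n_tot - a
  # guard against negative round-off and flag truly degenerate rows
  tol <- pmax(ss_tot, 1) * 1e-12
  ss_within <- pmax(ss_within, 0)
  f <- (ss_between / df_b) / (ss_within / df_w)
  p <- pf(f, df_b, df_w, lower.tail = FALSE)
  all_const <- ss_tot <= tol
  f[all_const] <- 0
  p[all_const] <- 1
  no_within <- !all_const & ss_within <= tol
  f[no_within] <- Inf
  p[no_within] <- 0
  data.frame(gene_id = rownames(x), f_stat = f, p_raw = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over a family of p-values,
#' returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values (q-values), capped at 1
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Maximum fold change over an ontogenic profile
#'
#' Ratio of the highest to the lowest age-mean FPKM, with a pseudocount to
#' stabilise low-expression genes: (max + pc) / (min + pc). Always >= 1.
#'
#' @param am an age-mean matrix from [age_means()]
#' @param pseudocount added to numerator and denominator (default 1)
#' @return named numeric vector of fold changes, one per gene
#' @export
max_fold_change <- function(am, pseudocount = 1) {
  hi <- apply(am, 1, max)
  lo <- apply(am, 1, min)
  setNames((hi + pseudocount) / (lo + pseudocount), rownames(am))
}

#' Call differentially expressed genes across a developmental time course
#'
#' A gene is significant when it passes all three criteria: (1) mean FPKM
#' over all samples above `mean_floor`; (2) maximum age-mean fold change
#' above `fc`; (3) Benjamini-Hochberg adjusted ANOVA p-value below `alpha`.
#' The BH family is all genes in the matrix.
#'
#' @param es an [expression_set()]
#' @param alpha adjusted-p threshold (default 0.05)
#' @param fc fold-change threshold (default 1.5)
#' @param mean_floor overall mean FPKM floor (default 1, strict `>`)
#' @param pseudocount pseudocount for the fold change (default 1)
#' @return data frame with one row per gene: `gene_id`, `f_stat`, `p_raw`,
#'   `p_adj`, `mean_fpkm_overall`, `max_fold_change`, `significant`
#' @export
call_de <- function(es, alpha = 0.05, fc = 1.5, mean_floor = 1,
                    pseudocount = 1) {
  stopifnot(inherits(es, "expr_set"))
  aov_res <- anova_across_ages(es)
  am <- age_means(es)
  res <- data.frame(
    gene_id = aov_res$gene_id,
    f_stat = aov_res$f_stat,
    p_raw = aov_res$p_raw,
    p_adj = bh_adjust(aov_res$p_raw),
    mean_fpkm_overall = rowMeans(es$values),
    max_fold_change = as.numeric(max_fold_change(am, pseudocount)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res$significant <- res$mean_fpkm_overall > mean_floor &
    res$max_fold_change > fc &
    res$p_adj < alpha
  res
}
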