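#' Build nearest-coding-neighbour gene pairs
#'
#' One pair per anchor gene of the requested class: the anchor together
#' with its nearest coding neighbour (smallest genomic gap on the same
#' chromosome, ties broken by start then gene_id; the anchor never pairs
#' with itself). Anchors on chromosomes without any other coding gene are
#' dropped. Coding anchors give PC-PC pairs; lncRNA anchors give PC-NC
#' pairs, with the lncRNA as the anchor.
#'
#' @param gs a classified `gene_set`
#' @param anchor_klass `"coding"` or `"lncRNA"`
#' @return data frame with columns `id_a` (anchor), `id_b` (coding
#'   neighbour), `pair_class` (`PC-PC` or `PC-NC`), `gap_bp`, `tier`
#'   (`"all"`)
#' @export
build_pairs <- function(gs, anchor_klass = c("lncRNA", "coding")) {
  stopifnot(inherits(gs, "gene_set"))
  anchor_klass <- match.arg(anchor_klass)
  if (all(is.na(gs$klass))) stop("build_pairs: gene set is not classified")
  pair_class <- if (anchor_klass == "coding") "PC-PC" else "PC-NC"
  anchors <- gs[gs$klass == anchor_klass, , drop = FALSE]
  coding <- gs[gs$klass == "coding", , drop = FALSE]
  out <- vector("list", length(unique(anchors$chrom)))
  names(out) <- unique(anchors$chrom)
  for (ch in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    cand <- coding[coding$chrom == ch, , drop = FALSE]
    if (nrow(cand) == 0) next
    # gap matrix anchors x candidates; self-pairs masked
    gaps <- outer(a$start, cand$start, pmax) - outer(a$end, cand$end, pmin)
    gaps[gaps < 0] <- 0L
    self <- outer(a$gene_id, cand$gene_id, "==")
    gaps[self] <- NA_integer_
    cand_rank <- order(cand$start, cand$gene_id)
    pick <- apply(gaps, 1, function(g) {
      ok <- which(!is.na(g))
      if (length(ok) == 0) return(NA_integer_)
      ok[order(g[ok], match(ok, cand_rank))][1]
    })
    keep <- !is.na(pick)
    if (!any(keep)) next
    out[[ch]] <- data.frame(
      id_a = a$gene_id[keep],
      id_b = cand$gene_id[pick[keep]],
      gap_bp = as.integer(gaps[cbind(which(keep), pick[keep])]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(id_a = character(0), id_b = character(0),
                      gap_bp = integer(0), stringsAsFactors = FALSE)
  }
  res <- res[order(res$id_a), , drop = FALSE]
  res$pair_class <- rep(pair_class, nrow(res))
  res$tier <- rep("all", nrow(res))
  rownames(res) <- NULL
  res[, c("id_a", "id_b", "pair_class", "gap_bp", "tier")]
}

#' High-stringency pair filter
#'
#' Restricts pairs to those within `max_gap` bases (strict `<`) whose
#' expression supports the pair: a PC-NC pair requires the lncRNA anchor to
#' be expressed; a PC-PC pair requires at least one of the two genes to be
#' expressed.
#'
#' @param pairs a pair table from [build_pairs()]
#' @param expressed character vector of expressed gene ids (see
#'   [expressed_genes()])
#' @param max_gap maximum genomic gap in bases (default 10 kb)
#' @return the subset of `pairs`, with `tier` set to `"hi"`
#' @export
filter_hi <- function(pairs, expressed, max_gap = 10000) {
  keep_expr <- ifelse(pairs$pair_class == "PC-NC",
                      pairs$id_a %in% expressed,
                      pairs$id_a %in% expressed | pairs$id_b %in% expressed)
  out <- pairs[pairs$gap_bp < max_gap & keep_expr, , drop = FALSE]
  out$tier <- rep("hi", nrow(out))
  rownames(out) <- NULL
  out
}

# Pearson r between rows a and b of the log2(FPKM+1) age-mean matrix,
# vectorized over pairs; constant profiles give NA.
profile_cor <- function(am, ids_a, ids_b) {
  x <- log2(am + 1)
  a <- x[ids_a, , drop = FALSE]
  b <- x[ids_b, , drop = FALSE]
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  unname(pmin(1, pmax(-1, r)))
}

#' Ontogenic correlation of gene pairs
#'
#' Pearson correlation across the ordered ages between the two genes'
#' log2(FPKM + 1) age-mean profiles. Pairs involving a constant profile get
#' an undefined (`NA`) correlation; these are excluded from downstream
#' distributions but remain in the table.
#'
#' @param pairs a pair table from [build_pairs()], [filter_hi()] or
#'   [random_pair_null()]
#' @param am an age-mean matrix from [age_means()] covering all paired genes
#' @return `pairs` with a numeric column `r` appended
#' @export
pair_correlations <- function(pairs, am) {
  missing_ids <- setdiff(c(pairs$id_a, pairs$id_b), rownames(am))
  if (length(missing_ids) > 0) {
    stop("pair_correlations: genes absent from expression: ",
         paste(head(missing_ids, 5), collapse = ", "))
  }
  pairs$r <- if (nrow(pairs) == 0) numeric(0) else
    profile_cor(am, pairs$id_a, pairs$id_b)
  pairs
}

#' Random coding-pair null distribution
#'
#' Draws `n_pairs` uniform random unordered pairs of distinct annotated
#' coding genes (pairs may repeat across draws) and computes their
#' ontogenic correlation, giving the no-linkage null against which the
#' neighbour-pair distributions are compared.
#'
#' @param gs a classified `gene_set` with at least two coding genes
#' @param am an age-mean matrix covering the coding genes
#' @param n_pairs number of random pairs (default 10000)
#' @param seed integer seed for reproducibility; the caller's RNG state is
#'   left untouched
#' @return pair table with `pair_class` `"random-PC"`, `gap_bp` `NA` and a
#'   correlation column `r`
#' @export
random_pair_null <- function(gs, am, n_pairs = 10000, seed = 1) {
  stopifnot(inherits(gs, "gene_set"))
  coding <- gs$gene_id[gs$klass == "coding" & !is.na(gs$klass)]
  if (length(coding) < 2) stop("random_pair_null: need >= 2 coding genes")
  if (n_pairs == 0) {
    out <- data.frame(id_a = character(0), id_b = character(0),
                      pair_class = character(0), gap_bp = integer(0),
                      tier = character(0), stringsAsFactors = FALSE)
    return(pair_correlations(out, am))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n <- length(coding)
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n - 1L, n_pairs, replace = TRUE)
  j <- j + (j >= i)   # distinct second member, uniform over the rest
  out <- data.frame(
    id_a = coding[i], id_b = coding[j],
    pair_class = "random-PC", gap_bp = NA_integer_, tier = "all",
    stringsAsFactors = FALSE
  )
  pair_correlations(out, am)
}

#' Histogram of pair correlations
#'
#' Bins defined correlations into fixed-width intervals over \[-1, 1\]
#' (left-closed, the last bin closed on both sides) and locates the modal
#' bin. A tie between equally tall bins is resolved towards 0 (smaller
#' absolute midpoint, then smaller midpoint).
#'
#' @param r numeric vector of correlations (NAs are dropped and counted)
#' @param bin_width histogram bin width (default 0.1)
#' @return list with `breaks`, `mids`, `counts`, `peak` (midpoint of the
#'   modal bin), `n` (defined correlations) and `n_undefined`
#' @export
r_distribution <- function(r, bin_width = 0.1) {
  n_undefined <- sum(is.na(r))
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("r_distribution: no defined correlations")
  breaks <- round(seq(-1, 1, by = bin_width), 10)
  if (abs(breaks[length(breaks)] - 1) > 1e-12) breaks <- c(breaks, 1)
  idx <- findInterval(r, breaks, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > length(breaks) - 1] <- length(breaks) - 1
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  mids <- round((breaks[-length(breaks)] + breaks[-1]) / 2, 10)
  best <- order(-counts, abs(mids), mids)[1]
  list(breaks = breaks, mids = mids, counts = counts,
       peak = mids[best], n = length(r), n_undefined = n_undefined)
}

#' Concordant cis-candidate pairs
#'
#' From high-stringency PC-NC pairs, keeps the candidate cis pairs in which
#' the lncRNA changes significantly across development (adjusted ANOVA p
#' below `alpha`), the genes lie within `max_gap` bases, and both genes
#' carry the same ontogenic pattern label. Pairs whose members lack a
#' pattern assignment are dropped.
#'
#' @param pairs a PC-NC pair table (typically tier `hi`)
#' @param de a DE table from [call_de()]
#' @param assignments pattern assignments from [cluster_patterns()]
#' @param alpha adjusted-p threshold for the lncRNA (default 0.05)
#' @param max_gap maximum genomic gap (default 10 kb, strict `<`)
#' @return the subset of `pairs` with columns `label_a`, `label_b`,
#'   `p_adj_nc` appended
#' @export
concordant_pairs <- function(pairs, de, assignments, alpha = 0.05,
                             max_gap = 10000) {
  if (any(pairs$pair_class != "PC-NC")) {
    stop("concordant_pairs: expects PC-NC pairs")
  }
  p_adj <- setNames(de$p_adj, de$gene_id)
  lab <- setNames(assignments$label, assignments$gene_id)
  pairs$p_adj_nc <- unname(p_adj[pairs$id_a])
  pairs$label_a <- unname(lab[pairs$id_a])
  pairs$label_b <- unname(lab[pairs$id_b])
  keep <- !is.na(pairs$p_adj_nc) & pairs$p_adj_nc < alpha &
    pairs$gap_bp < max_gap &
    !is.na(pairs$label_a) & !is.na(pairs$label_b) &
    pairs$label_a == pairs$label_b
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
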