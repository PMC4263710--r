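#' Developmental stage windows
#'
#' Age-day groupings used to label ontogenic clusters: perinatal (-2, 0),
#' neonatal (1-10), adolescent (15-30) and adult (45, 60). Day 30 sits on
#' the adolescent/adult boundary in the literature; it defaults to
#' adolescent here and can be moved by supplying custom windows.
#'
#' @param perinatal,neonatal,adolescent,adult integer vectors of age days
#' @return named list of stage windows
#' @export
stage_windows <- function(perinatal = c(-2L, 0L),
                          neonatal = c(1L, 3L, 5L, 10L),
                          adolescent = c(15L, 20L, 25L, 30L),
                          adult = c(45L, 60L)) {
  w <- list(perinatal = perinatal, neonatal = neonatal,
            adolescent = adolescent, adult = adult)
  all_ages <- unlist(w)
  if (anyDuplicated(all_ages)) stop("stage_windows: windows must be disjoint")
  w
}

stage_of_age <- function(age, windows) {
  for (nm in names(windows)) if (age %in% windows[[nm]]) return(nm)
  NA_character_
}

#' Z-score ontogenic profiles
#'
#' Converts age-mean FPKM profiles to per-gene z-scores of log2(FPKM + 1):
#' z = (x - mean(x)) / sd_pop(x), using the population (divide-by-n)
#' standard deviation. Constant profiles map to all-zero rows rather than
#' NaN.
#'
#' @param am an age-mean matrix from [age_means()]
#' @return matrix of z-scores with the same dimensions and dimnames; rows
#'   have mean 0 and population SD 1 unless constant
#' @export
zscore_profiles <- function(am) {
  x <- log2(am + 1)
  mu <- rowMeans(x)
  centered <- x - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  z <- centered / sd_pop
  z[sd_pop == 0, ] <- 0
  attr(z, "ages") <- attr(am, "ages")
  z
}

#' Cluster ontogenic expression patterns
#'
#' Agglomerative average-linkage clustering on Pearson correlation distance
#' (d = 1 - r) of z-scored profiles, cut into `k` clusters. Each cluster is
#' labelled by the developmental stage window containing the age at which
#' its centroid profile peaks (a perinatal peak maps to the neonatal
#' label). When `k > 3`, only the three largest clusters receive stage
#' labels; the rest are labelled `other`. Genes with zero-variance profiles
#' (undefined correlation) are excluded from the tree and labelled `other`
#' with no cluster index.
#'
#' Gene order does not affect the result: genes are canonically sorted by
#' `gene_id` before the linkage is built.
#'
#' @param z a z-score matrix from [zscore_profiles()] (rownames gene ids,
#'   columns ages)
#' @param k number of clusters to cut (default 3)
#' @param windows stage windows from [stage_windows()]
#' @return data frame with columns `gene_id`, `cluster`, `label`; the
#'   z-matrix (sorted by gene_id) is attached as attribute `zprofile` and
#'   the cluster centroids as attribute `centroids`
#' @export
cluster_patterns <- function(z, k = 3, windows = stage_windows()) {
  ages <- attr(z, "ages")
  if (is.null(ages)) ages <- as.integer(colnames(z))
  z <- z[order(rownames(z)), , drop = FALSE]
  if (nrow(z) < k) stop("cluster_patterns: fewer genes than clusters")
  degenerate <- rowSums(z != 0) == 0
  zc <- z[!degenerate, , drop = FALSE]
  if (nrow(zc) < k) stop("cluster_patterns: fewer variable genes than clusters")
  d <- as.dist(1 - cor(t(zc)))
  tree <- hclust(d, method = "average")
  cl <- cutree(tree, k = k)
  sizes <- sort(table(cl), decreasing = TRUE)
  major <- as.integer(names(sizes))[seq_len(min(3, k))]
  labels <- vapply(sort(unique(cl)), function(ci) {
    if (!(ci %in% major)) return("other")
    centroid <- colMeans(zc[cl == ci, , drop = FALSE])
    stage <- stage_of_age(ages[which.max(centroid)], windows)
    if (is.na(stage)) return("other")
    if (stage == "perinatal") "neonatal" else stage
  }, character(1))
  names(labels) <- as.character(sort(unique(cl)))
  out <- data.frame(
    gene_id = rownames(z),
    cluster = NA_integer_,
    label = "other",
    stringsAsFactors = FALSE
  )
  out$cluster[!degenerate] <- as.integer(cl)
  out$label[!degenerate] <- labels[as.character(cl)]
  centroids <- t(vapply(sort(unique(cl)), function(ci) {
    colMeans(zc[cl == ci, , drop = FALSE])
  }, numeric(ncol(zc))))
  rownames(centroids) <- as.character(sort(unique(cl)))
  attr(out, "zprofile") <- z
  attr(out, "centroids") <- centroids
  attr(out, "ages") <- ages
  out
}

#' Chromosomal density of pattern-labelled genes
#'
#' Counts labelled genes per chromosome, strand and pattern label — a plain
#' tabular replacement for an idiogram figure.
#'
#' @param assignments output of [cluster_patterns()]
#' @param gs a `gene_set` containing every assigned gene
#' @return data frame with columns `chrom`, `strand`, `label`, `n`
#' @export
chromosome_density <- function(assignments, gs) {
  stopifnot(inherits(gs, "gene_set"))
  missing_ids <- setdiff(assignments$gene_id, gs$gene_id)
  if (length(missing_ids) > 0) {
    stop("chromosome_density: genes absent from annotation: ",
         paste(head(missing_ids, 10), collapse = ", "))
  }
  if (nrow(assignments) == 0) {
    return(data.frame(chrom = character(0), strand = character(0),
                      label = character(0), n = integer(0)))
  }
  idx <- match(assignments$gene_id, gs$gene_id)
  tab <- as.data.frame(table(chrom = gs$chrom[idx], strand = gs$strand[idx],
                             label = assignments$label),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tab <- tab[tab$n > 0, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
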