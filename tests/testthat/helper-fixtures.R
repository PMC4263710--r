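# Shared fixtures and independent brute-force oracles.

# a gene_set from a compact spec: one row per gene, single exon spanning the
# gene unless exons are supplied
make_genes <- function(gene_id, chrom, start, end,
                       strand = rep("+", length(gene_id)),
                       biotype = rep("protein_coding", length(gene_id)),
                       source = rep("primary", length(gene_id)),
                       exons = NULL) {
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = start, end = end, biotype = biotype,
                   source = source, stringsAsFactors = FALSE)
  if (!is.null(exons)) df$exons <- exons
  gene_set(df)
}

# a random classified gene set on a small genome
random_genes <- function(n, n_chrom = 3, genome_len = 1e6,
                         coding_frac = 0.6) {
  start <- sample.int(genome_len - 5000L, n, replace = TRUE)
  len <- sample(200:4000, n, replace = TRUE)
  biotype <- ifelse(runif(n) < coding_frac, "protein_coding", "lincRNA")
  classify_genes(make_genes(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = biotype
  ))
}

# expression set from a genes x samples matrix laid out age-major
make_expr <- function(values, ages, replicates) {
  n_age <- length(ages)
  age_idx <- rep(seq_len(n_age), each = replicates)
  samples <- data.frame(
    sample_id = paste0("s", seq_len(n_age * replicates)),
    age_day = ages[age_idx],
    replicate = rep(seq_len(replicates), times = n_age),
    stringsAsFactors = FALSE
  )
  colnames(values) <- samples$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  expression_set(values, samples)
}

# O(n^2) nearest-coding-neighbour scan (independent of the package's search)
bf_nearest <- function(gs) {
  res <- list()
  for (i in seq_len(nrow(gs))) {
    g <- gs[i, ]
    best <- NULL
    for (j in seq_len(nrow(gs))) {
      if (i == j) next
      cand <- gs[j, ]
      if (cand$klass != "coding" || cand$chrom != g$chrom) next
      gap <- max(0, max(g$start, cand$start) - min(g$end, cand$end))
      if (is.null(best) || gap < best$gap ||
          (gap == best$gap && (cand$start < best$start ||
             (cand$start == best$start && cand$gene_id < best$id)))) {
        best <- list(id = cand$gene_id, gap = gap, start = cand$start)
      }
    }
    res[[g$gene_id]] <- best
  }
  res
}

# O(n^2) all-pairs overlap scan for the annotation merge
bf_merge_kept <- function(primary, secondary) {
  kept <- logical(nrow(secondary))
  for (i in seq_len(nrow(secondary))) {
    s <- secondary[i, ]
    ov <- FALSE
    for (j in seq_len(nrow(primary))) {
      p <- primary[j, ]
      if (s$chrom == p$chrom && s$start < p$end && p$start < s$end) {
        ov <- TRUE
        break
      }
    }
    kept[i] <- !ov
  }
  secondary$gene_id[kept]
}

# textbook sum-of-squares one-way ANOVA for a single numeric vector
bf_anova <- function(x, group) {
  group <- factor(group)
  grand <- mean(x)
  ssb <- sum(tapply(x, group, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(x, group, function(v) sum((v - mean(v))^2)))
  df_b <- nlevels(group) - 1
  df_w <- length(x) - nlevels(group)
  f <- (ssb / df_b) / (ssw / df_w)
  list(f = f, p = pf(f, df_b, df_w, lower.tail = FALSE))
}

# independent step-up Benjamini-Hochberg (direct formula, input order)
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# Pearson r by the covariance formula
bf_pearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}
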