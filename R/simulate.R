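#' Simulation configuration
#'
#' Parameters of the synthetic developmental transcriptome generator. The
#' defaults emulate the structure of a postnatal liver maturation study:
#' 12 ages from day -2 to day 60 with 3 replicates each, coding genes and
#' lncRNAs with lncRNAs roughly 10-fold less abundant, three ontogenic
#' pattern classes (neonatal-, adolescent- and adult-enriched, with the
#' neonatal class the largest) plus non-changing genes, and planted
#' cis-coupled coding/lncRNA neighbour pairs within 10 kb.
#'
#' @param seed integer RNG seed; the whole simulation is deterministic
#'   given the config
#' @param n_chrom,chrom_length synthetic genome shape
#' @param n_coding,n_lncrna,n_small_rna gene counts per class (totals;
#'   planted pairs draw from these pools)
#' @param ages integer vector of age days
#' @param replicates replicates per age
#' @param fractions named fractions of the pattern classes `neonatal`,
#'   `adolescent`, `adult`, `flat`; must sum to 1
#' @param lncrna_abundance_ratio lncRNA baseline abundance relative to
#'   coding genes (default 0.1, i.e. ~10-fold lower)
#' @param within_age_cv coefficient of variation of the multiplicative
#'   lognormal replicate noise (coding genes)
#' @param lncrna_cv_multiplier factor on `within_age_cv` for lncRNAs and
#'   small RNAs, reflecting the noisier measurement of low-abundance
#'   transcripts (default 1.5)
#' @param pattern_fc true max/min fold change of non-flat expression curves
#' @param class_purity weight of the class archetype in each gene's profile
#'   (within-class profile correlation is approximately this value)
#' @param n_cis number of planted concordant cis pairs (coding + lncRNA,
#'   same pattern class, correlated at `cis_rho`, gap < `cis_max_gap`)
#' @param cis_max_gap upper bound (exclusive) on planted pair gaps, bases
#' @param cis_rho coupling weight of planted pairs, in \[-1, 1\]
#' @param n_decoy number of planted discordant decoy pairs (adjacent like
#'   cis pairs but with different pattern classes and no coupling)
#' @param antisense_frac fraction of unpaired lncRNAs placed antisense
#'   (nested opposite-strand) inside a coding gene
#' @param secondary_frac fraction of (non-antisense) lncRNAs attributed to
#'   the secondary model source, which carries no biotype information
#' @param n_secondary_overlap extra secondary models written overlapping
#'   primary genes; [merge_nonoverlapping()] must exclude them
#' @param coding_baseline_meanlog,baseline_sdlog lognormal parameters of
#'   per-gene baseline FPKM for coding genes
#' @return a list of class `sim_config`
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 5,
                       chrom_length = 6e6,
                       n_coding = 500,
                       n_lncrna = 150,
                       n_small_rna = 20,
                       ages = c(-2L, 0L, 1L, 3L, 5L, 10L, 15L, 20L, 25L, 30L, 45L, 60L),
                       replicates = 3,
                       fractions = c(neonatal = 0.36, adolescent = 0.09,
                                     adult = 0.15, flat = 0.40),
                       lncrna_abundance_ratio = 0.1,
                       within_age_cv = 0.2,
                       lncrna_cv_multiplier = 1.5,
                       pattern_fc = 4,
                       class_purity = 0.9,
                       n_cis = 40,
                       cis_max_gap = 10000,
                       cis_rho = 0.8,
                       n_decoy = 40,
                       antisense_frac = 0.15,
                       secondary_frac = 0.3,
                       n_secondary_overlap = 10,
                       coding_baseline_meanlog = log(20),
                       baseline_sdlog = 1) {
  cfg <- list(seed = seed, n_chrom = n_chrom, chrom_length = chrom_length,
              n_coding = n_coding, n_lncrna = n_lncrna,
              n_small_rna = n_small_rna, ages = as.integer(ages),
              replicates = replicates, fractions = fractions,
              lncrna_abundance_ratio = lncrna_abundance_ratio,
              within_age_cv = within_age_cv,
              lncrna_cv_multiplier = lncrna_cv_multiplier,
              pattern_fc = pattern_fc,
              class_purity = class_purity, n_cis = n_cis,
              cis_max_gap = cis_max_gap, cis_rho = cis_rho,
              n_decoy = n_decoy, antisense_frac = antisense_frac,
              secondary_frac = secondary_frac,
              n_secondary_overlap = n_secondary_overlap,
              coding_baseline_meanlog = coding_baseline_meanlog,
              baseline_sdlog = baseline_sdlog)
  required_classes <- c("neonatal", "adolescent", "adult", "flat")
  if (!setequal(names(fractions), required_classes)) {
    stop("sim_config: fractions must be named ",
         paste(required_classes, collapse = ", "))
  }
  if (abs(sum(fractions) - 1) > 1e-8) stop("sim_config: fractions must sum to 1")
  if (cis_rho < -1 || cis_rho > 1) stop("sim_config: cis_rho must lie in [-1, 1]")
  counts <- c(n_chrom, n_coding, n_lncrna, n_small_rna, n_cis, n_decoy,
              n_secondary_overlap)
  if (any(counts < 0)) stop("sim_config: counts must be non-negative")
  if (n_cis + n_decoy > min(n_coding, n_lncrna)) {
    stop("sim_config: n_cis + n_decoy exceeds available coding or lncRNA genes")
  }
  if (length(ages) < 2 || replicates < 1) {
    stop("sim_config: need >= 2 ages and >= 1 replicate")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Ontogenic archetype curve
#'
#' The noise-free expression shape of a pattern class over the ages: a
#' Gaussian bump over age rank peaking at day 3 (neonatal), day 20
#' (adolescent) or day 60 (adult), scaled to run from 1 at its lowest age
#' to `fc` at its peak. The flat class is constant 1.
#'
#' @param pattern one of `neonatal`, `adolescent`, `adult`, `flat`
#' @param ages integer vector of age days (must contain the class peak age
#'   for non-flat patterns)
#' @param fc peak/trough ratio of the curve (default 4)
#' @return positive numeric vector, one value per age
#' @export
archetype <- function(pattern, ages, fc = 4) {
  peaks <- c(neonatal = 3L, adolescent = 20L, adult = 60L)
  if (identical(pattern, "flat")) return(rep(1, length(ages)))
  if (!pattern %in% names(peaks)) stop("archetype: unknown pattern: ", pattern)
  t0 <- match(peaks[[pattern]], ages)
  if (is.na(t0)) stop("archetype: ages must contain day ", peaks[[pattern]])
  t <- seq_along(ages)
  bump <- exp(-(t - t0)^2 / (2 * 1.5^2))
  bump <- (bump - min(bump)) / (max(bump) - min(bump))
  1 + (fc - 1) * bump
}

# population-SD standardization; zero-variance input returns zeros
standardize_pop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) return(rep(0, length(x)))
  (x - mu) / s
}

# smooth standardized noise curve over the ages (3-point moving average of
# white noise), used for per-gene profile individuality
smooth_noise <- function(n) {
  repeat {
    x <- rnorm(n + 2)
    e <- (x[1:n] + x[2:(n + 1)] + x[3:(n + 2)]) / 3
    if (sd(e) > 0) return(standardize_pop(e))
  }
}

# split a span into n_ex exons with introns between them (0-based half-open)
make_exons <- function(start, end, n_ex) {
  span <- end - start
  n_ex <- max(1L, min(n_ex, span %/% 4L))
  if (n_ex == 1L) return(cbind(start = start, end = end))
  cuts <- sort(sample(seq(start + 1L, end - 1L), 2L * (n_ex - 1L)))
  bounds <- c(start, cuts, end)
  idx <- seq(1, length(bounds) - 1, by = 2)
  m <- cbind(start = bounds[idx], end = bounds[idx + 1])
  m[m[, 1] < m[, 2], , drop = FALSE]
}

#' Simulate a developmental transcriptome with planted structure
#'
#' Generates a synthetic genome annotation (primary biotype-bearing source
#' plus a secondary biotype-free lncRNA model source, with deliberate
#' overlapping secondary decoys) and a replicated multi-age FPKM matrix.
#' Non-flat genes follow their class archetype mixed with per-gene smooth
#' individuality at weight `class_purity`; planted cis pairs sit within
#' `cis_max_gap` bases and share the coding partner's profile at coupling
#' weight `cis_rho`; decoy pairs are equally close but carry different
#' pattern classes. Replicate FPKM values are the true age means times
#' lognormal noise with the configured coefficient of variation. Full
#' ground truth is returned.
#'
#' @param config a [sim_config()]
#' @return a list of class `ontomap_sim` with elements `genes` (the merged
#'   `gene_set` underlying the expression matrix), `primary` and
#'   `secondary` (`gene_set`s as two annotation sources; `secondary`
#'   includes the overlapping decoys), `expr` (an `expr_set`), `truth`
#'   (list of data frames `genes` and `pairs`), and `config`
#' @export
simulate_ontogeny <- function(config = sim_config()) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  ages <- cfg$ages
  n_age <- length(ages)
  n_genes <- cfg$n_coding + cfg$n_lncrna + cfg$n_small_rna
  gene_id <- c(sprintf("PC%04d", seq_len(cfg$n_coding)),
               sprintf("NC%04d", seq_len(cfg$n_lncrna)),
               sprintf("SR%04d", seq_len(cfg$n_small_rna)))
  klass <- rep(c("coding", "lncRNA", "small_rna"),
               c(cfg$n_coding, cfg$n_lncrna, cfg$n_small_rna))

  ## ---- pattern classes -------------------------------------------------
  classes <- names(cfg$fractions)
  nonflat <- setdiff(classes, "flat")
  nonflat_mass <- sum(cfg$fractions[nonflat])
  pattern <- sample(classes, n_genes, replace = TRUE, prob = cfg$fractions)
  pattern[klass == "small_rna"] <- "flat"

  pc_pool <- which(klass == "coding")
  nc_pool <- which(klass == "lncRNA")
  cis_pc <- pc_pool[seq_len(cfg$n_cis)]
  cis_nc <- nc_pool[seq_len(cfg$n_cis)]
  decoy_pc <- pc_pool[cfg$n_cis + seq_len(cfg$n_decoy)]
  decoy_nc <- nc_pool[cfg$n_cis + seq_len(cfg$n_decoy)]
  pair_class_draw <- function(n) {
    if (nonflat_mass == 0) rep("flat", n)
    else sample(nonflat, n, replace = TRUE,
                prob = cfg$fractions[nonflat] / nonflat_mass)
  }
  if (cfg$n_cis > 0) {
    cls <- pair_class_draw(cfg$n_cis)
    pattern[cis_pc] <- cls
    pattern[cis_nc] <- cls
  }
  if (cfg$n_decoy > 0) {
    cls_a <- pair_class_draw(cfg$n_decoy)
    pattern[decoy_pc] <- cls_a
    if (nonflat_mass > 0 && length(nonflat) > 1) {
      pattern[decoy_nc] <- vapply(cls_a, function(cl) {
        sample(setdiff(nonflat, cl), 1)
      }, character(1))
    } else {
      pattern[decoy_nc] <- cls_a
    }
  }

  ## ---- expression profiles --------------------------------------------
  shapes <- lapply(setNames(nonflat, nonflat), function(cl) {
    standardize_pop(log2(archetype(cl, ages, cfg$pattern_fc)))
  })
  w <- cfg$class_purity
  x <- matrix(0, n_genes, n_age)
  for (i in seq_len(n_genes)) {
    if (pattern[i] != "flat") {
      x[i, ] <- standardize_pop(sqrt(w) * shapes[[pattern[i]]] +
                                  sqrt(1 - w) * smooth_noise(n_age))
    }
  }
  rho <- cfg$cis_rho
  for (p in seq_len(cfg$n_cis)) {
    i_pc <- cis_pc[p]; i_nc <- cis_nc[p]
    if (pattern[i_nc] == "flat") next
    x[i_nc, ] <- standardize_pop(rho * x[i_pc, ] +
                                   sqrt(1 - rho^2) * smooth_noise(n_age))
  }

  baseline <- rlnorm(n_genes, cfg$coding_baseline_meanlog, cfg$baseline_sdlog)
  baseline[klass == "lncRNA"] <- baseline[klass == "lncRNA"] *
    cfg$lncrna_abundance_ratio
  baseline[klass == "small_rna"] <- baseline[klass == "small_rna"] * 0.02

  # profiles are planted on the analysis scale log2(FPKM + 1): the baseline
  # is the minimum age mean and (max + 1)/(min + 1) equals pattern_fc exactly
  true_mean <- matrix(0, n_genes, n_age)
  lfc <- log2(cfg$pattern_fc)
  for (i in seq_len(n_genes)) {
    xi <- x[i, ]
    rng <- max(xi) - min(xi)
    true_mean[i, ] <- if (rng == 0) {
      rep(baseline[i], n_age)
    } else {
      2^(log2(baseline[i] + 1) + lfc * (xi - min(xi)) / rng) - 1
    }
  }

  ## ---- replicate noise -------------------------------------------------
  rep_idx <- rep(seq_len(cfg$replicates), times = n_age)
  age_idx <- rep(seq_len(n_age), each = cfg$replicates)
  age_tag <- ifelse(ages < 0, paste0("m", -ages), as.character(ages))
  sample_id <- paste0("d", age_tag[age_idx], "_r", rep_idx)
  samples <- data.frame(sample_id = sample_id, age_day = ages[age_idx],
                        replicate = rep_idx, stringsAsFactors = FALSE)
  cv_gene <- ifelse(klass == "coding", cfg$within_age_cv,
                    cfg$within_age_cv * cfg$lncrna_cv_multiplier)
  sdlog <- sqrt(log(1 + cv_gene^2))
  mu <- log(true_mean[, age_idx, drop = FALSE]) - sdlog^2 / 2
  values <- matrix(rlnorm(length(mu), meanlog = mu, sdlog = sdlog),
                   nrow = n_genes, dimnames = list(gene_id, sample_id))

  ## ---- genome placement ------------------------------------------------
  len <- integer(n_genes)
  len[klass == "coding"] <- sample(5000:30000, cfg$n_coding, replace = TRUE)
  len[klass == "lncRNA"] <- sample(1000:15000, cfg$n_lncrna, replace = TRUE)
  len[klass == "small_rna"] <- sample(80:300, cfg$n_small_rna, replace = TRUE)

  paired <- c(cis_pc, cis_nc, decoy_pc, decoy_nc)
  unpaired_nc <- setdiff(nc_pool, paired)
  n_anti <- round(cfg$antisense_frac * length(unpaired_nc))
  unpaired_pc <- setdiff(pc_pool, paired)
  n_anti <- min(n_anti, length(unpaired_pc))
  anti_nc <- if (n_anti > 0) sample(unpaired_nc, n_anti) else integer(0)
  anti_host <- if (n_anti > 0) sample(unpaired_pc, n_anti) else integer(0)
  len[anti_nc] <- pmin(len[anti_host] - 10L,
                       sample(500:5000, n_anti, replace = TRUE))

  pair_gap <- sample.int(cfg$cis_max_gap, cfg$n_cis + cfg$n_decoy,
                         replace = TRUE) - 1L
  units <- c(
    lapply(seq_len(cfg$n_cis + cfg$n_decoy), function(p) {
      a <- c(cis_pc, decoy_pc)[p]; b <- c(cis_nc, decoy_nc)[p]
      list(genes = c(a, b), gaps = pair_gap[p])
    }),
    lapply(setdiff(seq_len(n_genes), c(paired, anti_nc)), function(i) {
      list(genes = i, gaps = integer(0))
    })
  )
  units <- units[sample.int(length(units))]
  chrom_of_unit <- rep_len(seq_len(cfg$n_chrom), length(units))

  start <- integer(n_genes); end <- integer(n_genes)
  chrom <- character(n_genes)
  for (ch in seq_len(cfg$n_chrom)) {
    pos <- 0L
    prev_pair <- FALSE
    for (u in units[chrom_of_unit == ch]) {
      is_pair <- length(u$genes) > 1
      # pair units get flanks wider than the pairing distance so the planted
      # partner is guaranteed to be the nearest coding gene
      pad <- if (is_pair || prev_pair) cfg$cis_max_gap else 0L
      prev_pair <- is_pair
      pos <- pos + round(rexp(1, 1 / 15000)) + 200L + pad
      for (gi in seq_along(u$genes)) {
        i <- u$genes[gi]
        if (gi > 1) pos <- pos + u$gaps[gi - 1]
        start[i] <- pos
        end[i] <- pos + len[i]
        chrom[i] <- paste0("chr", ch)
        pos <- end[i]
      }
      if (pos > cfg$chrom_length) {
        stop("simulate_ontogeny: infeasible placement: chromosome ", ch,
             " needs more than chrom_length bases; reduce gene counts or ",
             "increase chrom_length/n_chrom")
      }
    }
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  if (n_anti > 0) {
    for (a in seq_len(n_anti)) {
      i <- anti_nc[a]; h <- anti_host[a]
      slack <- (end[h] - start[h]) - len[i]
      start[i] <- start[h] + sample.int(max(1L, slack), 1) - 1L
      end[i] <- start[i] + len[i]
      chrom[i] <- chrom[h]
      strand[i] <- if (strand[h] == "+") "-" else "+"
    }
  }

  ## ---- biotypes and sources -------------------------------------------
  biotype <- rep("protein_coding", n_genes)
  source_tag <- rep("primary", n_genes)
  lnc_biotypes <- c("lincRNA", "antisense", "processed_transcript",
                    "non_coding", "retained_intron", "ncRNA_host")
  biotype[nc_pool] <- sample(setdiff(lnc_biotypes, "antisense"),
                             cfg$n_lncrna, replace = TRUE)
  biotype[anti_nc] <- "antisense"
  biotype[klass == "small_rna"] <- sample(c("tRNA", "rRNA", "snRNA", "snoRNA",
                                            "miRNA", "miscRNA"),
                                          cfg$n_small_rna, replace = TRUE)
  non_anti_nc <- setdiff(nc_pool, anti_nc)
  n_secondary <- min(round(cfg$secondary_frac * cfg$n_lncrna),
                     length(non_anti_nc))
  secondary_idx <- if (n_secondary > 0) sample(non_anti_nc, n_secondary) else integer(0)
  biotype[secondary_idx] <- "unknown"
  source_tag[secondary_idx] <- "secondary"

  n_ex <- integer(n_genes)
  n_ex[klass == "coding"] <- sample(2:6, cfg$n_coding, replace = TRUE)
  n_ex[klass == "lncRNA"] <- sample(1:3, cfg$n_lncrna, replace = TRUE)
  n_ex[klass == "small_rna"] <- 1L
  exons <- lapply(seq_len(n_genes), function(i) make_exons(start[i], end[i], n_ex[i]))

  genes_df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                         start = start, end = end, biotype = biotype,
                         source = source_tag, stringsAsFactors = FALSE)
  genes_df$exons <- exons
  genes <- gene_set(genes_df)
  primary <- genes[genes$source == "primary", , drop = FALSE]
  secondary <- genes[genes$source == "secondary", , drop = FALSE]

  ## ---- overlapping secondary decoys (merge must drop these) -----------
  if (cfg$n_secondary_overlap > 0) {
    hosts <- sample(which(source_tag == "primary" & klass != "small_rna"),
                    cfg$n_secondary_overlap, replace = TRUE)
    ov_len <- sample(300:3000, cfg$n_secondary_overlap, replace = TRUE)
    ov_start <- start[hosts] +
      vapply(end[hosts] - start[hosts], function(s) sample.int(s, 1) - 1L,
             integer(1))
    ov <- data.frame(
      gene_id = sprintf("OV%04d", seq_len(cfg$n_secondary_overlap)),
      chrom = chrom[hosts],
      strand = sample(c("+", "-"), cfg$n_secondary_overlap, replace = TRUE),
      start = ov_start, end = ov_start + ov_len,
      biotype = "unknown", source = "secondary", stringsAsFactors = FALSE)
    ov$exons <- lapply(seq_len(nrow(ov)),
                       function(i) cbind(start = ov$start[i], end = ov$end[i]))
    ov$klass <- NA_character_
    secondary <- gene_set(rbind(as.data.frame(secondary), ov))
  }

  ## ---- ground truth ----------------------------------------------------
  peak_age <- ifelse(pattern == "flat", NA_integer_,
                     ages[apply(true_mean, 1, which.max)])
  truth_genes <- data.frame(
    gene_id = gene_id, klass = klass, pattern = pattern, peak_age = peak_age,
    baseline = baseline,
    true_max_mean = apply(true_mean, 1, max),
    true_min_mean = apply(true_mean, 1, min),
    true_mean_overall = rowMeans(true_mean),
    stringsAsFactors = FALSE
  )
  truth_genes$true_fc_pseudo <- (truth_genes$true_max_mean + 1) /
    (truth_genes$true_min_mean + 1)
  truth_genes$expressed_true <- truth_genes$true_max_mean > 1
  truth_pairs <- data.frame(
    pc_id = gene_id[c(cis_pc, decoy_pc)],
    nc_id = gene_id[c(cis_nc, decoy_nc)],
    kind = rep(c("concordant", "decoy"), c(cfg$n_cis, cfg$n_decoy)),
    rho = rep(c(rho, 0), c(cfg$n_cis, cfg$n_decoy)),
    gap_bp = pair_gap,
    stringsAsFactors = FALSE
  )

  structure(list(
    genes = genes, primary = primary, secondary = secondary,
    expr = expression_set(values, samples),
    truth = list(genes = truth_genes, pairs = truth_pairs),
    config = cfg
  ), class = "ontomap_sim")
}

#' @export
print.ontomap_sim <- function(x, ...) {
  cat("ontomap_sim:", nrow(x$genes), "genes (",
      sum(x$truth$genes$klass == "coding"), "coding,",
      sum(x$truth$genes$klass == "lncRNA"), "lncRNA ),",
      nrow(x$truth$pairs), "planted pairs, seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits `merged.gtf` (the annotation underlying the expression matrix),
#' `primary.gtf` / `secondary.gtf` (the two annotation sources, the latter
#' including overlap decoys), `expr.tsv`, `samples.tsv`, and the ground
#' truth tables `truth_genes.tsv` / `truth_pairs.tsv`.
#'
#' @param sim an `ontomap_sim` from [simulate_ontogeny()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ontomap_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gtf(sim$genes, file.path(dir, "merged.gtf"))
  write_gtf(sim$primary, file.path(dir, "primary.gtf"))
  write_gtf(sim$secondary, file.path(dir, "secondary.gtf"))
  write_expression(sim$expr, file.path(dir, "expr.tsv"),
                   file.path(dir, "samples.tsv"))
  write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$pairs, file.path(dir, "truth_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
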