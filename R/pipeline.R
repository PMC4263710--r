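#' Run the full ontogenic expression pipeline
#'
#' Drives every stage end to end: annotation merge and classification,
#' expressed-gene filtering, differential expression, ontogenic pattern
#' clustering, inter-age similarity, neighbour-pair correlation with a
#' random-pair null, concordant cis-pair selection, and (when a term map is
#' supplied) gene-set enrichment of the concordant coding partners. All
#' stage tables are written as TSV with `#`-prefixed header lines carrying
#' the parameters and seed, plus a plain-text `report.txt` of stage counts.
#' The run is a pure function of its inputs, parameters and seed.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{outdir}{output directory}
#'     \item{simulate}{optional [sim_config()] (or list of its arguments);
#'       when present the pipeline runs on freshly simulated data}
#'     \item{inputs}{otherwise, list with `primary_gtf`, `secondary_gtf`
#'       (or a single pre-merged `annot_gtf`), `expr`, `samples`, and
#'       optionally `term_map`}
#'     \item{params}{optional overrides: `fpkm_threshold` (1), `alpha`
#'       (0.05), `fc` (1.5), `mean_floor` (1), `k` (3), `max_gap` (10000),
#'       `n_random` (10000), `seed` (1)}
#'   }
#' @return the report as a named list of stage summaries (invisibly written
#'   to `report.txt`)
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir
  if (is.null(outdir)) stop("run_pipeline: config$outdir is required")
  p <- modifyList(list(fpkm_threshold = 1, alpha = 0.05, fc = 1.5,
                       mean_floor = 1, k = 3, max_gap = 10000,
                       n_random = 10000, seed = 1),
                  if (is.null(config$params)) list() else config$params)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stamp <- function(file, fields) {
    hdr <- sprintf("# %s", paste(names(fields), unlist(fields), sep = "=",
                                 collapse = " "))
    writeLines(hdr, file)
  }
  emit <- function(df, name, fields = list(seed = p$seed)) {
    file <- file.path(outdir, name)
    stamp(file, fields)
    suppressWarnings(write.table(df, file, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    file
  }

  ## ---- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    if (!inherits(sim_cfg, "sim_config")) sim_cfg <- do.call(sim_config, sim_cfg)
    sim <- simulate_ontogeny(sim_cfg)
    write_simulation(sim, file.path(outdir, "sim"))
    gs <- classify_genes(sim$genes)
    es <- sim$expr
    term_map <- NULL
  } else {
    inp <- config$inputs
    needed <- c(if (is.null(inp$annot_gtf)) c("primary_gtf", "secondary_gtf"),
                "expr", "samples")
    paths <- unlist(inp[needed])
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files) > 0) {
      stop("run_pipeline: missing input file(s): ",
           paste(missing_files, collapse = ", "))
    }
    gs <- if (!is.null(inp$annot_gtf)) {
      read_gtf(inp$annot_gtf)
    } else {
      merge_nonoverlapping(read_gtf(inp$primary_gtf), read_gtf(inp$secondary_gtf))
    }
    gs <- classify_genes(gs)
    es <- read_expression(inp$expr, inp$samples)
    term_map <- if (!is.null(inp$term_map)) {
      read.delim(inp$term_map, comment.char = "#", stringsAsFactors = FALSE)
    }
  }
  es$values <- es$values[intersect(rownames(es$values), gs$gene_id), ,
                         drop = FALSE]
  klass <- setNames(gs$klass, gs$gene_id)
  emit(as.data.frame(gs)[, c("gene_id", "chrom", "strand", "start", "end",
                             "biotype", "klass", "source")],
       "annotation.tsv")

  ## ---- expression filter ----------------------------------------------
  am <- age_means(es)
  expressed <- expressed_genes(am, p$fpkm_threshold)
  per_age <- expressed_per_age(am, klass, p$fpkm_threshold)
  emit(per_age, "expressed_per_age.tsv", list(threshold = p$fpkm_threshold))
  expr_coding <- sum(klass[expressed] == "coding", na.rm = TRUE)
  expr_lnc <- sum(klass[expressed] == "lncRNA", na.rm = TRUE)

  ## ---- differential expression ----------------------------------------
  de <- call_de(es, alpha = p$alpha, fc = p$fc, mean_floor = p$mean_floor)
  emit(de, "de.tsv", list(alpha = p$alpha, fc = p$fc,
                          mean_floor = p$mean_floor))
  de_sig <- de$gene_id[de$significant]
  de_coding <- sum(klass[de_sig] == "coding", na.rm = TRUE)
  de_lnc <- sum(klass[de_sig] == "lncRNA", na.rm = TRUE)

  ## ---- pattern clustering ---------------------------------------------
  de_for_clust <- intersect(de_sig, names(klass)[klass %in% c("coding", "lncRNA")])
  assignments <- NULL
  cluster_sizes <- integer(0)
  if (length(de_for_clust) >= p$k) {
    z <- zscore_profiles(am[de_for_clust, , drop = FALSE])
    assignments <- cluster_patterns(z, k = p$k)
    emit(assignments, "patterns.tsv", list(k = p$k))
    emit(chromosome_density(assignments, gs), "chromosome_density.tsv")
    cluster_sizes <- table(assignments$label)
  }

  ## ---- inter-age similarity -------------------------------------------
  subsets <- list(all = intersect(rownames(am), names(klass)),
                  coding = names(klass)[klass == "coding"],
                  lncrna = names(klass)[klass == "lncRNA"])
  for (nm in names(subsets)) {
    ids <- intersect(subsets[[nm]], rownames(am))
    if (length(ids) >= 2) {
      sim_m <- age_similarity(es, subset = ids)
      emit(data.frame(age_day = rownames(sim_m), sim_m, check.names = FALSE),
           paste0("similarity_", nm, ".tsv"))
    }
  }

  ## ---- neighbour pairs -------------------------------------------------
  pcpc <- pair_correlations(build_pairs(gs, "coding"), am)
  pcnc <- pair_correlations(build_pairs(gs, "lncRNA"), am)
  pcpc_hi <- pair_correlations(filter_hi(pcpc, expressed, p$max_gap), am)
  pcnc_hi <- pair_correlations(filter_hi(pcnc, expressed, p$max_gap), am)
  null_pairs <- random_pair_null(gs, am, n_pairs = p$n_random, seed = p$seed)
  all_pairs <- rbind(pcpc, pcnc, pcpc_hi, pcnc_hi, null_pairs)
  emit(all_pairs, "pairs.tsv",
       list(max_gap = p$max_gap, n_random = p$n_random, seed = p$seed))
  hist_rows <- lapply(list(pcpc, pcnc, pcpc_hi, pcnc_hi, null_pairs),
                      function(tab) {
    if (all(is.na(tab$r))) return(NULL)
    h <- r_distribution(tab$r)
    data.frame(pair_class = tab$pair_class[1], tier = tab$tier[1],
               mid = h$mids, count = h$counts, peak = h$peak,
               stringsAsFactors = FALSE)
  })
  emit(do.call(rbind, hist_rows), "r_histograms.tsv")

  ## ---- concordant cis pairs -------------------------------------------
  concordant <- NULL
  if (!is.null(assignments) && nrow(pcnc_hi) > 0) {
    concordant <- concordant_pairs(pcnc_hi, de, assignments,
                                   alpha = p$alpha, max_gap = p$max_gap)
    emit(concordant, "concordant_pairs.tsv",
         list(alpha = p$alpha, max_gap = p$max_gap))
  }

  ## ---- enrichment ------------------------------------------------------
  enrichment <- NULL
  if (!is.null(term_map) && !is.null(concordant) && nrow(concordant) > 0) {
    universe <- gs$gene_id[gs$klass == "coding"]
    enrichment <- enrich(intersect(unique(concordant$id_b), universe),
                         universe, term_map)
    emit(enrichment, "enrichment.tsv")
  }

  ## ---- report ----------------------------------------------------------
  report <- list(
    n_genes = nrow(gs),
    n_coding = sum(gs$klass == "coding"),
    n_lncrna = sum(gs$klass == "lncRNA"),
    n_small_rna = sum(gs$klass == "small_rna"),
    expressed_total = length(expressed),
    expressed_coding = expr_coding,
    expressed_lncrna = expr_lnc,
    de_coding = de_coding,
    de_lncrna = de_lnc,
    cluster_sizes = cluster_sizes,
    pairs = c(`PC-PC all` = nrow(pcpc), `PC-NC all` = nrow(pcnc),
              `PC-PC hi` = nrow(pcpc_hi), `PC-NC hi` = nrow(pcnc_hi),
              `random-PC` = nrow(null_pairs)),
    concordant_pairs = if (is.null(concordant)) 0L else nrow(concordant),
    enriched_terms = if (is.null(enrichment)) 0L else
      sum(enrichment$fdr < 0.05),
    params = p
  )
  lines <- c("ontomap pipeline report",
             sprintf("genes: %d (coding %d, lncRNA %d, small RNA %d)",
                     report$n_genes, report$n_coding, report$n_lncrna,
                     report$n_small_rna),
             sprintf("expressed: %d (coding %d, lncRNA %d)",
                     report$expressed_total, report$expressed_coding,
                     report$expressed_lncrna),
             sprintf("differentially expressed: coding %d, lncRNA %d",
                     report$de_coding, report$de_lncrna),
             sprintf("cluster sizes: %s",
                     paste(names(report$cluster_sizes), report$cluster_sizes,
                           sep = "=", collapse = " ")),
             sprintf("pairs: %s",
                     paste(names(report$pairs), report$pairs, sep = "=",
                           collapse = " ")),
             sprintf("concordant cis pairs: %d", report$concordant_pairs),
             sprintf("enriched terms (FDR<0.05): %d", report$enriched_terms),
             sprintf("params: %s",
                     paste(names(p), unlist(p), sep = "=", collapse = " ")))
  writeLines(lines, file.path(outdir, "report.txt"))
  report
}
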