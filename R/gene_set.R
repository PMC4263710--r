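#' Construct a gene set
#'
#' A `gene_set` is a data frame of gene models, one row per gene, with
#' internal 0-based half-open coordinates. It is the annotation container
#' used throughout the package.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `biotype`, `source`, and a list column `exons` holding
#'   one two-column (start, end) matrix per gene. Coordinates are 0-based
#'   half-open. A `klass` column ({`coding`, `lncRNA`, `small_rna`, `other`})
#'   may be present; [classify_genes()] fills it in.
#' @return an object of class `gene_set` (a data frame), sorted by
#'   (chrom, start, gene_id).
#' @seealso [read_gtf()], [classify_genes()], [gene_gap()]
#' @export
gene_set <- function(genes) {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "chrom", "strand", "start", "end", "biotype", "source")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene_set: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"exons" %in% names(genes)) {
    genes$exons <- lapply(seq_len(nrow(genes)), function(i) {
      cbind(start = genes$start[i], end = genes$end[i])
    })
  }
  if (!"klass" %in% names(genes)) genes$klass <- NA_character_
  if (anyDuplicated(genes$gene_id)) {
    stop("gene_set: duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  bad <- which(genes$start >= genes$end)
  if (length(bad) > 0) {
    stop("gene_set: start >= end for: ", paste(genes$gene_id[bad], collapse = ", "))
  }
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (is.null(dim(ex)) || nrow(ex) == 0) {
      stop("gene_set: gene ", genes$gene_id[i], " has no exons")
    }
    if (any(ex[, 1] < genes$start[i]) || any(ex[, 2] > genes$end[i]) ||
        any(ex[, 1] >= ex[, 2])) {
      stop("gene_set: exons outside span or degenerate for ", genes$gene_id[i])
    }
  }
  ord <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("gene_set", "data.frame")
  genes
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set with", nrow(x), "genes on",
      length(unique(x$chrom)), "chromosome(s)\n")
  if (!all(is.na(x$klass))) {
    print(table(klass = x$klass, useNA = "ifany"))
  }
  invisible(x)
}

#' @export
`[.gene_set` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("gene_id", "exons") %in% names(out))) {
    class(out) <- c("gene_set", "data.frame")
  }
  out
}

as_granges <- function(gs, seqlevels = unique(gs$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(gs$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = gs$start + 1L, end = gs$end),
    strand = ifelse(gs$strand %in% c("+", "-"), gs$strand, "*")
  )
}

#' Merge a secondary annotation keeping only non-overlapping models
#'
#' All primary genes are kept; a secondary gene is kept only if its span
#' overlaps no primary gene span by at least one base, on either strand
#' (overlap is strand-agnostic, so an antisense model overlapping a primary
#' gene is excluded). Abutting half-open spans do not overlap.
#'
#' @param primary,secondary `gene_set` objects. `gene_id`s must be unique
#'   across the two sets.
#' @return a `gene_set` with all primary genes plus the kept secondary genes,
#'   each retaining its `source` tag.
#' @export
merge_nonoverlapping <- function(primary, secondary) {
  stopifnot(inherits(primary, "gene_set"), inherits(secondary, "gene_set"))
  dup <- intersect(primary$gene_id, secondary$gene_id)
  if (length(dup) > 0) {
    stop("merge_nonoverlapping: gene_id present in both sets: ",
         paste(head(dup, 5), collapse = ", "))
  }
  if (nrow(secondary) == 0) return(primary)
  chroms <- union(primary$chrom, secondary$chrom)
  hits <- GenomicRanges::findOverlaps(as_granges(secondary, chroms),
                                      as_granges(primary, chroms),
                                      ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  kept <- if (length(drop) > 0) secondary[-drop, , drop = FALSE] else secondary
  out <- rbind(as.data.frame(primary), as.data.frame(kept))
  gene_set(out)
}

#' Assign gene classes from biotypes
#'
#' Maps source-supplied biotypes to analysis classes: `protein_coding`
#' becomes `coding`; small structural RNA biotypes (tRNA, rRNA, snRNA,
#' snoRNA, miRNA, miscRNA by default) become `small_rna` and are excluded
#' from lncRNA analyses; every remaining non-coding biotype (antisense,
#' lincRNA, processed transcript, ...) becomes `lncRNA`. Genes from a
#' secondary model source with no biotype information (`unknown`) are
#' treated as lncRNA.
#'
#' @param gs a `gene_set`
#' @param small_rna_biotypes character vector of biotypes to classify as
#'   `small_rna`
#' @return the `gene_set` with its `klass` column filled in
#' @export
classify_genes <- function(gs,
                           small_rna_biotypes = c("tRNA", "rRNA", "snRNA",
                                                  "snoRNA", "miRNA", "miscRNA")) {
  stopifnot(inherits(gs, "gene_set"))
  klass <- rep("lncRNA", nrow(gs))
  klass[gs$biotype == "protein_coding"] <- "coding"
  klass[gs$biotype %in% small_rna_biotypes] <- "small_rna"
  gs$klass <- klass
  gs
}

#' Genomic gap between two gene spans
#'
#' Number of bases strictly between two spans on the same chromosome, in
#' half-open arithmetic (`later start - earlier end`). Overlapping or
#' abutting spans have gap 0; genes on different chromosomes have no defined
#' gap (`NA`).
#'
#' @param a,b single-row gene records (rows of a `gene_set`)
#' @return a non-negative integer, or `NA_integer_` if the genes lie on
#'   different chromosomes
#' @export
gene_gap <- function(a, b) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (a$chrom != b$chrom) return(NA_integer_)
  as.integer(max(0L, max(a$start, b$start) - min(a$end, b$end)))
}

# vectorized gap from one span to many spans on the same chromosome
gap_to_many <- function(start, end, starts, ends) {
  pmax(0L, pmax(start, starts) - pmin(end, ends))
}

#' Nearest coding neighbour of a gene
#'
#' Finds the coding gene on the same chromosome minimising [gene_gap()],
#' excluding the query gene itself. Ties are broken deterministically by
#' smaller start coordinate, then lexicographic `gene_id`.
#'
#' @param g a single-row gene record
#' @param gs a classified `gene_set` providing the candidate coding genes
#' @return a one-row data frame with columns `id_a` (the query), `id_b`
#'   (the neighbour) and `gap_bp`, or `NULL` if the chromosome carries no
#'   other coding gene
#' @export
nearest_coding_neighbor <- function(g, gs) {
  stopifnot(inherits(gs, "gene_set"), nrow(g) == 1)
  cand <- gs[gs$klass == "coding" & gs$chrom == g$chrom &
               gs$gene_id != g$gene_id, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  gaps <- gap_to_many(g$start, g$end, cand$start, cand$end)
  ord <- order(gaps, cand$start, cand$gene_id)
  best <- ord[1]
  data.frame(id_a = g$gene_id, id_b = cand$gene_id[best],
             gap_bp = as.integer(gaps[best]), stringsAsFactors = FALSE)
}
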