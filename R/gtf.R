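#' Read gene models from a GTF file
#'
#' Parses an Ensembl-style GTF (1-based inclusive coordinates, attribute
#' column carrying `gene_id "..."`) into a [gene_set()]. Exon features are
#' collected per `gene_id`; the gene span is the min/max over its exons
#' (stand-alone `gene` features contribute their own span when a gene has no
#' exon rows). Coordinates are converted to the package's internal 0-based
#' half-open convention. The biotype is taken from the `gene_biotype` (or
#' `gene_type`) attribute when present, otherwise `"unknown"`.
#'
#' @param path path to a GTF file
#' @return a `gene_set`
#' @seealso [write_gtf()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("read_gtf: no such file: ", path)
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  for (i in which(body)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9) {
      stop("read_gtf: malformed line ", i, ": expected 9 tab-separated fields, got ",
           length(fields))
    }
    if (is.na(suppressWarnings(as.integer(fields[4]))) ||
        is.na(suppressWarnings(as.integer(fields[5])))) {
      stop("read_gtf: malformed line ", i, ": non-numeric coordinates")
    }
    if (!grepl("gene_id", fields[9], fixed = TRUE)) {
      stop("read_gtf: line ", i, ": missing gene_id attribute")
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("read_gtf: no gene_id attribute in file")
  biotype_col <- intersect(c("gene_biotype", "gene_type"), names(df))
  df$.biotype <- if (length(biotype_col) > 0) {
    as.character(df[[biotype_col[1]]])
  } else {
    NA_character_
  }
  df$type <- as.character(df$type)
  idx_by_gene <- split(seq_len(nrow(df)), df$gene_id)
  rows <- lapply(idx_by_gene, function(idx) {
    sub <- df[idx, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0) ex <- sub   # gene feature only: span acts as one exon
    exons <- cbind(start = as.integer(ex$start - 1L), end = as.integer(ex$end))
    exons <- exons[order(exons[, 1], exons[, 2]), , drop = FALSE]
    biotype <- sub$.biotype[!is.na(sub$.biotype)]
    rec <- data.frame(
      gene_id = sub$gene_id[1],
      chrom = as.character(sub$seqnames[1]),
      strand = as.character(sub$strand[1]),
      start = min(exons[, 1]),
      end = max(exons[, 2]),
      biotype = if (length(biotype) > 0) biotype[1] else "unknown",
      source = as.character(sub$source[1]),
      stringsAsFactors = FALSE
    )
    rec$exons <- list(exons)
    rec
  })
  gene_set(do.call(rbind, rows))
}

#' Write a gene set to GTF
#'
#' Emits one `gene` feature plus one `exon` feature per exon for every gene,
#' with Ensembl-style attributes (`gene_id "x"; gene_biotype "y";`),
#' converting internal 0-based half-open coordinates back to GTF's 1-based
#' inclusive convention. `write_gtf` followed by [read_gtf()] reproduces the
#' gene set exactly.
#'
#' @param gs a `gene_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_gtf <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set"))
  attrs <- sprintf('gene_id "%s"; gene_biotype "%s";', gs$gene_id, gs$biotype)
  lines <- character(0)
  for (i in seq_len(nrow(gs))) {
    gene_line <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                         gs$chrom[i], gs$source[i], gs$start[i] + 1L, gs$end[i],
                         gs$strand[i], attrs[i])
    ex <- gs$exons[[i]]
    exon_lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                          gs$chrom[i], gs$source[i], ex[, 1] + 1L, ex[, 2],
                          gs$strand[i], attrs[i])
    lines <- c(lines, gene_line, exon_lines)
  }
  writeLines(lines, path)
  invisible(path)
}
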