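#' Construct an expression set
#'
#' Container for a genes x samples FPKM matrix with the age/replicate
#' design of a developmental time course. Samples are ordered by
#' (age_day, replicate).
#'
#' @param values numeric matrix of FPKM values, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample ids). Values must be
#'   non-negative and finite; missing values are rejected.
#' @param samples data frame with columns `sample_id`, `age_day` (integer,
#'   may be negative) and `replicate` (positive integer); `(age_day,
#'   replicate)` must be unique and `sample_id` must match the matrix
#'   columns.
#' @return an object of class `expr_set`: a list with elements `values` and
#'   `samples`.
#' @export
expression_set <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(samples))
  required <- c("sample_id", "age_day", "replicate")
  if (!all(required %in% names(samples))) {
    stop("expression_set: samples needs columns ", paste(required, collapse = ", "))
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("expression_set: values must have unique rownames (gene ids)")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression_set: FPKM values must be finite and non-missing")
  }
  if (any(values < 0)) stop("expression_set: negative FPKM values")
  if (!setequal(colnames(values), samples$sample_id) ||
      ncol(values) != nrow(samples)) {
    stop("expression_set: matrix columns do not match samples$sample_id")
  }
  if (anyDuplicated(samples[, c("age_day", "replicate")])) {
    stop("expression_set: duplicate (age_day, replicate) combinations")
  }
  ord <- order(samples$age_day, samples$replicate)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  values <- values[, samples$sample_id, drop = FALSE]
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  ages <- sort(unique(x$samples$age_day))
  cat("expr_set:", nrow(x$values), "genes x", ncol(x$values), "samples;",
      length(ages), "ages (day", paste(range(ages), collapse = " to "), ")\n")
  invisible(x)
}

#' Per-age replicate-mean expression profiles
#'
#' Arithmetic mean of FPKM over the replicates within each age, per gene.
#'
#' @param es an [expression_set()]
#' @return numeric matrix, genes x ages, column names the age days sorted
#'   ascending; the integer age vector is attached as attribute `ages`.
#' @export
age_means <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  ages <- sort(unique(es$samples$age_day))
  out <- vapply(ages, function(a) {
    cols <- es$samples$sample_id[es$samples$age_day == a]
    rowMeans(es$values[, cols, drop = FALSE])
  }, numeric(nrow(es$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(es$values), NULL))
  colnames(out) <- as.character(ages)
  attr(out, "ages") <- ages
  out
}

#' Expressed genes
#'
#' A gene is expressed if its replicate-averaged FPKM exceeds the threshold
#' (strictly) at any age.
#'
#' @param am an age-mean matrix from [age_means()]
#' @param threshold expression cutoff (default FPKM 1; comparison is strict)
#' @return character vector of expressed gene ids
#' @export
expressed_genes <- function(am, threshold = 1) {
  rownames(am)[apply(am, 1, max) > threshold]
}

#' Expressed-gene counts per age, split by gene class
#'
#' @param am an age-mean matrix from [age_means()]
#' @param klass named character vector mapping gene_id to class (as from
#'   [classify_genes()]); genes absent from `klass` are ignored
#' @param threshold expression cutoff (strict)
#' @return data frame with columns `age_day`, `coding`, `lncRNA`
#' @export
expressed_per_age <- function(am, klass, threshold = 1) {
  ids <- rownames(am)
  kl <- klass[ids]
  ages <- attr(am, "ages")
  if (is.null(ages)) ages <- as.integer(colnames(am))
  counts <- function(what) {
    sel <- !is.na(kl) & kl == what
    colSums(am[sel, , drop = FALSE] > threshold)
  }
  data.frame(age_day = ages,
             coding = as.integer(counts("coding")),
             lncRNA = as.integer(counts("lncRNA")),
             row.names = NULL)
}

#' Read an expression matrix and its sample sheet
#'
#' The expression TSV has gene ids in the first column and one column per
#' sample; the sample sheet TSV has columns `sample_id`, `age_day`,
#' `replicate`. Lines starting with `#` are ignored in both files.
#'
#' @param expr_path path to the expression TSV
#' @param samples_path path to the sample sheet TSV
#' @return an `expr_set`
#' @export
read_expression <- function(expr_path, samples_path) {
  expr <- read.delim(expr_path, comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE)
  samples <- read.delim(samples_path, comment.char = "#",
                        stringsAsFactors = FALSE)
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- expr[[1]]
  expression_set(values, samples)
}

#' Write an expression matrix and its sample sheet
#'
#' @param es an `expr_set`
#' @param expr_path,samples_path output TSV paths
#' @return `expr_path`, invisibly
#' @export
write_expression <- function(es, expr_path, samples_path) {
  stopifnot(inherits(es, "expr_set"))
  df <- data.frame(gene_id = rownames(es$values), es$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(es$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(expr_path)
}
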