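#' Construct an expression matrix with sample conditions and a probe map
#'
#' The container used throughout the co-expression stage: normalized
#' log-scale intensities (probes x samples), one condition label per sample,
#' and a probe -> gene symbol map in which probes may be unmapped (`NA`).
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_conditions Character vector of condition labels, one per
#'   column of `values` (named by sample id, or in column order).
#' @param probe_to_gene Named character vector mapping probe id -> gene
#'   symbol; probes absent from the map (or mapped to `NA`) are unmapped.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, sample_conditions, probe_to_gene) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("values must have probe ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated probe ids are not allowed")
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  if (length(sample_conditions) != ncol(values))
    stop("need one condition label per sample")
  if (!is.null(names(sample_conditions))) {
    missing <- setdiff(colnames(values), names(sample_conditions))
    if (length(missing) > 0)
      stop("samples without a condition label: ", paste(missing, collapse = ", "))
    sample_conditions <- sample_conditions[colnames(values)]
  } else {
    names(sample_conditions) <- colnames(values)
  }
  if (anyNA(sample_conditions)) stop("every sample needs a condition label")
  probe_to_gene <- probe_to_gene[intersect(names(probe_to_gene), rownames(values))]
  structure(
    list(values = values,
         sample_conditions = sample_conditions,
         probe_to_gene = probe_to_gene),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$sample_conditions)
  cat("conditions:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("mapped probes: %d of %d\n",
              sum(!is.na(x$probe_to_gene)), nrow(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# Gene symbol for each probe id (NA when unmapped).
probe_genes <- function(matrix, probes = rownames(matrix$values)) {
  out <- matrix$probe_to_gene[probes]
  names(out) <- probes
  out
}

#' Read an expression matrix from delimited text files
#'
#' The matrix file is tab-separated with probe ids in the first column and a
#' header row of sample ids. Lines starting with `!` (the GEO series-matrix
#' dialect's metadata lines) are skipped, and a `"ID_REF"` header cell is
#' accepted, so plain TSV exports and series-matrix files both load.
#'
#' @param matrix_file Path to the probes x samples TSV.
#' @param condition_file Path to a two-column TSV `sample<TAB>condition`
#'   (no header required; a `sample`/`condition` header row is tolerated).
#' @param probe_map_file Path to a two-column TSV `probe<TAB>gene`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(matrix_file, condition_file, probe_map_file) {
  tab <- read.delim(matrix_file, comment.char = "!", check.names = FALSE,
                    stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  storage.mode(values) <- "double"
  cond <- read_two_column(condition_file, c("sample", "condition"))
  pmap <- read_two_column(probe_map_file, c("probe", "gene"))
  expression_matrix(values,
                    setNames(cond$condition, cond$sample),
                    setNames(pmap$gene, pmap$probe))
}

# Two-column TSV, optional header row matching `header_names`.
read_two_column <- function(path, header_names) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "!")
  if (ncol(tab) < 2) stop("expected two tab-separated columns in ", path)
  if (identical(tolower(as.character(tab[1, 1:2])), header_names))
    tab <- tab[-1, , drop = FALSE]
  setNames(tab[, 1:2], header_names)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to a text file with one gene symbol per line; blank lines
#'   and lines starting with `#` are ignored.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a gene -> GO term annotation table
#'
#' @param path TSV with columns `gene<TAB>term`, one row per (gene, term).
#' @return Named list: gene -> character vector of terms.
#' @export
read_go_annotation <- function(path) {
  tab <- read_two_column(path, c("gene", "term"))
  split(tab$term, tab$gene)
}
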