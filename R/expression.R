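#' Construct an expression matrix
#'
#' A light container for a genes x samples (or genes x cells) matrix of
#' non-negative expression values. Row names are gene IDs, column names are
#' sample IDs; an optional per-sample cell-type label vector and a species
#' tag travel with the matrix.
#'
#' @param values numeric matrix, genes in rows, samples/cells in columns.
#'   Must be finite and non-negative, with unique row and column names.
#' @param cell_types optional character vector of cell-type labels, one per
#'   column of `values`.
#' @param species character scalar tagging the species (default `"?"`).
#' @return An object of class `coex_expr`: a list with elements `values`,
#'   `cell_types` (possibly `NULL`) and `species`.
#' @examples
#' m <- matrix(rpois(6, 5), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expression_matrix(m, species = "A")
#' @export
expression_matrix <- function(values, cell_types = NULL, species = "?") {
  if (!is.matrix(values) || !is.numeric(values))
    cx_input_error("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    cx_input_error("'values' must have gene row names and sample column names")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    cx_input_error(sprintf("duplicate gene ID(s): %s",
                           paste(unique(dup_g), collapse = ", ")))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    cx_input_error(sprintf("duplicate sample ID(s): %s",
                           paste(unique(dup_s), collapse = ", ")))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    cx_input_error(sprintf(
      "negative or non-finite value at gene '%s', sample '%s'",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  if (!is.null(cell_types)) {
    cell_types <- as.character(cell_types)
    if (length(cell_types) != ncol(values))
      cx_input_error("'cell_types' must have one label per sample")
  }
  structure(list(values = values, cell_types = cell_types,
                 species = as.character(species)[1]),
            class = "coex_expr")
}

#' @export
print.coex_expr <- function(x, ...) {
  cat(sprintf("<coex_expr> %d genes x %d samples, species '%s'%s\n",
              nrow(x$values), ncol(x$values), x$species,
              if (is.null(x$cell_types)) ""
              else sprintf(", %d cell types", length(unique(x$cell_types)))))
  invisible(x)
}

#' @export
dim.coex_expr <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Counts-per-million normalization
#'
#' Scales each sample (column) to a total of one million. Samples with a zero
#' library size are left as all-zero columns with a warning.
#'
#' @param expr a [expression_matrix()] object.
#' @return A numeric matrix of the same shape.
#' @export
cpm <- function(expr) {
  v <- expr$values
  tot <- colSums(v)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("%d sample(s) have zero total counts; their CPM is all-zero",
                    sum(zero)))
    tot[zero] <- 1
  }
  sweep(v, 2, tot, "/") * 1e6
}

# Tolerant line reader: accepts CRLF line endings and '#' comment lines.
read_clean_lines <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("\r$", "", x)
  x <- x[!grepl("^\\s*#", x)]
  x[nzchar(trimws(x))]
}

#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported. `format = "tsv"`: a dense tab-separated
#' table whose first column holds gene IDs and whose header row holds sample
#' IDs. `format = "mtx"`: a Matrix Market triplet file plus a gene-ID file
#' (one ID per line) and a sample-ID file (one ID per line, optional second
#' tab-separated column holding the cell-type label). Matrix Market indices
#' are 1-based on disk per the standard; all in-memory indexing is R-native.
#' `'#'` comment lines and CRLF endings are accepted in the ID files.
#'
#' @param path path to the dense TSV (format `"tsv"`) or `.mtx` file
#'   (format `"mtx"`).
#' @param format `"tsv"` or `"mtx"`.
#' @param genes,samples ID file paths, required for `format = "mtx"`.
#' @param species species tag to attach.
#' @return A [expression_matrix()] object; gene and sample order as in the
#'   file.
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            genes = NULL, samples = NULL, species = "?") {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                     check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
      cx_input_error(sprintf("non-numeric entry at row %d, column %d of '%s'",
                             bad[1, 1], bad[1, 2] + 1L, path))
    }
    rownames(m) <- ids
    return(expression_matrix(m, species = species))
  }
  if (is.null(genes) || is.null(samples))
    cx_input_error("'genes' and 'samples' ID files are required for mtx input")
  m <- as.matrix(Matrix::readMM(path))
  gid <- read_clean_lines(genes)
  sfields <- strsplit(read_clean_lines(samples), "\t", fixed = TRUE)
  sid <- vapply(sfields, `[[`, "", 1L)
  ct <- NULL
  if (all(lengths(sfields) >= 2L)) ct <- vapply(sfields, `[[`, "", 2L)
  if (length(gid) != nrow(m))
    cx_input_error(sprintf("gene ID file has %d IDs but matrix has %d rows",
                           length(gid), nrow(m)))
  if (length(sid) != ncol(m))
    cx_input_error(sprintf("sample ID file has %d IDs but matrix has %d columns",
                           length(sid), ncol(m)))
  dimnames(m) <- list(gid, sid)
  expression_matrix(m, cell_types = ct, species = species)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]; `read(write(x)) == x` for both layouts.
#'
#' @param expr a [expression_matrix()] object.
#' @param path output path (`.tsv` table or `.mtx` triplet file).
#' @param format `"tsv"` or `"mtx"`.
#' @param genes,samples ID file paths, required for `format = "mtx"`; the
#'   samples file gains a second cell-type column when labels are present.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("tsv", "mtx"),
                             genes = NULL, samples = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = gene_ids(expr), expr$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(genes) || is.null(samples))
    cx_input_error("'genes' and 'samples' paths are required for mtx output")
  Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), path)
  writeLines(gene_ids(expr), genes)
  if (is.null(expr$cell_types)) writeLines(sample_ids(expr), samples)
  else writeLines(paste(sample_ids(expr), expr$cell_types, sep = "\t"), samples)
  invisible(path)
}
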