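#' Read a tab-delimited expression matrix
#'
#' Parses the plain tab-delimited dialect used throughout the package: a
#' header row of sample IDs with a `gene_id` corner cell, one row per gene,
#' log2 intensities.  Comment lines starting with `!` (as found in GEO
#' series-matrix exports) are skipped.  Malformed input is rejected rather
#' than coerced: duplicate IDs and non-numeric cells raise errors naming the
#' offending row/column.
#'
#' @param path file to read.
#' @param genes_in_rows if `FALSE` the file is transposed on read (samples in
#'   rows, genes in columns).
#' @return A validated genes x samples numeric matrix with gene IDs as
#'   rownames and sample IDs as colnames.
#' @export
read_expression_matrix <- function(path, genes_in_rows = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("malformed matrix file (no data rows): %s", path)
  df <- read.delim(text = lines, header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "\"")
  if (ncol(df) < 2L) stopf("malformed matrix file (fewer than 2 columns): %s", path)
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stopf("duplicate %s IDs in %s: %s",
          if (genes_in_rows) "gene" else "sample", path,
          paste(unique(dup), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-numeric value '%s' at data row %d, column '%s' in %s",
          vals[bad[1, 1], bad[1, 2]], bad[1, 1], colnames(vals)[bad[1, 2]], path)
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stopf("missing value at data row %d, column '%s' in %s",
          bad[1, 1], colnames(vals)[bad[1, 2]], path)
  }
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  if (!genes_in_rows) num <- t(num)
  assert_expression_matrix(num)
  num
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_expression_matrix(write_expression_matrix(m))` reproduces `m`
#' exactly (double-precision round trip).
#'
#' @param matrix validated genes x samples matrix.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(matrix, path) {
  assert_expression_matrix(matrix)
  header <- paste(c("gene_id", colnames(matrix)), collapse = "\t")
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], sprintf("%.17g", matrix[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a two-column sample annotation table
#'
#' Expects a tab-delimited file with at least `sample_id` and `group`
#' columns; extra covariate columns (age, sex, biopsy site, ...) are kept.
#'
#' @param path file to read.
#' @return A data.frame with exactly two group labels, both non-empty.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  assert_annotation(df)
  df
}

#' @rdname read_sample_annotation
#' @param annotation annotation data.frame to write.
#' @export
write_sample_annotation <- function(annotation, path) {
  assert_annotation(annotation)
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Members are deduplicated; lines with fewer than three fields are rejected.
#'
#' @param path GMT file.
#' @return Named list of character vectors (set name -> unique members).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stopf("malformed GMT line %d (fewer than 3 fields) in %s", i, path)
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  sets
}

#' @rdname read_gene_sets
#' @param gene_sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gene_sets <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], unique(gene_sets[[i]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Convert signed linear fold changes to log2 fold changes
#'
#' Printed microarray tables often report signed linear fold changes, where
#' e.g. -4.82 means 4.82-fold down.  The log2 equivalent is
#' `sign(FC) * log2(|FC|)`.
#'
#' @param fc numeric vector of signed linear fold changes (|FC| >= 1).
#' @return log2 fold changes.
#' @export
fc_to_log2fc <- function(fc) {
  if (any(!is.finite(fc) | fc == 0)) stopf("fold changes must be nonzero and finite")
  sign(fc) * log2(abs(fc))
}
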