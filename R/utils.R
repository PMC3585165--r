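# internal helpers shared across modules

stopf <- function(fmt, ..., call. = FALSE) {
  stop(sprintf(fmt, ...), call. = call.)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a validated genes x samples numeric matrix with unique dimnames
assert_expression_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("'%s' must be a numeric genes x samples matrix", arg)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stopf("'%s' must have at least one gene and one sample", arg)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("'%s' must carry gene IDs as rownames and sample IDs as colnames", arg)
  }
  dup_g <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_g)) {
    stopf("duplicate gene IDs in '%s': %s", arg,
          paste(unique(dup_g), collapse = ", "))
  }
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s)) {
    stopf("duplicate sample IDs in '%s': %s", arg,
          paste(unique(dup_s), collapse = ", "))
  }
  if (!all(is.finite(x))) {
    stopf("'%s' contains non-finite values", arg)
  }
  invisible(x)
}

# annotation: data.frame with sample_id and group columns, exactly two groups
assert_annotation <- function(annotation, sample_ids = NULL) {
  if (!is.data.frame(annotation) ||
      !all(c("sample_id", "group") %in% names(annotation))) {
    stopf("annotation must be a data.frame with columns 'sample_id' and 'group'")
  }
  if (anyDuplicated(annotation$sample_id)) {
    stopf("annotation has duplicated sample IDs")
  }
  groups <- unique(as.character(annotation$group))
  if (length(groups) != 2L) {
    stopf("annotation must define exactly two groups, found: %s",
          paste(groups, collapse = ", "))
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, annotation$sample_id)
    if (length(missing)) {
      stopf("samples missing from annotation: %s",
            paste(missing, collapse = ", "))
    }
  }
  invisible(annotation)
}

# sample ids belonging to one group, in matrix column order
group_samples <- function(matrix, annotation, group) {
  assert_annotation(annotation, colnames(matrix))
  keep <- annotation$sample_id[as.character(annotation$group) == group]
  out <- intersect(colnames(matrix), keep)
  if (!length(out)) stopf("no samples found for group '%s'", group)
  out
}

# resolve the case label against an annotation's two groups
resolve_case_label <- function(annotation, case = NULL) {
  groups <- unique(as.character(annotation$group))
  if (is.null(case)) {
    if ("case" %in% groups) return("case")
    stopf("ambiguous group labels (%s); supply 'case' explicitly",
          paste(groups, collapse = ", "))
  }
  if (!case %in% groups) {
    stopf("case label '%s' not among annotation groups (%s)", case,
          paste(groups, collapse = ", "))
  }
  case
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

assert_seed <- function(seed) {
  if (!is_count(seed) || seed >= 2^31 - 1) {
    stopf("'seed' must be a single non-negative integer below 2^31")
  }
  as.integer(seed)
}
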