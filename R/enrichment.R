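#' Fisher-exact over-representation analysis of gene sets
#'
#' For each gene set, tests whether the query list contains more members of
#' the set than expected from random draws out of the background, using the
#' one-sided hypergeometric tail (equivalent to the one-sided Fisher exact
#' test on the 2x2 table).  This is a generic, database-free stand-in for
#' tools like DAVID: gene sets come from local files ([read_gene_sets()])
#' and the background should be the full assayed universe (e.g. every gene
#' on the array).  `ease = TRUE` applies the conservative EASE variant,
#' which subtracts one from the overlap before testing.
#'
#' Sets with fewer than two members after intersection with the background
#' are reported as untested (`tested = FALSE`, p and FDR `NA`).  FDR is
#' Benjamini-Hochberg across tested sets.
#'
#' @param gene_list character vector of query gene IDs; must be a subset of
#'   `background`.
#' @param gene_sets named list of character vectors (see [read_gene_sets()]).
#' @param background character vector: the gene universe.
#' @param ease apply the EASE overlap-minus-one correction (default off).
#' @return data.frame of class `enrichment_result`, sorted by p ascending:
#'   `set`, `set_size` (after background intersection), `overlap`,
#'   `list_size`, `background_size`, `p_value`, `fdr`, `genes`
#'   (comma-separated overlap members), `tested`.
#' @export
fisher_enrichment <- function(gene_list, gene_sets, background, ease = FALSE) {
  background <- unique(as.character(background))
  if (!length(background)) stopf("'background' must be non-empty")
  gene_list <- unique(as.character(gene_list))
  stray <- setdiff(gene_list, background)
  if (length(stray)) {
    stopf("genes in list but not in background: %s",
          paste(stray, collapse = ", "))
  }
  if (!is.list(gene_sets) || is.null(names(gene_sets))) {
    stopf("'gene_sets' must be a named list")
  }
  n_bg <- length(background)
  n_list <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), background)
    hit <- intersect(gene_list, s)
    k <- length(hit)
    tested <- length(s) >= 2L
    p <- NA_real_
    if (tested) {
      x <- if (ease) max(k - 1L, 0L) else k
      p <- phyper(x - 1L, length(s), n_bg - length(s), n_list,
                  lower.tail = FALSE)
    }
    data.frame(set = nm, set_size = length(s), overlap = k,
               list_size = n_list, background_size = n_bg,
               p_value = p, fdr = NA_real_,
               genes = paste(sort(hit), collapse = ","),
               tested = tested, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr[res$tested] <- bh_adjust(res$p_value[res$tested])
  res <- res[order(!res$tested, res$p_value, res$set, method = "radix"), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Over-representation analysis: %d sets (%d tested), list of %d over background of %d\n",
              nrow(x), sum(x$tested), x$list_size[1], x$background_size[1]))
  print.data.frame(head(x[, c("set", "set_size", "overlap", "p_value", "fdr")],
                        10), digits = 3)
  invisible(x)
}

#' Filter enrichment results by FDR
#'
#' @param result a [fisher_enrichment()] result.
#' @param fdr_max FDR cutoff (default 0.05).
#' @return The tested rows with `fdr <= fdr_max`.
#' @export
filter_enriched <- function(result, fdr_max = 0.05) {
  if (!is.numeric(fdr_max) || fdr_max < 0) stopf("'fdr_max' must be >= 0")
  out <- result[result$tested & !is.na(result$fdr) & result$fdr <= fdr_max, ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}
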