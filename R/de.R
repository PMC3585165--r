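#' Interquartile-range nonspecific filter
#'
#' Removes genes whose spread across all samples is too small to be
#' informative.  The IQR is the difference between the 75th and 25th
#' percentiles of a gene's log2 values over all samples, computed with the
#' linear-interpolation percentile rule (R quantile type 7); the retained-
#' gene count is sensitive to this convention, so it is fixed and documented.
#'
#' @param matrix genes x samples expression matrix.
#' @param iqr_min retention threshold (log2 units); the conventional
#'   nonspecific-filter default is 0.25.
#' @param strict if `TRUE` (default) keep genes with IQR strictly greater
#'   than `iqr_min`; if `FALSE` use `>=`.
#' @return The matrix restricted to retained genes, order preserved, with an
#'   attribute `n_removed`.
#' @export
iqr_filter <- function(matrix, iqr_min = 0.25, strict = TRUE) {
  assert_expression_matrix(matrix)
  if (ncol(matrix) < 2L) stopf("IQR filter needs at least 2 samples")
  if (!is.numeric(iqr_min) || iqr_min < 0) stopf("'iqr_min' must be >= 0")
  q <- apply(matrix, 1L, quantile, probs = c(0.25, 0.75), names = FALSE,
             type = 7)
  iqr <- q[2L, ] - q[1L, ]
  keep <- if (strict) iqr > iqr_min else iqr >= iqr_min
  out <- matrix[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Newton solve of trigamma(y) = x, vectorised; standard asymptotic starts
trigamma_inverse <- function(x) {
  y <- ifelse(x > 1e7, 1 / sqrt(x), ifelse(x < 1e-6, 1 / x, 0.5 + 1 / x))
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y), na.rm = TRUE) < 1e-8) break
  }
  y
}

# moment-matching fit of the scaled inverse chi-square prior on residual
# variances: returns prior df (possibly Inf) and prior variance
fit_variance_prior <- function(s2, df_resid) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stopf("all residual variances are zero; cannot fit prior")
  z <- log(s2[ok])
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  emean <- mean(e)
  evar <- mean((e - emean)^2) * length(e) / (length(e) - 1) -
    trigamma(df_resid / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(df_prior = Inf, var_prior = exp(emean)))
  }
  df_prior <- 2 * trigamma_inverse(evar)
  var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Fits the standard two-group equal-variance linear model per gene and
#' shrinks the residual variances toward a common prior estimated by moment
#' matching on the log variances (the empirical-Bayes recipe of moderated-t
#' analysis).  The posterior variance is the degrees-of-freedom-weighted
#' combination of the gene's pooled variance and the prior; the moderated t
#' is the log2 fold change divided by its posterior standard error, with p
#' from a t distribution on residual-plus-prior degrees of freedom.  With
#' `prior_df = 0` no shrinkage occurs and the statistic is exactly the
#' classical pooled-variance two-sample t; with `prior_df = Inf` all genes
#' share the prior variance.
#'
#' @param matrix genes x samples expression matrix (log2 scale).
#' @param annotation sample annotation with two groups, each of size >= 2.
#' @param case which group label is the case group (fold changes are case
#'   minus control); required unless a group is literally named "case".
#' @param prior_df `"auto"` (estimate by moment matching; genes with zero
#'   residual variance are excluded from the fit but still shrunk) or a
#'   non-negative number overriding the prior degrees of freedom.
#' @return A data.frame of class `de_test` with one row per gene:
#'   `gene_id`, per-group means, `log2_fc`, signed linear `fc`,
#'   `var_pooled`, `var_post`, `t`, `df_total`, `p_value`, `p_adj` (BH).
#'   Attributes record the fitted prior.
#' @export
moderated_t_test <- function(matrix, annotation, case = NULL,
                             prior_df = "auto") {
  assert_expression_matrix(matrix)
  assert_annotation(annotation, colnames(matrix))
  case <- resolve_case_label(annotation, case)
  groups <- unique(as.character(annotation$group))
  control <- setdiff(groups, case)
  idx_case <- colnames(matrix) %in%
    annotation$sample_id[annotation$group == case]
  idx_ctrl <- colnames(matrix) %in%
    annotation$sample_id[annotation$group == control]
  n1 <- sum(idx_ctrl); n2 <- sum(idx_case)
  if (n1 < 2L || n2 < 2L) {
    stopf("each group needs >= 2 samples (control: %d, case: %d)", n1, n2)
  }

  m_ctrl <- rowMeans(matrix[, idx_ctrl, drop = FALSE])
  m_case <- rowMeans(matrix[, idx_case, drop = FALSE])
  log2_fc <- m_case - m_ctrl
  ss_ctrl <- rowSums((matrix[, idx_ctrl, drop = FALSE] - m_ctrl)^2)
  ss_case <- rowSums((matrix[, idx_case, drop = FALSE] - m_case)^2)
  df_resid <- n1 + n2 - 2L
  s2 <- (ss_ctrl + ss_case) / df_resid

  if (identical(prior_df, "auto")) {
    prior <- fit_variance_prior(s2, df_resid)
  } else {
    if (!is.numeric(prior_df) || length(prior_df) != 1L || prior_df < 0) {
      stopf("'prior_df' must be \"auto\" or a single non-negative number")
    }
    if (prior_df == 0) {
      prior <- list(df_prior = 0, var_prior = 0)
    } else {
      p0 <- fit_variance_prior(s2, df_resid)
      prior <- list(df_prior = prior_df, var_prior = p0$var_prior)
    }
  }
  d0 <- prior$df_prior
  s2_post <- if (is.infinite(d0)) {
    rep(prior$var_prior, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * prior$var_prior + df_resid * s2) / (d0 + df_resid)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, log2_fc / se,
                   ifelse(log2_fc == 0, 0, sign(log2_fc) * Inf))
  df_total <- df_resid + d0
  p <- 2 * pt(-abs(t_stat), df = df_total)
  p[is.nan(p)] <- 1  # t = 0/0 for an all-constant gene under no shrinkage

  res <- data.frame(
    gene_id = rownames(matrix),
    mean_control = m_ctrl,
    mean_case = m_case,
    log2_fc = log2_fc,
    fc = sign(log2_fc) * 2^abs(log2_fc),
    var_pooled = s2,
    var_post = s2_post,
    t = t_stat,
    df_total = df_total,
    p_value = p,
    p_adj = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "prior_df") <- d0
  attr(res, "prior_var") <- prior$var_prior
  attr(res, "case") <- case
  attr(res, "control") <- control
  attr(res, "n_per_group") <- c(control = n1, case = n2)
  class(res) <- c("de_test", "data.frame")
  res
}

#' @export
print.de_test <- function(x, ...) {
  cat(sprintf("Moderated two-group differential expression: %d genes\n", nrow(x)))
  cat(sprintf("  groups: %s (n=%d) vs %s (n=%d); prior df = %s\n",
              attr(x, "case"), attr(x, "n_per_group")[["case"]],
              attr(x, "control"), attr(x, "n_per_group")[["control"]],
              format(attr(x, "prior_df"), digits = 3)))
  cat(sprintf("  genes with BH-adjusted p <= 0.05: %d\n", sum(x$p_adj <= 0.05)))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated interface over `stats::p.adjust(method = "BH")`: sorts the
#' p-values, applies the step-up rule `min_{j >= i} m p_(j) / j` capped at 1,
#' and returns the adjusted values in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must be finite numbers in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Select differentially expressed genes by fold-change and p cutoffs
#'
#' @param result a [moderated_t_test()] result, or any data.frame carrying
#'   `gene_id`, `log2_fc` and the chosen p column (e.g. the packaged printed
#'   DE table after [fc_to_log2fc()] conversion).
#' @param min_abs_log2fc minimum absolute log2 fold change (1 means 2-fold).
#' @param max_p maximum p in `p_column`.
#' @param p_column which p column the cutoff applies to; the default is the
#'   BH-adjusted column.
#' @return Rows passing both cutoffs with a `direction` ("up"/"down") label,
#'   sorted by the p column ascending.
#' @export
select_de_genes <- function(result, min_abs_log2fc = 1, max_p = 0.05,
                            p_column = "p_adj") {
  if (!all(c("gene_id", "log2_fc", p_column) %in% names(result))) {
    stopf("'result' must have columns gene_id, log2_fc and '%s'", p_column)
  }
  keep <- abs(result$log2_fc) >= min_abs_log2fc & result[[p_column]] <= max_p
  out <- result[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2_fc >= 0, "up", "down")
  out <- out[order(out[[p_column]]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Write DE results and volcano-plot coordinates
#'
#' `write_de_results()` emits the full per-gene table; `volcano_coordinates()`
#' returns (log2 fold change, -log10 raw p) pairs for plotting.
#'
#' @param result a [moderated_t_test()] result.
#' @param path output TSV path.
#' @return Invisibly, `path` (writer) or the coordinate data.frame.
#' @export
write_de_results <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_results
#' @export
volcano_coordinates <- function(result) {
  data.frame(gene_id = result$gene_id, log2_fc = result$log2_fc,
             neg_log10_p = -log10(pmax(result$p_value, .Machine$double.xmin)),
             stringsAsFactors = FALSE)
}
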