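#' End-to-end pipeline configuration
#'
#' Collects every tunable of the analysis: input paths, the IQR filter
#' threshold, the differential-expression cutoffs, the discriminant top-K,
#' the surrogate calibration grid and ensemble size, the edge rule, and the
#' correlation scope.  Defaults reproduce the canonical 7-vs-7 microarray
#' design: IQR > 0.25, |log2FC| >= 1 with BH p <= 0.05, top 100 discriminant
#' genes, 1000 surrogate realisations with a 10% margin, positive edge rule,
#' per-group correlations.
#'
#' @param matrix_path tab-delimited expression matrix.
#' @param annotation_path sample annotation TSV (`sample_id`, `group`).
#' @param case_label which annotation group is the case group (explicit,
#'   never inferred from label strings).
#' @param output_dir directory for the report bundle (created if needed).
#' @param gmt_path optional GMT gene-set file; enables the enrichment stage.
#' @param genes_in_rows orientation of the matrix file.
#' @param iqr_min IQR filter threshold.
#' @param min_abs_log2fc,max_adj_p DE selection cutoffs.
#' @param prior_df moderated-t prior df ("auto" or a number).
#' @param top_k discriminant list length.
#' @param grid,n_surrogates,margin calibration parameters
#'   (see [calibrate_threshold()]).
#' @param tau "auto" (use the case-group calibration; falls back to the top
#'   of the grid when no threshold qualifies) or a fixed number in (0, 1).
#' @param edge_rule "positive" or "absolute".
#' @param correlation_scope "per_group" (each network from its own group's
#'   samples, default) or "pooled" (both networks wired from correlations
#'   over the entire population).
#' @param mds_dims MDS embedding dimension.
#' @param seed seed for the surrogate ensemble; recorded in the manifest.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path, annotation_path, case_label,
                            output_dir, gmt_path = NULL, genes_in_rows = TRUE,
                            iqr_min = 0.25, min_abs_log2fc = 1,
                            max_adj_p = 0.05, prior_df = "auto", top_k = 100,
                            grid = seq(0.50, 0.99, by = 0.01),
                            n_surrogates = 1000, margin = 0.10, tau = "auto",
                            edge_rule = "positive",
                            correlation_scope = c("per_group", "pooled"),
                            mds_dims = 3, seed = 1) {
  correlation_scope <- match.arg(correlation_scope)
  cfg <- list(matrix_path = matrix_path, annotation_path = annotation_path,
              case_label = case_label, output_dir = output_dir,
              gmt_path = gmt_path, genes_in_rows = genes_in_rows,
              iqr_min = iqr_min, min_abs_log2fc = min_abs_log2fc,
              max_adj_p = max_adj_p, prior_df = prior_df, top_k = top_k,
              grid = grid, n_surrogates = n_surrogates, margin = margin,
              tau = tau, edge_rule = match.arg(edge_rule,
                                               c("positive", "absolute")),
              correlation_scope = correlation_scope, mds_dims = mds_dims,
              seed = assert_seed(seed))
  if (!is.character(cfg$case_label) || length(cfg$case_label) != 1L) {
    stopf("'case_label' must be a single group label")
  }
  if (!is.numeric(cfg$iqr_min) || cfg$iqr_min < 0) stopf("'iqr_min' must be >= 0")
  if (!is.numeric(cfg$min_abs_log2fc) || cfg$min_abs_log2fc < 0) {
    stopf("'min_abs_log2fc' must be >= 0")
  }
  if (!is.numeric(cfg$max_adj_p) || cfg$max_adj_p < 0 || cfg$max_adj_p > 1) {
    stopf("'max_adj_p' must lie in [0, 1]")
  }
  if (!is_count(cfg$top_k) || cfg$top_k < 2) stopf("'top_k' must be a count >= 2")
  if (!identical(cfg$tau, "auto") &&
      (!is.numeric(cfg$tau) || cfg$tau <= 0 || cfg$tau >= 1)) {
    stopf("'tau' must be \"auto\" or a number in (0, 1)")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full two-group network analysis pipeline
#'
#' Executes, in order: matrix and annotation ingestion, IQR filtering,
#' moderated differential expression, MDS quality control, transposed PCA
#' with discriminant-component selection and top-K gene ranking, surrogate
#' threshold calibration on the case and control groups, per-group network
#' construction, network comparison, and (when a GMT file is configured)
#' over-representation analysis of the top-K genes against the full matrix
#' background.  Every stage writes its table into the output directory and a
#' machine-readable JSON-like manifest records all parameters, the seed and
#' input checksums, so a rerun with the same configuration is byte
#' identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all intermediate objects (`filtered`,
#'   `de`, `de_selected`, `mds`, `pca`, `discriminant`, `top_genes`,
#'   `calibration_case`, `calibration_control`, `tau`, `net_case`,
#'   `net_control`, `comparison`, `enrichment`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stopf("'config' must be created by pipeline_config()")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  mat <- run_stage("ingest", {
    m <- read_expression_matrix(config$matrix_path, config$genes_in_rows)
    ann <- read_sample_annotation(config$annotation_path)
    assert_annotation(ann, colnames(m))
    resolve_case_label(ann, config$case_label)
    list(m = m, ann = ann)
  })
  m <- mat$m; ann <- mat$ann
  control_label <- setdiff(unique(as.character(ann$group)), config$case_label)

  filtered <- run_stage("iqr_filter", iqr_filter(m, config$iqr_min))
  writeLines(c("metric\tvalue",
               sprintf("genes_before\t%d", nrow(m)),
               sprintf("genes_after\t%d", nrow(filtered)),
               sprintf("iqr_min\t%s", format(config$iqr_min))),
             out("filter_summary.tsv"))

  de <- run_stage("differential_expression",
                  moderated_t_test(filtered, ann, case = config$case_label,
                                   prior_df = config$prior_df))
  write_de_results(de, out("de_results.tsv"))
  de_sel <- select_de_genes(de, config$min_abs_log2fc, config$max_adj_p)
  write.table(de_sel, out("de_selected.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(volcano_coordinates(de), out("volcano.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  mds <- run_stage("mds", classical_mds(m, config$mds_dims))
  write.table(data.frame(sample_id = rownames(mds), mds,
                         stringsAsFactors = FALSE),
              out("mds_coordinates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  pca <- run_stage("pca", transpose_pca(m))
  write.table(summary(pca), out("pca_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  disc <- run_stage("discriminant_selection",
                    select_discriminant_component(pca, ann))
  top <- run_stage("gene_ranking",
                   rank_genes_by_score(pca, disc$component, config$top_k))
  write.table(top, out("top_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  sub <- m[top$gene_id, , drop = FALSE]
  case_cols <- group_samples(sub, ann, config$case_label)
  ctrl_cols <- group_samples(sub, ann, control_label)
  cal_case <- run_stage("calibration", calibrate_threshold(
    sub[, case_cols, drop = FALSE], grid = config$grid,
    n_surrogates = config$n_surrogates, margin = config$margin,
    seed = config$seed, edge_rule = config$edge_rule))
  cal_ctrl <- run_stage("calibration", calibrate_threshold(
    sub[, ctrl_cols, drop = FALSE], grid = config$grid,
    n_surrogates = config$n_surrogates, margin = config$margin,
    seed = config$seed, edge_rule = config$edge_rule))
  write.table(cal_case$table, out("calibration_case.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cal_ctrl$table, out("calibration_control.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tau <- if (identical(config$tau, "auto")) {
    if (is.na(cal_case$selected)) max(config$grid) else cal_case$selected
  } else config$tau

  nets <- run_stage("network", {
    if (config$correlation_scope == "pooled") {
      r <- pearson_matrix(sub)
      list(case = build_network(r, tau, config$edge_rule),
           control = build_network(r, tau, config$edge_rule))
    } else {
      list(case = build_network(
             pearson_matrix(sub[, case_cols, drop = FALSE]),
             tau, config$edge_rule),
           control = build_network(
             pearson_matrix(sub[, ctrl_cols, drop = FALSE]),
             tau, config$edge_rule))
    }
  })
  write_network_graphml(nets$case, out("network_case.graphml"))
  write_network_graphml(nets$control, out("network_control.graphml"))
  write_network_edges(nets$case, out("network_case_edges.tsv"))
  write_network_edges(nets$control, out("network_control_edges.tsv"))
  comparison <- run_stage("network_summary",
                          network_summary(nets$case, nets$control))
  writeLines(c("metric\tvalue",
               sprintf("n_nodes\t%d", comparison$n_nodes),
               sprintf("potential_connections\t%d",
                       comparison$potential_connections),
               sprintf("tau\t%s", format(tau)),
               sprintf("case_average_degree\t%s",
                       format(comparison$case$average_degree)),
               sprintf("case_edges\t%d", comparison$case$n_edges),
               sprintf("case_isolated\t%d", comparison$case$n_isolated),
               sprintf("case_largest_component\t%d",
                       length(comparison$largest_case_component)),
               sprintf("control_average_degree\t%s",
                       format(comparison$control$average_degree)),
               sprintf("control_edges\t%d", comparison$control$n_edges),
               sprintf("control_isolated\t%d", comparison$control$n_isolated),
               sprintf("control_largest_component\t%d",
                       length(comparison$largest_control_component))),
             out("network_comparison.tsv"))

  enr <- NULL
  if (!is.null(config$gmt_path)) {
    enr <- run_stage("enrichment", {
      sets <- read_gene_sets(config$gmt_path)
      fisher_enrichment(top$gene_id, sets, rownames(m))
    })
    write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  sums <- tools::md5sum(c(config$matrix_path, config$annotation_path))
  manifest <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("surrnet"))),
    sprintf("seed\t%d", config$seed),
    sprintf("case_label\t%s", config$case_label),
    sprintf("iqr_min\t%s", format(config$iqr_min)),
    sprintf("min_abs_log2fc\t%s", format(config$min_abs_log2fc)),
    sprintf("max_adj_p\t%s", format(config$max_adj_p)),
    sprintf("prior_df\t%s", format(attr(de, "prior_df"), digits = 10)),
    sprintf("top_k\t%d", config$top_k),
    sprintf("n_surrogates\t%d", config$n_surrogates),
    sprintf("margin\t%s", format(config$margin)),
    sprintf("edge_rule\t%s", config$edge_rule),
    sprintf("correlation_scope\t%s", config$correlation_scope),
    sprintf("tau_mode\t%s", if (identical(config$tau, "auto")) "auto" else "fixed"),
    sprintf("tau\t%s", format(tau)),
    sprintf("selected_threshold_case\t%s", format(cal_case$selected)),
    sprintf("selected_threshold_control\t%s", format(cal_ctrl$selected)),
    sprintf("discriminant_component\t%d", disc$component),
    sprintf("md5_matrix\t%s", unname(sums[1])),
    sprintf("md5_annotation\t%s", unname(sums[2]))
  )
  writeLines(manifest, out("manifest.tsv"))

  invisible(list(filtered = filtered, de = de, de_selected = de_sel,
                 mds = mds, pca = pca, discriminant = disc, top_genes = top,
                 calibration_case = cal_case, calibration_control = cal_ctrl,
                 tau = tau, net_case = nets$case, net_control = nets$control,
                 comparison = comparison, enrichment = enr))
}

#' Recompute the packaged-table sanity checks
#'
#' Re-derives, from the packaged fixtures and small generated graphs, the
#' quantities the printed study tables imply: the 96/16/80 re-filter counts
#' of the DE table under the |FC| >= 2 and p <= 0.05 cutoffs, the 64-year
#' median age of both cohort groups, the completeness of the 100-entry
#' discriminant ranking, the exact `AD = 2C/N` identity on a random network,
#' and the 4950 potential connections among 100 genes.  Failures are
#' reported, not raised.
#'
#' @param seed seed for the random-graph identity check.
#' @return data.frame of class `fixture_checks` with columns `check`,
#'   `expected`, `observed`, `pass`.
#' @export
run_fixture_checks <- function(seed = 1) {
  tabs <- load_fixture_tables()
  de <- tabs$de_genes
  de$gene_id <- de$probe_id
  de$log2_fc <- fc_to_log2fc(de$fc)
  sel <- select_de_genes(de, min_abs_log2fc = 1, max_p = 0.05,
                         p_column = "p_value")
  ages <- tapply(tabs$cohort$age, tabs$cohort$group, median)

  set.seed(assert_seed(seed))
  n <- 30L
  r <- cor(base::matrix(rnorm(8L * n), 8L, n))
  rownames(r) <- colnames(r) <- sprintf("g%02d", seq_len(n))
  net <- build_network(r, tau = 0.5)
  ad_exact <- isTRUE(all.equal(net$average_degree * n, 2 * net$n_edges)) &&
    net$average_degree == 2 * net$n_edges / n

  checks <- data.frame(
    check = c("de_refilter_total", "de_refilter_down", "de_refilter_up",
              "median_age_control", "median_age_case",
              "discriminant_ranks_complete", "ad_identity",
              "potential_connections_100"),
    expected = c(96, 16, 80, 64, 64, 1, 1, 4950),
    observed = c(nrow(sel), sum(sel$direction == "down"),
                 sum(sel$direction == "up"),
                 unname(ages[["control"]]), unname(ages[["ALS"]]),
                 as.numeric(all(seq_len(100) %in% tabs$discriminant$rank)),
                 as.numeric(ad_exact), 100 * 99 / 2),
    stringsAsFactors = FALSE
  )
  checks$pass <- checks$expected == checks$observed
  class(checks) <- c("fixture_checks", "data.frame")
  checks
}

#' @export
print.fixture_checks <- function(x, ...) {
  cat(sprintf("Fixture checks: %d/%d passed\n", sum(x$pass), nrow(x)))
  print.data.frame(x)
  invisible(x)
}
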