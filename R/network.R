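#' Pairwise Pearson correlation matrix of genes
#'
#' Correlations are computed between gene expression vectors over the
#' supplied samples (typically one group's samples only).  Constant genes
#' have undefined correlations; these are recorded as 0 and the genes are
#' flagged with a warning.
#'
#' @param matrix genes x samples expression matrix restricted to the genes
#'   and samples of interest (>= 2 genes, >= 3 samples).
#' @return A symmetric genes x genes correlation matrix with unit diagonal;
#'   attributes `n_samples` and `constant_genes`.
#' @export
pearson_matrix <- function(matrix) {
  assert_expression_matrix(matrix)
  if (ncol(matrix) < 3L) stopf("correlation needs at least 3 samples")
  if (nrow(matrix) < 2L) stopf("correlation needs at least 2 genes")
  sds <- apply(matrix, 1L, sd)
  const <- rownames(matrix)[sds == 0]
  r <- suppressWarnings(cor(t(matrix)))
  if (length(const)) {
    warning(sprintf("constant genes with undefined correlation set to 0: %s",
                    paste(const, collapse = ", ")), call. = FALSE)
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  attr(r, "n_samples") <- ncol(matrix)
  attr(r, "constant_genes") <- const
  r
}

#' Permutation surrogate of an expression matrix
#'
#' Independently permutes each gene's values across the individuals,
#' destroying all inter-gene correlation while preserving every gene's
#' marginal distribution exactly (each value is reassigned to the individual
#' indexed by a random permutation).  Uses R's global random number
#' generator; seed it for reproducibility.
#'
#' @param matrix genes x samples expression matrix.
#' @return A matrix of the same shape and dimnames with rows independently
#'   permuted.
#' @export
shuffle_surrogate <- function(matrix) {
  assert_expression_matrix(matrix)
  n <- ncol(matrix)
  out <- matrix
  for (i in seq_len(nrow(matrix))) {
    out[i, ] <- matrix[i, sample.int(n)]
  }
  out
}

#' Analytic null tail of the Pearson correlation
#'
#' For independent Gaussian vectors of length `n`, `r * sqrt(n-2) /
#' sqrt(1-r^2)` follows a t distribution with `n - 2` degrees of freedom,
#' giving the closed-form probability that a null correlation exceeds `tau`.
#'
#' @param tau threshold in (0, 1).
#' @param n sample size (>= 3).
#' @return `P(r > tau)` under independence.
#' @export
pearson_null_tail <- function(tau, n) {
  if (any(tau <= -1 | tau >= 1)) stopf("'tau' must lie in (-1, 1)")
  if (n < 3) stopf("'n' must be >= 3")
  pt(tau * sqrt(n - 2) / sqrt(1 - tau^2), df = n - 2, lower.tail = FALSE)
}

count_connections <- function(r_upper, grid, edge_rule) {
  v <- if (edge_rule == "absolute") abs(r_upper) else r_upper
  vapply(grid, function(tau) sum(v > tau), numeric(1))
}

#' Calibrate the correlation threshold against surrogate data
#'
#' For every threshold on a grid, counts the connections (gene pairs with
#' correlation above the threshold) in the original data and, averaged over
#' many independent surrogate shuffles, in correlation-free data with the
#' same marginals.  The selected threshold is the smallest grid value at
#' which the mean surrogate count is at least `margin` (default 10%) lower
#' than the original count; if no grid value qualifies the selection is
#' `NA`, indicating that the observed correlation structure is
#' indistinguishable from chance.
#'
#' Because edge counts at high thresholds are small integers, a fixed
#' relative margin alone can be crossed by Monte-Carlo noise on fully
#' independent data.  Qualification therefore additionally applies the
#' standard surrogate-data rank test: the original count must strictly
#' exceed the count of every surrogate realisation at that threshold
#' (empirical p below `1 / n_surrogates`), so that a selected threshold
#' always reflects an excess outside the surrogate null band.  Set
#' `exceed_surrogates = FALSE` to recover the bare relative-margin rule.
#'
#' Surrogate realisation `i` is generated after seeding the RNG with
#' `seed + i`, so the calibration is reproducible bit for bit and
#' realisation-indexed.
#'
#' @param matrix genes x samples expression matrix (selected genes, one
#'   group's samples).
#' @param grid ascending thresholds in (0, 1); default 0.50 to 0.99 by 0.01.
#' @param n_surrogates number of surrogate realisations (default 1000).
#' @param margin required relative margin between original and surrogate
#'   counts (default 0.10).
#' @param seed RNG seed for the surrogate ensemble.
#' @param edge_rule count pairs with `r > tau` ("positive", default) or
#'   `|r| > tau` ("absolute").
#' @param exceed_surrogates Monte-Carlo guard: a threshold qualifies only
#'   if the original count also strictly exceeds every surrogate
#'   realisation's count (default `TRUE`).
#' @return Object of class `threshold_calibration`: data.frame `table`
#'   (threshold, original, surrogate_mean, surrogate_sd, surrogate_max,
#'   qualifies), `selected` (threshold or `NA`), plus the calibration
#'   parameters.
#' @export
calibrate_threshold <- function(matrix, grid = seq(0.50, 0.99, by = 0.01),
                                n_surrogates = 1000, margin = 0.10,
                                seed = 1, edge_rule = c("positive", "absolute"),
                                exceed_surrogates = TRUE) {
  edge_rule <- match.arg(edge_rule)
  if (!length(grid)) stopf("threshold grid must be non-empty")
  if (is.unsorted(grid) || any(grid <= 0 | grid >= 1)) {
    stopf("threshold grid must be ascending values in (0, 1)")
  }
  if (!is_count(n_surrogates) || n_surrogates < 1) {
    stopf("'n_surrogates' must be a positive count")
  }
  if (!is.numeric(margin) || margin < 0 || margin >= 1) {
    stopf("'margin' must lie in [0, 1)")
  }
  seed <- assert_seed(seed)
  r <- pearson_matrix(matrix)
  up <- r[upper.tri(r)]
  original <- count_connections(up, grid, edge_rule)
  surr_total <- numeric(length(grid))
  surr_sq <- numeric(length(grid))
  surr_max <- numeric(length(grid))
  for (i in seq_len(n_surrogates)) {
    set.seed(seed + i)
    rs <- suppressWarnings(cor(t(shuffle_surrogate(matrix))))
    rs[is.na(rs)] <- 0
    cnt <- count_connections(rs[upper.tri(rs)], grid, edge_rule)
    surr_total <- surr_total + cnt
    surr_sq <- surr_sq + cnt^2
    surr_max <- pmax(surr_max, cnt)
  }
  surrogate_mean <- surr_total / n_surrogates
  surrogate_sd <- if (n_surrogates > 1) {
    sqrt(pmax(surr_sq - n_surrogates * surrogate_mean^2, 0) /
           (n_surrogates - 1))
  } else rep(0, length(grid))
  ok <- original > 0 & surrogate_mean <= (1 - margin) * original
  if (exceed_surrogates) ok <- ok & original > surr_max
  selected <- if (any(ok)) grid[which(ok)[1L]] else NA_real_
  out <- list(table = data.frame(threshold = grid, original = original,
                                 surrogate_mean = surrogate_mean,
                                 surrogate_sd = surrogate_sd,
                                 surrogate_max = surr_max,
                                 qualifies = ok),
              selected = selected, margin = margin,
              exceed_surrogates = exceed_surrogates,
              n_surrogates = n_surrogates, seed = seed,
              edge_rule = edge_rule, n_genes = nrow(matrix),
              n_samples = ncol(matrix))
  class(out) <- "threshold_calibration"
  out
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("Surrogate threshold calibration: %d genes, %d samples, %d realisations\n",
              x$n_genes, x$n_samples, x$n_surrogates))
  cat(sprintf("  selected threshold (margin %.0f%%): %s\n", 100 * x$margin,
              if (is.na(x$selected)) "none (no threshold beats the surrogate null)"
              else format(x$selected)))
  invisible(x)
}

#' @export
plot.threshold_calibration <- function(x, ...) {
  with(x$table, {
    plot(threshold, original, type = "b", pch = 16, log = "y",
         xlab = "correlation threshold", ylab = "connections (log scale)", ...)
    graphics::lines(threshold, pmax(surrogate_mean, 0.01), type = "b",
                    pch = 1, lty = 2)
    graphics::legend("topright", c("original", "surrogate mean"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
  })
  invisible(x)
}

#' Build a thresholded gene correlation network
#'
#' Connects gene pairs whose correlation exceeds the threshold (strictly;
#' "higher than"), then computes the degree sequence, average degree
#' `AD = 2C/N` for `C` edges over `N` nodes, connected components and
#' isolated (degree-0) node count.
#'
#' @param corr symmetric correlation matrix from [pearson_matrix()].
#' @param tau edge threshold in (0, 1).
#' @param edge_rule "positive" (`r > tau`, default) or "absolute"
#'   (`|r| > tau`).
#' @return Object of class `gene_network`: `nodes`, `edges` (data.frame
#'   gene_a, gene_b, r), `degree`, `n_edges`, `average_degree`,
#'   `components` (list of node-set character vectors, largest first),
#'   `n_isolated`, `tau`, `edge_rule`, and the underlying igraph `graph`.
#' @export
build_network <- function(corr, tau, edge_rule = c("positive", "absolute")) {
  edge_rule <- match.arg(edge_rule)
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stopf("'corr' must be a square correlation matrix")
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau <= 0 || tau > 1) {
    stopf("'tau' must be a single value in (0, 1]")
  }
  nodes <- rownames(corr) %||% sprintf("G%d", seq_len(nrow(corr)))
  v <- if (edge_rule == "absolute") abs(corr) else corr
  sel <- which(upper.tri(corr) & v > tau, arr.ind = TRUE)
  edges <- data.frame(gene_a = nodes[sel[, 1L]], gene_b = nodes[sel[, 2L]],
                      r = corr[sel], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  comp_sets <- split(nodes, comp$membership)
  comp_sets <- comp_sets[order(-comp$csize)]
  names(comp_sets) <- NULL
  out <- list(nodes = nodes, edges = edges, degree = deg,
              n_edges = nrow(edges),
              average_degree = 2 * nrow(edges) / length(nodes),
              components = comp_sets,
              n_isolated = sum(deg == 0),
              tau = tau, edge_rule = edge_rule, graph = g)
  class(out) <- "gene_network"
  out
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene correlation network (tau = %s, %s rule)\n",
              format(x$tau), x$edge_rule))
  cat(sprintf("  N = %d nodes, C = %d edges, AD = 2C/N = %.3g\n",
              length(x$nodes), x$n_edges, x$average_degree))
  cat(sprintf("  components: %d (largest %d nodes), isolated nodes: %d\n",
              length(x$components), length(x$components[[1]]), x$n_isolated))
  invisible(x)
}

#' @export
summary.gene_network <- function(object, ...) {
  list(n_nodes = length(object$nodes), n_edges = object$n_edges,
       average_degree = object$average_degree,
       n_isolated = object$n_isolated,
       component_sizes = lengths(object$components))
}

#' @export
plot.gene_network <- function(x, ...) {
  plot(x$graph, vertex.size = 4, vertex.label.cex = 0.5, ...)
  invisible(x)
}

#' Export a network
#'
#' @param network a [build_network()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edges <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character(0))
  a <- pmin(net$edges$gene_a, net$edges$gene_b)
  b <- pmax(net$edges$gene_a, net$edges$gene_b)
  paste(a, b, sep = "|")
}

#' Compare case and control networks over the same nodes
#'
#' @param net_case,net_control [build_network()] results over an identical
#'   node set.
#' @return Object of class `network_comparison` reporting, per group, the
#'   average degree, edge count, isolated-node count and largest component
#'   (size and members), plus the potential connection count `N(N-1)/2` and
#'   the edge-set difference.
#' @export
network_summary <- function(net_case, net_control) {
  if (!setequal(net_case$nodes, net_control$nodes)) {
    stopf("case and control networks must share the same node set")
  }
  n <- length(net_case$nodes)
  ek_case <- edge_keys(net_case)
  ek_ctrl <- edge_keys(net_control)
  out <- list(
    n_nodes = n,
    potential_connections = n * (n - 1) / 2,
    case = summary(net_case),
    control = summary(net_control),
    largest_case_component = net_case$components[[1]],
    largest_control_component = net_control$components[[1]],
    edges_only_case = setdiff(ek_case, ek_ctrl),
    edges_only_control = setdiff(ek_ctrl, ek_case),
    edges_shared = intersect(ek_case, ek_ctrl)
  )
  class(out) <- "network_comparison"
  out
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("Network comparison over N = %d genes (%d potential connections)\n",
              x$n_nodes, x$potential_connections))
  cat(sprintf("  case:    AD = %.3g, C = %d, isolated = %d, largest component = %d\n",
              x$case$average_degree, x$case$n_edges, x$case$n_isolated,
              length(x$largest_case_component)))
  cat(sprintf("  control: AD = %.3g, C = %d, isolated = %d, largest component = %d\n",
              x$control$average_degree, x$control$n_edges,
              x$control$n_isolated, length(x$largest_control_component)))
  cat(sprintf("  edges only in case: %d, only in control: %d, shared: %d\n",
              length(x$edges_only_case), length(x$edges_only_control),
              length(x$edges_shared)))
  invisible(x)
}

#' Rank all genes by correlation with a query gene
#'
#' @param matrix genes x samples expression matrix (the correlation scope:
#'   typically one group's samples).
#' @param gene query gene ID, present in `matrix`.
#' @return data.frame `gene_id`, `r`, all genes other than the query, ranked
#'   by correlation descending.
#' @export
correlation_partners <- function(matrix, gene) {
  assert_expression_matrix(matrix)
  if (!gene %in% rownames(matrix)) stopf("unknown gene: %s", gene)
  if (ncol(matrix) < 3L) stopf("correlation needs at least 3 samples")
  r <- suppressWarnings(as.vector(cor(matrix[gene, ], t(matrix))))
  r[is.na(r)] <- 0
  names(r) <- rownames(matrix)
  r <- r[names(r) != gene]
  ord <- order(-r, names(r), method = "radix")
  data.frame(gene_id = names(r)[ord], r = r[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
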