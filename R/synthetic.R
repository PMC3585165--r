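#' Configuration for the synthetic two-group expression generator
#'
#' Defines a balanced two-group expression study on the log2 scale with known
#' ground truth: a shared per-gene baseline ("tissue profile") drawn once and
#' common to all samples, a minority of genes with a fixed group mean shift,
#' and correlation blocks planted in exactly one group.  The defaults emulate
#' a 14-sample microarray case-control design (7 vs 7) on an 8793-probeset
#' array with one 22-gene block of near-perfectly co-expressed genes in the
#' case group, the regime in which the surrogate-calibrated network contrast
#' is most informative.
#'
#' @param n_genes number of genes (rows).
#' @param n_per_group samples per group; total samples is `2 * n_per_group`.
#' @param n_de number of genes given a group mean shift (sign random per gene).
#' @param log2_shift absolute shift, log2 units, added to case-group means of
#'   differentially expressed genes.
#' @param tissue_axis_sd standard deviation (log2 units) of the shared
#'   per-gene baseline; when it dominates `noise_sd` the first component of
#'   the transposed PCA carries essentially all variance.
#' @param noise_sd residual per-observation noise standard deviation
#'   (log2 units); must be positive.
#' @param baseline_mean centre of the shared baseline (log2 units); 8 is a
#'   typical RMA-normalised intensity.
#' @param blocks list of correlation blocks, each created by [corr_block()].
#' @param seed RNG seed used by the generator.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_two_group_dataset()], [generate_null_dataset()]
#' @export
synthetic_config <- function(n_genes = 8793, n_per_group = 7, n_de = 96,
                             log2_shift = 1.5, tissue_axis_sd = 2,
                             noise_sd = 0.3, baseline_mean = 8,
                             blocks = list(corr_block(22, 0.97, "case")),
                             seed = 1) {
  cfg <- list(n_genes = n_genes, n_per_group = n_per_group, n_de = n_de,
              log2_shift = log2_shift, tissue_axis_sd = tissue_axis_sd,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              blocks = blocks, seed = seed)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

#' Planted correlation block description
#'
#' @param size number of genes in the block.
#' @param rho target pairwise Pearson correlation within the block, in
#'   `[0, 1)`; induced by one latent factor shared by the block's genes.
#' @param group group label ("case" or "control") whose samples carry the
#'   block; in the other group the same genes are independent.
#' @param shift optional mean shift (log2 units) added to the block's genes
#'   in the block's group, making the block discriminant as well as
#'   co-expressed — the signature of a coherently perturbed module.
#' @return A list describing the block.
#' @export
corr_block <- function(size, rho, group = "case", shift = 0) {
  list(size = size, rho = rho, group = group, shift = shift)
}

validate_synthetic_config <- function(cfg) {
  if (!is_count(cfg$n_genes) || cfg$n_genes < 1) {
    stopf("invalid config: 'n_genes' must be a positive count")
  }
  if (!is_count(cfg$n_per_group) || cfg$n_per_group < 2) {
    stopf("invalid config: 'n_per_group' must be a count >= 2")
  }
  if (!is_count(cfg$n_de) || cfg$n_de > cfg$n_genes) {
    stopf("invalid config: 'n_de' must be a count <= n_genes")
  }
  if (!is.numeric(cfg$log2_shift) || cfg$log2_shift < 0) {
    stopf("invalid config: 'log2_shift' must be non-negative")
  }
  if (!is.numeric(cfg$tissue_axis_sd) || cfg$tissue_axis_sd < 0) {
    stopf("invalid config: 'tissue_axis_sd' must be non-negative")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stopf("invalid config: 'noise_sd' must be positive")
  }
  if (!is.list(cfg$blocks)) stopf("invalid config: 'blocks' must be a list")
  for (b in cfg$blocks) {
    if (!is_count(b$size) || b$size < 2) {
      stopf("invalid config: block 'size' must be a count >= 2")
    }
    if (!is.numeric(b$rho) || b$rho < 0 || b$rho >= 1) {
      stopf("invalid config: block 'rho' must lie in [0, 1)")
    }
    if (!b$group %in% c("case", "control")) {
      stopf("invalid config: block 'group' must be \"case\" or \"control\"")
    }
    if (!is.numeric(b$shift %||% 0) || !is.finite(b$shift %||% 0)) {
      stopf("invalid config: block 'shift' must be a finite number")
    }
  }
  if (sum(vapply(cfg$blocks, `[[`, numeric(1), "size")) > cfg$n_genes) {
    stopf("invalid config: sum of block sizes exceeds 'n_genes'")
  }
  assert_seed(cfg$seed)
  cfg
}

#' Generate a synthetic two-group expression dataset with known truth
#'
#' Draws a genes x samples log2 expression matrix under the generative model
#' described in [synthetic_config()].  Each gene value is
#' `baseline + shift + noise_sd * e`, where `e` is standard normal except for
#' genes of a planted block within that block's group, where
#' `e = sqrt(rho) * f + sqrt(1 - rho) * z` with one latent factor `f` per
#' block and sample, giving pairwise correlation `rho` in expectation while
#' preserving unit marginal variance.  Differentially expressed genes receive
#' `+/- log2_shift` in the case group only.
#'
#' @param config a [synthetic_config()] object.
#' @return A list with elements `matrix` (genes x samples), `annotation`
#'   (data.frame: `sample_id`, `group`, controls first), and `truth`, a list
#'   with `de_genes` (named sign vector, +1 up in case), `block_membership`
#'   (gene id -> block label, `NA` for unassigned genes) and `group_of_block`.
#' @examples
#' d <- generate_two_group_dataset(synthetic_config(n_genes = 50, seed = 7,
#'                                                  n_de = 5, blocks = list()))
#' dim(d$matrix)
#' @export
generate_two_group_dataset <- function(config) {
  config <- validate_synthetic_config(config)
  n_g <- config$n_genes
  n_s <- 2L * config$n_per_group
  gene_ids <- sprintf("G%05d", seq_len(n_g))
  sample_ids <- c(sprintf("control_%d", seq_len(config$n_per_group)),
                  sprintf("case_%d", seq_len(config$n_per_group)))
  group <- rep(c("control", "case"), each = config$n_per_group)

  set.seed(config$seed)
  baseline <- rnorm(n_g, config$baseline_mean, config$tissue_axis_sd)

  # planted differential expression: first n_de genes after the blocks
  block_sizes <- vapply(config$blocks, `[[`, numeric(1), "size")
  block_genes <- if (length(block_sizes)) seq_len(sum(block_sizes)) else integer(0)
  membership <- rep(NA_character_, n_g)
  group_of_block <- character(0)
  at <- 0L
  for (i in seq_along(config$blocks)) {
    lab <- sprintf("block_%d", i)
    membership[at + seq_len(block_sizes[i])] <- lab
    group_of_block[lab] <- config$blocks[[i]]$group
    at <- at + block_sizes[i]
  }
  de_pool <- setdiff(seq_len(n_g), block_genes)
  if (config$n_de > length(de_pool)) {
    stopf("invalid config: 'n_de' exceeds the number of non-block genes")
  }
  de_idx <- de_pool[seq_len(config$n_de)]
  de_sign <- if (config$n_de) sample(c(-1, 1), config$n_de, replace = TRUE) else numeric(0)

  e <- matrix(rnorm(n_g * n_s), n_g, n_s)
  for (i in seq_along(config$blocks)) {
    b <- config$blocks[[i]]
    rows <- which(membership == sprintf("block_%d", i))
    cols <- which(group == b$group)
    f <- rnorm(length(cols))  # one latent factor value per sample in the group
    e[rows, cols] <- sqrt(b$rho) * matrix(f, length(rows), length(cols),
                                          byrow = TRUE) +
      sqrt(1 - b$rho) * e[rows, cols]
  }

  x <- baseline + config$noise_sd * e
  if (config$n_de) {
    x[de_idx, group == "case"] <- x[de_idx, group == "case"] +
      de_sign * config$log2_shift
  }
  for (i in seq_along(config$blocks)) {
    b <- config$blocks[[i]]
    sh <- b$shift %||% 0
    if (sh != 0) {
      rows <- which(membership == sprintf("block_%d", i))
      x[rows, group == b$group] <- x[rows, group == b$group] + sh
    }
  }
  dimnames(x) <- list(gene_ids, sample_ids)

  truth <- list(
    de_genes = setNames(de_sign, gene_ids[de_idx]),
    block_membership = setNames(membership, gene_ids),
    group_of_block = group_of_block
  )
  list(matrix = x,
       annotation = data.frame(sample_id = sample_ids, group = group,
                               stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate a signal-free synthetic dataset
#'
#' Identical to [generate_two_group_dataset()] with the differential
#' expression count forced to zero and all correlation blocks removed: both
#' groups are draws from the same distribution, providing the null regime for
#' type-I error and surrogate-calibration checks.
#'
#' @inheritParams generate_two_group_dataset
#' @return Same structure as [generate_two_group_dataset()]; `truth` is empty.
#' @export
generate_null_dataset <- function(config) {
  config <- validate_synthetic_config(config)
  config$n_de <- 0L
  config$blocks <- list()
  generate_two_group_dataset(config)
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' The matrix and annotation use the package's tab-delimited dialects; the
#' truth is serialised as a plain `key<TAB>value` text file.
#'
#' @param dataset result of [generate_two_group_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "expression_matrix.tsv"),
             annotation = file.path(dir, "sample_annotation.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_matrix(dataset$matrix, paths[["matrix"]])
  write_sample_annotation(dataset$annotation, paths[["annotation"]])
  tr <- dataset$truth
  lines <- c(
    sprintf("de_gene\t%s\t%d", names(tr$de_genes), as.integer(tr$de_genes)),
    sprintf("block\t%s\t%s",
            names(tr$block_membership)[!is.na(tr$block_membership)],
            tr$block_membership[!is.na(tr$block_membership)]),
    sprintf("block_group\t%s\t%s", names(tr$group_of_block), tr$group_of_block)
  )
  writeLines(lines, paths[["truth"]])
  invisible(paths)
}
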