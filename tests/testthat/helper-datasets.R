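# shared in-code fixtures: small synthetic designs reused across test files

small_null_config <- function(n_genes = 200, seed = 11) {
  synthetic_config(n_genes = n_genes, n_per_group = 7, n_de = 0,
                   blocks = list(), seed = seed)
}

block_config <- function(n_genes = 100, rho = 0.97, size = 22, seed = 101) {
  synthetic_config(n_genes = n_genes, n_per_group = 7, n_de = 0,
                   blocks = list(corr_block(size, rho, "case")), seed = seed)
}

# toy matrix with explicit values, genes in rows
toy_matrix <- function(values, n_samples) {
  m <- matrix(values, ncol = n_samples, byrow = TRUE)
  rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

two_group_annotation <- function(sample_ids, n_per_group) {
  data.frame(sample_id = sample_ids,
             group = rep(c("control", "case"), each = n_per_group),
             stringsAsFactors = FALSE)
}

# closed-form Pearson correlation, independent of stats::cor
hand_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# classical pooled-variance two-sample t, the oracle for the moderated test
hand_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# hypergeometric upper tail by direct summation over more-extreme tables
hand_hyper_tail <- function(overlap, set_size, list_size, background) {
  js <- overlap:min(set_size, list_size)
  sum(choose(set_size, js) * choose(background - set_size, list_size - js)) /
    choose(background, list_size)
}

# connected components by breadth-first search over an edge data.frame
bfs_components <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      for (w in adj[[v]]) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps[order(-lengths(comps))]
}
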