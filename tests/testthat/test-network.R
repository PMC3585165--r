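test_that("Pearson matrix matches the closed-form coefficient and handles edge cases", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  m <- toy_matrix(c(x, y, x, -x), 4)
  r <- pearson_matrix(m)
  expect_equal(r["g1", "g2"], hand_pearson(x, y))
  expect_equal(r["g1", "g3"], 1)
  expect_equal(r["g1", "g4"], -1)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 4))

  const <- rbind(m, g5 = rep(2, 4))
  colnames(const) <- colnames(m)
  expect_warning(rc <- pearson_matrix(const), "g5")
  expect_equal(unname(rc["g5", "g1"]), 0)
  expect_error(pearson_matrix(m[, 1:2]), "3 samples")
})

test_that("surrogate shuffling preserves each gene's marginal exactly", {
  d <- generate_two_group_dataset(block_config(n_genes = 40, seed = 71))
  m <- d$matrix
  set.seed(7)
  s <- shuffle_surrogate(m)
  expect_identical(dimnames(s), dimnames(m))
  for (i in seq_len(nrow(m))) {
    expect_identical(sort(unname(s[i, ])), sort(unname(m[i, ])),
                     info = rownames(m)[i])
  }
  expect_equal(rowMeans(s), rowMeans(m))
  expect_equal(apply(s, 1, var), apply(m, 1, var))
})

test_that("shuffling collapses planted correlation to the analytic null level", {
  d <- generate_two_group_dataset(
    synthetic_config(n_genes = 12, n_per_group = 7, n_de = 0,
                     blocks = list(corr_block(12, 0.99, "case")), seed = 73))
  case <- d$matrix[, grepl("^case", colnames(d$matrix))]
  r_before <- cor(t(case))
  expect_gt(mean(abs(r_before[upper.tri(r_before)])), 0.9)

  set.seed(99)
  vals <- replicate(300, {
    rs <- cor(t(shuffle_surrogate(case)))
    mean(abs(rs[upper.tri(rs)]))
  })
  # E|r| under the null at n = 7: 2 / ((n-2) * Beta(1/2, (n-2)/2))
  expected <- 2 / (5 * beta(0.5, 2.5))
  expect_equal(mean(vals), expected, tolerance = 0.05)
})

test_that("the analytic Pearson null tail matches direct Monte Carlo", {
  set.seed(12)
  r <- replicate(4000, cor(rnorm(7), rnorm(7)))
  for (tau in c(0.5, 0.75)) {
    tail <- pearson_null_tail(tau, 7)
    expect_lt(abs(mean(r > tau) - tail), 4 * sqrt(tail / 4000) + 0.005)
  }
})

test_that("threshold calibration selects a threshold only when real structure exists", {
  d <- generate_two_group_dataset(block_config(seed = 101))
  case <- d$matrix[, grepl("^case", colnames(d$matrix))]
  cal <- calibrate_threshold(case, n_surrogates = 150, seed = 3)
  expect_false(is.na(cal$selected))
  expect_true(cal$selected %in% cal$table$threshold)
  row <- cal$table[cal$table$threshold == cal$selected, ]
  expect_true(row$surrogate_mean <= 0.9 * row$original)
  expect_true(row$original > row$surrogate_max)
  # the rule takes the smallest qualifying grid member
  expect_identical(cal$selected,
                   cal$table$threshold[which(cal$table$qualifies)[1]])

  # counts are bounded by the number of potential connections and monotone
  expect_true(all(cal$table$original <= 100 * 99 / 2))
  expect_true(all(diff(cal$table$original) <= 0))
  expect_true(all(diff(cal$table$surrogate_mean) <= 1e-9))

  # calibration is reproducible bit for bit under the same seed
  cal2 <- calibrate_threshold(case, n_surrogates = 150, seed = 3)
  expect_identical(cal$table, cal2$table)
  expect_error(calibrate_threshold(case, grid = numeric(0)), "grid")
})

test_that("the selected threshold recovers planted edges but almost no surrogate edges", {
  d <- generate_two_group_dataset(block_config(seed = 107))
  block <- names(d$truth$block_membership)[!is.na(d$truth$block_membership)]
  case <- d$matrix[, grepl("^case", colnames(d$matrix))]
  cal <- calibrate_threshold(case, n_surrogates = 100, seed = 5)
  expect_false(is.na(cal$selected))
  net <- build_network(pearson_matrix(case), 0.95)
  within_block <- net$edges$gene_a %in% block & net$edges$gene_b %in% block
  expect_gt(sum(within_block), 0.5 * choose(22, 2))
  # at the top of the grid the surrogate ensemble is essentially edge-free
  row95 <- cal$table[cal$table$threshold == 0.95, ]
  expect_lt(row95$surrogate_mean, 0.1 * row95$original)
})

test_that("networks compute degrees, AD, components and isolates correctly", {
  # 6-node toy: a 3-clique and 3 isolated nodes
  r <- diag(6)
  r[1, 2] <- r[2, 1] <- r[1, 3] <- r[3, 1] <- r[2, 3] <- r[3, 2] <- 0.99
  dimnames(r) <- list(letters[1:6], letters[1:6])
  net <- build_network(r, 0.9)
  expect_identical(net$n_edges, 3L)
  expect_equal(net$average_degree, 1)
  expect_identical(net$n_isolated, 3L)
  oracle <- bfs_components(letters[1:6], net$edges)
  got <- lapply(net$components, sort)
  expect_identical(got[order(-lengths(got))], oracle)

  # tau = 1 under the strict rule yields the empty network
  empty <- build_network(r, 1)
  expect_identical(empty$n_edges, 0L)
  expect_equal(empty$average_degree, 0)
  expect_identical(empty$n_isolated, 6L)
  expect_error(build_network(r, 1.5), "tau")

  # AD = 2C/N from the printed-control inverse: 100 nodes, 10 edges
  set.seed(61)
  r2 <- diag(100)
  dimnames(r2) <- list(sprintf("n%03d", 1:100), sprintf("n%03d", 1:100))
  pairs <- cbind(1:10, 51:60)
  for (i in 1:10) r2[pairs[i, 1], pairs[i, 2]] <-
      r2[pairs[i, 2], pairs[i, 1]] <- 0.99
  net2 <- build_network(r2, 0.95)
  expect_identical(net2$n_edges, 10L)
  expect_equal(net2$average_degree, 0.2)
})

test_that("AD = 2C/N holds exactly on fuzzed random networks and is monotone in tau", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:60, 1)
    m <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:6)))
    r <- pearson_matrix(m)
    prev_edges <- Inf
    for (tau in c(0.3, 0.5, 0.7, 0.9)) {
      net <- build_network(r, tau)
      expect_identical(net$average_degree, 2 * net$n_edges / n)
      expect_identical(net$n_isolated, sum(net$degree == 0L))
      expect_identical(sort(unlist(net$components)), sort(net$nodes))
      expect_lte(net$n_edges, prev_edges)
      prev_edges <- net$n_edges
    }
  }
})

test_that("the absolute edge rule also links strong negative correlations", {
  set.seed(21)
  x <- rnorm(6)
  m <- toy_matrix(c(x, -x, rnorm(6)), 6)
  r <- pearson_matrix(m)
  pos <- build_network(r, 0.95, edge_rule = "positive")
  absn <- build_network(r, 0.95, edge_rule = "absolute")
  expect_identical(pos$n_edges, 0L)
  expect_identical(absn$n_edges, 1L)
  expect_identical(sort(c(absn$edges$gene_a, absn$edges$gene_b)),
                   c("g1", "g2"))
})

test_that("network comparison reports group contrast and edge-set differences", {
  d <- generate_two_group_dataset(block_config(seed = 113))
  block <- names(d$truth$block_membership)[!is.na(d$truth$block_membership)]
  case <- d$matrix[, grepl("^case", colnames(d$matrix))]
  ctrl <- d$matrix[, grepl("^control", colnames(d$matrix))]
  net_case <- build_network(pearson_matrix(case), 0.95)
  net_ctrl <- build_network(pearson_matrix(ctrl), 0.95)
  cmp <- network_summary(net_case, net_ctrl)
  expect_identical(cmp$potential_connections, 4950)
  expect_gt(cmp$case$average_degree, cmp$control$average_degree)
  inside <- mean(cmp$largest_case_component %in% block)
  expect_gt(inside, 0.8)
  expect_lte(length(cmp$largest_control_component), 5)

  same <- network_summary(net_case, net_case)
  expect_length(same$edges_only_case, 0)
  expect_length(same$edges_only_control, 0)

  bad <- build_network(pearson_matrix(case[1:50, ]), 0.95)
  expect_error(network_summary(net_case, bad), "node set")
})

test_that("correlation partners rank by r with the duplicate on top", {
  set.seed(83)
  m <- matrix(rnorm(10 * 7), 10, 7,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:7)))
  m <- rbind(m, dup = m["g01", ])
  partners <- correlation_partners(m, "g01")
  expect_identical(partners$gene_id[1], "dup")
  expect_equal(partners$r[1], 1)

  oracle <- sapply(setdiff(rownames(m), "g01"),
                   function(g) hand_pearson(m["g01", ], m[g, ]))
  oracle <- sort(oracle, decreasing = TRUE)
  expect_equal(partners$r, unname(oracle), tolerance = 1e-12)
  expect_identical(partners$gene_id, names(oracle))
  expect_error(correlation_partners(m, "nope"), "unknown gene")
})
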