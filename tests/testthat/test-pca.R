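test_that("transposed PCA satisfies its algebraic invariants on random data", {
  set.seed(41)
  m <- matrix(rnorm(300 * 10, mean = 8), 300, 10,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%d", 1:10)))
  p <- transpose_pca(m)

  expect_true(all(diff(p$eigenvalues) <= 1e-10))
  expect_equal(sum(p$variance_fraction), 1)
  expect_true(all(p$variance_fraction >= 0 & p$variance_fraction <= 1))
  expect_true(all(abs(p$loadings) <= 1 + 1e-12))

  # component score vectors are mutually orthogonal
  g <- crossprod(p$scores)
  expect_equal(g - diag(diag(g)), 0 * g, tolerance = 1e-8)

  # full-rank reconstruction of the centered matrix
  xc <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(p$scores %*% t(p$rotation), xc, tolerance = 1e-8,
               ignore_attr = TRUE)

  # factor loadings equal independently recomputed Pearson correlations
  for (j in c(1, 4, 10)) {
    for (k in c(1, 2, 5)) {
      expect_equal(p$loadings[j, k], hand_pearson(m[, j], p$scores[, k]),
                   tolerance = 1e-10)
    }
  }

  # deterministic sign: the dominant gene score of each component is positive
  for (k in seq_len(ncol(p$scores))) {
    expect_gte(p$scores[which.max(abs(p$scores[, k])), k], 0)
  }
})

test_that("duplicated sample columns put all variance on the first component", {
  set.seed(3)
  v <- rnorm(50, 8)
  m <- matrix(rep(v, 4), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  p <- transpose_pca(m)
  expect_equal(p$variance_fraction[1], 1)
  expect_error(transpose_pca(m * 0 + 1), "constant")
})

test_that("the discriminant component maximises the Fisher ratio of loadings", {
  # constructed case: loadings separated by group only on component 2
  set.seed(17)
  fake <- structure(list(
    loadings = cbind(PC1 = rnorm(8, 0.99, 0.001),
                     PC2 = c(rnorm(4, -0.5, 0.05), rnorm(4, 0.5, 0.05)),
                     PC3 = rnorm(8, 0, 0.3)),
    sample_ids = sprintf("s%d", 1:8)), class = "transpose_pca")
  rownames(fake$loadings) <- fake$sample_ids
  ann <- two_group_annotation(fake$sample_ids, 4)
  sel <- select_discriminant_component(fake, ann)
  expect_identical(sel$component, 2L)
  expect_true(sel$discriminating)

  # identical distributions: flagged non-discriminating above any real floor
  flat <- fake
  flat$loadings[] <- rep(c(0.1, 0.2, 0.3, 0.4), 6)
  sel2 <- select_discriminant_component(flat, ann, floor = 0.5)
  expect_false(sel2$discriminating)

  # synthetic group shift: exhaustive comparison over eligible components
  d <- generate_two_group_dataset(
    synthetic_config(n_genes = 600, n_per_group = 7, n_de = 60,
                     log2_shift = 1.5, noise_sd = 0.3, blocks = list(),
                     seed = 23))
  p <- transpose_pca(d$matrix)
  sel3 <- select_discriminant_component(p, d$annotation)
  grp <- d$annotation$group[match(p$sample_ids, d$annotation$sample_id)]
  brute <- vapply(2:ncol(p$loadings), function(k) {
    a <- p$loadings[grp == "control", k]; b <- p$loadings[grp == "case", k]
    (mean(a) - mean(b))^2 /
      (((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
         (length(a) + length(b) - 2))
  }, numeric(1))
  expect_identical(sel3$component, (2:ncol(p$loadings))[which.max(brute)])
  expect_identical(sel3$component, 2L)
})

test_that("gene ranking orders by absolute score with lexicographic ties", {
  fake <- structure(list(
    scores = cbind(PC1 = setNames(c(3, -5, 2), c("A", "B", "C")))),
    class = "transpose_pca")
  r <- rank_genes_by_score(fake, 1, k = 2)
  expect_identical(r$gene_id, c("B", "A"))
  full <- rank_genes_by_score(fake, 1, k = 10)
  expect_identical(nrow(full), 3L)

  tie <- structure(list(
    scores = cbind(PC1 = setNames(c(2, -2, 1), c("Z", "A", "M")))),
    class = "transpose_pca")
  expect_identical(rank_genes_by_score(tie, 1, 3)$gene_id, c("A", "Z", "M"))
  expect_error(rank_genes_by_score(fake, 1, k = 0), "'k'")
  expect_error(rank_genes_by_score(fake, 9, k = 1), "component")
})

test_that("planted discriminant genes dominate the top of the ranking", {
  d <- generate_two_group_dataset(
    synthetic_config(n_genes = 1000, n_per_group = 7, n_de = 120,
                     log2_shift = 1.5, noise_sd = 0.3, blocks = list(),
                     seed = 29))
  p <- transpose_pca(d$matrix)
  sel <- select_discriminant_component(p, d$annotation)
  top <- rank_genes_by_score(p, sel$component, 100)
  expect_gte(mean(top$gene_id %in% names(d$truth$de_genes)), 0.9)
})

test_that("classical MDS reproduces distances and embeds duplicates together", {
  # a 3-4-5 right triangle in the plane, expressed as 2-gene samples
  m <- t(toy_matrix(c(0, 0, 3, 0, 0, 4), 2))
  dimnames(m) <- list(c("gx", "gy"), c("s1", "s2", "s3"))
  coords <- classical_mds(m, n_dims = 2)
  expect_equal(as.matrix(dist(coords)), as.matrix(dist(t(m))),
               tolerance = 1e-10)

  m2 <- cbind(m, s4 = m[, "s3"])
  coords2 <- classical_mds(m2, n_dims = 2)
  expect_equal(coords2["s3", ], coords2["s4", ], tolerance = 1e-10)

  expect_error(classical_mds(m, n_dims = 3), "sample count")
})

test_that("MDS agrees with transposed-PCA sample coordinates on centered data", {
  set.seed(59)
  m <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:8)))
  m <- scale(m, center = TRUE, scale = FALSE)  # per-sample centering
  attr(m, "scaled:center") <- NULL
  p <- transpose_pca(m, center = TRUE)
  pc_coords <- p$rotation %*% diag(sqrt(p$eigenvalues * (nrow(m) - 1)))
  mds_coords <- classical_mds(m, n_dims = 7)
  expect_equal(as.matrix(dist(pc_coords)), as.matrix(dist(mds_coords)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("strong group signal makes groups linearly separable in 3-D MDS", {
  d <- generate_two_group_dataset(
    synthetic_config(n_genes = 500, n_per_group = 7, n_de = 100,
                     log2_shift = 2, noise_sd = 0.3, blocks = list(),
                     seed = 37))
  coords <- classical_mds(d$matrix, n_dims = 3)
  grp <- d$annotation$group[match(rownames(coords), d$annotation$sample_id)]
  fit <- suppressWarnings(
    glm(I(grp == "case") ~ ., family = binomial(),
        data = data.frame(coords)))
  expect_true(all((fitted(fit) > 0.5) == (grp == "case")))
})
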