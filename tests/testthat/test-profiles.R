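test_that("build_ratio_matrix computes depth-gated ratios per sample", {
  counts <- tibble::tibble(
    feature_id = c("V1", "V2", "V1", "V2"),
    sample = c("s1", "s1", "s2", "s2"),
    b6 = c(30L, 5L, 10L, 8L),
    cast = c(10L, 4L, 30L, 4L)
  )
  rm1 <- suppressMessages(build_ratio_matrix(counts, min_depth = 10))
  expect_equal(rm1$s1[rm1$feature_id == "V1"], 0.75)
  expect_true(is.na(rm1$s1[rm1$feature_id == "V2"])) # 9 reads < 10
  expect_equal(rm1$s2[rm1$feature_id == "V2"], 8 / 12)
  expect_error(build_ratio_matrix(dplyr::bind_rows(counts, counts[1, ])),
               "Duplicate")
})

test_that("all-NA features are dropped and allele swap flips the matrix", {
  counts <- tibble::tibble(
    feature_id = rep(c("V1", "V2"), 2),
    sample = rep(c("s1", "s2"), each = 2),
    b6 = c(30L, 1L, 12L, 2L),
    cast = c(10L, 1L, 28L, 1L)
  )
  expect_message(rm1 <- build_ratio_matrix(counts, min_depth = 10),
                 "Dropping 1")
  expect_equal(rm1$feature_id, "V1")
  swapped <- suppressMessages(build_ratio_matrix(
    dplyr::mutate(counts, tmp = b6, b6 = cast, cast = tmp), min_depth = 10))
  expect_equal(as.numeric(swapped[1, c("s1", "s2")]),
               1 - as.numeric(rm1[1, c("s1", "s2")]))
})

test_that("identical samples collapse to zero distance in PCA", {
  counts <- tibble::tibble(
    feature_id = rep(sprintf("V%d", 1:5), 2),
    sample = rep(c("a", "b"), each = 5),
    b6 = rep(c(40L, 5L, 20L, 35L, 10L), 2),
    cast = rep(c(5L, 40L, 20L, 10L, 35L), 2)
  )
  rm1 <- build_ratio_matrix(counts, min_depth = 10)
  pc <- pca_profiles(rm1)
  expect_equal(as.numeric(pc$scores[1, -1]), as.numeric(pc$scores[2, -1]),
               tolerance = 1e-10)
  expect_true(all(pc$var_explained >= 0) && sum(pc$var_explained) <= 1 + 1e-9)
})

test_that("PCA is deterministic with a fixed sign convention", {
  counts <- four_clone_counts(seed = 202)
  rm1 <- suppressMessages(build_ratio_matrix(counts))
  p1 <- suppressMessages(pca_profiles(rm1))
  p2 <- suppressMessages(pca_profiles(rm1))
  expect_identical(p1$scores, p2$scores)
  for (j in seq_len(ncol(p1$loadings))) {
    expect_gte(p1$loadings[which.max(abs(p1$loadings[, j])), j], 0)
  }
  expect_equal(tidy(p1), p1$scores)
  expect_equal(glance(p1)$n_samples, 8)
})

test_that("replicates neighbor each other; pools sit near the centroid", {
  seed <- 303
  locus <- make_locus(96, 60, seed = derive_seed(seed, 1))
  counts <- four_clone_counts(seed, locus = locus)
  pool <- simulate_pool(locus, ref_params(), n_clones = 200,
                        noise = noise_params(mu_active = 5, n_replicates = 2),
                        seed = derive_seed(seed, 999))
  pool$sample <- paste0("pool_", pool$sample)
  rm1 <- suppressMessages(build_ratio_matrix(dplyr::bind_rows(counts, pool)))
  pc <- suppressMessages(pca_profiles(rm1))
  sc <- as.matrix(as.data.frame(pc$scores)[, c("PC1", "PC2")])
  rownames(sc) <- pc$scores$sample
  d <- as.matrix(dist(sc)); diag(d) <- Inf
  clones <- clone_of_sample(rownames(sc))
  nn <- apply(d, 1, which.min)
  expect_true(all(clones[nn] == clones))
  # the pool lies nearer the clone centroid than any individual clone does
  centroid <- colMeans(sc[clones != "pool", ])
  pool_d <- sqrt(sum((colMeans(sc[clones == "pool", , drop = FALSE]) -
                        centroid)^2))
  clone_d <- vapply(unique(clones[clones != "pool"]), function(cl) {
    sqrt(sum((colMeans(sc[clones == cl, , drop = FALSE]) - centroid)^2))
  }, numeric(1))
  expect_lt(pool_d, min(clone_d))
})

test_that("clustering separates clones and ignores sample order", {
  counts <- four_clone_counts(seed = 404)
  rm1 <- suppressMessages(build_ratio_matrix(counts))
  tree <- suppressMessages(cluster_profiles(rm1))
  ct <- cutree(tree, k = 4)
  expect_equal(length(unique(ct)), 4)
  per_cluster <- tapply(clone_of_sample(names(ct)), ct,
                        function(x) length(unique(x)))
  expect_true(all(per_cluster == 1))

  # duplicated sample merges at height zero
  dup <- rm1
  dup$dup_sample <- dup[[2]]
  tree2 <- suppressMessages(cluster_profiles(dup))
  expect_equal(min(tree2$height), 0)

  perm <- rm1[, c(1, sample(2:9))]
  tree3 <- suppressMessages(cluster_profiles(perm))
  ct3 <- cutree(tree3, 4)[names(ct)]
  # same partition up to cluster relabeling
  expect_equal(outer(ct3, ct3, "=="), outer(ct, ct, "=="))
})

test_that("promoter concordance detects shared allelic state", {
  calls <- tibble::tibble(
    feature_id = sprintf("g%02d", 1:30),
    category = rep(c("mono_b6", "mono_cast", "biallelic"), 10)
  )
  conc <- promoter_concordance(calls, calls)
  expect_equal(conc$concordance, 1)
  expect_lt(conc$p.value, 1e-6)
  expect_equal(sum(conc$table), 30)
  expect_error(
    promoter_concordance(calls,
                         dplyr::mutate(calls, feature_id = paste0("x", feature_id))),
    "shared"
  )
})

test_that("accessibility-driven expression yields high concordance", {
  # ATAC and RNA libraries generated from the same clone activation state
  locus <- make_locus(60, 45, seed = 505)
  params <- activation_params(0.5, 0.4, 45, 60)
  cl <- simulate_clone(locus, params, seed = 506)
  noise <- noise_params(mu_active = 120, mu_leak = 1, n_replicates = 2)
  atac <- call_with_replicates(
    simulate_counts(cl, noise, seed = 507), min_depth = 20)
  rna <- call_with_replicates(
    simulate_counts(cl, noise, seed = 508), min_depth = 20)
  conc <- promoter_concordance(atac, rna)
  expect_gt(conc$concordance, 0.9)
  expect_lt(conc$p.value, 0.01)
})

test_that("independent random calls show near-nominal false concordance", {
  cats <- c("mono_b6", "mono_cast", "biallelic")
  rejections <- vapply(1:200, function(k) {
    with_seed_local(derive_seed(601, k), {
      a <- tibble::tibble(feature_id = sprintf("f%03d", 1:300),
                          category = sample(cats, 300, replace = TRUE))
      b <- tibble::tibble(feature_id = a$feature_id,
                          category = sample(cats, 300, replace = TRUE))
      promoter_concordance(a, b)$p.value < 0.05
    })
  }, logical(1))
  expect_lt(mean(rejections), 0.1)
})
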