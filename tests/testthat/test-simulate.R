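test_that("simulate_clone respects degenerate activation probabilities", {
  locus <- tiny_locus()
  none <- simulate_clone(locus, activation_params(0, 0, 5, 8), seed = 1)
  expect_false(any(none$b6_active) || any(none$cast_active))
  all_on <- simulate_clone(locus, activation_params(1, 1, 5, 8), seed = 1)
  expect_true(all(all_on$b6_active[all_on$potential]))
  expect_true(all(all_on$cast_active[all_on$potential]))
  expect_false(any(all_on$b6_active[!all_on$potential]))
})

test_that("clone category frequencies match analytic probabilities", {
  # Monte-Carlo check of the Bernoulli activation structure
  locus <- make_locus(96, 60, seed = 3)
  params <- ref_params()
  n_clones <- 400
  tallies <- vapply(seq_len(n_clones), function(k) {
    cl <- simulate_clone(locus, params, seed = derive_seed(77, k))
    clone_categories(cl)$n
  }, numeric(4))
  freq <- rowMeans(tallies) / 60
  expected <- category_probs(params)$prob_potential
  mc_se <- sqrt(expected * (1 - expected) / (60 * n_clones))
  expect_true(all(abs(freq - expected) <= 3 * mc_se + 1e-12))
})

test_that("simulated counts are reproducible nonnegative integers", {
  locus <- tiny_locus()
  cl <- simulate_clone(locus, activation_params(0.5, 0.5, 5, 8), seed = 4)
  a <- simulate_counts(cl, noise_params(), seed = 9)
  b <- simulate_counts(cl, noise_params(), seed = 9)
  expect_identical(a, b)
  expect_true(all(a$b6 >= 0 & a$cast >= 0))
  expect_true(all(a$b6 == round(a$b6) & a$cast == round(a$cast)))
  expect_equal(dplyr::n_distinct(a$sample), 2)
})

test_that("zero leak means inactive alleles yield exactly zero counts", {
  locus <- tiny_locus()
  cl <- fixed_clone(locus, b6_on = locus$id[locus$potential][1])
  noise <- noise_params(mu_active = 50, mu_leak = 0, n_replicates = 3)
  cnt <- simulate_counts(cl, noise, seed = 5)
  inactive <- cnt$feature_id != locus$id[locus$potential][1]
  expect_true(all(cnt$b6[inactive] == 0))
  expect_true(all(cnt$cast == 0))
})

test_that("count means track activation state and bias", {
  locus <- tiny_locus()
  on_id <- locus$id[locus$potential][1]
  cl <- fixed_clone(locus, b6_on = on_id, cast_on = on_id)
  noise <- noise_params(mu_active = 100, mu_leak = 1, n_replicates = 400)
  cnt <- simulate_counts(cl, noise, seed = 6)
  bi <- cnt[cnt$feature_id == on_id, ]
  # biallelic, no bias: mean B6 ratio ~ 0.5 by the law of large numbers
  expect_equal(mean(bi$b6 / (bi$b6 + bi$cast)), 0.5, tolerance = 0.02)

  # mono-B6 at mu_active 50 / mu_leak 1: expected ratio ~ 50/51
  cl2 <- fixed_clone(locus, b6_on = on_id)
  noise2 <- noise_params(mu_active = 50, mu_leak = 1, n_replicates = 500)
  cnt2 <- simulate_counts(cl2, noise2, seed = 7)
  mono <- cnt2[cnt2$feature_id == on_id, ]
  expect_equal(sum(mono$b6) / sum(mono$b6 + mono$cast), 50 / 51,
               tolerance = 0.01)

  # 10:1 Cast bias drags the pooled ratio under 0.2
  biased <- simulate_counts(cl, noise, bias = setNames(10, on_id), seed = 8)
  bb <- biased[biased$feature_id == on_id, ]
  expect_lt(sum(bb$b6) / sum(bb$b6 + bb$cast), 0.2)
  expect_error(simulate_counts(cl, noise, bias = c(nope = 2), seed = 1),
               "segment ids")
})

test_that("a singleton pool reproduces simulate_counts under seed discipline", {
  locus <- tiny_locus()
  params <- activation_params(0.5, 0.5, 5, 8)
  noise <- noise_params()
  pool <- simulate_pool(locus, params, n_clones = 1, noise = noise, seed = 21)
  s1 <- derive_seed(21, 1)
  cl <- simulate_clone(locus, params, seed = s1, clone_id = "pool_clone1")
  direct <- simulate_counts(cl, noise, seed = derive_seed(s1, 1, salt = 1))
  expect_equal(pool$b6, direct$b6)
  expect_equal(pool$cast, direct$cast)
})

test_that("large symmetric pools look biallelic at every potential segment", {
  locus <- make_locus(24, 16, seed = 2)
  params <- activation_params(0.4, 0.4, 16, 24)
  noise <- noise_params(mu_active = 30, n_replicates = 1)
  pool <- simulate_pool(locus, params, n_clones = 300, noise = noise,
                        seed = 31)
  calls <- call_features(dplyr::select(pool, -"sample"), min_depth = 50)
  pot <- calls[calls$feature_id %in% locus$id[locus$potential], ]
  expect_true(all(pot$category == "biallelic"))

  # one segment biased 10:1 toward Cast keeps a pooled ratio < 0.2
  target <- locus$id[locus$potential][1]
  biased <- simulate_pool(locus, params, n_clones = 300, noise = noise,
                          bias = setNames(10, target), seed = 31)
  row <- biased[biased$feature_id == target, ]
  expect_lt(sum(row$b6) / sum(row$b6 + row$cast), 0.2)
})

test_that("simulated reads carry parental bases and round-trip to counts", {
  locus <- tiny_locus(6, 6, seed = 12)
  params <- activation_params(0.6, 0.6, 6, 6)
  cl <- simulate_clone(locus, params, seed = 13)
  snps <- make_snps(locus, n_per_window = 150, seed = 14)
  noise <- noise_params(mu_active = 60, mu_leak = 1, n_replicates = 1)
  reads <- simulate_reads(cl, locus, snps, noise, seed = 15)
  expect_true(all(reads$end > reads$start))

  tags <- tag_alleles(reads, snps)
  informative <- tags %in% c("B6", "Cast")
  # tags recover the generating allele wherever a SNP was covered
  expect_true(all(tags[informative] == reads$origin[informative]))
  expect_gt(mean(informative), 0.9) # dense SNPs: nearly all reads taggable

  asn <- assign_reads(reads, locus, snps)
  # conservation: every read lands in the counts or a tally
  expect_equal(sum(asn$counts$b6 + asn$counts$cast) +
                 sum(asn$tally$reads[asn$tally$category %in%
                                       c("unassigned", "ambiguous", "conflict")]),
               nrow(reads))
  # per-segment totals track the count-level noise model marginals
  truth <- simulate_counts(cl, noise, seed = 15, sample_prefix = "rep")
  expect_gt(cor(asn$counts$b6 + asn$counts$cast, truth$b6 + truth$cast), 0.8)
})

test_that("windows without SNPs warn and yield untaggable reads", {
  locus <- tiny_locus(3, 3, seed = 16)
  cl <- simulate_clone(locus, activation_params(1, 1, 3, 3), seed = 17)
  snps <- make_snps(locus, n_per_window = 2, seed = 18)
  win <- assignment_window(locus)
  outside <- snps[!(snps$pos >= win$window_start[1] &
                      snps$pos < win$window_end[1]), ]
  expect_warning(
    reads <- simulate_reads(cl, locus, outside,
                            noise_params(mu_active = 20, n_replicates = 1),
                            seed = 19),
    "without SNPs"
  )
  first_win <- reads$start >= win$window_start[1] & reads$end <= win$window_end[1]
  expect_true(all(tag_alleles(reads[first_win, ], outside) == "unassigned"))
})
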