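test_that("normalize_repertoire yields percent views that invert exactly", {
  counts <- tibble::tibble(
    v_id = c("V1", "V2", "V1", "V2"),
    allele = c("B6", "B6", "Cast", "Cast"),
    count = c(50L, 50L, 30L, 10L)
  )
  norm <- normalize_repertoire(counts)
  expect_equal(norm$percent[norm$allele == "B6"], c(50, 50))
  expect_equal(norm$percent[norm$allele == "Cast"], c(75, 25))
  # percent conservation within each allele
  sums <- tapply(norm$percent, norm$allele, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-9)
  expect_equal(sum(norm$percent_library), 100, tolerance = 1e-9)
  # round trip: percent * total / 100 recovers the raw counts
  expect_equal(norm$percent_library * sum(counts$count) / 100, norm$count)

  single <- normalize_repertoire(
    tibble::tibble(v_id = "V1", allele = "B6", count = 7L))
  expect_equal(single$percent, 100)
  expect_error(normalize_repertoire(
    tibble::tibble(v_id = "V1", allele = "B6", count = 0L)), "zero")
})

test_that("rearrangement ratios share the allelic-ratio conventions", {
  tab <- tibble::tibble(
    v_id = c("V1", "V1", "V2", "V3"),
    allele = c("B6", "Cast", "B6", "Cast"),
    count = c(90L, 10L, 0L, 0L)
  )
  rr <- rearrangement_allelic_ratio(tab, min_depth = 20)
  expect_equal(rr$ratio[rr$v_id == "V1"], 0.9)
  expect_true(all(is.na(rr$ratio[rr$v_id != "V1"]))) # absent on both alleles

  swapped <- tab
  swapped$allele <- c("Cast", "B6", "Cast", "B6")
  rs <- rearrangement_allelic_ratio(swapped, min_depth = 20)
  expect_equal(rs$ratio[rs$v_id == "V1"], 1 - rr$ratio[rr$v_id == "V1"])
})

test_that("correlation requires shared segments and finds identity", {
  x <- tibble::tibble(v_id = sprintf("V%d", 1:10),
                      ratio = seq(0.05, 0.95, length.out = 10))
  expect_equal(ncrna_repertoire_correlation(x, x)$estimate, 1)
  expect_error(ncrna_repertoire_correlation(x[1:2, ], x[1:2, ]), "at least 3")

  null_r <- vapply(1:200, function(k) {
    with_seed_local(derive_seed(701, k), {
      a <- tibble::tibble(v_id = x$v_id, ratio = runif(10))
      b <- tibble::tibble(v_id = x$v_id, ratio = runif(10))
      ncrna_repertoire_correlation(a, b)$estimate
    })
  }, numeric(1))
  expect_lt(abs(mean(null_r)), 0.05)
})

test_that("skew_fraction counts strictly skewed segments", {
  expect_equal(skew_fraction(rep(0.5, 10)), 0)
  expect_equal(skew_fraction(c(0.95, 0.05, 0.5, 0.6)), 0.5)
  expect_equal(skew_fraction(c(0.8, 0.2)), 0) # boundary is strict
  expect_error(skew_fraction(c(NA_real_, NA_real_)), "non-missing")
  expect_error(skew_fraction(0.5, threshold = 0.4), "threshold")
})

test_that("symmetric unbiased pools show almost no skew", {
  locus <- make_locus(48, 32, seed = 801)
  pool <- simulate_pool(locus, activation_params(0.4, 0.4, 32, 48),
                        n_clones = 300,
                        noise = noise_params(mu_active = 5, n_replicates = 1),
                        seed = 802)
  ratios <- allelic_ratio(pool$b6, pool$cast, min_depth = 100)
  expect_lt(skew_fraction(ratios), 0.05)
})

test_that("degenerate repertoire weights behave at the limits", {
  locus <- tiny_locus(6, 6, seed = 811)
  on_id <- locus$id[2]
  cl <- fixed_clone(locus, b6_on = on_id)
  nc <- simulate_counts(cl, noise_params(mu_active = 80, mu_leak = 0),
                        seed = 812)
  # coupling 1, leak-free ncRNA, single B6-active segment: 100% of the B6
  # repertoire on that segment; time_fraction 0 leaves Cast with no events
  rep1 <- suppressWarnings(
    simulate_repertoire(cl, nc, coupling = 1, early_allele = "B6",
                        time_fraction = 0, depth = 1e4, seed = 813))
  b6_side <- rep1[rep1$allele == "B6", ]
  expect_equal(b6_side$count[b6_side$v_id == on_id], 1e4)
  expect_equal(sum(rep1$count[rep1$allele == "Cast"]), 0)
  expect_equal(attr(rep1, "empty_alleles"), "Cast")
})

test_that("repertoire tracks ncRNA ratios when coupled", {
  seed <- 821
  locus <- make_locus(96, 60, seed = derive_seed(seed, 1))
  cl <- simulate_clone(locus, ref_params(), seed = derive_seed(seed, 2))
  cnt <- simulate_counts(cl, noise_params(), seed = derive_seed(seed, 3))
  rep1 <- simulate_repertoire(cl, cnt, coupling = 0.9, depth = 1e5,
                              seed = derive_seed(seed, 4))
  nc <- dplyr::summarise(cnt, b6 = sum(.data$b6), cast = sum(.data$cast),
                         .by = "feature_id")
  ncr <- tibble::tibble(v_id = nc$feature_id,
                        ratio = allelic_ratio(nc$b6, nc$cast))
  corr <- ncrna_repertoire_correlation(ncr, rearrangement_allelic_ratio(rep1))
  expect_gt(corr$estimate, 0.5)
  expect_lt(corr$p.value, 0.001)
})

test_that("kinetics summary is exact at the endpoints and monotone", {
  seed <- 831
  locus <- make_locus(24, 16, seed = derive_seed(seed, 1))
  cl <- simulate_clone(locus, activation_params(0.6, 0.6, 16, 24),
                       seed = derive_seed(seed, 2))
  cnt <- simulate_counts(cl, noise_params(), seed = derive_seed(seed, 3))
  hours <- c(12, 24, 36, 48)
  tc <- dplyr::bind_rows(lapply(seq_along(hours), function(i) {
    rt <- simulate_repertoire(cl, cnt, coupling = 0.9, early_allele = "B6",
                              time_fraction = (i - 1) / (length(hours) - 1),
                              depth = 2e4, seed = derive_seed(seed, 10 + i))
    dplyr::mutate(rt, time = hours[i])
  }))
  ks <- kinetics_summary(tc, early_allele = "B6")
  expect_equal(ks$time, hours)
  expect_equal(ks$early_fraction[1], 1)              # t = 0 limit
  expect_equal(ks$early_fraction[4], 0.5, tolerance = 0.02)
  expect_true(all(diff(ks$early_fraction) <= 0))     # non-increasing
  expect_error(kinetics_summary(tc[tc$time == 12, ]), "two timepoints")
})
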