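# Shared synthetic fixtures, built in code at test time.

ref_params <- function() activation_params(0.43, 0.25, 60, 96)

tiny_locus <- function(n_total = 8, n_potential = 5, seed = 42) {
  make_locus(n_total, n_potential, seed = seed)
}

# A clone with a prescribed activation pattern on a tiny locus.
fixed_clone <- function(locus, b6_on = character(), cast_on = character()) {
  tibble::tibble(
    clone_id = "fixed",
    segment_id = locus$id,
    potential = locus$potential,
    b6_active = locus$id %in% b6_on,
    cast_active = locus$id %in% cast_on
  )
}

# Simulate 4 clones x 2 replicates and return the combined count table.
four_clone_counts <- function(seed, locus = NULL, params = ref_params(),
                              noise = noise_params()) {
  if (is.null(locus)) locus <- make_locus(96, 60, seed = derive_seed(seed, 1))
  dplyr::bind_rows(lapply(1:4, function(k) {
    cl <- simulate_clone(locus, params, seed = derive_seed(seed, 10 + k),
                         clone_id = paste0("c", k))
    simulate_counts(cl, noise, seed = derive_seed(seed, 100 + k),
                    sample_prefix = paste0("c", k, "_rep"))
  }))
}

clone_of_sample <- function(x) sub("_rep[0-9]+$", "", x)

with_seed_local <- function(seed, code) withr::with_seed(seed, code)
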