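# allelochoice

Allele-specific analysis of clonal V-segment choice in hybrid pre-B cells.

In F1 hybrid (C57BL/6 × CAST, "B6" × "Cast") pre-B-cell clones, each
immunoglobulin kappa V segment is independently "opened" — made accessible
and transcribed as germline ncRNA — on the B6 allele, the Cast allele, both,
or neither, and the choice is stable across cell divisions. `allelochoice`
provides a tested, reproducible toolkit for studying this phenomenon from
allele-resolved sequencing counts:

- **SNP read tagging and V-segment assignment**: sort read pairs to their
  parental genome by SNP content, assign them to segments with the
  strand-aware 500 bp-upstream / 10 kb-downstream window rule, and compute
  allelic ratios `B6/(B6+Cast)` with depth gating.
- **Monoallelic calling**: exact two-sided binomial test against allelic
  balance, Benjamini–Hochberg FDR, a ≥2-fold allele-difference rule, and
  replicate consistency (`call_features()`, `call_with_replicates()`).
- **Stochastic activation model**: each activatable segment turns on
  independently per allele with probabilities (p_B6, p_Cast); category
  probabilities are Bernoulli products (e.g. P(biallelic) = p_B6·p_Cast)
  and the expected active fraction is
  `(1 − (1−p_B6)(1−p_Cast)) · n_potential/n_total`. Closed-form maximum
  likelihood (`fit_activation()`, with broom-style `tidy()`/`glance()`),
  chi-square / exact-multinomial goodness of fit, and a profile likelihood
  over the activatable-set size.
- **Clonal profiling**: allelic-ratio matrices, deterministic PCA and
  hierarchical clustering of samples, `autoplot()` heatmaps on the red
  (Cast) → blue (B6) scale, and accessibility/expression concordance tests.
- **Rearrangement repertoires**: library- and allele-wise normalization,
  allelic skew, induction kinetics, and the correlation between ncRNA
  ratios before differentiation and rearrangement ratios after.
- **Synthetic hybrid-clone generator**: Bernoulli activation states,
  negative-binomial counts with leakage and optional fixed genetic bias,
  clone pools, SNP-bearing reads, and activation-coupled repertoires — all
  bit-reproducible from one master seed, so the entire pipeline is testable
  without external data.

All user-facing functions take and return tibbles and chain with the pipe.

## Worked example

```r
library(allelochoice)

# The activation model at the reference conditions
params <- activation_params(p_b6 = 0.43, p_cast = 0.25,
                            n_potential = 60, n_total = 96)
category_probs(params)
#>   category  prob_potential prob_marginal
#> 1 silent             0.428        0.642
#> 2 mono_b6            0.322        0.202
#> 3 mono_cast          0.143        0.0891
#> 4 biallelic          0.108        0.0672
expected_active_fraction(params)
#> [1] 0.3578125
```

So in any one clone only ~36% of the 96 functional V segments are expected
to be active on at least one allele: most of the locus stays closed, and
which segments open differs clone to clone.

```r
# Fit the model to observed per-clone category counts
fit_activation(c(silent = 26, mono_b6 = 19, mono_cast = 8, biallelic = 7),
               n_potential = 60)
#> Per-allele activation model fit
#>   p_b6  = 0.4333 (SE 0.0640)
#>   p_cast = 0.2500 (SE 0.0559)
#>   potential segments: 60; log-likelihood -5.90

# End-to-end synthetic run: 4 clones x 2 replicates, calling, model fits,
# PCA/clustering, repertoires and ncRNA correlation
res <- run_pipeline(default_config(seed = 1))
sapply(res$fits, function(f) c(p_b6 = f$p_b6, p_cast = f$p_cast))
#>        clone1 clone2 clone3 clone4
#> p_b6     0.45   0.35  0.433    0.5
#> p_cast   0.30   0.25  0.250    0.4
res$correlations
#>   clone_id estimate  p.value     n method
#> 1 clone1      0.997 1.72e-41    38 pearson/identity
#> 2 clone2      0.999 6.68e-45    33 pearson/identity
#> 3 clone3      0.995 6.09e-34    34 pearson/identity
#> 4 clone4      0.998 2.61e-55    45 pearson/identity
```

Per-clone probability estimates scatter around the generative values
(0.43, 0.25) with binomial noise at n = 60, and each clone's rearrangement
repertoire tracks its ncRNA allelic ratios tightly at the default coupling.
`autoplot(res$ratio_matrix)` draws the clone-by-segment heatmap;
`autoplot(res$pca)` shows replicate pairs coinciding while clones separate.

A thin command-line wrapper is installed at `inst/cli/allelochoice.R`
(subcommands `simulate`, `call`, `model fit`, `model predict`, `run`).

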