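#' Per-allele activation model parameters
#'
#' The stochastic activation model: each of the `n_potential` activatable
#' segments turns on independently on the B6 allele with probability `p_b6`
#' and on the Cast allele with probability `p_cast`; the remaining
#' `n_total - n_potential` functional segments never activate. The reference
#' conditions estimated from clonal pre-B-cell data are
#' `activation_params(0.43, 0.25, 60, 96)`.
#'
#' @param p_b6,p_cast Activation probability per potential segment on each
#'   allele, in `[0, 1]`.
#' @param n_potential Number of activatable segments.
#' @param n_total Total number of functional segments
#'   (`n_potential <= n_total`).
#' @return An object of class `activation_params`.
#' @examples
#' activation_params(0.43, 0.25, 60, 96)
#' @export
activation_params <- function(p_b6, p_cast, n_potential = 60L, n_total = 96L) {
  stopifnot(length(p_b6) == 1, length(p_cast) == 1)
  if (!is.numeric(p_b6) || p_b6 < 0 || p_b6 > 1 ||
      !is.numeric(p_cast) || p_cast < 0 || p_cast > 1) {
    abort("Activation probabilities must lie in [0, 1].")
  }
  if (n_potential < 0 || n_total < 1 || n_potential > n_total) {
    abort("Need 0 <= n_potential <= n_total.")
  }
  structure(
    list(p_b6 = p_b6, p_cast = p_cast,
         n_potential = as.integer(n_potential),
         n_total = as.integer(n_total)),
    class = "activation_params"
  )
}

#' @export
print.activation_params <- function(x, ...) {
  cat("Activation model parameters\n")
  cat(sprintf("  p_b6 = %.3f, p_cast = %.3f\n", x$p_b6, x$p_cast))
  cat(sprintf("  activatable segments: %d of %d functional\n",
              x$n_potential, x$n_total))
  invisible(x)
}

#' Negative-binomial count-noise parameters
#'
#' Sequencing counts for a segment-allele are drawn from a negative binomial
#' (Gamma-Poisson) with mean `mu_active` when the allele is active and
#' `mu_leak` when it is inactive. Leakage defaults to 1% of the active mean:
#' inactive alleles are lowly covered rather than exactly silent. The
#' `dispersion` parameter follows the usual sequencing convention
#' `Var = mu + dispersion * mu^2` (`size = 1/dispersion` in [stats::rnbinom]);
#' `dispersion -> 0` recovers Poisson noise.
#'
#' @param mu_active Mean read count of an active allele per replicate.
#' @param mu_leak Mean read count of an inactive allele (`< mu_active`).
#' @param dispersion Overdispersion (> 0).
#' @param n_replicates Biological replicates resampled from the same clone
#'   state.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(mu_active = 100, mu_leak = mu_active / 100,
                         dispersion = 0.05, n_replicates = 2L) {
  if (!(mu_active > mu_leak) || mu_leak < 0) {
    abort("Need mu_active > mu_leak >= 0.")
  }
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  structure(
    list(mu_active = mu_active, mu_leak = mu_leak,
         dispersion = dispersion, n_replicates = as.integer(n_replicates)),
    class = "noise_params"
  )
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf(
    "NB count noise: mu_active = %g, mu_leak = %g, dispersion = %g, %d replicate(s)\n",
    x$mu_active, x$mu_leak, x$dispersion, x$n_replicates))
  invisible(x)
}
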