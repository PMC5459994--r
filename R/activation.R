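#' Analytic category probabilities of the activation model
#'
#' Under independent per-allele Bernoulli activation, a potential segment is
#' biallelic with probability `p_b6 * p_cast`, mono-B6 with
#' `p_b6 * (1 - p_cast)`, mono-Cast with `(1 - p_b6) * p_cast` and silent
#' with `(1 - p_b6) * (1 - p_cast)`. The marginal view over all functional
#' segments scales the three active categories by
#' `n_potential / n_total` (non-potential segments are always silent).
#'
#' @param params [activation_params()].
#' @return A tibble `category`, `prob_potential`, `prob_marginal`; both
#'   probability columns sum to 1.
#' @examples
#' category_probs(activation_params(0.43, 0.25, 60, 96))
#' @export
category_probs <- function(params) {
  stopifnot(inherits(params, "activation_params"))
  b <- unname(params$p_b6); c <- unname(params$p_cast)
  pp <- c(silent = (1 - b) * (1 - c),
          mono_b6 = b * (1 - c),
          mono_cast = (1 - b) * c,
          biallelic = b * c)
  f <- params$n_potential / params$n_total
  pm <- pp * f
  pm["silent"] <- 1 - sum(pm[c("mono_b6", "mono_cast", "biallelic")])
  tibble::tibble(
    category = names(pp),
    prob_potential = unname(pp),
    prob_marginal = unname(pm)
  )
}

#' Expected fraction of segments active on at least one allele
#'
#' The model's headline prediction: with activation probabilities 0.43 (B6)
#' and 0.25 (Cast) over 60 activatable of 96 functional segments, the
#' expected fraction of all functional segments active on one or both
#' alleles is `(1 - (1-0.43)(1-0.25)) * 60/96 = 0.3578` — i.e. only about a
#' third of the V segments are activated in any one clone.
#'
#' @param params [activation_params()].
#' @return A single number in `[0, n_potential/n_total]`.
#' @examples
#' expected_active_fraction(activation_params(0.43, 0.25, 60, 96))
#' @export
expected_active_fraction <- function(params) {
  stopifnot(inherits(params, "activation_params"))
  (1 - (1 - params$p_b6) * (1 - params$p_cast)) *
    params$n_potential / params$n_total
}

#' Maximum-likelihood fit of per-allele activation probabilities
#'
#' From category counts tallied over a clone's potential segments
#' (see [clone_categories()] or [tally_categories()]), the MLEs are closed
#' form: `p_b6 = (mono_b6 + biallelic) / n_potential` and
#' `p_cast = (mono_cast + biallelic) / n_potential`, because each allele's
#' activations are independent Bernoulli draws. Binomial (Wald) standard
#' errors are attached.
#'
#' @param counts Category counts: a tibble `category`, `n` or a named
#'   numeric vector with names silent, mono_b6, mono_cast, biallelic.
#' @param n_potential Number of potential segments tallied; defaults to the
#'   sum of the counts.
#' @return An object of class `activation_fit` with elements `p_b6`,
#'   `p_cast`, `se_b6`, `se_cast`, `counts`, `n_potential`, `loglik`.
#'   Supports [tidy()], [glance()] and `print()`.
#' @examples
#' cc <- c(silent = 26, mono_b6 = 19, mono_cast = 8, biallelic = 7)
#' fit_activation(cc) # p_b6 ~ 0.433, p_cast = 0.25
#' @export
fit_activation <- function(counts, n_potential = NULL) {
  cc <- as_category_counts(counts)
  n <- n_potential %||% sum(cc)
  if (sum(cc) > n) abort("Category counts exceed `n_potential`.")
  p_b6 <- unname((cc[["mono_b6"]] + cc[["biallelic"]]) / n)
  p_cast <- unname((cc[["mono_cast"]] + cc[["biallelic"]]) / n)
  probs <- category_probs(activation_params(p_b6, p_cast, n, n))$prob_potential
  ll <- sum(cc[probs > 0] * log(probs[probs > 0])) +
    lfactorial(sum(cc)) - sum(lfactorial(cc))
  structure(
    list(p_b6 = unname(p_b6), p_cast = unname(p_cast),
         se_b6 = unname(sqrt(p_b6 * (1 - p_b6) / n)),
         se_cast = unname(sqrt(p_cast * (1 - p_cast) / n)),
         counts = cc, n_potential = as.integer(n), loglik = unname(ll)),
    class = "activation_fit"
  )
}

as_category_counts <- function(counts) {
  cats <- c("silent", "mono_b6", "mono_cast", "biallelic")
  if (is.data.frame(counts)) {
    stopifnot(all(c("category", "n") %in% names(counts)))
    counts <- setNames(counts$n, counts$category)
  }
  if (is.null(names(counts)) || !all(cats %in% names(counts))) {
    abort("Counts must be named silent, mono_b6, mono_cast, biallelic.")
  }
  cc <- counts[cats]
  if (any(cc < 0) || any(cc != round(cc))) {
    abort("Category counts must be nonnegative integers.")
  }
  cc
}

#' @export
print.activation_fit <- function(x, ...) {
  cat("Per-allele activation model fit\n")
  cat(sprintf("  p_b6  = %.4f (SE %.4f)\n", x$p_b6, x$se_b6))
  cat(sprintf("  p_cast = %.4f (SE %.4f)\n", x$p_cast, x$se_cast))
  cat(sprintf("  potential segments: %d; log-likelihood %.2f\n",
              x$n_potential, x$loglik))
  invisible(x)
}

#' @export
tidy.activation_fit <- function(x, conf.level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = c("p_b6", "p_cast"),
    estimate = c(x$p_b6, x$p_cast),
    std.error = c(x$se_b6, x$se_cast),
    conf.low = pmax(0, estimate - z * std.error),
    conf.high = pmin(1, estimate + z * std.error)
  )
}

#' @export
glance.activation_fit <- function(x, ...) {
  tibble::tibble(
    p_b6 = x$p_b6, p_cast = x$p_cast,
    n_potential = x$n_potential,
    logLik = x$loglik,
    expected_active_fraction = expected_active_fraction(
      activation_params(x$p_b6, x$p_cast, x$n_potential, x$n_potential))
  )
}

#' Goodness of fit of observed categories to the activation model
#'
#' Pearson chi-square of observed category counts (over potential segments)
#' against the model's analytic probabilities. Degrees of freedom are
#' `4 - 1 - n_fitted`; set `n_fitted = 2` when the parameters were estimated
#' from the same counts. When any expected count falls below 1 the
#' chi-square approximation is abandoned for an exact multinomial test
#' (summing the probability of every outcome no more likely than the
#' observed one).
#'
#' @param observed Category counts (tibble or named vector, as in
#'   [fit_activation()]).
#' @param params [activation_params()] to test against.
#' @param n_fitted Number of parameters estimated from `observed` (0 when
#'   testing externally given probabilities).
#' @return An `htest`-like list: `statistic`, `parameter` (df), `p.value`,
#'   `method`, `observed`, `expected`.
#' @export
goodness_of_fit <- function(observed, params, n_fitted = 0) {
  stopifnot(inherits(params, "activation_params"))
  cc <- as_category_counts(observed)
  n <- sum(cc)
  if (n < 1) abort("Observed counts sum to zero.")
  probs <- setNames(category_probs(params)$prob_potential,
                    c("silent", "mono_b6", "mono_cast", "biallelic"))
  expected <- probs * n
  zero_bad <- expected == 0 & cc > 0
  if (any(expected < 1) || any(zero_bad)) {
    p <- exact_multinomial_p(cc, probs)
    out <- list(statistic = NA_real_, parameter = NA_real_, p.value = p,
                method = "Exact multinomial goodness-of-fit",
                observed = cc, expected = expected)
  } else {
    stat <- sum((cc - expected)^2 / expected)
    df <- length(cc) - 1 - n_fitted
    out <- list(statistic = stat, parameter = df,
                p.value = pchisq(stat, df, lower.tail = FALSE),
                method = "Pearson chi-square goodness-of-fit",
                observed = cc, expected = expected)
  }
  class(out) <- "gof_test"
  out
}

#' @export
print.gof_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) {
    cat(sprintf("  X-squared = %.4f, df = %g, p = %.4g\n",
                x$statistic, x$parameter, x$p.value))
  } else {
    cat(sprintf("  p = %.4g (exact)\n", x$p.value))
  }
  invisible(x)
}

# Exact multinomial test by full enumeration of outcomes (4 categories);
# feasible for n up to a few hundred.
exact_multinomial_p <- function(cc, probs) {
  n <- sum(cc)
  if (n > 300) abort("Exact multinomial test limited to n <= 300.")
  g <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
  g <- g[g$a + g$b + g$c <= n, ]
  g$d <- n - g$a - g$b - g$c
  m <- as.matrix(g)
  lp <- lfactorial(n) - rowSums(lfactorial(m))
  for (j in 1:4) {
    col <- m[, j]
    lp <- lp + ifelse(col == 0, 0, col * log(probs[j]))
  }
  lp[apply(m, 1, function(r) any(r > 0 & probs == 0))] <- -Inf
  lobs <- lfactorial(n) - sum(lfactorial(cc)) +
    sum(ifelse(cc == 0, 0, cc * log(probs)))
  sum(exp(lp[lp <= lobs + 1e-10]))
}

#' Profile likelihood over the unknown number of activatable segments
#'
#' When the size of the potential set is not assumed, each candidate value
#' `m` implies closed-form probability estimates and a multinomial
#' log-likelihood for the observed categories tallied over all `n_total`
#' functional segments (silent then includes every non-potential segment).
#'
#' @param observed Category counts over all `n_total` segments.
#' @param n_total Total functional segments.
#' @return A tibble `n_potential`, `p_b6`, `p_cast`, `loglik`, ordered by
#'   candidate; the maximum-likelihood row is flagged in `best`.
#' @export
profile_n_potential <- function(observed, n_total) {
  cc <- as_category_counts(observed)
  if (sum(cc) != n_total) {
    abort("Counts over all segments must sum to `n_total`.")
  }
  n_active <- sum(cc[c("mono_b6", "mono_cast", "biallelic")])
  lo <- max(n_active, 1)
  grid <- purrr::map(lo:n_total, function(m) {
    p_b6 <- min(1, (cc[["mono_b6"]] + cc[["biallelic"]]) / m)
    p_cast <- min(1, (cc[["mono_cast"]] + cc[["biallelic"]]) / m)
    pr <- category_probs(activation_params(p_b6, p_cast, m, n_total))
    probs <- setNames(pr$prob_marginal, pr$category)
    ll <- if (any(probs == 0 & cc > 0)) -Inf else
      sum(cc[probs > 0] * log(probs[probs > 0]))
    tibble::tibble(n_potential = m, p_b6 = p_b6, p_cast = p_cast, loglik = ll)
  })
  out <- dplyr::bind_rows(grid)
  out$best <- out$loglik == max(out$loglik)
  out
}
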