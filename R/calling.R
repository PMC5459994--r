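#' Exact two-sided binomial p-value for allelic balance
#'
#' Tests the null hypothesis that a feature's reads come equally from both
#' alleles (success probability 0.5). The two-sided p-value doubles the
#' smaller tail, includes the observed outcome's point mass, and is capped
#' at 1 — under the symmetric null this coincides with the
#' minimum-likelihood definition used by [stats::binom.test].
#'
#' @param b6,cast Nonnegative counts (vectorized); `b6 + cast >= 1` for a
#'   defined p-value, otherwise `NA`.
#' @return Numeric vector of p-values in `(0, 1]`, symmetric in its
#'   arguments.
#' @examples
#' binomial_p(10, 10)  # 1: balanced
#' binomial_p(15, 5)   # ~0.0414
#' binomial_p(40, 0)   # ~1.8e-12
#' @export
binomial_p <- function(b6, cast) {
  if (any(b6 < 0, na.rm = TRUE) || any(cast < 0, na.rm = TRUE)) {
    abort("Counts must be nonnegative.")
  }
  n <- b6 + cast
  k <- pmin(b6, cast)
  out <- pmin(1, 2 * pbinom(k, n, 0.5))
  out[n < 1] <- NA_real_
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a family of p-values
#' (delegates to [stats::p.adjust]); `q >= p` elementwise and the ranking
#' of the sorted values is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return Adjusted q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5)) # 0.04 0.04 0.04 0.50
#' @export
bh_fdr <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Call monoallelic features from one allele count table
#'
#' Applies the monoallelic rule to each feature of a single library:
#' a feature is `mono_b6` (or `mono_cast`) when its FDR-corrected exact
#' binomial p-value is below `alpha` AND the favoured allele has at least
#' `fold_min` times the reads of the other; features below `min_depth` total
#' reads are `insufficient`; everything else is `biallelic`. The FDR family
#' is the set of depth-sufficient features in the table.
#'
#' @param counts Tibble with columns `feature_id`, `b6`, `cast` (a `sample`
#'   column, if present, must contain a single sample — use
#'   [call_with_replicates()] for several).
#' @param alpha FDR significance threshold (default 0.05).
#' @param fold_min Minimum fold difference between alleles (default 2).
#' @param min_depth Minimum allele-informative depth (default 20).
#' @return A tibble `feature_id`, `b6`, `cast`, `depth`, `ratio`, `fold`,
#'   `p_value`, `q_value`, `category` with
#'   `category in {mono_b6, mono_cast, biallelic, insufficient}`.
#' @export
call_features <- function(counts, alpha = 0.05, fold_min = 2, min_depth = 20) {
  check_counts(counts, require_sample = FALSE)
  if ("sample" %in% names(counts) && dplyr::n_distinct(counts$sample) > 1) {
    abort("`counts` holds several samples; use call_with_replicates().")
  }
  res <- counts |>
    dplyr::mutate(
      depth = .data$b6 + .data$cast,
      ratio = allelic_ratio(.data$b6, .data$cast, min_depth = min_depth),
      fold = pmax(.data$b6, .data$cast) / pmin(.data$b6, .data$cast),
      p_value = binomial_p(.data$b6, .data$cast)
    )
  tested <- res$depth >= min_depth
  res$q_value <- NA_real_
  res$q_value[tested] <- bh_fdr(res$p_value[tested])
  res$category <- dplyr::case_when(
    !tested ~ "insufficient",
    res$q_value < alpha & res$b6 >= fold_min * res$cast ~ "mono_b6",
    res$q_value < alpha & res$cast >= fold_min * res$b6 ~ "mono_cast",
    TRUE ~ "biallelic"
  )
  dplyr::select(res, "feature_id", "b6", "cast", "depth", "ratio", "fold",
                "p_value", "q_value", "category")
}

#' Call monoallelic features with replicate consistency
#'
#' The replicate-consistent rule used for accessibility peaks: a feature is
#' called mono-B6 (mono-Cast) only when every biological replicate
#' independently satisfies the full monoallelic rule (FDR-significant within
#' that replicate AND at least `fold_min`-fold skewed) on the same allele.
#' Any replicate under the depth threshold makes the feature
#' `insufficient`; otherwise inconsistent or non-significant features are
#' `biallelic`. Pooled-count statistics (p, q, ratio, fold) are reported for
#' the record.
#'
#' @param counts Long allele count table (`feature_id`, `sample`, `b6`,
#'   `cast`) with at least two samples covering the same feature set.
#' @inheritParams call_features
#' @return A tibble `feature_id`, `b6`, `cast`, `depth`, `ratio`, `fold`,
#'   `p_value`, `q_value` (all from pooled counts), `category`,
#'   `n_replicates`.
#' @export
call_with_replicates <- function(counts, alpha = 0.05, fold_min = 2,
                                 min_depth = 20) {
  check_counts(counts, require_sample = TRUE)
  samples <- unique(counts$sample)
  if (length(samples) < 2) abort("Need at least two replicate samples.")
  sets <- counts |>
    dplyr::summarise(k = dplyr::n(), .by = "feature_id")
  if (any(sets$k != length(samples)) ||
      nrow(counts) != nrow(sets) * length(samples)) {
    abort("All replicates must cover the same feature set exactly once.")
  }
  per_rep <- counts |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_map(function(tbl, key) {
      call_features(tbl, alpha = alpha, fold_min = fold_min,
                    min_depth = min_depth) |>
        dplyr::select("feature_id", "category")
    }) |>
    dplyr::bind_rows()
  consensus <- per_rep |>
    dplyr::summarise(
      category = dplyr::case_when(
        any(.data$category == "insufficient") ~ "insufficient",
        all(.data$category == "mono_b6") ~ "mono_b6",
        all(.data$category == "mono_cast") ~ "mono_cast",
        TRUE ~ "biallelic"
      )[1],
      .by = "feature_id"
    )
  pooled <- counts |>
    dplyr::summarise(b6 = sum(.data$b6), cast = sum(.data$cast),
                     .by = "feature_id") |>
    call_features(alpha = alpha, fold_min = fold_min,
                  min_depth = min_depth) |>
    dplyr::select(-"category")
  pooled |>
    dplyr::inner_join(consensus, by = "feature_id") |>
    dplyr::mutate(n_replicates = length(samples))
}

#' Tally activation categories from monoallelic calls
#'
#' Maps per-segment monoallelic calls to the activation-model categories
#' over the locus' potential segments: mono and biallelic calls keep their
#' category and `insufficient` (no appreciable signal on either allele,
#' i.e. leak-level coverage) counts as silent.
#'
#' @param calls Call tibble (from [call_features()] or
#'   [call_with_replicates()]).
#' @param locus Segment tibble carrying a `potential` column; only potential
#'   segments are tallied.
#' @return A tibble `category`, `n` as in [clone_categories()].
#' @export
tally_categories <- function(calls, locus) {
  stopifnot(all(c("feature_id", "category") %in% names(calls)),
            "potential" %in% names(locus))
  keep <- calls[calls$feature_id %in% locus$id[locus$potential], ]
  tibble::tibble(
    category = c("silent", "mono_b6", "mono_cast", "biallelic"),
    n = c(sum(keep$category == "insufficient"),
          sum(keep$category == "mono_b6"),
          sum(keep$category == "mono_cast"),
          sum(keep$category == "biallelic"))
  )
}

check_counts <- function(counts, require_sample = FALSE) {
  need <- c("feature_id", "b6", "cast")
  if (require_sample) need <- c("feature_id", "sample", "b6", "cast")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    abort(paste0("Count table must have columns ",
                 paste(need, collapse = ", "), "."))
  }
  if (any(counts$b6 < 0) || any(counts$cast < 0)) {
    abort("Counts must be nonnegative.")
  }
  invisible(counts)
}
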