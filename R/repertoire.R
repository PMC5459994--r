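#' Normalize a rearrangement count table
#'
#' Converts raw per-V, per-allele rearranged-fragment counts into percent
#' contributions: `percent_library` normalizes to the total mapped
#' rearranged fragments of the library (so contributions are comparable
#' between libraries) and `percent` normalizes within each allele (each
#' allele's column sums to 100 when the allele has any events).
#'
#' @param counts Tibble `v_id`, `allele` (`"B6"`/`"Cast"`), `count`
#'   (nonnegative).
#' @return A tibble `v_id`, `allele`, `count`, `percent`,
#'   `percent_library`.
#' @export
normalize_repertoire <- function(counts) {
  need <- c("v_id", "allele", "count")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    abort("Repertoire counts need columns v_id, allele, count.")
  }
  if (any(counts$count < 0)) abort("Counts must be nonnegative.")
  if (!all(counts$allele %in% c("B6", "Cast"))) {
    abort("`allele` must be 'B6' or 'Cast'.")
  }
  total <- sum(counts$count)
  if (total <= 0) abort("Total mapped rearranged fragments is zero.")
  counts |>
    dplyr::mutate(
      percent = if (sum(.data$count) > 0) {
        100 * .data$count / sum(.data$count)
      } else {
        rep(NA_real_, dplyr::n())
      },
      .by = "allele"
    ) |>
    dplyr::mutate(percent_library = 100 * .data$count / total)
}

#' Per-V allelic ratio of rearrangement events
#'
#' Shares the ratio and missing-data conventions of [allelic_ratio()]:
#' B6 / (B6 + Cast) rearranged fragments per V segment, `NA` under
#' `min_depth` total events (including Vs absent from both alleles).
#'
#' @param rep_table Repertoire tibble (`v_id`, `allele`, `count`), e.g. from
#'   [normalize_repertoire()] or [simulate_repertoire()].
#' @param min_depth Minimum combined events for a defined ratio.
#' @return A tibble `v_id`, `b6`, `cast`, `ratio`.
#' @export
rearrangement_allelic_ratio <- function(rep_table, min_depth = 20) {
  stopifnot(all(c("v_id", "allele", "count") %in% names(rep_table)))
  wide <- rep_table |>
    dplyr::select("v_id", "allele", "count") |>
    tidyr::pivot_wider(names_from = "allele", values_from = "count",
                       values_fill = 0L)
  for (al in c("B6", "Cast")) if (!al %in% names(wide)) wide[[al]] <- 0L
  tibble::tibble(
    v_id = wide$v_id,
    b6 = wide$B6,
    cast = wide$Cast,
    ratio = allelic_ratio(wide$B6, wide$Cast, min_depth = min_depth)
  )
}

#' Correlate ncRNA and rearrangement allelic ratios
#'
#' Pearson correlation between the allelic ratio of germline (ncRNA)
#' transcription before differentiation and the allelic ratio of
#' rearrangement events after differentiation, over V segments with defined
#' ratios in both — the quantitative link between V-segment "opening" and
#' subsequent recombination.
#'
#' @param ncrna_ratios,rearr_ratios Tibbles with columns `v_id` and `ratio`
#'   (as produced by [rearrangement_allelic_ratio()], or any table of
#'   per-V ratios).
#' @param transform `"identity"` (default) correlates the linear ratios;
#'   `"log"` correlates `log(ratio + eps)`.
#' @return A one-row tibble `estimate` (Pearson r), `p.value`, `n`,
#'   `method`.
#' @export
ncrna_repertoire_correlation <- function(ncrna_ratios, rearr_ratios,
                                         transform = c("identity", "log")) {
  transform <- match.arg(transform)
  j <- dplyr::inner_join(
    dplyr::select(ncrna_ratios, "v_id", x = "ratio"),
    dplyr::select(rearr_ratios, "v_id", y = "ratio"),
    by = "v_id"
  ) |>
    dplyr::filter(!is.na(.data$x), !is.na(.data$y))
  if (nrow(j) < 3) abort("Need at least 3 shared V segments with ratios.")
  if (transform == "log") {
    eps <- 1e-3
    j$x <- log(j$x + eps)
    j$y <- log(j$y + eps)
  }
  ct <- cor.test(j$x, j$y, method = "pearson")
  tibble::tibble(
    estimate = unname(ct$estimate),
    p.value = ct$p.value,
    n = nrow(j),
    method = paste0("pearson/", transform)
  )
}

#' Fraction of V segments skewed toward one allele
#'
#' The fraction of ratio-defined V segments whose allelic ratio exceeds
#' `threshold` (B6-skewed) or falls below `1 - threshold` (Cast-skewed);
#' with the default 0.8 this is the ">80% skewed" summary. Boundaries are
#' strict: a ratio exactly at the threshold does not count as skewed.
#'
#' @param ratios Numeric vector of allelic ratios (`NA` dropped).
#' @param threshold Skew threshold in `(0.5, 1]`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' skew_fraction(c(0.95, 0.05, 0.5, 0.6)) # 0.5
#' @export
skew_fraction <- function(ratios, threshold = 0.8) {
  r <- ratios[!is.na(ratios)]
  if (length(r) == 0) abort("No non-missing ratios.")
  if (threshold <= 0.5 || threshold > 1) {
    abort("`threshold` must be in (0.5, 1].")
  }
  mean(r > threshold | r < 1 - threshold)
}

#' Early-allele event fraction along an induction time course
#'
#' For each timepoint of a rearrangement time course, the fraction of all
#' rearranged fragments carried by the early-replicating allele. Shortly
#' after induction nearly all events sit on the early allele; as the time
#' course proceeds the second allele engages and the fraction decays
#' toward 0.5.
#'
#' @param time_course Tibble `time`, `v_id`, `allele`, `count` (stacked
#'   repertoire tables with a `time` column; >= 2 timepoints).
#' @param early_allele `"B6"` or `"Cast"`.
#' @return A tibble `time`, `early_fraction`, `total`, ordered by time.
#' @export
kinetics_summary <- function(time_course, early_allele = c("B6", "Cast")) {
  early_allele <- match.arg(early_allele)
  need <- c("time", "allele", "count")
  if (!is.data.frame(time_course) || !all(need %in% names(time_course))) {
    abort("Time course needs columns time, allele, count.")
  }
  if (!all(c("B6", "Cast") %in% time_course$allele)) {
    abort("Time course must contain both allele columns (B6 and Cast).")
  }
  if (dplyr::n_distinct(time_course$time) < 2) {
    abort("Need at least two timepoints.")
  }
  time_course |>
    dplyr::summarise(
      early_fraction = sum(.data$count[.data$allele == early_allele]) /
        sum(.data$count),
      total = sum(.data$count),
      .by = "time"
    ) |>
    dplyr::arrange(.data$time)
}
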