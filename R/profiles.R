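#' Build an allelic-ratio matrix across samples
#'
#' Combines per-sample allele count tables into a features-by-samples
#' matrix of allelic ratios on the 0 (100% Cast) to 1 (100% B6) scale.
#' Entries under the depth threshold are `NA` (rendered white in the
#' heatmap); features that are `NA` in every sample are dropped with a
#' message.
#'
#' @param counts Long allele count table (`feature_id`, `sample`, `b6`,
#'   `cast`), one row per feature-sample pair.
#' @param min_depth Minimum allele-informative depth for a defined ratio
#'   (default 10, the heatmap-inclusion threshold).
#' @return A `ratio_matrix`: tibble with `feature_id` and one numeric
#'   column per sample, values in `[0, 1]` or `NA`.
#' @export
build_ratio_matrix <- function(counts, min_depth = 10) {
  check_counts(counts, require_sample = TRUE)
  if (anyDuplicated(counts[c("feature_id", "sample")])) {
    abort("Duplicate (feature_id, sample) rows in `counts`.")
  }
  wide <- counts |>
    dplyr::mutate(ratio = allelic_ratio(.data$b6, .data$cast,
                                        min_depth = min_depth)) |>
    dplyr::select("feature_id", "sample", "ratio") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "ratio")
  all_na <- rowSums(!is.na(as.matrix(wide[-1]))) == 0
  if (any(all_na)) {
    inform(sprintf("Dropping %d feature(s) with no depth-sufficient sample.",
                   sum(all_na)))
    wide <- wide[!all_na, ]
  }
  structure(wide, class = c("ratio_matrix", class(tibble::tibble())),
            min_depth = min_depth)
}

ratio_as_matrix <- function(rm) {
  m <- as.matrix(as.data.frame(rm)[-1])
  rownames(m) <- rm$feature_id
  m
}

filter_na_rows <- function(m, na_policy = c("impute", "complete")) {
  na_policy <- match.arg(na_policy)
  if (na_policy == "complete") {
    keep <- complete.cases(m)
    if (!all(keep)) {
      inform(sprintf("Dropping %d feature row(s) with missing ratios.",
                     sum(!keep)))
    }
    m <- m[keep, , drop = FALSE]
  } else {
    mu <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- mu[idx[, 1]]
    m <- m[!is.na(rowMeans(m)), , drop = FALSE]
  }
  m
}

#' Principal-component profile of allelic ratios
#'
#' Column-centered PCA of samples in allelic-ratio space, the summary used
#' to show that replicate libraries of a clone sit together while clones sit
#' apart and a many-clone pool sits near the centroid. Deterministic sign
#' convention: within each component the loading of largest magnitude is
#' made positive.
#'
#' @param rm A `ratio_matrix` from [build_ratio_matrix()].
#' @param na_policy `"impute"` (default; replace `NA` by the feature's mean
#'   ratio across defined samples, so segments silent in only some clones —
#'   the majority, and the informative ones — are retained) or
#'   `"complete"` (drop feature rows with any `NA`, keeping only segments
#'   covered in every sample).
#' @return An `allelic_pca` object: `scores` (tibble `sample`, `PC1`, ...),
#'   `loadings`, `sdev`, `var_explained`, `n_features`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
pca_profiles <- function(rm, na_policy = c("impute", "complete")) {
  m <- ratio_as_matrix(rm)
  if (ncol(m) < 2) abort("PCA needs at least two samples.")
  m <- filter_na_rows(m, na_policy)
  if (nrow(m) < 1) abort("No feature rows left after NA filtering.")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  # fixed sign convention for reproducibility
  for (j in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  structure(
    list(
      scores = dplyr::bind_cols(tibble::tibble(sample = rownames(pc$x)),
                                tibble::as_tibble(pc$x)),
      loadings = pc$rotation,
      sdev = pc$sdev,
      var_explained = ve,
      n_features = nrow(m)
    ),
    class = "allelic_pca"
  )
}

#' @export
print.allelic_pca <- function(x, ...) {
  cat(sprintf("Allelic-ratio PCA: %d samples, %d features\n",
              nrow(x$scores), x$n_features))
  k <- min(3, length(x$var_explained))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_explained[1:k]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.allelic_pca <- function(x, ...) x$scores

#' @export
glance.allelic_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_features = x$n_features,
    var_pc1 = x$var_explained[1],
    var_pc2 = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_
  )
}

#' @rdname pca_profiles
#' @param object An `allelic_pca` object.
#' @param ... Unused.
#' @export
autoplot.allelic_pca <- function(object, ...) {
  sc <- object$scores
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                   label = .data$sample)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      title = "Allelic-ratio principal components"
    ) +
    ggplot2::theme_minimal()
}

#' Hierarchical clustering of allelic-ratio profiles
#'
#' Agglomerative clustering of samples by their allelic-ratio vectors
#' (Euclidean distance, average linkage by default). On well-separated
#' clones, replicate libraries merge before any cross-clone merge.
#'
#' @inheritParams pca_profiles
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return An [stats::hclust] tree over samples.
#' @export
cluster_profiles <- function(rm, distance = "euclidean", linkage = "average",
                             na_policy = c("impute", "complete")) {
  m <- ratio_as_matrix(rm)
  if (ncol(m) < 2) abort("Clustering needs at least two samples.")
  if (any(colSums(!is.na(m)) == 0)) {
    abort("Sample column(s) with no defined ratios.")
  }
  m <- filter_na_rows(m, na_policy)
  if (nrow(m) < 1) abort("No feature rows left after NA filtering.")
  hclust(dist(t(m), method = distance), method = linkage)
}

#' Heatmap of an allelic-ratio matrix
#'
#' Linear red-to-blue scale from 0 (100% Cast, red) to 1 (100% B6, blue);
#' entries without sufficient depth are white.
#'
#' @param object A `ratio_matrix`.
#' @param ... Unused.
#' @export
autoplot.ratio_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"feature_id",
                              names_to = "sample", values_to = "ratio")
  long$feature_id <- factor(long$feature_id, levels = rev(object$feature_id))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$feature_id,
                                     fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "red", high = "blue", limits = c(0, 1), na.value = "white",
      name = "B6 ratio"
    ) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Allelic ratio (0 = Cast, 1 = B6; white = low depth)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Concordance between accessibility and expression calls
#'
#' Cross-tabulates two monoallelic call sets (e.g. promoter accessibility
#' peaks vs. gene expression) over shared features in the three informative
#' categories and tests independence with Pearson's chi-square — the
#' analysis behind the observation that open chromatin and transcription
#' agree on the allele level.
#'
#' @param calls_a,calls_b Call tibbles (`feature_id`, `category`); features
#'   are matched by `feature_id` and `insufficient` calls are excluded.
#' @return A list of class `concordance`: `table` (3x3), `statistic`, `df`,
#'   `p.value`, `n`, `concordance` (diagonal fraction).
#' @export
promoter_concordance <- function(calls_a, calls_b) {
  cats <- c("mono_b6", "mono_cast", "biallelic")
  j <- dplyr::inner_join(
    dplyr::select(calls_a, "feature_id", a = "category"),
    dplyr::select(calls_b, "feature_id", b = "category"),
    by = "feature_id"
  ) |>
    dplyr::filter(.data$a %in% cats, .data$b %in% cats)
  if (nrow(j) == 0) abort("No shared informative features.")
  tab <- table(factor(j$a, cats), factor(j$b, cats))
  ct <- suppressWarnings(chisq.test(tab))
  structure(
    list(table = tab, statistic = unname(ct$statistic),
         df = unname(ct$parameter), p.value = ct$p.value, n = nrow(j),
         concordance = sum(diag(tab)) / nrow(j)),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Allelic call concordance over %d features\n", x$n))
  print(x$table)
  cat(sprintf("  on-diagonal %.1f%%; chi-square %.2f (df %g), p = %.3g\n",
              100 * x$concordance, x$statistic, x$df, x$p.value))
  invisible(x)
}
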