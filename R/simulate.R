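#' Simulate the activation state of one hybrid clone
#'
#' Draws, for every potential segment of the locus, independent Bernoulli
#' activation on the B6 and Cast alleles. Segments outside the potential set
#' stay inactive on both alleles. The activation state is the clone's stable
#' epigenetic identity: replicate libraries simulated from the same clone
#' share it unchanged.
#'
#' @param locus Segment tibble from [make_locus()] (must carry `potential`).
#' @param params [activation_params()].
#' @param seed Integer seed.
#' @param clone_id Label for the clone.
#' @return A tibble `clone_id`, `segment_id`, `potential`, `b6_active`,
#'   `cast_active`.
#' @examples
#' locus <- make_locus(10, 6, seed = 1)
#' simulate_clone(locus, activation_params(0.43, 0.25, 6, 10), seed = 2)
#' @export
simulate_clone <- function(locus, params, seed = 1L, clone_id = "clone1") {
  check_locus(locus)
  stopifnot(inherits(params, "activation_params"), "potential" %in% names(locus))
  n <- nrow(locus)
  with_seed(seed, {
    b6 <- locus$potential & (rbinom(n, 1, params$p_b6) == 1)
    cast <- locus$potential & (rbinom(n, 1, params$p_cast) == 1)
    tibble::tibble(
      clone_id = clone_id,
      segment_id = locus$id,
      potential = locus$potential,
      b6_active = b6,
      cast_active = cast
    )
  })
}

#' Simulate allele-resolved counts for a clone
#'
#' For each segment and replicate, draws B6 and Cast read counts from the
#' negative-binomial noise model: mean `mu_active` for an active allele,
#' `mu_leak` for an inactive one. An optional per-segment genetic bias
#' multiplies the Cast-allele mean (constant across clones, emulating fixed
#' sequence-driven skew at particular segments).
#'
#' @param clone Clone state from [simulate_clone()].
#' @param noise [noise_params()].
#' @param bias Optional named numeric vector, segment id -> multiplicative
#'   factor on the Cast mean (e.g. `c(V005 = 0.1)` biases V005 10:1 toward
#'   B6). Unknown ids are an error.
#' @param seed Integer seed.
#' @param sample_prefix Sample names become `<prefix>1 ... <prefix>R`.
#' @return An allele count table: tibble `feature_id`, `sample`, `b6`,
#'   `cast` with nonnegative integer counts.
#' @export
simulate_counts <- function(clone, noise = noise_params(), bias = NULL,
                            seed = 1L, sample_prefix = "rep") {
  stopifnot(inherits(noise, "noise_params"))
  check_clone(clone)
  bias_factor <- rep(1, nrow(clone))
  if (!is.null(bias)) {
    if (is.null(names(bias)) || !all(names(bias) %in% clone$segment_id)) {
      abort("`bias` must be named by segment ids present in the clone.")
    }
    bias_factor[match(names(bias), clone$segment_id)] <- bias
  }
  size <- 1 / noise$dispersion
  mu_b6 <- ifelse(clone$b6_active, noise$mu_active, noise$mu_leak)
  mu_cast <- ifelse(clone$cast_active, noise$mu_active, noise$mu_leak) *
    bias_factor
  n <- nrow(clone)
  with_seed(seed, {
    reps <- purrr::map(seq_len(noise$n_replicates), function(r) {
      tibble::tibble(
        feature_id = clone$segment_id,
        sample = paste0(sample_prefix, r),
        b6 = rnbinom_mu(n, size, mu_b6),
        cast = rnbinom_mu(n, size, mu_cast)
      )
    })
    dplyr::bind_rows(reps)
  })
}

# rnbinom with mu = 0 allowed (degenerate at 0)
rnbinom_mu <- function(n, size, mu) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) out[pos] <- rnbinom(sum(pos), size = size, mu = mu[pos])
  out
}

#' Simulate a pool of clones
#'
#' Sums allele counts over `n_clones` independently simulated clones from the
#' same locus, emulating bulk pre-B cells sorted from bone marrow: a mixture
#' of clones each making its own stochastic allelic choices, so per-segment
#' allelic ratios converge toward the population expectation (balanced when
#' the two alleles have equal activation probability and no genetic bias).
#'
#' Per-clone child seeds are derived with [derive_seed()], so
#' `simulate_pool(n_clones = 1)` reproduces exactly one
#' [simulate_clone()] + [simulate_counts()] run under the same discipline.
#'
#' @inheritParams simulate_counts
#' @param locus Segment tibble from [make_locus()].
#' @param params [activation_params()].
#' @param n_clones Number of clones in the mixture (>= 1).
#' @return An allele count table (`feature_id`, `sample`, `b6`, `cast`) of
#'   summed counts.
#' @export
simulate_pool <- function(locus, params, n_clones, noise = noise_params(),
                          bias = NULL, seed = 1L, sample_prefix = "rep") {
  stopifnot(n_clones >= 1)
  tabs <- purrr::map(seq_len(n_clones), function(k) {
    sk <- derive_seed(seed, k)
    clone <- simulate_clone(locus, params, seed = sk,
                            clone_id = paste0("pool_clone", k))
    simulate_counts(clone, noise, bias = bias,
                    seed = derive_seed(sk, 1, salt = 1),
                    sample_prefix = sample_prefix)
  })
  dplyr::bind_rows(tabs) |>
    dplyr::summarise(b6 = sum(.data$b6), cast = sum(.data$cast),
                     .by = c("feature_id", "sample")) |>
    dplyr::arrange(.data$sample, match(.data$feature_id, locus$id))
}

#' Simulate allele-bearing read pairs for a clone
#'
#' Emits read-pair intervals placed uniformly within each segment's
#' assignment window, on the segment's strand, carrying the parental base at
#' every SNP the pair covers. The number of pairs per (segment, allele)
#' follows the same negative-binomial noise model as [simulate_counts()]
#' (one replicate). Windows containing no SNP trigger a warning; their reads
#' are still emitted but carry no allele information.
#'
#' @inheritParams simulate_counts
#' @param locus Segment tibble from [make_locus()].
#' @param snps SNP table from [make_snps()].
#' @param read_length Span of a read pair in bp.
#' @return A tibble `chrom`, `start`, `end`, `name`, `strand`, `origin`
#'   (ground-truth allele, for validation only) and `snp_obs`
#'   (`"pos:base"` observations, comma-separated; `""` when none).
#' @export
simulate_reads <- function(clone, locus, snps, noise = noise_params(),
                           seed = 1L, read_length = 300L) {
  check_locus(locus)
  check_clone(clone)
  win <- assignment_window(locus)
  no_snp <- vapply(seq_len(nrow(win)), function(i) {
    !any(snps$chrom == win$chrom[i] & snps$pos >= win$window_start[i] &
           snps$pos < win$window_end[i])
  }, logical(1))
  if (any(no_snp)) {
    warn(paste0("Assignment window(s) without SNPs: ",
                paste(win$id[no_snp], collapse = ", "),
                "; their reads cannot be allele-tagged."))
  }
  size <- 1 / noise$dispersion
  with_seed(seed, {
    out <- purrr::map(seq_len(nrow(win)), function(i) {
      st <- clone[match(win$id[i], clone$segment_id), ]
      purrr::map(c("B6", "Cast"), function(allele) {
        active <- if (allele == "B6") st$b6_active else st$cast_active
        mu <- if (active) noise$mu_active else noise$mu_leak
        n_reads <- rnbinom_mu(1, size, mu)
        if (n_reads == 0) return(NULL)
        span <- min(read_length, win$window_end[i] - win$window_start[i])
        rs <- win$window_start[i] +
          sample.int(win$window_end[i] - win$window_start[i] - span + 1,
                     n_reads, replace = TRUE) - 1
        re <- rs + span
        obs <- vapply(seq_len(n_reads), function(j) {
          hit <- snps$chrom == win$chrom[i] & snps$pos >= rs[j] &
            snps$pos < re[j]
          if (!any(hit)) return("")
          base <- if (allele == "B6") snps$b6_base[hit] else snps$cast_base[hit]
          paste(snps$pos[hit], base, sep = ":", collapse = ",")
        }, "")
        tibble::tibble(
          chrom = win$chrom[i], start = rs, end = re,
          name = sprintf("%s_%s_%d", win$id[i], allele, seq_len(n_reads)),
          strand = win$strand[i], origin = allele, snp_obs = obs
        )
      })
    })
    dplyr::bind_rows(purrr::map(out, dplyr::bind_rows))
  })
}

#' Simulate an allelic rearrangement repertoire
#'
#' Draws per-allele V-J rearrangement counts for a clone. V segments are
#' chosen multinomially with weights mixing the clone's germline ncRNA
#' profile (weight `coupling`) with a uniform choice over the allele's
#' active segments (weight `1 - coupling`), so the repertoire tracks
#' non-coding transcription to a tunable degree. Events are split between
#' alleles according to rearrangement kinetics: the early-replicating allele
#' receives a fraction `1 - time_fraction/2` of all events
#' (`time_fraction = 0`: all events on the early allele, the 12 h induction
#' limit; `time_fraction = 1`: both alleles equally engaged).
#'
#' @param clone Clone state from [simulate_clone()].
#' @param ncrna_counts Allele count table for the same clone (germline
#'   ncRNA), e.g. from [simulate_counts()]; replicates are summed.
#' @param coupling Mixing weight in `[0, 1]` between ncRNA-proportional and
#'   uniform-over-active V choice.
#' @param early_allele `"B6"` or `"Cast"`: the early-replicating allele.
#' @param time_fraction Progress of the induction time course in `[0, 1]`.
#' @param depth Total rearranged fragments across both alleles.
#' @param seed Integer seed.
#' @return A repertoire tibble `v_id`, `allele`, `count`, `percent` (within
#'   allele), `percent_library`, as from [normalize_repertoire()]. Alleles
#'   with no active segment yield zero counts and are flagged in the
#'   `empty_alleles` attribute.
#' @export
simulate_repertoire <- function(clone, ncrna_counts, coupling = 0.9,
                                early_allele = c("B6", "Cast"),
                                time_fraction = 1, depth = 1e5, seed = 1L) {
  early_allele <- match.arg(early_allele)
  check_clone(clone)
  if (coupling < 0 || coupling > 1) abort("`coupling` must be in [0, 1].")
  if (time_fraction < 0 || time_fraction > 1) {
    abort("`time_fraction` must be in [0, 1].")
  }
  nc <- ncrna_counts |>
    dplyr::summarise(b6 = sum(.data$b6), cast = sum(.data$cast),
                     .by = "feature_id")
  nc <- nc[match(clone$segment_id, nc$feature_id), ]
  if (anyNA(nc$b6)) abort("`ncrna_counts` must cover every clone segment.")

  early_frac <- 1 - time_fraction / 2
  totals <- c(B6 = NA_real_, Cast = NA_real_)
  totals[early_allele] <- round(depth * early_frac)
  totals[setdiff(c("B6", "Cast"), early_allele)] <-
    depth - totals[early_allele]

  empty <- character(0)
  with_seed(seed, {
    draws <- purrr::map(c("B6", "Cast"), function(allele) {
      active <- if (allele == "B6") clone$b6_active else clone$cast_active
      if (!any(active)) {
        empty <<- c(empty, allele)
        return(tibble::tibble(v_id = clone$segment_id, allele = allele,
                              count = 0L))
      }
      share_raw <- if (allele == "B6") nc$b6 else nc$cast
      share <- if (sum(share_raw) > 0) share_raw / sum(share_raw) else
        rep(1 / length(share_raw), length(share_raw))
      unif <- active / sum(active)
      w <- coupling * share + (1 - coupling) * unif
      cnt <- as.integer(rmultinom(1, totals[allele], prob = w)[, 1])
      tibble::tibble(v_id = clone$segment_id, allele = allele, count = cnt)
    })
    rep_tab <- normalize_repertoire(dplyr::bind_rows(draws))
    attr(rep_tab, "empty_alleles") <- empty
    if (length(empty)) {
      warn(paste0("No active segment on allele(s): ",
                  paste(empty, collapse = ", "),
                  "; their repertoire is empty."))
    }
    rep_tab
  })
}

#' Tally activation categories from a clone's true state
#'
#' Counts, over the potential segments of a simulated clone, how many are
#' silent, mono-B6, mono-Cast or biallelically active — the observable the
#' activation model is fitted to.
#'
#' @param clone Clone state from [simulate_clone()].
#' @return A tibble `category` (silent, mono_b6, mono_cast, biallelic) and
#'   `n`, summing to the number of potential segments.
#' @export
clone_categories <- function(clone) {
  check_clone(clone)
  p <- clone[clone$potential, ]
  tibble::tibble(
    category = c("silent", "mono_b6", "mono_cast", "biallelic"),
    n = c(sum(!p$b6_active & !p$cast_active),
          sum(p$b6_active & !p$cast_active),
          sum(!p$b6_active & p$cast_active),
          sum(p$b6_active & p$cast_active))
  )
}

check_clone <- function(clone) {
  need <- c("segment_id", "potential", "b6_active", "cast_active")
  if (!is.data.frame(clone) || !all(need %in% names(clone))) {
    abort(paste0("`clone` must be a data frame with columns ",
                 paste(need, collapse = ", "), "."))
  }
  bad <- !clone$potential & (clone$b6_active | clone$cast_active)
  if (any(bad)) abort("Non-potential segments cannot be active.")
  invisible(clone)
}
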