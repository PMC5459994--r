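#' Generate a synthetic V-segment locus
#'
#' Lays out `n_total` functional V segments along one chromosome with
#' inter-segment gaps large enough that the strand-aware assignment windows
#' (see [assignment_window()]) of consecutive segments never overlap, and
#' marks a fixed subset of `n_potential` segments as having the potential to
#' be activated. The potential set is a property of the locus: every clone
#' simulated from the same locus shares it, mirroring the model in which only
#' a subset of functional segments (60 of 96 in the reference conditions) can
#' ever be turned on.
#'
#' @param n_total Number of functional V segments (>= 1).
#' @param n_potential Number of segments in the activatable set
#'   (`0 <= n_potential <= n_total`).
#' @param seed Integer seed; the layout and potential set are reproducible.
#' @param chrom Chromosome name used for all segments.
#' @param origin Start coordinate (bp, 0-based) of the first segment.
#' @return A tibble with one row per segment and columns `id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`),
#'   `functional` (all `TRUE`) and `potential` (logical, `n_potential` rows
#'   `TRUE`).
#' @examples
#' locus <- make_locus(96, 60, seed = 1)
#' sum(locus$potential)
#' @export
make_locus <- function(n_total, n_potential, seed = 1L, chrom = "chr6",
                       origin = 3e6) {
  if (!is.numeric(n_total) || length(n_total) != 1 || n_total < 1 ||
      n_total != round(n_total)) {
    abort("`n_total` must be a single positive integer.")
  }
  if (!is.numeric(n_potential) || length(n_potential) != 1 ||
      n_potential < 0 || n_potential > n_total ||
      n_potential != round(n_potential)) {
    abort("`n_potential` must be an integer in [0, n_total].")
  }
  n_total <- as.integer(n_total)
  n_potential <- as.integer(n_potential)
  with_seed(seed, {
    seg_len <- sample(300:600, n_total, replace = TRUE)
    # gaps > 21 kb keep windows disjoint for every strand combination:
    # a window adds at most 10,000 bp on one side and 500 bp on the other
    gap <- sample(21000:26000, n_total, replace = TRUE)
    start <- origin + cumsum(gap) + c(0, cumsum(seg_len[-n_total]))
    strand <- sample(c("+", "-"), n_total, replace = TRUE)
    potential <- rep(FALSE, n_total)
    potential[sample.int(n_total, n_potential)] <- TRUE
    tibble::tibble(
      id = sprintf("V%03d", seq_len(n_total)),
      chrom = chrom,
      start = start,
      end = start + seg_len,
      strand = strand,
      functional = TRUE,
      potential = potential
    )
  })
}

#' Strand-aware read-assignment window of a V segment
#'
#' Read pairs are assigned to a V segment when they fall within a window
#' extending 500 bp upstream to 10,000 bp downstream of the annotated
#' segment, where upstream/downstream follow the segment's transcription
#' direction. Windows are clipped at coordinate 0.
#'
#' @param locus A tibble of segments as returned by [make_locus()] (columns
#'   `id`, `chrom`, `start`, `end`, `strand`).
#' @param upstream,downstream Window extent in bp relative to transcription
#'   direction; defaults 500 and 10,000.
#' @return A tibble `id`, `chrom`, `window_start`, `window_end`, `strand`
#'   with 0-based half-open windows.
#' @examples
#' seg <- tibble::tibble(id = "V1", chrom = "chr6", start = 10000,
#'                       end = 10500, strand = "+")
#' assignment_window(seg)
#' @export
assignment_window <- function(locus, upstream = 500, downstream = 10000) {
  check_locus(locus)
  plus <- locus$strand == "+"
  ws <- ifelse(plus, locus$start - upstream, locus$start - downstream)
  we <- ifelse(plus, locus$end + downstream, locus$end + upstream)
  tibble::tibble(
    id = locus$id,
    chrom = locus$chrom,
    window_start = pmax(0, ws),
    window_end = we,
    strand = locus$strand
  )
}

#' Scatter diagnostic SNPs across assignment windows
#'
#' Places `n_per_window` biallelic SNPs uniformly at random inside every
#' segment's assignment window, with distinct parental bases, emulating the
#' ~1% sequence divergence between the B6 and Cast genomes that makes
#' allele-resolved read sorting possible.
#'
#' @param locus Segment tibble from [make_locus()].
#' @param n_per_window SNPs per assignment window (>= 1 recommended).
#' @param seed Integer seed.
#' @return A tibble `chrom`, `pos` (0-based), `b6_base`, `cast_base` with
#'   `b6_base != cast_base`, sorted by position.
#' @export
make_snps <- function(locus, n_per_window = 5L, seed = 1L) {
  check_locus(locus)
  stopifnot(n_per_window >= 1)
  win <- assignment_window(locus)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    snp <- purrr::pmap(
      list(win$chrom, win$window_start, win$window_end),
      function(chrom, ws, we) {
        pos <- sort(sample(seq.int(ws, we - 1), n_per_window))
        b6 <- sample(bases, n_per_window, replace = TRUE)
        alt <- vapply(b6, function(b) sample(setdiff(bases, b), 1), "")
        tibble::tibble(chrom = chrom, pos = pos, b6_base = b6,
                       cast_base = unname(alt))
      }
    )
    dplyr::arrange(dplyr::bind_rows(snp), .data$chrom, .data$pos)
  })
}

check_locus <- function(locus) {
  need <- c("id", "chrom", "start", "end", "strand")
  if (!is.data.frame(locus) || !all(need %in% names(locus))) {
    abort(paste0("`locus` must be a data frame with columns ",
                 paste(need, collapse = ", "), "."))
  }
  if (any(locus$start < 0) || any(locus$start >= locus$end)) {
    abort("Segments must satisfy 0 <= start < end.")
  }
  if (anyDuplicated(locus$id)) abort("Segment ids must be unique.")
  if (!all(locus$strand %in% c("+", "-"))) {
    abort("Strand must be '+' or '-'.")
  }
  invisible(locus)
}
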