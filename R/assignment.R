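#' Tag reads to their parental genome by SNP content
#'
#' Classifies each read pair by the parental bases it carries at known SNP
#' positions: `B6` when every informative SNP matches the B6 base, `Cast`
#' when every informative SNP matches the Cast base, `conflict` when at
#' least one SNP supports each parent, and `unassigned` when the read covers
#' no SNP or none of its observed bases matches either parent.
#'
#' @param reads Tibble with columns `chrom` and `snp_obs` (comma-separated
#'   `"pos:base"` observations, `""` for none), as from [simulate_reads()]
#'   or [read_reads()].
#' @param snps SNP table `chrom`, `pos`, `b6_base`, `cast_base`.
#' @return A character vector, one of `"B6"`, `"Cast"`, `"unassigned"`,
#'   `"conflict"` per read.
#' @examples
#' snps <- tibble::tibble(chrom = "chr6", pos = 1000,
#'                        b6_base = "A", cast_base = "G")
#' reads <- tibble::tibble(chrom = "chr6", snp_obs = c("1000:A", "1000:G", ""))
#' tag_alleles(reads, snps)
#' @export
tag_alleles <- function(reads, snps) {
  stopifnot(all(c("chrom", "snp_obs") %in% names(reads)))
  stopifnot(all(c("chrom", "pos", "b6_base", "cast_base") %in% names(snps)))
  key <- paste(snps$chrom, snps$pos)
  vapply(seq_len(nrow(reads)), function(i) {
    obs <- reads$snp_obs[i]
    if (is.na(obs) || obs == "") return("unassigned")
    parts <- strsplit(strsplit(obs, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    pos <- vapply(parts, function(p) as.numeric(p[1]), 0)
    base <- vapply(parts, function(p) p[2], "")
    j <- match(paste(reads$chrom[i], pos), key)
    known <- !is.na(j)
    if (!any(known)) return("unassigned")
    b6_hit <- base[known] == snps$b6_base[j[known]]
    cast_hit <- base[known] == snps$cast_base[j[known]]
    informative <- b6_hit | cast_hit
    if (!any(informative)) return("unassigned")
    has_b6 <- any(b6_hit)
    has_cast <- any(cast_hit)
    if (has_b6 && has_cast) "conflict"
    else if (has_b6) "B6"
    else "Cast"
  }, "")
}

#' Assign allele-tagged read pairs to V segments
#'
#' A read pair is counted toward a segment when its span is fully contained
#' in the segment's strand-aware assignment window (500 bp upstream to
#' 10,000 bp downstream of the annotation), its strand matches the
#' segment's transcription direction, and it carries an unambiguous parental
#' tag. Reads contained in more than one window are discarded as ambiguous;
#' conflict-tagged reads are discarded; everything else that fails the rule
#' is tallied as unassigned. The tallies together with the per-segment
#' counts conserve the total number of input reads.
#'
#' @param reads Read tibble (`chrom`, `start`, `end`, `strand`, `snp_obs`).
#' @param locus Segment tibble from [make_locus()] or [read_bed()].
#' @param snps SNP table used for tagging.
#' @param sample Sample name recorded in the count table.
#' @return A list with `counts` (tibble `feature_id`, `sample`, `b6`,
#'   `cast`; one row per locus segment, zero-filled) and `tally` (tibble
#'   `category` in assigned_b6 / assigned_cast / unassigned / ambiguous /
#'   conflict, with read totals).
#' @export
assign_reads <- function(reads, locus, snps, sample = "sample1") {
  check_locus(locus)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  win <- assignment_window(locus)
  tag <- tag_alleles(reads, snps)

  n_win <- nrow(win)
  b6 <- integer(n_win)
  cast <- integer(n_win)
  names(b6) <- names(cast) <- win$id
  n_unassigned <- 0L; n_ambiguous <- 0L; n_conflict <- 0L
  for (i in seq_len(nrow(reads))) {
    if (tag[i] == "conflict") { n_conflict <- n_conflict + 1L; next }
    if (tag[i] == "unassigned") { n_unassigned <- n_unassigned + 1L; next }
    hit <- which(win$chrom == reads$chrom[i] &
                   win$window_start <= reads$start[i] &
                   reads$end[i] <= win$window_end &
                   win$strand == reads$strand[i])
    if (length(hit) == 0) { n_unassigned <- n_unassigned + 1L; next }
    if (length(hit) > 1) { n_ambiguous <- n_ambiguous + 1L; next }
    if (tag[i] == "B6") b6[hit] <- b6[hit] + 1L else cast[hit] <- cast[hit] + 1L
  }
  list(
    counts = tibble::tibble(feature_id = win$id, sample = sample,
                            b6 = unname(b6), cast = unname(cast)),
    tally = tibble::tibble(
      category = c("assigned_b6", "assigned_cast", "unassigned",
                   "ambiguous", "conflict"),
      reads = c(sum(b6), sum(cast), n_unassigned, n_ambiguous, n_conflict)
    )
  )
}

#' Allelic ratio with a minimum-depth rule
#'
#' The fraction of allele-informative reads from the B6 allele,
#' `b6 / (b6 + cast)`, on the scale 0 (100% Cast) to 1 (100% B6). Features
#' below the depth threshold return `NA`: 20 reads is the default used for
#' amplicon and ncRNA ratios; 10 reads is the threshold for inclusion in
#' accessibility heatmaps.
#'
#' @param b6,cast Nonnegative integer counts (vectorized).
#' @param min_depth Minimum `b6 + cast` for a defined ratio.
#' @return Numeric vector in `[0, 1]`, `NA` below depth.
#' @examples
#' allelic_ratio(30, 10)            # 0.75
#' allelic_ratio(5, 5)              # NA: depth 10 < 20
#' allelic_ratio(0, 40)             # 0: 100% Cast
#' @export
allelic_ratio <- function(b6, cast, min_depth = 20) {
  if (any(b6 < 0, na.rm = TRUE) || any(cast < 0, na.rm = TRUE)) {
    abort("Counts must be nonnegative.")
  }
  depth <- b6 + cast
  ifelse(depth >= min_depth & depth > 0, b6 / depth, NA_real_)
}
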