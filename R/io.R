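#' Read a V-segment locus from a 6-column BED file
#'
#' BED convention: 0-based half-open intervals, tab-separated
#' `chrom start end name score strand`, no header. Malformed lines are
#' rejected with their line numbers.
#'
#' @param path File path.
#' @return A segment tibble (`id`, `chrom`, `start`, `end`, `strand`,
#'   `functional`) compatible with [assignment_window()] and
#'   [assign_reads()].
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
  if (ncol(raw) < 6 || any(is.na(raw$strand))) {
    abort("BED file must have 6 columns including strand.")
  }
  bad <- which(is.na(raw$start) | is.na(raw$end) | raw$start < 0 |
                 raw$start >= raw$end | !raw$strand %in% c("+", "-"))
  if (length(bad)) {
    abort(paste0("Malformed BED line(s): ", paste(bad, collapse = ", "),
                 " (need 0 <= start < end and strand +/-)."))
  }
  tibble::tibble(id = raw$name, chrom = raw$chrom, start = raw$start,
                 end = raw$end, strand = raw$strand, functional = TRUE)
}

#' @rdname read_bed
#' @param locus Segment tibble (columns `id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
write_bed <- function(locus, path) {
  check_locus(locus)
  readr::write_tsv(
    tibble::tibble(chrom = locus$chrom, start = locus$start, end = locus$end,
                   name = locus$id, score = 0L, strand = locus$strand),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read and write allele count tables
#'
#' TSV with header `feature_id  sample  b6  cast`; counts must be
#' nonnegative integers and (feature, sample) pairs unique.
#'
#' @param path File path.
#' @return `read_counts()`: a tibble `feature_id`, `sample`, `b6`, `cast`.
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    sample = readr::col_character(),
    b6 = readr::col_double(),
    cast = readr::col_double()
  ), progress = FALSE)
  need <- c("feature_id", "sample", "b6", "cast")
  if (!all(need %in% names(tab))) {
    abort("Count file must have header: feature_id sample b6 cast.")
  }
  if (anyNA(tab$b6) || anyNA(tab$cast) ||
      any(tab$b6 != round(tab$b6)) || any(tab$cast != round(tab$cast))) {
    abort("Counts must be integers.")
  }
  if (any(tab$b6 < 0) || any(tab$cast < 0)) abort("Counts must be nonnegative.")
  if (anyDuplicated(tab[c("feature_id", "sample")])) {
    abort("Duplicate (feature_id, sample) rows.")
  }
  dplyr::mutate(tab, b6 = as.integer(.data$b6), cast = as.integer(.data$cast))
}

#' @rdname read_counts
#' @param counts Allele count table.
#' @export
write_counts <- function(counts, path) {
  check_counts(counts, require_sample = TRUE)
  readr::write_tsv(counts[c("feature_id", "sample", "b6", "cast")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read and write SNP tables
#'
#' TSV with header `chrom  pos  b6_base  cast_base`; positions 0-based,
#' parental bases must differ.
#'
#' @param path File path.
#' @export
read_snps <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    b6_base = readr::col_character(), cast_base = readr::col_character()
  ), progress = FALSE)
  if (!all(c("chrom", "pos", "b6_base", "cast_base") %in% names(tab))) {
    abort("SNP file must have header: chrom pos b6_base cast_base.")
  }
  if (any(tab$b6_base == tab$cast_base)) {
    abort("Parental bases must differ at every SNP.")
  }
  tab
}

#' @rdname read_snps
#' @param snps SNP tibble.
#' @export
write_snps <- function(snps, path) {
  readr::write_tsv(snps[c("chrom", "pos", "b6_base", "cast_base")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read and write read-pair tables
#'
#' BED-like TSV with header: `chrom start end name strand snp_obs` where
#' `snp_obs` holds comma-separated `pos:base` observations (empty for
#' none).
#'
#' @param path File path.
#' @export
read_reads <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), name = readr::col_character(),
    strand = readr::col_character(), snp_obs = readr::col_character()
  ), progress = FALSE)
  tab$snp_obs[is.na(tab$snp_obs)] <- ""
  tab
}

#' @rdname read_reads
#' @param reads Read tibble.
#' @export
write_reads <- function(reads, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "strand", "snp_obs"),
                    names(reads))
  readr::write_tsv(reads[cols], path, progress = FALSE)
  invisible(path)
}

#' Read and write repertoire tables
#'
#' TSV with header `v_id  allele  count  percent` (extra columns are
#' preserved on write, ignored on read).
#'
#' @param path File path.
#' @export
read_repertoire <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("v_id", "allele", "count") %in% names(tab))) {
    abort("Repertoire file must have columns v_id, allele, count.")
  }
  tab
}

#' @rdname read_repertoire
#' @param rep_table Repertoire tibble.
#' @export
write_repertoire <- function(rep_table, path) {
  cols <- intersect(c("v_id", "allele", "count", "percent", "percent_library"),
                    names(rep_table))
  readr::write_tsv(rep_table[cols], path, progress = FALSE)
  invisible(path)
}

#' Write a ratio matrix or a dendrogram
#'
#' `write_ratio_matrix()` emits the features-by-samples TSV;
#' `write_newick()` exports an [stats::hclust] tree in Newick format (via
#' the ape package).
#'
#' @param rm A `ratio_matrix`.
#' @param path File path.
#' @export
write_ratio_matrix <- function(rm, path) {
  readr::write_tsv(tibble::as_tibble(rm), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ratio_matrix
#' @param tree An [stats::hclust] object.
#' @export
write_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the 'ape' package.")
  }
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
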