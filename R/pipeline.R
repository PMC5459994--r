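#' Default end-to-end run configuration
#'
#' The reference study conditions: 96 functional V segments of which 60 are
#' activatable, per-allele activation probabilities 0.43 (B6) and 0.25
#' (Cast), negative-binomial count noise with active mean 100 and 1% leak,
#' two biological replicates per clone, the standard calling thresholds
#' (FDR 0.05, 2-fold, depth 20; ratio-matrix depth 10), four clones, and a
#' repertoire simulation coupled at 0.9 to the ncRNA profile.
#'
#' @param seed Master seed for the whole run.
#' @param ... Named overrides merged into the defaults (nested lists are
#'   merged key-wise).
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    locus = list(n_total = 96L, n_potential = 60L),
    activation = list(p_b6 = 0.43, p_cast = 0.25),
    noise = list(mu_active = 100, mu_leak = 1, dispersion = 0.05,
                 n_replicates = 2L),
    calling = list(alpha = 0.05, fold_min = 2, min_depth = 20),
    ratio_min_depth = 10,
    n_clones = 4L,
    repertoire = list(coupling = 0.9, depth = 1e5, time_fraction = 1,
                      early_allele = "B6")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      modifyList(cfg[[nm]], dots[[nm]])
    } else {
      dots[[nm]]
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a locus and a set of clones under the configured activation
#' model, generates replicate allele count tables, calls monoallelic
#' segments with replicate consistency, fits per-clone activation
#' probabilities with goodness-of-fit, builds the allelic-ratio matrix with
#' PCA and hierarchical clustering, simulates coupled rearrangement
#' repertoires and correlates them with the ncRNA ratios. All randomness
#' descends from `config$seed`; reruns with the same configuration write
#' bit-identical outputs.
#'
#' @param config A configuration from [default_config()].
#' @param outdir Optional directory: when given, every stage output is
#'   written (TSV/Newick) together with a JSON `manifest.json` recording the
#'   resolved configuration, seed and output checksums.
#' @return A list with elements `locus`, `snps`, `clones`, `counts`,
#'   `calls`, `fits`, `gof`, `ratio_matrix`, `pca`, `tree`, `repertoires`,
#'   `correlations`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  seed <- config$seed
  params <- activation_params(config$activation$p_b6, config$activation$p_cast,
                              config$locus$n_potential, config$locus$n_total)
  noise <- noise_params(config$noise$mu_active, config$noise$mu_leak,
                        config$noise$dispersion, config$noise$n_replicates)

  locus <- stage("simulate", make_locus(config$locus$n_total,
                                        config$locus$n_potential,
                                        seed = derive_seed(seed, 1)))
  snps <- stage("simulate", make_snps(locus, seed = derive_seed(seed, 2)))

  clone_ids <- paste0("clone", seq_len(config$n_clones))
  clones <- stage("simulate", purrr::imap(
    setNames(clone_ids, clone_ids),
    function(id, k) simulate_clone(locus, params,
                                   seed = derive_seed(seed, 10 + match(id, clone_ids)),
                                   clone_id = id)
  ))
  counts <- stage("simulate", purrr::imap(clones, function(cl, id) {
    simulate_counts(cl, noise,
                    seed = derive_seed(seed, 100 + match(id, clone_ids)),
                    sample_prefix = paste0(id, "_rep"))
  }))

  calls <- stage("call", purrr::map(counts, function(tab) {
    call_with_replicates(tab, alpha = config$calling$alpha,
                         fold_min = config$calling$fold_min,
                         min_depth = config$calling$min_depth)
  }))

  fits <- stage("model", purrr::map(calls, function(cl) {
    fit_activation(tally_categories(cl, locus),
                   n_potential = config$locus$n_potential)
  }))
  gof <- stage("model", purrr::map(fits, function(f) {
    goodness_of_fit(f$counts, params)
  }))

  all_counts <- dplyr::bind_rows(counts)
  ratio_matrix <- stage("profile", build_ratio_matrix(
    all_counts, min_depth = config$ratio_min_depth))
  pca <- stage("profile", pca_profiles(ratio_matrix))
  tree <- stage("profile", cluster_profiles(ratio_matrix))

  repertoires <- stage("repertoire", purrr::imap(clones, function(cl, id) {
    simulate_repertoire(
      cl, counts[[id]],
      coupling = config$repertoire$coupling,
      early_allele = config$repertoire$early_allele,
      time_fraction = config$repertoire$time_fraction,
      depth = config$repertoire$depth,
      seed = derive_seed(seed, 200 + match(id, clone_ids))
    )
  }))
  correlations <- stage("repertoire", purrr::imap(
    repertoires,
    function(rt, id) {
      nc <- counts[[id]] |>
        dplyr::summarise(b6 = sum(.data$b6), cast = sum(.data$cast),
                         .by = "feature_id")
      ncr <- tibble::tibble(
        v_id = nc$feature_id,
        ratio = allelic_ratio(nc$b6, nc$cast,
                              min_depth = config$calling$min_depth)
      )
      ncrna_repertoire_correlation(ncr, rearrangement_allelic_ratio(rt))
    }
  ) |> dplyr::bind_rows(.id = "clone_id"))

  manifest <- list(
    package = "allelochoice",
    version = as.character(utils::packageVersion("allelochoice")),
    seed = seed,
    config = unclass(config)
  )
  result <- list(locus = locus, snps = snps, clones = clones, counts = counts,
                 calls = calls, fits = fits, gof = gof,
                 ratio_matrix = ratio_matrix, pca = pca, tree = tree,
                 repertoires = repertoires, correlations = correlations,
                 manifest = manifest)
  if (!is.null(outdir)) {
    result$manifest <- write_pipeline_outputs(result, outdir)
  }
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_bed(result$locus, p("locus.bed"))
  write_snps(result$snps, p("snps.tsv"))
  write_counts(dplyr::bind_rows(result$counts), p("counts.tsv"))
  readr::write_tsv(dplyr::bind_rows(result$calls, .id = "clone_id"),
                   p("calls.tsv"), progress = FALSE)
  fits <- purrr::imap(result$fits, function(f, id) {
    tibble::tibble(clone_id = id, p_b6 = f$p_b6, p_cast = f$p_cast,
                   se_b6 = f$se_b6, se_cast = f$se_cast,
                   gof_p = result$gof[[id]]$p.value)
  })
  readr::write_tsv(dplyr::bind_rows(fits), p("activation_fits.tsv"),
                   progress = FALSE)
  write_ratio_matrix(result$ratio_matrix, p("ratio_matrix.tsv"))
  readr::write_tsv(result$pca$scores, p("pca_scores.tsv"), progress = FALSE)
  if (requireNamespace("ape", quietly = TRUE)) {
    write_newick(result$tree, p("dendrogram.nwk"))
  }
  readr::write_tsv(dplyr::bind_rows(result$repertoires, .id = "clone_id") |>
                     dplyr::relocate("clone_id"),
                   p("repertoire.tsv"), progress = FALSE)
  readr::write_tsv(result$correlations, p("correlations.tsv"),
                   progress = FALSE)
  manifest <- result$manifest
  files <- setdiff(list.files(outdir), "manifest.json")
  manifest$outputs <- as.list(tools::md5sum(file.path(outdir, files)))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}
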