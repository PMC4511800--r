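#' Pipeline configuration
#'
#' Paths and thresholds for the end-to-end analysis run. Defaults follow
#' standard GWAS practice: genome-wide significance at `5e-8`, at least 20
#' reported SNPs for a disease to enter the MiRA table and at least 50 for
#' its frequency spectrum to be estimated, and three ELI groups (tertiles).
#'
#' @param association Path to the association TSV.
#' @param counts Path to the literature-count TSV.
#' @param manifests Named character vector of platform manifest paths
#'   (optional).
#' @param selected Path to the positively-selected SNP id list (required
#'   when `manifests` is given).
#' @param gwas_snps Path to the GWAS-reported SNP id list; default `NULL`
#'   uses the `snp_id` column of the association table.
#' @param out_dir Directory for the TSV report bundle.
#' @param p_threshold Association p-value filter (default `5e-8`); `NULL`
#'   disables it.
#' @param min_snps_mira Minimum SNPs per disease for the MiRA table
#'   (default 20).
#' @param min_snps_spectra Minimum SNPs per disease for a per-disease
#'   spectrum (default 50).
#' @param n_tertiles Number of ELI groups (default 3).
#' @param alpha Significance level for overlap comparisons (default 0.05).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(association, counts, manifests = NULL,
                            selected = NULL, gwas_snps = NULL, out_dir,
                            p_threshold = 5e-8, min_snps_mira = 20,
                            min_snps_spectra = 50, n_tertiles = 3,
                            alpha = 0.05) {
  stopifnot(min_snps_mira >= 1, min_snps_spectra >= 1, n_tertiles >= 2,
            alpha > 0, alpha < 1)
  if (!is.null(manifests) && is.null(selected)) {
    rlang::abort("manifests given without a selected-SNP list",
                 class = "riskspectra_domain_error")
  }
  structure(
    list(association = association, counts = counts, manifests = manifests,
         selected = selected, gwas_snps = gwas_snps, out_dir = out_dir,
         p_threshold = p_threshold, min_snps_mira = min_snps_mira,
         min_snps_spectra = min_snps_spectra, n_tertiles = n_tertiles,
         alpha = alpha),
    class = "pipeline_config"
  )
}

spectrum_long <- function(group, freqs) {
  obs <- bin_spectrum(freqs)
  nul <- neutral_null_spectrum(freqs)
  tibble::tibble(
    group = group, bin = obs$bin, lower = obs$lower, upper = obs$upper,
    n_snps = length(freqs),
    observed = obs$proportion, null = nul$proportion
  )
}

#' Run the full analysis pipeline
#'
#' Composes every stage: reads and filters the association table
#' (significance filter, then per-disease SNP deduplication keeping the
#' lowest p-value), computes the per-disease ELI table and its tertiles,
#' per-disease and per-tertile MiRA proportions, observed and
#' frequency-independence-null five-bin spectra (per eligible disease, per
#' tertile, and pooled), cross-disease and cross-tertile ANOVAs plus the
#' ELI-vs-frequency Spearman correlation, and — when manifests are supplied —
#' platform/GWAS positive-selection overlap with Bonferroni-adjusted
#' pairwise chi-squares. All outputs are written as TSV files under
#' `out_dir` together with `run_log.txt`, which accounts for every record
#' kept or dropped at each filter. Reruns with the same inputs are
#' byte-identical (every stage is deterministic).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the result tibbles (`eli`, `mira`,
#'   `mira_tertile`, `spectra`, `tests`, and `overlap`/`overlap_comparisons`
#'   when computed) plus `log` (character).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    rlang::inform(line)
  }

  assoc <- read_association_table(config$association)
  note("associations: read %d records", nrow(assoc))
  if (!is.null(config$p_threshold)) {
    keep <- !is.na(assoc$p_value) & assoc$p_value <= config$p_threshold
    note("associations: p <= %g filter kept %d, dropped %d",
         config$p_threshold, sum(keep), sum(!keep))
    assoc <- assoc[keep, , drop = FALSE]
  }
  n_before <- nrow(assoc)
  assoc <- assoc |>
    dplyr::mutate(.key = disease_key(.data$disease)) |>
    dplyr::arrange(.data$.key, .data$snp_id, .data$p_value) |>
    dplyr::distinct(.data$.key, .data$snp_id, .keep_all = TRUE) |>
    dplyr::select(-".key")
  note("associations: deduplication kept %d, dropped %d duplicate disease-SNP pairs",
       nrow(assoc), n_before - nrow(assoc))

  counts <- read_literature_counts(config$counts)
  note("literature counts: %d diseases", nrow(counts))
  eli <- eli_table(counts)
  tert <- assign_tertiles(eli, n_groups = config$n_tertiles)
  note("ELI: %d diseases split into %d groups", nrow(tert), config$n_tertiles)

  mira <- mira_summary(assoc, min_snps = config$min_snps_mira)
  note("MiRA table: %d diseases with >= %d SNPs", nrow(mira), config$min_snps_mira)

  assoc_t <- assoc |>
    dplyr::mutate(.key = disease_key(.data$disease)) |>
    dplyr::inner_join(
      dplyr::mutate(tert, .key = disease_key(.data$disease)) |>
        dplyr::select(".key", "tertile"),
      by = ".key") |>
    dplyr::select(-".key")
  note("tertile join: %d of %d association records matched an indexed disease",
       nrow(assoc_t), nrow(assoc))
  mira_tert <- mira_summary(assoc_t, by = "tertile")

  # spectra: per eligible disease, per tertile, and pooled
  eligible <- mira$disease[mira$n_snps >= config$min_snps_spectra]
  note("spectra: %d disease(s) with >= %d SNPs", length(eligible),
       config$min_snps_spectra)
  spectra <- dplyr::bind_rows(
    purrr::map(eligible, \(d) {
      spectrum_long(d, assoc$risk_allele_freq[assoc$disease == d])
    }),
    purrr::map(sort(unique(assoc_t$tertile)), \(tt) {
      spectrum_long(sprintf("tertile_%d", tt),
                    assoc_t$risk_allele_freq[assoc_t$tertile == tt])
    }),
    spectrum_long("all", assoc$risk_allele_freq)
  )

  tests <- list()
  big <- assoc$disease %in% mira$disease
  if (length(unique(assoc$disease[big])) >= 2) {
    tests$anova_disease <- anova_binary(
      is_minor(assoc$risk_allele_freq[big]), assoc$disease[big])
  }
  if (length(unique(assoc_t$tertile)) >= 2) {
    tests$anova_tertile <- anova_binary(
      is_minor(assoc_t$risk_allele_freq), assoc_t$tertile)
  }
  eli_keyed <- dplyr::mutate(eli, .key = disease_key(.data$disease))
  joined <- assoc |>
    dplyr::mutate(.key = disease_key(.data$disease)) |>
    dplyr::inner_join(dplyr::select(eli_keyed, ".key", "eli"), by = ".key")
  if (nrow(joined) >= 3) {
    tests$spearman_eli_freq <- spearman_test(joined$eli, joined$risk_allele_freq)
  }
  tests_tbl <- dplyr::bind_rows(purrr::imap(tests, \(t, nm) {
    dplyr::mutate(tidy(t), analysis = nm, .before = 1)
  }))
  if (sum(!is.na(assoc$sample_size)) >= 3) {
    size_rows <- mira_vs_sample_size(assoc) |>
      dplyr::mutate(analysis = paste0("spearman_size_vs_", .data$measure),
                    .before = 1) |>
      dplyr::select(-"measure")
    tests_tbl <- dplyr::bind_rows(tests_tbl, size_rows)
  }

  results <- list(eli = tert, mira = mira, mira_tertile = mira_tert,
                  spectra = spectra, tests = tests_tbl)

  if (!is.null(config$manifests)) {
    selected <- read_snp_ids(config$selected)
    note("selected set: %d SNPs", length(selected))
    plat_rows <- dplyr::bind_rows(purrr::imap(config$manifests, \(path, nm) {
      overlap_result(read_snp_ids(path), selected, label = nm)
    }))
    gwas_ids <- if (is.null(config$gwas_snps)) unique(assoc$snp_id)
      else read_snp_ids(config$gwas_snps)
    gwas_row <- overlap_result(gwas_ids, selected, label = "GWAS-reported")
    results$overlap <- dplyr::bind_rows(plat_rows, gwas_row)
    results$overlap_comparisons <-
      compare_all_platforms(plat_rows, gwas_row, alpha = config$alpha)
    pool <- pooled_platform_mean(plat_rows)
    note("overlap: platform mean %.2f%% (SD %.2f%%) vs GWAS %.2f%%",
         pool$mean_pct, pool$sd_pct, gwas_row$proportion_pct)
  }

  out <- function(df, name) {
    readr::write_tsv(df, file.path(config$out_dir, name), progress = FALSE)
  }
  out(results$eli, "eli.tsv")
  out(results$mira, "mira_by_disease.tsv")
  out(results$mira_tertile, "mira_by_tertile.tsv")
  out(results$spectra, "spectra.tsv")
  out(results$tests, "tests.tsv")
  if (!is.null(results$overlap)) {
    out(results$overlap, "overlap.tsv")
    out(results$overlap_comparisons, "overlap_comparisons.tsv")
  }
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  results$log <- log
  invisible(results)
}
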