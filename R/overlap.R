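#' Overlap between a SNP set and the positively-selected set
#'
#' Counts how many SNPs of a genotyping-platform manifest (or of a
#' GWAS-reported SNP set) carry a signature of recent positive selection —
#' i.e. are members of the supplied selected-SNP set — and expresses it as a
#' percentage with its binomial standard error
#' `100 * sqrt(p (1 - p) / n)`.
#'
#' @param snp_ids Character vector of SNP ids (deduplicated; must be
#'   non-empty).
#' @param selected Character vector of positively-selected SNP ids.
#' @param label Label for the result row.
#' @return One-row tibble: `label`, `n_snps`, `n_selected`,
#'   `proportion_pct`, `se_pct` (unrounded).
#' @seealso [overlap_from_counts()], [compare_overlap()],
#'   [compare_all_platforms()]
#' @export
overlap_result <- function(snp_ids, selected, label = "manifest") {
  snp_ids <- unique(as.character(snp_ids))
  if (length(snp_ids) == 0) {
    rlang::abort("manifest is empty", class = "riskspectra_domain_error")
  }
  n_selected <- sum(snp_ids %in% unique(as.character(selected)))
  overlap_from_counts(label, length(snp_ids), n_selected)
}

#' Overlap proportion from published counts
#'
#' Same result shape as [overlap_result()] but starting from counts, for
#' reproducing published per-platform tables where only totals are printed.
#'
#' @param label Row label.
#' @param n_snps Total SNPs (positive integer), vectorised.
#' @param n_selected Selected SNPs among them, `0 <= n_selected <= n_snps`.
#' @return Tibble with `label`, `n_snps`, `n_selected`, `proportion_pct`,
#'   `se_pct`.
#' @export
overlap_from_counts <- function(label, n_snps, n_selected) {
  if (any(n_snps < 1) || any(n_selected < 0) || any(n_selected > n_snps)) {
    rlang::abort("need 0 <= n_selected <= n_snps with n_snps >= 1",
                 class = "riskspectra_domain_error")
  }
  p <- n_selected / n_snps
  tibble::tibble(
    label = label,
    n_snps = as.integer(n_snps),
    n_selected = as.integer(n_selected),
    proportion_pct = 100 * p,
    se_pct = 100 * binom_se(p, n_snps)
  )
}

#' Compare two overlap proportions by chi-square
#'
#' 2x2 Pearson chi-square (no continuity correction) on the
#' (selected, not selected) x (group a, group b) table; 1 degree of freedom.
#'
#' @param a,b One-row overlap tibbles from [overlap_result()] /
#'   [overlap_from_counts()].
#' @return An `rs_test` (see [chi2_2x2()]); an expected cell below 1 attaches
#'   a warning note.
#' @export
compare_overlap <- function(a, b) {
  tab <- rbind(
    c(a$n_selected, a$n_snps - a$n_selected),
    c(b$n_selected, b$n_snps - b$n_selected)
  )
  chi2_2x2(tab)
}

#' Compare every platform against the GWAS-reported SNP set
#'
#' One chi-square comparison per platform against the GWAS overlap result,
#' with Bonferroni adjustment (`p_adj = min(1, p * k)` for `k` platforms) and
#' significance flags before and after adjustment.
#'
#' @param platform_results Tibble of platform overlap rows (stacked
#'   [overlap_result()] rows).
#' @param gwas_result One-row overlap tibble for the GWAS-reported SNPs.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `label`, `proportion_pct`, `gwas_pct`, `statistic`,
#'   `p_raw`, `p_adj`, `significant_raw`, `significant_adj`.
#' @export
compare_all_platforms <- function(platform_results, gwas_result, alpha = 0.05) {
  platform_results <- tibble::as_tibble(platform_results)
  if (nrow(platform_results) < 2) {
    rlang::abort("need at least 2 platforms", class = "riskspectra_domain_error")
  }
  tests <- purrr::map(seq_len(nrow(platform_results)), \(i) {
    compare_overlap(platform_results[i, ], gwas_result)
  })
  p_raw <- purrr::map_dbl(tests, "p_value")
  tibble::tibble(
    label = platform_results$label,
    proportion_pct = platform_results$proportion_pct,
    gwas_pct = gwas_result$proportion_pct,
    statistic = purrr::map_dbl(tests, "statistic"),
    p_raw = p_raw,
    p_adj = stats::p.adjust(p_raw, method = "bonferroni"),
    significant_raw = p_raw < alpha,
    significant_adj = stats::p.adjust(p_raw, method = "bonferroni") < alpha
  )
}

#' Unweighted mean overlap proportion across platforms
#'
#' Mean and standard deviation of the per-platform selected-SNP percentages,
#' for comparison with the percentage among GWAS-reported SNPs.
#'
#' @param platform_results Tibble of platform overlap rows.
#' @return One-row tibble: `n_platforms`, `mean_pct`, `sd_pct`.
#' @export
pooled_platform_mean <- function(platform_results) {
  tibble::tibble(
    n_platforms = nrow(platform_results),
    mean_pct = mean(platform_results$proportion_pct),
    sd_pct = stats::sd(platform_results$proportion_pct)
  )
}
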