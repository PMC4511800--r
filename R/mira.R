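SPECTRUM_EDGES <- c(0, 0.2, 0.4, 0.6, 0.8, 1)

#' Is a risk allele minor?
#'
#' A risk allele is *minor* when its control frequency is below 50%. A
#' frequency of exactly 0.5 is classed as non-minor (the minor/major
#' definition covers `< 50%` and `> 50%`; the knife-edge case is logged when
#' it occurs).
#'
#' @param freq Risk-allele frequencies, strictly inside (0, 1).
#' @return Logical vector: `TRUE` where `freq < 0.5`.
#' @export
is_minor <- function(freq) {
  if (any(!is.finite(freq) | freq <= 0 | freq >= 1)) {
    rlang::abort("frequencies must lie strictly inside (0, 1)",
                 class = "riskspectra_domain_error")
  }
  n_half <- sum(freq == 0.5)
  if (n_half > 0) {
    rlang::inform(sprintf(
      "%d frequenc%s exactly 0.5 classed as non-minor", n_half,
      if (n_half == 1) "y" else "ies"))
  }
  freq < 0.5
}

#' Minor-risk-allele (MiRA) proportion with binomial standard error
#'
#' For each group of associations, the fraction of risk alleles that are
#' minor (frequency < 0.5) together with its binomial standard error
#' `sqrt(p (1 - p) / n)`. Under frequency-independent risk assignment the
#' expected MiRA proportion is 0.5; negative selection against risk alleles
#' pushes it above 0.5.
#'
#' @param records Association tibble (see [read_association_table()]).
#' @param by Grouping column name (default `"disease"`); `NULL` pools all
#'   records into a single group labelled `"all"`.
#' @param min_snps Drop groups with fewer than this many SNPs (default 1,
#'   i.e. keep all); dropped groups are reported in a message.
#' @return Tibble with `disease` (or the `by` column), `n_snps`, `mira`,
#'   `se`, sorted by descending `n_snps`. Values are unrounded.
#' @export
mira_summary <- function(records, by = "disease", min_snps = 1) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    rlang::abort("no records: MiRA proportion undefined for an empty group",
                 class = "riskspectra_domain_error")
  }
  if (is.null(by)) {
    records$.group <- "all"
    by <- ".group"
  }
  records$.minor <- is_minor(records$risk_allele_freq)
  out <- records |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      mira = mean(.data$.minor),
      .groups = "drop"
    ) |>
    dplyr::mutate(se = binom_se(.data$mira, .data$n_snps)) |>
    dplyr::arrange(dplyr::desc(.data$n_snps), disease_key(.data$group))
  dropped <- out$group[out$n_snps < min_snps]
  if (length(dropped) > 0) {
    rlang::inform(sprintf("dropped %d group(s) with fewer than %d SNPs",
                          length(dropped), min_snps))
    out <- out[out$n_snps >= min_snps, , drop = FALSE]
  }
  names(out)[names(out) == "group"] <- if (by == ".group") "group" else by
  out
}

new_spectrum_bins <- function(weights, n_snps) {
  total <- sum(weights)
  out <- tibble::tibble(
    bin = seq_len(5),
    lower = SPECTRUM_EDGES[1:5],
    upper = SPECTRUM_EDGES[2:6],
    count = weights,
    proportion = if (total > 0) weights / total else rep(0, 5)
  )
  class(out) <- c("spectrum_bins", class(out))
  attr(out, "n_snps") <- n_snps
  out
}

bin_index <- function(freqs) {
  if (any(!is.finite(freqs) | freqs <= 0 | freqs >= 1)) {
    rlang::abort("frequencies must lie strictly inside (0, 1)",
                 class = "riskspectra_domain_error")
  }
  # half-open bins, lower edge closed from the second bin on:
  # (0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8), [0.8,1)
  findInterval(freqs, SPECTRUM_EDGES[2:5]) + 1L
}

#' Five-bin risk-allele frequency spectrum
#'
#' Bins risk-allele frequencies into the five fixed groups
#' `(0, 0.2), [0.2, 0.4), [0.4, 0.6), [0.6, 0.8), [0.8, 1)` and returns the
#' normalised spectrum. Lower edges are closed from the second bin on, so
#' `F = 0.2` falls in the second bin.
#'
#' @param freqs Frequencies strictly inside (0, 1).
#' @param weights Optional non-negative per-observation weights (default 1).
#' @return A `spectrum_bins` tibble (5 rows: `bin`, `lower`, `upper`,
#'   `count`, `proportion`); proportions sum to 1. The number of underlying
#'   SNPs is carried in the `n_snps` attribute.
#' @seealso [neutral_null_spectrum()], [spectrum_asymmetry()],
#'   [autoplot.spectrum_bins()]
#' @export
bin_spectrum <- function(freqs, weights = NULL) {
  if (length(freqs) == 0) {
    rlang::abort("cannot bin an empty frequency vector",
                 class = "riskspectra_domain_error")
  }
  idx <- bin_index(freqs)
  w <- weights %||% rep(1, length(freqs))
  if (any(w < 0)) {
    rlang::abort("weights must be non-negative", class = "riskspectra_domain_error")
  }
  counts <- vapply(1:5, function(b) sum(w[idx == b]), numeric(1))
  new_spectrum_bins(counts, n_snps = length(freqs))
}

#' Frequency-independence null spectrum
#'
#' The empirical null used to judge a left shift: if an allele's chance of
#' being the risk allele does not depend on its frequency, each SNP's two
#' alleles are equally likely to be risk-associated. The null spectrum
#' therefore gives each SNP weight 1/2 at its observed frequency `f` and 1/2
#' at the mirrored frequency `1 - f`, producing a spectrum symmetric under
#' `f -> 1 - f` with MiRA mass exactly 0.5 (when no `f` equals 0.5). No
#' parametric neutral site-frequency spectrum is assumed: platform
#' ascertainment already shapes the observed GWAS spectrum, and mirroring
#' preserves that shape while removing any frequency-direction preference.
#'
#' @inheritParams bin_spectrum
#' @return A `spectrum_bins` tibble.
#' @export
neutral_null_spectrum <- function(freqs) {
  if (length(freqs) == 0) {
    rlang::abort("cannot bin an empty frequency vector",
                 class = "riskspectra_domain_error")
  }
  bin_spectrum(c(freqs, 1 - freqs),
               weights = rep(0.5, 2 * length(freqs)))
}

#' Left-shift score of an observed spectrum against its null
#'
#' Mass of the observed spectrum in the two lowest-frequency bins (F < 0.4)
#' minus the corresponding null mass. Positive values mean the risk-allele
#' spectrum is shifted towards low frequencies relative to the
#' frequency-independence null — the footprint of negative selection.
#'
#' @param observed,null `spectrum_bins` built on the same bin edges.
#' @return A single number in `[-1, 1]`.
#' @export
spectrum_asymmetry <- function(observed, null) {
  for (s in list(observed, null)) {
    if (!inherits(s, "spectrum_bins")) {
      rlang::abort("inputs must be spectrum_bins objects",
                   class = "riskspectra_domain_error")
    }
  }
  if (!identical(observed$lower, null$lower) || !identical(observed$upper, null$upper)) {
    rlang::abort("spectra built on different bin edges",
                 class = "riskspectra_domain_error")
  }
  sum(observed$proportion[1:2]) - sum(null$proportion[1:2])
}

#' Sample-size effects on rarity and risk direction
#'
#' Two Spearman correlations with GWAS sample size: (a) against the
#' indicator that the SNP is rare (`MAF <= 0.05`, with
#' `MAF = min(f, 1 - f)`) — larger studies are better powered to detect rare
#' variants, so a positive correlation is expected; and (b) against the
#' minor-risk indicator — the direction of an allele's effect should not
#' depend on how many samples were genotyped, so no correlation is expected.
#'
#' @param records Association tibble with a `sample_size` column; rows with
#'   unknown sample size are dropped with a message.
#' @return Tibble with one row per correlation (`measure`, `statistic` = rho,
#'   `df1`, `p_value`, `n`, `note`); degenerate inputs yield a
#'   `"not computable"` note rather than an error.
#' @export
mira_vs_sample_size <- function(records) {
  records <- tibble::as_tibble(records)
  known <- !is.na(records$sample_size)
  if (sum(!known) > 0) {
    rlang::inform(sprintf("dropped %d record(s) without sample_size", sum(!known)))
  }
  records <- records[known, , drop = FALSE]
  if (nrow(records) < 3) {
    rlang::abort("need at least 3 records with sample_size",
                 class = "riskspectra_domain_error")
  }
  f <- records$risk_allele_freq
  maf <- pmin(f, 1 - f)
  tests <- list(
    rare_maf_le_0.05 = spearman_test(records$sample_size, as.numeric(maf <= 0.05)),
    minor_risk = spearman_test(records$sample_size, as.numeric(is_minor(f)))
  )
  dplyr::bind_rows(purrr::imap(tests, \(t, nm) {
    dplyr::mutate(tidy(t), measure = nm, .before = 1)
  }))
}
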