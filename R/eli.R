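#' Environment/lifestyle index (ELI)
#'
#' The ELI measures how strongly the published literature ties a disease to
#' environmental or lifestyle factors: the number of abstracts mentioning the
#' disease AND "environment" plus those mentioning the disease AND
#' "lifestyle", per 1,000 abstracts mentioning the disease,
#'
#' \deqn{ELI = (n_{env} + n_{lifestyle}) / n_{disease} \times 1000.}
#'
#' For rheumatoid arthritis, (1,578 + 393) / 120,346 x 1000 = 16.4 after
#' rounding to one decimal. Values are returned unrounded; round with
#' [round_half_up()] only for presentation.
#'
#' @param n_disease Abstract count mentioning the disease (must be >= 1).
#' @param n_env Abstract count mentioning the disease AND "environment".
#' @param n_lifestyle Abstract count mentioning the disease AND "lifestyle".
#' @return Numeric vector of ELI values (papers per 1,000 disease papers).
#' @seealso [compute_extended_eli()], [eli_table()], [assign_tertiles()]
#' @export
#' @examples
#' compute_eli(120346, 1578, 393) # 16.377...
compute_eli <- function(n_disease, n_env, n_lifestyle) {
  if (any(!is.finite(n_disease) | n_disease < 1)) {
    rlang::abort("n_disease must be >= 1", class = "riskspectra_domain_error")
  }
  if (any(n_env < 0) || any(n_lifestyle < 0)) {
    rlang::abort("co-occurrence counts must be non-negative",
                 class = "riskspectra_domain_error")
  }
  (n_env + n_lifestyle) / n_disease * 1000
}

#' Extended ELI including the "exposure" term
#'
#' Same ratio as [compute_eli()] with "exposure" co-mentions added to the
#' numerator: `(n_env + n_lifestyle + n_exposure) / n_disease * 1000`.
#' Term-level counts are summed, so an abstract matching several terms can
#' contribute more than once — consistent with how the base index treats
#' "environment" and "lifestyle".
#'
#' @inheritParams compute_eli
#' @param n_exposure Abstract count mentioning the disease AND "exposure";
#'   must be present (non-`NA`).
#' @return Numeric vector of extended ELI values.
#' @export
compute_extended_eli <- function(n_disease, n_env, n_lifestyle, n_exposure) {
  if (any(is.na(n_exposure))) {
    rlang::abort(
      "n_exposure is absent for some diseases; use compute_eli() for the base index",
      class = "riskspectra_domain_error"
    )
  }
  if (any(n_exposure < 0)) {
    rlang::abort("n_exposure must be non-negative", class = "riskspectra_domain_error")
  }
  compute_eli(n_disease, n_env, n_lifestyle) + n_exposure / n_disease * 1000
}

#' Per-disease ELI table
#'
#' Computes the ELI (and, where exposure counts are available, the extended
#' ELI) for every disease in a literature-count table, sorted by descending
#' ELI — the ordering used when ranking diseases from most to least
#' environment/lifestyle dependent.
#'
#' @param counts Literature-count tibble as returned by
#'   [read_literature_counts()] or [gen_literature_counts()].
#' @param extended If `TRUE`, require exposure counts and add an `eeli` column;
#'   if `NA` (default), add `eeli` when exposure counts are present.
#' @return Tibble with `disease`, `eli` and optionally `eeli`, sorted by
#'   descending `eli` (ties by case-folded disease name).
#' @export
eli_table <- function(counts, extended = NA) {
  counts <- validate_literature_counts(tibble::as_tibble(counts))
  out <- tibble::tibble(
    disease = counts$disease,
    eli = compute_eli(counts$n_disease, counts$n_env, counts$n_lifestyle)
  )
  has_exposure <- "n_exposure" %in% names(counts) && all(!is.na(counts$n_exposure))
  if (isTRUE(extended) || (is.na(extended) && has_exposure)) {
    out$eeli <- compute_extended_eli(counts$n_disease, counts$n_env,
                                     counts$n_lifestyle, counts$n_exposure)
  }
  dplyr::arrange(out, dplyr::desc(.data$eli), disease_key(.data$disease))
}

#' Split diseases into ELI tertiles
#'
#' Ranks diseases by ascending ELI and splits them into `n_groups` groups of
#' as-equal-as-possible size; when the count does not divide evenly the extra
#' diseases go to the lower-numbered groups. Group 1 holds the lowest-ELI
#' (environment/lifestyle independent) diseases and group `n_groups` the
#' highest. Ties in ELI are broken by ascending case-folded disease name so
#' the partition is deterministic.
#'
#' @param eli_df Tibble with columns `disease` and `eli` (e.g. from
#'   [eli_table()]).
#' @param n_groups Number of groups (default 3, i.e. tertiles).
#' @return The input tibble with an integer `tertile` column, sorted by
#'   ascending ELI.
#' @export
assign_tertiles <- function(eli_df, n_groups = 3) {
  eli_df <- tibble::as_tibble(eli_df)
  if (n_groups < 2) {
    rlang::abort("n_groups must be >= 2", class = "riskspectra_domain_error")
  }
  n <- nrow(eli_df)
  if (n < n_groups) {
    rlang::abort(sprintf("need at least %d diseases to form %d groups", n_groups, n_groups),
                 class = "riskspectra_domain_error")
  }
  out <- dplyr::arrange(eli_df, .data$eli, disease_key(.data$disease))
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  out$tertile <- rep(seq_len(n_groups), times = sizes)
  out
}

#' Rank agreement between ELI and extended ELI
#'
#' Dense-ranks diseases under both indices (rank 1 = highest index) and
#' measures their agreement with a Spearman rank correlation.
#'
#' @param eli_df Tibble with `disease`, `eli` and `eeli` columns; every
#'   disease must carry both indices.
#' @return A list with `ranks` (tibble `disease`, `eli`, `eeli`, `rank_eli`,
#'   `rank_eeli`) and `test` (an `rs_test` from [spearman_test()]).
#' @export
eli_rank_correlation <- function(eli_df) {
  eli_df <- tibble::as_tibble(eli_df)
  if (!all(c("eli", "eeli") %in% names(eli_df))) {
    rlang::abort("eli_df must have 'eli' and 'eeli' columns",
                 class = "riskspectra_domain_error")
  }
  missing <- eli_df$disease[is.na(eli_df$eeli) | is.na(eli_df$eli)]
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "index missing for: %s", paste(missing, collapse = ", ")
    ), class = "riskspectra_domain_error")
  }
  if (nrow(eli_df) < 3) {
    rlang::abort("need at least 3 diseases", class = "riskspectra_domain_error")
  }
  ranks <- dplyr::mutate(
    eli_df,
    rank_eli = dplyr::dense_rank(dplyr::desc(.data$eli)),
    rank_eeli = dplyr::dense_rank(dplyr::desc(.data$eeli))
  )
  list(ranks = ranks, test = spearman_test(eli_df$eli, eli_df$eeli))
}
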