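#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col labs
#'   autoplot geom_errorbar scale_x_continuous geom_hline theme_minimal
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

bin_mid <- function(s) (s$lower + s$upper) / 2

#' Plot a five-bin frequency spectrum
#'
#' Line-and-point plot of bin proportions against bin midpoints, the usual
#' way binned risk-allele spectra are displayed.
#'
#' @param object A `spectrum_bins` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum_bins <- function(object, ...) {
  df <- tibble::tibble(mid = bin_mid(object), proportion = object$proportion)
  ggplot(df, aes(x = .data$mid, y = .data$proportion)) +
    geom_line() +
    geom_point() +
    scale_x_continuous(breaks = bin_mid(object)) +
    labs(x = "risk allele frequency (bin midpoint)", y = "proportion of SNPs") +
    theme_minimal()
}

#' Observed spectrum against its frequency-independence null
#'
#' Overlays the observed risk-allele spectrum (colour) and the mirrored null
#' (black), mimicking the standard presentation of binned spectra with the
#' neutral expectation drawn through them.
#'
#' @param observed,null `spectrum_bins` on the same edges.
#' @param label Label for the observed series.
#' @return A ggplot.
#' @export
plot_spectrum_vs_null <- function(observed, null, label = "observed") {
  df <- dplyr::bind_rows(
    tibble::tibble(mid = bin_mid(observed), proportion = observed$proportion,
                   series = label),
    tibble::tibble(mid = bin_mid(null), proportion = null$proportion,
                   series = "frequency-independence null")
  )
  ggplot(df, aes(x = .data$mid, y = .data$proportion, colour = .data$series)) +
    geom_line() +
    geom_point() +
    scale_x_continuous(breaks = bin_mid(observed)) +
    labs(x = "risk allele frequency (bin midpoint)", y = "proportion of SNPs",
         colour = NULL) +
    theme_minimal()
}

#' Plot per-group MiRA proportions with standard errors
#'
#' Bar chart of MiRA proportions (e.g. per ELI tertile) with +/- 1 SE bars
#' and the 0.5 frequency-independence expectation as a dashed line.
#'
#' @param mira_tbl Tibble from [mira_summary()]; first column is the group.
#' @return A ggplot.
#' @export
plot_mira <- function(mira_tbl) {
  group_col <- names(mira_tbl)[1]
  df <- dplyr::mutate(mira_tbl, .group = factor(.data[[group_col]]))
  ggplot(df, aes(x = .data$.group, y = .data$mira)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mira - .data$se, ymax = .data$mira + .data$se),
                  width = 0.2) +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    labs(x = group_col, y = "MiRA proportion") +
    theme_minimal()
}

#' Plot the MiRA trajectory of a Wright-Fisher run
#'
#' MiRA proportion among segregating loci per generation, with the 0.5
#' neutral expectation dashed.
#'
#' @param object A `wf_sim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wf_sim <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$generation, y = .data$mira)) +
    geom_line() +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    labs(x = "generation since environment change", y = "MiRA proportion") +
    theme_minimal()
}
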