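#' @importFrom stats pt pchisq pf sd var rbinom rpois runif rgamma setNames
NULL

# Every test statistic in the pipeline is computed from first principles here
# (ranks, sums of squares, observed-vs-expected sums); only the tail
# probabilities come from the standard t / chi-square / F distributions.

rs_test <- function(method, statistic, df, p_value, n, note = NA_character_) {
  structure(
    list(method = method, statistic = statistic, df = df,
         p_value = p_value, n = n, note = note),
    class = "rs_test"
  )
}

#' @export
print.rs_test <- function(x, ...) {
  cat(sprintf("<rs_test> %s\n", x$method))
  if (!is.na(x$note)) cat(sprintf("  note: %s\n", x$note))
  cat(sprintf("  statistic = %s, df = %s, p = %s, n = %d\n",
              format(x$statistic, digits = 4),
              paste(x$df, collapse = ", "),
              format(x$p_value, digits = 3), x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname spearman_test
#' @param x An `rs_test` object (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @export
tidy.rs_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    df1 = unname(x$df[1]),
    df2 = if (length(x$df) > 1) unname(x$df[2]) else NA_real_,
    p_value = x$p_value,
    n = x$n,
    note = x$note
  )
}

#' @rdname spearman_test
#' @export
glance.rs_test <- function(x, ...) tidy(x)

# mid-ranks (average ranks for ties), the rank convention all Spearman
# computations in the package share
midrank <- function(x) rank(x, ties.method = "average")

# Pearson correlation written out as sums, used on ranks
pearson_raw <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# all permutations of seq_len(n), one per row; used for exact Spearman p
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1)
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation computed from first principles: both vectors are replaced
#' by mid-ranks (average ranks on ties) and the Pearson correlation of the
#' ranks is evaluated directly. The two-sided p-value uses the large-sample
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom; for very small samples (`n <= 8`) an exact permutation p-value
#' over all `n!` rank permutations is available via `exact = TRUE`.
#'
#' If either vector is constant its ranks are degenerate and the correlation
#' is undefined; the result is returned with `NA` statistic and a
#' `"not computable"` note rather than an error, so callers can report it.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param exact Use the exact permutation null (only for `n <= 8`).
#' @return An `rs_test` with `statistic` = rho.
#' @export
#' @examples
#' spearman_test(1:10, (1:10)^3)$statistic # 1: invariant to monotone maps
spearman_test <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n) {
    rlang::abort("x and y must have equal length", class = "riskspectra_domain_error")
  }
  if (n < 3) {
    rlang::abort("need n >= 3", class = "riskspectra_domain_error")
  }
  if (anyNA(x) || anyNA(y)) {
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]; n <- length(x)
    if (n < 3) rlang::abort("need n >= 3 complete pairs", class = "riskspectra_domain_error")
  }
  rx <- midrank(x)
  ry <- midrank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    return(rs_test("Spearman rank correlation", NA_real_, c(df = n - 2),
                   NA_real_, n, note = "not computable: degenerate ranks"))
  }
  rho <- pearson_raw(rx, ry)
  if (isTRUE(exact)) {
    if (n > 8) {
      rlang::abort("exact permutation p-value is only available for n <= 8",
                   class = "riskspectra_domain_error")
    }
    perms <- permutations(n)
    rho_perm <- apply(perms, 1, function(idx) pearson_raw(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    return(rs_test("Spearman rank correlation (exact)", rho, c(df = NA_real_), p, n))
  }
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  rs_test("Spearman rank correlation", rho, c(df = n - 2), p, n)
}

#' Chi-square goodness-of-fit test
#'
#' Pearson's statistic `sum((O - E)^2 / E)` comparing observed counts with
#' counts expected under given proportions, on `k - 1` degrees of freedom.
#' Expected proportions may be supplied on any scale (weights); they are
#' normalised to sum to 1.
#'
#' @param observed Non-negative counts.
#' @param expected_prop Expected proportions (or weights), same length,
#'   strictly positive after normalisation.
#' @return An `rs_test`.
#' @export
chi2_gof <- function(observed, expected_prop) {
  if (length(observed) != length(expected_prop)) {
    rlang::abort("observed and expected_prop must have equal length",
                 class = "riskspectra_domain_error")
  }
  if (any(observed < 0)) {
    rlang::abort("counts must be non-negative", class = "riskspectra_domain_error")
  }
  prop <- expected_prop / sum(expected_prop)
  if (any(prop <= 0)) {
    rlang::abort("expected proportions must be strictly positive",
                 class = "riskspectra_domain_error")
  }
  n <- sum(observed)
  expected <- n * prop
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  rs_test("chi-square goodness of fit", stat, c(df = df),
          pchisq(stat, df, lower.tail = FALSE), n)
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson's chi-square on a 2x2 table with expected counts from the margins,
#' without Yates continuity correction, on 1 degree of freedom. An expected
#' cell below 1 attaches a small-sample warning note to the result instead of
#' failing.
#'
#' @param tab A 2x2 numeric matrix of counts.
#' @return An `rs_test`.
#' @export
chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) {
    rlang::abort("tab must be 2x2", class = "riskspectra_domain_error")
  }
  if (any(tab < 0)) {
    rlang::abort("counts must be non-negative", class = "riskspectra_domain_error")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0)) {
    rlang::abort("a margin of the table is zero; expected counts undefined",
                 class = "riskspectra_domain_error")
  }
  note <- NA_character_
  if (any(expected < 1)) note <- "expected cell count < 1; p-value unreliable"
  stat <- sum((tab - expected)^2 / expected)
  rs_test("chi-square 2x2", stat, c(df = 1),
          pchisq(stat, 1, lower.tail = FALSE), n, note = note)
}

#' One-way ANOVA on a binary indicator
#'
#' Classical one-way analysis of variance applied to a 0/1 indicator (here:
#' whether a risk allele is minor), with the F statistic built from explicit
#' sums of squares: between-group `sum n_g (m_g - m)^2` over `k - 1` df and
#' within-group residual sum of squares over `N - k` df. Groups of size one
#' contribute nothing to the within-group df (it is pooled across groups);
#' if every group has size one there is no residual df and the test is
#' undefined.
#'
#' @param indicator Numeric or logical 0/1 vector.
#' @param group Group labels, same length.
#' @return An `rs_test` with `statistic` = F and `df = c(df1, df2)`.
#' @export
anova_binary <- function(indicator, group) {
  indicator <- as.numeric(indicator)
  if (length(indicator) != length(group)) {
    rlang::abort("indicator and group must have equal length",
                 class = "riskspectra_domain_error")
  }
  if (!all(indicator %in% c(0, 1))) {
    rlang::abort("indicator must be 0/1", class = "riskspectra_domain_error")
  }
  group <- as.factor(as.character(group))
  k <- nlevels(group)
  if (k < 2) {
    rlang::abort("need at least 2 groups", class = "riskspectra_domain_error")
  }
  N <- length(indicator)
  if (N == k) {
    rlang::abort("all groups have size 1: no within-group degrees of freedom",
                 class = "riskspectra_domain_error")
  }
  ng <- tapply(indicator, group, length)
  mg <- tapply(indicator, group, mean)
  m <- mean(indicator)
  ssb <- sum(ng * (mg - m)^2)
  ssw <- sum((indicator - mg[group])^2)
  df1 <- k - 1
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  fstat <- if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
  p <- if (is.infinite(fstat)) 0 else pf(fstat, df1, df2, lower.tail = FALSE)
  rs_test("one-way ANOVA (binary indicator)", fstat, c(df1 = df1, df2 = df2), p, N)
}
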