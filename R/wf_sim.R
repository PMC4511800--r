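#' Selection-coefficient samplers
#'
#' Constructors for the per-locus selection-coefficient distribution of the
#' Wright-Fisher simulator. The simulator's convention is that `s` is the
#' cost of carrying the *risk* allele: `s > 0` means the risk allele is
#' deleterious (negative selection), `s = 0` neutral, and `s < 0`
#' advantageous. `wf_s_const()` assigns the same coefficient to every locus;
#' `wf_s_gamma()` draws coefficients from a gamma distribution (scaled by
#' `sign`), giving the heterogeneous selection profile of an environment
#' change that reassigns selective values across standing variants.
#'
#' @param s Constant selection coefficient, `s < 1`.
#' @param shape,scale Gamma parameters for the magnitude of `s`.
#' @param sign `+1` for deleterious risk alleles (default), `-1` for
#'   advantageous.
#' @return A function `f(n)` returning `n` selection coefficients.
#' @export
wf_s_const <- function(s) {
  if (any(s >= 1)) rlang::abort("s must be < 1", class = "riskspectra_domain_error")
  force(s)
  function(n) rep(s, n)
}

#' @rdname wf_s_const
#' @export
wf_s_gamma <- function(shape, scale, sign = 1) {
  function(n) {
    out <- sign * rgamma(n, shape = shape, scale = scale)
    pmin(out, 1 - 1e-9) # gamma tails can exceed the s < 1 support
  }
}

#' Wright-Fisher simulation configuration
#'
#' Parameters of the forward simulation of the recently-neutral,
#' currently-deleterious risk-allele model: a set of independent biallelic
#' loci carrying standing variation shaped by neutrality, whose risk alleles
#' acquire selection coefficients at an environment change (generation 0) and
#' then evolve under genic selection and binomial drift.
#'
#' @param n_loci Number of independent loci (>= 1).
#' @param pop_size Diploid population size N (>= 1); drift samples 2N allele
#'   copies per generation.
#' @param generations Number of generations after the environment change.
#' @param s_dist Selection-coefficient sampler (see [wf_s_const()]).
#' @param init Initial-frequency mode: `"folded_neutral"` draws the minor
#'   allele frequency with density proportional to `1/f` on `(1/(2N), 0.5]`
#'   (the folded neutral spectrum) and labels the risk allele minor or major
#'   with probability 1/2 each — frequency-independent risk assignment, so
#'   the expected starting MiRA is 0.5; `"uniform"` draws the risk-allele
#'   frequency uniformly on `(1/(2N), 1 - 1/(2N))`.
#' @param seed Integer seed; a run is fully reproducible from `seed` plus the
#'   configuration.
#' @return A `wf_config` list.
#' @seealso [wf_run()]
#' @export
wf_config <- function(n_loci = 5000, pop_size = 10000, generations = 500,
                      s_dist = wf_s_const(0.01),
                      init = c("folded_neutral", "uniform"), seed = 1) {
  init <- match.arg(init)
  stopifnot(n_loci >= 1, pop_size >= 1, generations >= 0)
  structure(
    list(n_loci = as.integer(n_loci), pop_size = as.integer(pop_size),
         generations = as.integer(generations), s_dist = s_dist,
         init = init, seed = as.integer(seed)),
    class = "wf_config"
  )
}

#' Draw initial risk-allele frequencies
#'
#' @param n_loci Number of loci.
#' @param pop_size Diploid population size.
#' @param init `"folded_neutral"` or `"uniform"` (see [wf_config()]).
#' @return Numeric vector of risk-allele frequencies in (0, 1).
#' @export
wf_init_frequencies <- function(n_loci, pop_size, init = "folded_neutral") {
  f0 <- 1 / (2 * pop_size)
  if (init == "uniform") {
    return(runif(n_loci, f0, 1 - f0))
  }
  # inverse-CDF draw from density ~ 1/f on (f0, 0.5]:
  # F(f) = log(f/f0) / log(0.5/f0)  =>  f = f0 * (0.5/f0)^u
  maf <- f0 * (0.5 / f0)^runif(n_loci)
  risk_is_minor <- runif(n_loci) < 0.5
  ifelse(risk_is_minor, maf, 1 - maf)
}

#' One Wright-Fisher generation
#'
#' Deterministic genic selection against the risk allele,
#' `f* = f (1 - s) / (1 - s f)`, followed (optionally) by binomial drift:
#' the next frequency is `Binomial(2N, f*) / 2N`. Frequencies 0 and 1 are
#' absorbing. `s` may be a scalar or per-locus vector; negative `s` models an
#' advantageous risk allele.
#'
#' @param freqs Current risk-allele frequencies in `[0, 1]`.
#' @param s Selection coefficient(s), each `< 1`.
#' @param pop_size Diploid population size.
#' @param drift If `FALSE`, return the deterministic post-selection
#'   frequencies (the infinite-population limit).
#' @return Next-generation frequencies.
#' @export
wf_step <- function(freqs, s, pop_size, drift = TRUE) {
  if (any(s >= 1)) rlang::abort("s must be < 1", class = "riskspectra_domain_error")
  if (any(freqs < 0 | freqs > 1)) {
    rlang::abort("frequencies must lie in [0, 1]", class = "riskspectra_domain_error")
  }
  fstar <- freqs * (1 - s) / (1 - s * freqs)
  if (!drift) return(fstar)
  rbinom(length(fstar), 2 * pop_size, fstar) / (2 * pop_size)
}

segregating_mira <- function(freqs) {
  seg <- freqs > 0 & freqs < 1
  if (!any(seg)) return(NA_real_)
  mean(freqs[seg] < 0.5)
}

#' Run a Wright-Fisher simulation
#'
#' Initialises standing variation, assigns each locus a selection
#' coefficient from the configured sampler (the environment change), and
#' iterates selection + drift for the configured number of generations.
#' The MiRA proportion — the fraction of risk alleles below frequency 0.5,
#' taken over segregating loci (`0 < f < 1`), since fixed or lost alleles are
#' no longer observable polymorphisms — is recorded every generation, and
#' five-bin spectra are kept for generation 0 and the final generation.
#'
#' @param config A [wf_config()].
#' @return A `wf_sim` object: list with `config`, `s` (per-locus
#'   coefficients), `freq_t0`, `freq_tT`, `mira_trajectory` (length
#'   `generations + 1`, starting at generation 0), `spectrum_t0`,
#'   `spectrum_tT` (on segregating loci), and `left_shift` =
#'   [spectrum_asymmetry()] of the final spectrum against the initial one.
#'   Identical seed and configuration give bit-identical results.
#' @export
wf_run <- function(config) {
  stopifnot(inherits(config, "wf_config"))
  set.seed(config$seed)
  freqs <- wf_init_frequencies(config$n_loci, config$pop_size, config$init)
  s <- config$s_dist(config$n_loci)
  freq_t0 <- freqs
  mira <- numeric(config$generations + 1)
  mira[1] <- segregating_mira(freqs)
  if (config$generations > 0) {
    for (t in seq_len(config$generations)) {
      freqs <- wf_step(freqs, s, config$pop_size)
      mira[t + 1] <- segregating_mira(freqs)
    }
  }
  seg0 <- freq_t0 > 0 & freq_t0 < 1
  segT <- freqs > 0 & freqs < 1
  sp0 <- bin_spectrum(freq_t0[seg0])
  spT <- if (any(segT)) bin_spectrum(freqs[segT]) else NULL
  structure(
    list(config = config, s = s, freq_t0 = freq_t0, freq_tT = freqs,
         mira_trajectory = mira, spectrum_t0 = sp0, spectrum_tT = spT,
         left_shift = if (is.null(spT)) NA_real_ else spectrum_asymmetry(spT, sp0)),
    class = "wf_sim"
  )
}

#' @export
print.wf_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<wf_sim> %d loci, N = %d, %d generations (seed %d)\n",
              cfg$n_loci, cfg$pop_size, cfg$generations, cfg$seed))
  cat(sprintf("  MiRA: %.3f (t = 0) -> %.3f (t = %d); left shift %.3f\n",
              x$mira_trajectory[1], utils::tail(x$mira_trajectory, 1),
              cfg$generations, x$left_shift))
  invisible(x)
}

#' Tidy a Wright-Fisher run
#'
#' `tidy()` returns the per-generation MiRA trajectory; `glance()` a one-row
#' summary with the endpoints and the left-shift score.
#'
#' @param x A `wf_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wf_sim <- function(x, ...) {
  tibble::tibble(
    generation = seq_along(x$mira_trajectory) - 1L,
    mira = x$mira_trajectory
  )
}

#' @rdname tidy.wf_sim
#' @export
glance.wf_sim <- function(x, ...) {
  tibble::tibble(
    n_loci = x$config$n_loci,
    pop_size = x$config$pop_size,
    generations = x$config$generations,
    seed = x$config$seed,
    mira_t0 = x$mira_trajectory[1],
    mira_tT = utils::tail(x$mira_trajectory, 1),
    left_shift = x$left_shift,
    n_segregating_tT = sum(x$freq_tT > 0 & x$freq_tT < 1)
  )
}
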