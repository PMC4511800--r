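#' Synthetic-data generator specification
#'
#' Controls the generator that emulates every pipeline input: a
#' disease-by-SNP association table with a tunable excess of minor risk
#' alleles, Poisson-sampled literature counts with known true ELI, and
#' platform manifests plus a positively-selected SNP set with a known
#' selected fraction. Because every parameter is known, the pipeline's
#' estimates can be checked for parameter recovery.
#'
#' The key knob is `delta`, the per-disease left-shift strength in `[0, 1]`:
#' the risk allele is the minor allele with probability `1/2 + delta/2`, so
#' the expected MiRA proportion is `0.5 + delta/2` — `delta = 0` is the
#' frequency-independence null and `delta = 1` makes every risk allele
#' minor. By default `delta` decreases linearly in the disease's true ELI,
#' encoding the hypothesis under study: diseases with strong
#' environment/lifestyle components carry recently-neutral risk alleles
#' (weak left shift), diseases with weak environmental components carry
#' anciently selected ones (strong left shift).
#'
#' @param n_diseases Number of diseases (default 25, the size of a
#'   well-populated per-disease MiRA table).
#' @param snps_per_disease Inclusive range of reported SNPs per disease
#'   (default `c(20, 150)`, matching the spread seen across well-studied
#'   diseases).
#' @param true_eli Per-disease true ELI values; default a geometric ladder
#'   from 110 down to 10 papers per 1,000, the observed dynamic range of the
#'   index.
#' @param delta Per-disease left-shift strengths in `[0, 1]`; default the
#'   decreasing-in-ELI linear map `delta_max * (max(eli) - eli) / diff(range(eli))`.
#' @param delta_max Maximum of the default delta map (default 0.3).
#' @param n_pubs Abstracts mentioning each disease (scalar or per-disease;
#'   default 100,000).
#' @param exposure If `TRUE`, also generate "exposure" co-mention counts
#'   (at `exposure_frac` times the true ELI rate) for extended-ELI work.
#' @param exposure_frac Exposure rate as a fraction of the true ELI
#'   (default 0.5).
#' @param universe_size SNP universe for platform sampling (default 500,000).
#' @param platform_sizes Manifest sizes (default three platforms of 50k,
#'   100k and 200k SNPs).
#' @param q True fraction of the universe carrying a positive-selection
#'   signature (default 0.0075, i.e. 0.75%).
#' @param n_gwas Number of GWAS-reported SNPs to sample (default 2,000).
#' @param enrichment Enrichment `e` of selected SNPs among GWAS-reported
#'   ones: expected GWAS overlap is `q * e` (default 1 = null mode; requires
#'   `q * e <= 1`).
#' @param size_effect If `TRUE` (default), the probability that a reported
#'   SNP is rare (MAF <= 0.05) increases with the study's sample size,
#'   emulating the power of large GWAS to detect rare variants; the risk
#'   *direction* never depends on sample size in either mode.
#' @param seed Integer seed; all `gen_*` output is a deterministic function
#'   of the spec.
#' @return A `synth_spec` list.
#' @seealso [gen_association_table()], [gen_literature_counts()],
#'   [gen_platform_data()], [write_input_bundle()]
#' @export
synth_spec <- function(n_diseases = 25,
                       snps_per_disease = c(20, 150),
                       true_eli = NULL,
                       delta = NULL,
                       delta_max = 0.3,
                       n_pubs = 1e5,
                       exposure = FALSE,
                       exposure_frac = 0.5,
                       universe_size = 5e5,
                       platform_sizes = c(platform_A = 5e4, platform_B = 1e5, platform_C = 2e5),
                       q = 0.0075,
                       n_gwas = 2000,
                       enrichment = 1,
                       size_effect = TRUE,
                       seed = 1) {
  stopifnot(n_diseases >= 1, length(snps_per_disease) == 2,
            snps_per_disease[1] >= 1, diff(snps_per_disease) >= 0)
  if (is.null(true_eli)) {
    true_eli <- exp(seq(log(110), log(10), length.out = n_diseases))
  }
  stopifnot(length(true_eli) == n_diseases, all(true_eli >= 0))
  if (is.null(delta)) {
    rng <- range(true_eli)
    delta <- if (diff(rng) == 0) rep(0, n_diseases) else
      delta_max * (rng[2] - true_eli) / diff(rng)
  }
  stopifnot(length(delta) == n_diseases, all(delta >= 0 & delta <= 1))
  if (q < 0 || q > 1) rlang::abort("q must lie in [0, 1]", class = "riskspectra_domain_error")
  if (q * enrichment > 1) {
    rlang::abort("q * enrichment exceeds 1: expected overlap is not a proportion",
                 class = "riskspectra_domain_error")
  }
  n_pubs <- rep_len(n_pubs, n_diseases)
  structure(
    list(n_diseases = n_diseases, diseases = sprintf("disease_%02d", seq_len(n_diseases)),
         snps_per_disease = snps_per_disease, true_eli = true_eli, delta = delta,
         n_pubs = n_pubs, exposure = exposure, exposure_frac = exposure_frac,
         universe_size = as.integer(universe_size),
         platform_sizes = platform_sizes, q = q, n_gwas = as.integer(n_gwas),
         enrichment = enrichment, size_effect = size_effect,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# ascertainment-like MAF draw: bell-shaped on (0.05, 0.5), emulating the
# over-representation of common SNPs on genotyping platforms
draw_maf <- function(n) 0.05 + 0.45 * stats::rbeta(n, 2, 2)

#' Generate a synthetic association table
#'
#' Per disease, draws a MAF for each SNP from a bell-shaped
#' (Beta(2,2)-based) ascertainment distribution on (0.05, 0.5), then labels
#' the *minor* allele as the risk allele with probability
#' `1/2 + delta/2` (else the major allele), so the expected MiRA proportion
#' is exactly `0.5 + delta/2`. Sample sizes are log-normal around 20,000;
#' with `size_effect = TRUE`, larger studies draw a rare MAF
#' (uniform on (0.01, 0.05)) with a probability increasing in log sample
#' size. Output passes [read_association_table()] validation.
#'
#' @param spec A [synth_spec()].
#' @return Association tibble (`disease`, `snp_id`, `risk_allele_freq`,
#'   `sample_size`, `p_value`).
#' @export
gen_association_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  lo <- spec$snps_per_disease[1]
  hi <- spec$snps_per_disease[2]
  # sample() treats a length-1 vector as 1:x, so guard the degenerate range
  n_per <- if (lo == hi) rep(lo, spec$n_diseases) else
    sample(seq(lo, hi), spec$n_diseases, replace = TRUE)
  total <- sum(n_per)
  ids <- sprintf("rs%08d", sample.int(9.9e7, total))
  disease <- rep(spec$diseases, times = n_per)
  delta <- rep(spec$delta, times = n_per)
  sample_size <- round(stats::rlnorm(total, meanlog = log(2e4), sdlog = 0.6))
  maf <- draw_maf(total)
  if (spec$size_effect) {
    # detection of rare variants scales with study size; ~4% of reported
    # SNPs are rare at the median study size, rising steeply with n
    p_rare <- stats::plogis(-3.2 + 1.5 * (log(sample_size) - log(2e4)))
    rare <- runif(total) < p_rare
    maf[rare] <- runif(sum(rare), 0.01, 0.05)
  }
  minor_is_risk <- runif(total) < 0.5 + delta / 2
  tibble::tibble(
    disease = disease,
    snp_id = ids,
    risk_allele_freq = ifelse(minor_is_risk, maf, 1 - maf),
    sample_size = sample_size,
    p_value = 10^runif(total, -20, log10(5e-8))
  )
}

#' Generate synthetic literature counts
#'
#' Per disease, the total number of environment/lifestyle co-mentions is
#' drawn as `Poisson(true_eli * n_pubs / 1000)` and split binomially
#' (p = 1/2) between the "environment" and "lifestyle" terms, so the
#' estimated ELI is unbiased for the true ELI. With `exposure = TRUE` an
#' independent `Poisson(exposure_frac * true_eli * n_pubs / 1000)` exposure
#' count is added.
#'
#' @param spec A [synth_spec()].
#' @return Literature-count tibble (passes [read_literature_counts()]
#'   validation).
#' @export
gen_literature_counts <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 1L)
  lambda <- spec$true_eli * spec$n_pubs / 1000
  total <- rpois(spec$n_diseases, lambda)
  total <- pmin(total, spec$n_pubs) # co-mentions cannot exceed disease mentions
  n_env <- rbinom(spec$n_diseases, total, 0.5)
  out <- tibble::tibble(
    disease = spec$diseases,
    n_disease = spec$n_pubs,
    n_env = n_env,
    n_lifestyle = total - n_env
  )
  if (spec$exposure) {
    out$n_exposure <- pmin(
      rpois(spec$n_diseases, spec$exposure_frac * lambda), spec$n_pubs)
  }
  out
}

#' Generate platform manifests, a selected-SNP set and a GWAS SNP set
#'
#' Builds a SNP universe, marks a fraction `q` of it as carrying a
#' positive-selection signature, samples each platform manifest uniformly
#' from the universe (so every platform's expected overlap is `q`), and
#' samples a GWAS-reported set whose expected overlap is `q * enrichment`
#' (the number of selected GWAS SNPs is `Binomial(n_gwas, q * e)`).
#'
#' @param spec A [synth_spec()].
#' @return List with `platforms` (named list of id vectors), `selected`
#'   (id vector) and `gwas` (id vector).
#' @export
gen_platform_data <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 2L)
  universe <- sprintf("rs%d", seq_len(spec$universe_size))
  n_sel <- round(spec$q * spec$universe_size)
  selected <- sample(universe, n_sel)
  platforms <- lapply(spec$platform_sizes, function(sz) sample(universe, sz))
  names(platforms) <- names(spec$platform_sizes) %||%
    sprintf("platform_%d", seq_along(spec$platform_sizes))
  p_gwas_sel <- spec$q * spec$enrichment
  n_gwas_sel <- rbinom(1, spec$n_gwas, p_gwas_sel)
  not_selected <- setdiff(universe, selected)
  gwas <- c(sample(selected, min(n_gwas_sel, length(selected))),
            sample(not_selected, spec$n_gwas - min(n_gwas_sel, length(selected))))
  list(platforms = platforms, selected = selected, gwas = gwas)
}

#' Write a complete synthetic input bundle
#'
#' Generates every pipeline input from one spec and writes it under `dir`:
#' `associations.tsv`, `literature_counts.tsv`, one `manifest_<name>.txt`
#' per platform, `selected_snps.txt` and `gwas_snps.txt`. Identical specs
#' produce byte-identical files.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_input_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  assoc <- gen_association_table(spec)
  counts <- gen_literature_counts(spec)
  plat <- gen_platform_data(spec)
  paths <- list(
    associations = file.path(dir, "associations.tsv"),
    counts = file.path(dir, "literature_counts.tsv"),
    selected = file.path(dir, "selected_snps.txt"),
    gwas = file.path(dir, "gwas_snps.txt")
  )
  write_association_table(assoc, paths$associations)
  write_literature_counts(counts, paths$counts)
  write_snp_ids(plat$selected, paths$selected)
  write_snp_ids(plat$gwas, paths$gwas)
  paths$manifests <- vapply(names(plat$platforms), function(nm) {
    p <- file.path(dir, sprintf("manifest_%s.txt", nm))
    write_snp_ids(plat$platforms[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
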