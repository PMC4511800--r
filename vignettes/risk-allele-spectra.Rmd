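---
title: "Methods: allelic spectra of risk alleles under negative selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic spectra of risk alleles under negative selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskspectra)
```

## The scientific question

Most standing genetic variation is selectively neutral, but an allele's
selective value depends on the environment. When lifestyle or environment
changes, some previously neutral variants become disease risk alleles. The
package is built around one observable consequence: negative selection
against a risk allele lowers its frequency over generations, so a class of
risk alleles under long-standing selection becomes enriched for *minor*
alleles (frequency < 50%) and its frequency spectrum shifts left. Risk
alleles recruited *recently* from the neutral pool have not had time to
respond, so their spectrum still looks neutral. If environment/lifestyle
dependent diseases disproportionately carry recently recruited risk
alleles, their spectra should be more symmetric than those of
environment-independent diseases.

`riskspectra` operationalises each piece of that argument: a literature
index to order diseases by environmental dependence, MiRA and binned
spectra to quantify the left shift, an empirical null for "no
frequency-direction preference", overlap statistics for positive
selection, and a forward simulator of the model itself.

## The statistics

**ELI.** For each disease, `ELI = (n_env + n_lifestyle) / n_disease * 1000`
(papers per 1,000 disease papers). The unit makes indices comparable across
diseases with very different literature volumes; the index is invariant to
scaling all three counts. The extended index adds an `n_exposure` term to
the numerator. Both sum term-level counts, so an abstract matching two
terms counts twice; this follows the base index's worked definition, and we
apply the same reading to the extended index for consistency. Diseases are
ranked by ELI and split into tertiles: ascending ELI order, groups as equal
as possible, remainder diseases placed in the lower-numbered (lower-ELI)
groups, ties broken by case-folded disease name. The remainder and
tie-break rules are the package's own choices — any fixed rule would do;
these make the partition deterministic and reproducible.

**MiRA.** For a group of `n` risk alleles, the MiRA proportion `p` is the
fraction with control frequency `f < 0.5`, with standard error
`sqrt(p(1-p)/n)` — the binomial SE, which is the natural choice for a
proportion of independent SNPs and reproduces published per-disease SE
columns. A frequency of exactly 0.5 counts as non-minor (the minor/major
dichotomy is defined by strict inequalities; the event is logged when it
occurs, since with measured frequencies it usually indicates rounding in
the source data).

**Spectra and the null.** Frequencies are binned into five fixed intervals
`(0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8), [0.8,1)` — lower edges closed
from the second bin on — and normalised. The null spectrum gives each SNP
weight ½ at `f` and ½ at `1−f`. This *empirical mirrored null* encodes
exactly "the probability of being risk-associated is independent of
frequency" while inheriting the real data's ascertainment shape: GWAS
spectra are bell-shaped (platforms over-represent common SNPs and studies
are underpowered for rare ones), so a parametric neutral site-frequency
spectrum (∝ 1/f) would be the wrong reference for observed data. The
left-shift score is the observed-minus-null mass below 0.4; positive values
indicate the negative-selection footprint.

**Inference.** Spearman rank correlation (mid-ranks, Pearson on ranks),
chi-square tests (goodness-of-fit and 2×2 without continuity correction —
at the sample sizes involved the correction is negligible) and one-way
ANOVA on the 0/1 minor-risk indicator are implemented from explicit sums;
only the t, chi-square and F tail probabilities come from the standard
distributions. The Spearman p-value uses the t approximation
`t = rho * sqrt((n−2)/(1−rho²))`, adequate at the hundreds-to-thousands of
records the pipeline handles; an exact permutation p is offered for
`n ≤ 8`, where full enumeration (at most 8! = 40,320 permutations) is
cheap — beyond that the enumeration cost grows factorially and the
approximation is already accurate. ANOVA on the SNP-level binary indicator
reports both degree-of-freedom components (`k−1`, `N−k`); groups of size
one simply contribute no within-group df. Multiple testing across platform
comparisons uses Bonferroni (`min(1, p·k)`), the strictest standard choice.
Chi-square comparisons with an expected cell below 1 attach a warning note
rather than failing, so pipelines can surface rather than hide fragile
cells.

**Overlap.** The positively-selected SNP set is an *input* (a curated id
list); the package never recomputes selection scans. Overlap is plain set
intersection with the same binomial SE machinery, reported in percentage
points. The pooled platform summary is the unweighted mean ± SD of
per-platform percentages.

## The Wright–Fisher simulator

The conceptual model — an environment change reassigns selection
coefficients across standing neutral variants — is simulated forward:

- **Initial state.** `folded_neutral` mode draws each locus's minor-allele
  frequency with density ∝ 1/f on `(1/(2N), 0.5]` (the classical neutral
  folded spectrum, sampled by inverse CDF) and labels the risk allele minor
  or major with probability ½ each, so the expected starting MiRA is 0.5.
  The pre-change neutral history is represented by this initial
  distribution rather than simulated — the claim under study concerns what
  happens *after* the change. A `uniform` mode exists for sensitivity
  checks.
- **Dynamics.** Per generation, deterministic genic selection against the
  risk allele, `f* = f(1−s)/(1−s f)`, then binomial drift
  `f' = Binomial(2N, f*)/(2N)`. Genic (per-copy) selection is used because
  no dominance structure is specified by the model; it equals additive
  diploid selection to first order, and dominance is left as an extension
  point of the coefficient sampler. Loci evolve independently (the
  argument is per-locus; no linkage, recombination or demography beyond
  constant `N`). Boundaries 0 and 1 are absorbing.
- **Coefficients.** `wf_s_const(s)` or `wf_s_gamma(shape, scale, sign)`;
  `s > 0` is deleterious, `s < 0` advantageous (the advantageous side of
  the model is representable but defaults are deleterious-only, matching
  the focus on risk alleles). `s < 1` is enforced.
- **Output.** MiRA per generation and five-bin spectra at `t = 0` and
  `t = T`, both computed over *segregating* loci (`0 < f < 1`): fixed and
  lost alleles are no longer observable polymorphisms, which mirrors how
  real GWAS data condition on segregation. A run is a pure function of
  `(seed, config)`.

Defaults (`n_loci = 5000`, `N = 10,000`, `T = 500`, `s = 0.01`) put the
simulation in the regime the model describes — selection strong enough
(`2Ns = 200`) to reshape spectra within hundreds of generations — and are
labelled illustrative: the model itself specifies no quantitative
coefficient distribution or timescale beyond "tens to hundreds of
generations, depending on selective pressure".

## The synthetic-data generator

The generator exists so every stage is testable without downloads, and so
the pipeline can be checked for *parameter recovery*:

- **Associations.** Per disease, MAF ~ `0.05 + 0.45·Beta(2,2)` — a
  bell-shaped ascertainment-like distribution mimicking the shape of
  GWAS-detected SNP frequencies (platforms favour common SNPs); the risk
  allele is the *minor* allele with probability `½ + δ/2`, so
  `E[MiRA] = 0.5 + δ/2` exactly and the left-shift strength δ ∈ [0,1] is
  recoverable as `2·(MiRA − 0.5)`. By default δ decreases linearly in the
  disease's true ELI (maximum 0.3 at the lowest ELI), encoding the
  hypothesis under study so that preset scenarios show a tertile gradient.
  Sample sizes are log-normal around 20,000; with `size_effect = TRUE` the
  probability that a record is rare (MAF ≤ 0.05, the closed-threshold
  convention) follows `plogis(-3.2 + 1.5·(log n − log 20000))`, about 4%
  at the median size — realistic for GWAS catalogs and large enough that
  the designed rare-vs-size correlation is detectable — while the risk
  *direction* never depends on sample size in any mode.
- **Literature counts.** Total co-mentions ~ `Poisson(ELI·n_pubs/1000)`,
  split binomially between "environment" and "lifestyle", so the estimated
  ELI is unbiased for the true ELI and independent of the publication
  volume.
- **Platforms.** A SNP universe with a fraction `q` (default 0.0075,
  i.e. 0.75%) marked selected; manifests sampled uniformly (expected
  overlap `q`), and a GWAS-reported set with expected overlap
  `q·enrichment` (the selected count is `Binomial(n_gwas, q·e)`).

What the generator does **not** emulate: linkage disequilibrium between
SNPs, genotyping error, per-study heterogeneity beyond sample size,
synonym structure in disease labels, or any real ascertainment pipeline.
Tests passing on generated data therefore demonstrate that the statistics
recover the parameters of *this* data-generating process, not that the
biological conclusions hold for any particular real catalog.

## Numerical and interface conventions

- Internal values are never rounded; comparisons against published tables
  use explicit round-half-up (`round_half_up()`), since half-even rounding
  would disagree with how printed tables are conventionally rounded.
- Readers are strict: thousands separators, out-of-range frequencies and
  inverted count relationships fail with row-addressed errors; values are
  never silently coerced. Disease labels join case-insensitively after
  trimming, with no fuzzy matching.
- Degenerate statistics (constant ranks, empty groups) return explicit
  "not computable" results or errors rather than NaNs.
- The pipeline deduplicates repeated disease–SNP pairs keeping the
  smallest p-value, filters at genome-wide significance `5e-8` by default,
  requires 20 SNPs per disease for MiRA tables and 50 for per-disease
  spectra (below those counts the proportion/spectrum estimates are too
  noisy to display), and logs every record kept or dropped so that
  input = kept + dropped at each stage.
- The whole analysis is callable from R (`run_pipeline()` plus the
  exported building blocks); outputs are plain TSV so runs diff cleanly,
  and reruns on identical inputs are byte-identical.

## Test problem sizes

The test suite checks stochastic properties at sizes chosen to make the
Monte-Carlo noise floor explicit: 50 replicates of 10,000 SNPs for the
null-MiRA recovery (tolerance `3·sqrt(0.25/500000)`), 20 seeded runs of
the 5,000-locus/`N = 10,000`/500-generation simulation for the
direction-of-shift property (≥ 95% of seeds), 500–600 replicates for
drift-martingale checks, 100 fuzzed instances for statistic/oracle
equivalence at `1e-10`, and 2,000 null simulations for the ANOVA type-I
error (band `0.05 ± 3·sqrt(0.05·0.95/2000)`).

## Known limitations

- The ELI depends on literature coverage, not biology: heavily studied
  exposures inflate the index, and term-level counts can double-count
  abstracts. The extended index exists precisely to probe that
  sensitivity.
- The mirrored null conditions on the observed frequencies; it tests
  direction-independence, not neutrality of the underlying SNP set.
- Published summary tables are reproduced only where they are internally
  consistent; rows whose printed ratio or SE disagrees with their own
  printed counts are documented exclusions in the tests rather than
  targets.
- The simulator's constant-`N`, no-linkage assumptions make it a model
  demonstration, not a demographic inference tool.
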