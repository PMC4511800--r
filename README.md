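# riskspectra

Negative selection against disease risk alleles leaves a footprint in
population data: risk alleles drift to lower frequencies than the neutral
expectation, so they become over-represented among *minor* alleles
(frequency < 50%). `riskspectra` provides the statistical toolkit for
detecting and interpreting that footprint in GWAS-reported associations,
and for asking whether it differs between diseases driven by
environment/lifestyle and diseases that are not. It is aimed at population
and statistical geneticists working with GWAS-catalog-style association
tables.

The package has five building blocks:

- **Environment/Lifestyle Index (ELI)** — a literature co-occurrence
  measure of how environment/lifestyle-dependent a disease is:

  `ELI = (n_env + n_lifestyle) / n_disease × 1000`,

  the number of abstracts co-mentioning the disease with "environment" or
  "lifestyle" per 1,000 abstracts mentioning the disease (for rheumatoid
  arthritis, (1,578 + 393)/120,346 × 1000 = 16.4). An extended index adds
  an "exposure" term. Diseases are ranked and split into ELI tertiles.
- **MiRA statistics** — the Minor-Risk-Allele proportion `p` of a SNP
  group, with binomial standard error `sqrt(p(1−p)/n)`. Under
  frequency-independent risk assignment `E[p] = 0.5`; negative selection
  pushes it above 0.5.
- **Binned spectra vs a frequency-independence null** — risk-allele
  frequencies binned into `(0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8),
  [0.8,1)` and compared against an empirical null in which each SNP's two
  alleles carry weight ½ at `f` and ½ at `1−f`; the left-shift score is
  the excess observed mass below 0.4.
- **Positive-selection overlap** — the percentage of a genotyping
  platform's SNPs (or of GWAS-reported SNPs) that appear in a
  positively-selected SNP list, with pairwise chi-square comparisons under
  Bonferroni adjustment.
- **A Wright–Fisher simulator** of the *recently neutral, currently
  deleterious* model: standing neutral variation whose risk alleles
  acquire a selection coefficient `s` at an environment change, updated by
  genic selection `f* = f(1−s)/(1−s f)` plus binomial drift
  `Binomial(2N, f*)/2N`.

Spearman rank correlation, chi-square tests and one-way ANOVA on the
minor-risk indicator are implemented from first principles (`spearman_test`,
`chi2_gof`, `chi2_2x2`, `anova_binary`), so every reported number is
reproducible from elementary operations. A synthetic-data generator
(`synth_spec`, `gen_*`, `write_input_bundle`) produces all pipeline inputs
with known parameters for parameter-recovery testing, and `run_pipeline()`
drives the whole analysis from TSV inputs to a TSV report bundle.

## Worked example

```r
library(riskspectra)

# ELI per disease from a shipped abstract-count table, split into tertiles
counts <- read_literature_counts(
  system.file("extdata", "disease_literature_counts.tsv", package = "riskspectra"))
head(assign_tertiles(eli_table(counts)) |> dplyr::arrange(dplyr::desc(eli)), 5)
#>   disease                     eli tertile
#> 1 Obesity                   113.        3
#> 2 Type 2 diabetes            76.4       3
#> 3 Major depressive disorder  73.2       3
#> 4 Asthma                     70.3       3
#> 5 Atopic dermatitis          63.1       3

# synthetic associations with a known ELI-linked left shift, then MiRA
assoc <- gen_association_table(synth_spec(seed = 2024))
head(mira_summary(assoc, min_snps = 20), 4)
#>   disease    n_snps  mira     se
#> 1 disease_14    148 0.676 0.0385
#> 2 disease_06    141 0.624 0.0408
#> 3 disease_22    135 0.637 0.0414
#> 4 disease_04    128 0.547 0.0440

# observed spectrum vs the frequency-independence null
obs <- bin_spectrum(assoc$risk_allele_freq)
nul <- neutral_null_spectrum(assoc$risk_allele_freq)
spectrum_asymmetry(obs, nul)
#> [1] 0.1191  # positive: excess low-frequency risk alleles

# the conceptual model, simulated forward in time
sim <- wf_run(wf_config(n_loci = 5000, pop_size = 10000, generations = 500,
                        s_dist = wf_s_const(0.01), seed = 1))
sim
#> <wf_sim> 5000 loci, N = 10000, 500 generations (seed 1)
#>   MiRA: 0.497 (t = 0) -> 0.767 (t = 500); left shift 0.232
```

The MiRA column is the fraction of each disease's risk alleles with
frequency below 0.5 (0.5 would be the neutral expectation; `disease_14`'s
0.676 ± 0.039 reflects the generator's built-in left shift for
low-ELI diseases). The simulation shows the model's core prediction:
starting from a neutral spectrum (MiRA ≈ 0.5), five hundred generations of
selection at `s = 0.01` drive MiRA among segregating loci to 0.77 and shift
the spectrum left by 0.23.

`autoplot()` methods exist for spectra and simulations, `plot_mira()` and
`plot_spectrum_vs_null()` for the summary tables, and `tidy()`/`glance()`
for test results and simulation objects.

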