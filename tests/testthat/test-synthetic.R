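test_that("the left-shift knob delta maps onto the MiRA proportion as designed", {
  all_minor <- gen_association_table(
    synth_spec(n_diseases = 2, snps_per_disease = c(50, 50),
               delta = c(1, 1), seed = 5))
  expect_true(all(all_minor$risk_allele_freq < 0.5))

  # delta = 0.2 -> expected MiRA 0.6, recovered within Monte-Carlo tolerance
  spec <- synth_spec(n_diseases = 1, snps_per_disease = c(10000, 10000),
                     delta = 0.2, size_effect = FALSE, seed = 11)
  df <- gen_association_table(spec)
  mira <- mean(is_minor(df$risk_allele_freq))
  expect_lt(abs(mira - 0.6), 3 * sqrt(0.25 / 10000))
})

test_that("generated tables satisfy the reader contracts and are seed-deterministic", {
  spec <- synth_spec(n_diseases = 4, snps_per_disease = c(10, 30),
                     universe_size = 2e4,
                     platform_sizes = c(a = 2000, b = 3000),
                     n_gwas = 500, exposure = TRUE, seed = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- quiet(write_input_bundle(spec, d1))
  p2 <- quiet(write_input_bundle(spec, d2))

  # readers accept everything the generator writes
  assoc <- quiet(read_association_table(p1$associations))
  expect_gt(nrow(assoc), 0)
  counts <- quiet(read_literature_counts(p1$counts))
  expect_equal(nrow(counts), 4)
  expect_true(all(!is.na(counts$n_exposure)))
  expect_gt(length(quiet(read_snp_ids(p1$selected))), 0)
  for (m in p1$manifests) expect_gt(length(quiet(read_snp_ids(m))), 0)

  # same spec -> byte-identical files
  for (nm in c("associations", "counts", "selected", "gwas")) {
    expect_identical(unname(tools::md5sum(p1[[nm]])), unname(tools::md5sum(p2[[nm]])))
  }
  expect_identical(unname(tools::md5sum(p1$manifests)), unname(tools::md5sum(p2$manifests)))
})

test_that("literature counts recover the true ELI and ignore the publication volume", {
  zero <- gen_literature_counts(
    synth_spec(n_diseases = 3, true_eli = rep(0, 3), seed = 1))
  expect_true(all(zero$n_env + zero$n_lifestyle == 0))

  recovered <- vapply(1:200, function(i) {
    cts <- gen_literature_counts(
      synth_spec(n_diseases = 1, true_eli = 16.4, n_pubs = 120346, seed = i))
    compute_eli(cts$n_disease, cts$n_env, cts$n_lifestyle)
  }, numeric(1))
  lambda <- 16.4 * 120346 / 1000
  se_mean <- sqrt(lambda) * 1000 / 120346 / sqrt(200)
  expect_lt(abs(mean(recovered) - 16.4), 2 * se_mean)

  # the expected index does not depend on how many papers mention the disease
  small_pubs <- vapply(1:50, function(i) {
    cts <- gen_literature_counts(
      synth_spec(n_diseases = 1, true_eli = 16.4, n_pubs = 12000, seed = 1000 + i))
    compute_eli(cts$n_disease, cts$n_env, cts$n_lifestyle)
  }, numeric(1))
  se_small <- sqrt(16.4 * 12) * 1000 / 12000 / sqrt(50)
  expect_lt(abs(mean(small_pubs) - 16.4), 3 * se_small)
})

test_that("platform generator hits the selected fraction q in null mode", {
  spec <- synth_spec(universe_size = 2e5, q = 0.0075,
                     platform_sizes = c(p1 = 5e4), n_gwas = 2000, seed = 33)
  dat <- gen_platform_data(spec)
  plat <- overlap_result(dat$platforms$p1, dat$selected, "p1")
  gwas <- overlap_result(dat$gwas, dat$selected, "gwas")
  expect_lt(abs(plat$proportion_pct - 0.75), 3 * 100 * sqrt(0.0075 * 0.9925 / 5e4))
  expect_lt(abs(gwas$proportion_pct - 0.75), 3 * 100 * sqrt(0.0075 * 0.9925 / 2000))

  none <- gen_platform_data(synth_spec(universe_size = 1e4, q = 0,
                                       platform_sizes = c(p1 = 1000), seed = 2))
  expect_length(none$selected, 0)

  expect_error(synth_spec(q = 0.6, enrichment = 2),
               class = "riskspectra_domain_error")
})

test_that("an enriched GWAS set is detected by the overlap comparison", {
  rejections <- vapply(1:20, function(seed) {
    spec <- synth_spec(universe_size = 2e5, q = 0.0075, enrichment = 2,
                       platform_sizes = c(p1 = 2e5), n_gwas = 2000, seed = seed)
    dat <- gen_platform_data(spec)
    plat <- overlap_result(dat$platforms$p1, dat$selected, "p1")
    gwas <- overlap_result(dat$gwas, dat$selected, "gwas")
    compare_overlap(plat, gwas)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})
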