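test_that("minor classification follows the strict < 0.5 rule", {
  expect_true(is_minor(0.49))
  expect_false(quiet(is_minor(0.5)))
  expect_false(is_minor(0.96))
  expect_message(is_minor(c(0.5, 0.3)), "0.5")
  expect_error(is_minor(0), class = "riskspectra_domain_error")
  expect_error(is_minor(1.1), class = "riskspectra_domain_error")
})

test_that("mira_summary counts minor risk alleles with the binomial SE", {
  all_minor <- mira_summary(make_assoc(runif(30, 0.05, 0.49)))
  expect_equal(all_minor$mira, 1)
  expect_equal(all_minor$se, 0)

  set.seed(14)
  freqs <- runif(200, 0.01, 0.99)
  got <- mira_summary(make_assoc(freqs))
  # oracle: explicit loop count
  cnt <- 0L
  for (f in freqs) if (f < 0.5) cnt <- cnt + 1L
  expect_equal(got$mira, cnt / 200)
  expect_equal(got$se, sqrt(got$mira * (1 - got$mira) / 200))

  expect_error(mira_summary(make_assoc(numeric(0))),
               class = "riskspectra_domain_error")
})

test_that("mira_summary groups per disease and drops small groups on request", {
  df <- dplyr::bind_rows(
    make_assoc(runif(30, 0.05, 0.95), disease = "big", snp_prefix = "a"),
    make_assoc(runif(5, 0.05, 0.95), disease = "small", snp_prefix = "b")
  )
  out <- quiet(mira_summary(df, min_snps = 20))
  expect_equal(out$disease, "big")
})

test_that("published MiRA standard errors are reproduced where arithmetically consistent", {
  t2 <- read_table2()
  se <- sqrt(t2$mira * (1 - t2$mira) / t2$n_snps)
  agree <- round_half_up(se, 2) == t2$se
  # three printed rows are internally inconsistent (each one cent high)
  expect_equal(t2$disease[!agree],
               c("Myopia (pathological)", "Colorectal cancer",
                 "Chronic lymphocytic leukemia"))
  expect_equal(sum(agree), 22)
})

test_that("spectrum bins partition (0,1) with lower edges closed from bin 2 on", {
  expect_equal(bin_spectrum(0.2)$proportion, c(0, 1, 0, 0, 0))
  expect_equal(bin_spectrum(rep(0.1, 7))$proportion, c(1, 0, 0, 0, 0))
  expect_error(bin_spectrum(c(0.3, 1)), class = "riskspectra_domain_error")
  expect_error(bin_spectrum(numeric(0)), class = "riskspectra_domain_error")

  set.seed(2)
  f <- runif(1000, 0.0001, 0.9999)
  got <- bin_spectrum(f)
  # oracle: per-element interval tests
  edges <- list(c(0, 0.2), c(0.2, 0.4), c(0.4, 0.6), c(0.6, 0.8), c(0.8, 1))
  counts <- vapply(seq_along(edges), function(b) {
    lo <- edges[[b]][1]; hi <- edges[[b]][2]
    if (b == 1) sum(f > lo & f < hi) else sum(f >= lo & f < hi)
  }, numeric(1))
  expect_equal(got$count, counts)
  expect_equal(sum(got$proportion), 1, tolerance = 1e-9)
})

test_that("spectrum proportions always sum to 1 and every frequency lands in one bin", {
  set.seed(77)
  for (i in 1:25) {
    f <- runif(sample(1:400, 1), 1e-6, 1 - 1e-6)
    s <- bin_spectrum(f)
    expect_equal(sum(s$proportion), 1, tolerance = 1e-9)
    expect_equal(sum(s$count), length(f))
  }
})

test_that("the frequency-independence null mirrors each SNP with weight 1/2", {
  set.seed(4)
  f <- runif(100, 0.01, 0.99)
  nul <- neutral_null_spectrum(f)
  # oracle: duplicate-and-mirror then bin
  oracle <- bin_spectrum(c(f, 1 - f))
  expect_equal(nul$proportion, oracle$proportion)
  # mirror symmetry of the bins
  expect_equal(nul$proportion[1], nul$proportion[5])
  expect_equal(nul$proportion[2], nul$proportion[4])
  # minor-side mass is exactly 1/2 when no frequency equals 0.5
  idx <- findInterval(c(f, 1 - f), c(0.2, 0.4, 0.6, 0.8)) + 1
  expect_equal(sum(rep(0.5, 200)[c(f, 1 - f) < 0.5]) / 100, 0.5)

  # an already-symmetric input is its own null
  fs <- c(f, 1 - f)
  expect_equal(neutral_null_spectrum(fs)$proportion, bin_spectrum(fs)$proportion)
})

test_that("spectrum_asymmetry measures the low-frequency mass excess", {
  f <- runif(50, 0.01, 0.99)
  s <- bin_spectrum(f)
  expect_equal(spectrum_asymmetry(s, s), 0)

  obs <- bin_spectrum(rep(0.1, 10))
  nul <- bin_spectrum(c(rep(0.1, 5), rep(0.9, 5)))
  expect_equal(spectrum_asymmetry(obs, nul), 0.5)

  shifted <- nul
  shifted$lower[1] <- 0.01
  expect_error(spectrum_asymmetry(obs, shifted), class = "riskspectra_domain_error")
})

test_that("sample-size correlations recover the generator's design", {
  const <- make_assoc(runif(10, 0.1, 0.9))
  const$sample_size <- 5000
  out <- mira_vs_sample_size(const)
  expect_true(all(grepl("not computable", out$note)))

  spec <- synth_spec(n_diseases = 5, snps_per_disease = c(1500, 1500),
                     delta = rep(0, 5), size_effect = TRUE, seed = 19)
  df <- gen_association_table(spec)
  out <- mira_vs_sample_size(df)
  rho_rare <- out$statistic[out$measure == "rare_maf_le_0.05"]
  rho_dir <- out$statistic[out$measure == "minor_risk"]
  expect_gt(rho_rare, 0.05)       # bigger studies find rarer SNPs
  expect_lt(abs(rho_dir), 0.05)   # but risk direction is independent of size

  expect_error(mira_vs_sample_size(make_assoc(c(0.2, 0.3))),
               class = "riskspectra_domain_error")
})
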