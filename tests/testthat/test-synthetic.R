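test_that("genotype simulation hits frequencies, HWE and missingness", {
  v <- candidate_panel_variants()
  cfg <- sim_config(n_individuals = 10000, variants = v,
                    missing_rate = 0.002, seed = 17)
  p <- simulate_genotypes(cfg)
  eaf <- observed_eaf(p)
  # spot check at the 3-sigma binomial sampling bound ...
  expect_lt(abs(eaf[["rs187238"]] - 0.283),
            3 * sqrt(0.283 * 0.717 / (2 * 10000)))
  # ... and the whole panel at 4 sigma (32 simultaneous checks)
  for (k in seq_len(nrow(v))) {
    tol <- 4 * sqrt(v$eaf[k] * (1 - v$eaf[k]) / (2 * 10000))
    expect_lt(abs(eaf[[v$variant_id[k]]] - v$eaf[k]), tol + 1e-12,
              label = v$variant_id[k])
  }
  expect_equal(mean(is.na(p$dosages)), 0.002, tolerance = 0.5)

  # HWE holds for unperturbed variants at alpha = 0.001
  plain <- v$variant_id[v$hwe_f == 0]
  ps <- vapply(plain, function(id) {
    cnt <- genotype_counts(p, id)
    hwe_exact_test(cnt[1], cnt[2], cnt[3])
  }, numeric(1))
  expect_gte(mean(ps >= 0.001), 0.99)
})

test_that("inbreeding perturbation depletes heterozygotes as 2pq(1-F)", {
  v <- candidate_panel_variants()[1, ]
  v$eaf <- 0.3
  cfg <- sim_config(n_individuals = 20000, variants = v, ld_pairs = NULL,
                    hwe_violations = data.frame(variant_id = v$variant_id,
                                                f = 0.2),
                    missing_rate = 0, seed = 4)
  p <- simulate_genotypes(cfg)
  het <- mean(p$dosages[, 1] == 1)
  expect_equal(het, 2 * 0.3 * 0.7 * (1 - 0.2), tolerance = 0.03)
  cnt <- genotype_counts(p, v$variant_id)
  expect_lt(hwe_exact_test(cnt[1], cnt[2], cnt[3]), 1e-6)
})

test_that("degenerate frequencies and prevalences behave as limits", {
  v <- candidate_panel_variants()[1:2, ]
  v$eaf <- c(0, 0.5)
  cfg <- sim_config(n_individuals = 50, variants = v, ld_pairs = NULL,
                    hwe_violations = data.frame(variant_id = character(),
                                                f = numeric()),
                    missing_rate = 0, seed = 2)
  p <- simulate_genotypes(cfg)
  expect_true(all(p$dosages[, 1] == 0))

  pv <- default_covariate_prevalences()
  pv$woman <- 1.0
  co <- simulate_covariates(sim_config(n_individuals = 40,
                                       covariate_prevalences = pv,
                                       seed = 6))
  expect_true(all(co$sex == "woman"))

  pv$ethnicity <- pv$ethnicity * 2
  expect_error(sim_config(covariate_prevalences = pv), "sum to 1")
})

test_that("covariate margins approach the configured prevalences", {
  co <- simulate_covariates(sim_config(n_individuals = 10000, seed = 31))
  expect_equal(mean(co$sex == "woman"), 0.7925, tolerance = 0.026)
  expect_lt(abs(mean(co$sex == "woman") - 0.7925), 0.02)
  expect_equal(mean(co$income == "lower-than-average"), 0.1057,
               tolerance = 0.15)
  pv <- default_covariate_prevalences()$pbi_high
  expect_equal(mean(co$maternal_care_cat == "high"),
               unname(pv["maternal_care"]), tolerance = 0.05)
  expect_equal(mean(co$paternal_protection_cat == "high"),
               unname(pv["paternal_protection"]), tolerance = 0.05)
  expect_true(all(co$age >= 18 & co$age <= 25))
})

test_that("simulation is a pure function of the seed", {
  c1 <- sim_config(n_individuals = 200, seed = 77)
  b1 <- simulate_cohort(c1)
  b2 <- simulate_cohort(sim_config(n_individuals = 200, seed = 77))
  expect_identical(b1$panel$dosages, b2$panel$dosages)
  expect_identical(b1$cohort$depression, b2$cohort$depression)
  b3 <- simulate_cohort(sim_config(n_individuals = 200, seed = 78))
  expect_false(identical(b1$panel$dosages, b3$panel$dosages))
  expect_identical(dim(b1$panel$dosages), dim(b3$panel$dosages))
})

test_that("phenotype model degenerates and orders correctly", {
  v <- candidate_panel_variants()[21, ]  # rs2715157
  eff0 <- default_covariate_effects() * 0
  cfg <- sim_config(n_individuals = 60, variants = v, ld_pairs = NULL,
                    hwe_violations = data.frame(variant_id = character(),
                                                f = numeric()),
                    missing_rate = 0,
                    true_snp_betas = setNames(0, v$variant_id),
                    covariate_effects = eff0, noise_sd = 0,
                    mean_depression = 12, seed = 9)
  b <- simulate_cohort(cfg)
  expect_equal(length(unique(b$cohort$depression)), 1)

  cfg2 <- sim_config(n_individuals = 60, variants = v, ld_pairs = NULL,
                     hwe_violations = data.frame(variant_id = character(),
                                                 f = numeric()),
                     missing_rate = 0,
                     true_snp_betas = setNames(4, v$variant_id),
                     covariate_effects = eff0, noise_sd = 0,
                     mean_depression = 12, seed = 9)
  b2 <- simulate_cohort(cfg2)
  dep <- b2$cohort$depression
  dos <- b2$panel$dosages[, 1]
  expect_gt(min(dep[dos == 2]), max(dep[dos == 1]))
  expect_gt(min(dep[dos == 1]), max(dep[dos == 0]))

  # dimension mismatch between panel and cohort
  co <- simulate_covariates(cfg2)
  expect_error(simulate_phenotype(b2$panel, co[1:10, ], cfg2), "aligned")
})

test_that("study cohort bundle realizes its design targets", {
  b <- simulate_study_cohort(seed = 12)
  expect_equal(n_variants(b$panel), 32)
  expect_equal(nrow(b$cohort), 1065)
  expect_true(all(b$cohort$depression >= 0 & b$cohort$depression <= 63))
  # marginal depression scale close to the cohort it emulates
  expect_equal(mean(b$cohort$depression), 8.3, tolerance = 0.15)
  expect_equal(sd(b$cohort$depression), 7, tolerance = 0.2)
  # different seeds, different matrices, same shape
  b2 <- simulate_study_cohort(seed = 13)
  expect_false(identical(b$panel$dosages, b2$panel$dosages))
  expect_identical(dim(b$panel$dosages), dim(b2$panel$dosages))
})
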