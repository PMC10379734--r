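test_that("fit_linear_model matches summary statistics and conventions", {
  b <- quick_bundle(seed = 33, n = 200, n_var = 6)
  dat <- b$cohort
  set.seed(1); dat$pgs <- rnorm(200)
  fit <- fit_linear_model(dat, c("pgs", "sex", "age", "ethnicity"))
  # adjusted r2 follows 1 - (1 - R2)(n-1)/(n-k-1), k = non-intercept cols
  k <- nrow(fit$coefficients) - 1
  expect_equal(fit$adjusted_r2,
               1 - (1 - fit$r2) * (fit$n_used - 1) / (fit$n_used - k - 1),
               tolerance = 1e-12)
  expect_true(fit$adjusted_r2 <= fit$r2)
  # our AIC convention differs from stats::AIC by a data-independent
  # constant, so model differences agree
  fit2 <- fit_linear_model(dat, c("sex", "age", "ethnicity"))
  expect_equal(fit$aic - fit2$aic,
               stats::AIC(fit$lm) - stats::AIC(fit2$lm),
               tolerance = 1e-8)

  # outcome duplicated as predictor: perfect fit
  dat$dep_copy <- dat$depression
  perfect <- suppressWarnings(  # summary.lm flags the perfect fit
    fit_linear_model(dat, "dep_copy"))
  expect_equal(perfect$r2, 1, tolerance = 1e-12)
  expect_equal(perfect$adjusted_r2, 1, tolerance = 1e-12)
})

test_that("OLS agrees with the normal-equations solution", {
  b <- quick_bundle(seed = 35, n = 150, n_var = 5)
  dat <- b$cohort
  set.seed(2); dat$pgs <- rnorm(150)
  fit <- fit_linear_model(dat, c("pgs", "age"))
  X <- cbind(1, dat$pgs, dat$age)
  beta_ne <- solve(t(X) %*% X, t(X) %*% dat$depression)
  expect_equal(unname(fit$coefficients$beta), as.vector(beta_ne),
               tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the aliased term", {
  b <- quick_bundle(seed = 36, n = 100, n_var = 5)
  dat <- b$cohort
  set.seed(3); dat$pgs <- rnorm(100)
  dat$pgs_copy <- dat$pgs
  expect_error(fit_linear_model(dat, c("pgs", "pgs_copy")), "pgs_copy")
})

test_that("pure-noise predictors give near-zero mean adjusted r2", {
  set.seed(91)
  vals <- replicate(200, {
    d <- data.frame(depression = sample(0:30, 100, TRUE),
                    x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100))
    fit_linear_model(d, c("x1", "x2", "x3"))$adjusted_r2
  })
  expect_lt(abs(mean(vals)), 0.01)
  expect_true(any(vals < 0))  # slightly negative values are expected
})

test_that("backward elimination: identity, contract, and step() agreement", {
  b <- quick_bundle(seed = 41, n = 500, n_var = 8)
  dat <- merge(b$cohort,
               score_individuals(
                 b$panel,
                 build_weights(fit_snp_regression(b$panel, b$cohort)))[,
                   c("sample_id", "pgs")],
               by = "sample_id")
  terms <- c("pgs", "sex", "age", "ethnicity", "income", "full_family",
             "maltreatment", "maternal_care_cat",
             "maternal_protection_cat", "paternal_care_cat",
             "paternal_protection_cat")
  forced <- c("pgs", "sex", "age", "ethnicity")

  # all terms forced: returns the input model unchanged
  same <- backward_eliminate(dat, forced, forced = forced)
  expect_equal(nrow(attr(same, "path")), 0)

  fit <- backward_eliminate(dat, terms, forced = forced)
  path <- attr(fit, "path")
  full <- fit_linear_model(dat, terms)
  expect_lte(fit$aic, full$aic)
  if (nrow(path) > 0) {
    expect_true(all(path$aic_after < path$aic_before))
    expect_false(any(path$removed %in% forced))
  }

  # stats::step with the same scope lands on the same term set
  d2 <- dat
  d2$ethnicity <- stats::relevel(factor(d2$ethnicity), ref = "mixed")
  lower <- as.formula(paste("~", paste(forced, collapse = "+")))
  st <- stats::step(lm(as.formula(paste("depression ~",
                                        paste(terms, collapse = "+"))),
                       data = d2),
                    scope = list(lower = lower), direction = "backward",
                    trace = 0)
  expect_setequal(fit$terms, all.vars(stats::formula(st))[-1])
})

test_that("a pure-noise social predictor is eliminated at the AIC rate", {
  # AIC drops a 1-df pure-noise term iff its chi-square deviance
  # contribution is below 2, i.e. with probability P(chisq_1 < 2)
  # ~ 0.843, independent of n.  Over 40 replicates the observed rate
  # should not fall more than ~3 binomial SDs below that.
  hits <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    b <- quick_bundle(seed = 500 + i, n = 1500, n_var = 6)
    dat <- b$cohort
    set.seed(600 + i)
    dat$pgs <- rnorm(1500)  # irrelevant; forced anyway
    dat$noise_social <- rnorm(1500)
    fit <- backward_eliminate(
      dat, c("pgs", "sex", "age", "maternal_care_cat", "noise_social"),
      forced = c("pgs", "sex", "age"))
    if (!"noise_social" %in% fit$terms) hits <- hits + 1L
  }
  p_theory <- pchisq(2, df = 1)  # ~ 0.843
  lower <- p_theory - 3 * sqrt(p_theory * (1 - p_theory) / n_rep)
  expect_gte(hits / n_rep, lower)
})

test_that("model suite: nesting, mode independence, and subgroup logic", {
  b <- simulate_study_cohort(seed = 55)
  qc <- run_qc(b$panel, proxy_keep = candidate_ld_pairs()$keep)
  suite <- run_model_suite(qc$panel, b$cohort)
  expect_setequal(names(suite$fits),
                  c("weighted_all", "weighted_women", "unweighted_all",
                    "unweighted_women"))
  for (cond in names(suite$fits)) {
    f <- suite$fits[[cond]]
    # unadjusted R2 monotone over nested models
    expect_gte(f$model3$r2, f$model1$r2)
    if (!grepl("women", cond)) expect_gte(f$model3$r2, f$model2$r2)
    expect_true(all(f$model4$n_used > 0))
  }
  # Model 2 has no PGS term, so it cannot depend on the scoring mode
  expect_equal(suite$fits$weighted_all$model2$adjusted_r2,
               suite$fits$unweighted_all$model2$adjusted_r2,
               tolerance = 1e-12)
  # women subgroup drops sex from the design
  expect_false("sex" %in% suite$fits$weighted_women$model3$terms)
  expect_true("sex" %in% suite$fits$weighted_all$model3$terms)
  # forced terms survive elimination in every condition
  for (cond in names(suite$fits))
    expect_true(all(c("pgs", "age", "ethnicity") %in%
                      suite$fits[[cond]]$model4$terms))
  tab <- variance_explained_table(suite)
  expect_equal(nrow(tab), 16)
})

test_that("tiny subgroups are skipped with a warning", {
  b <- quick_bundle(seed = 66, n = 120, n_var = 5)
  co <- b$cohort
  co$sex[1:119] <- "man"
  co$sex[120] <- "woman"
  expect_warning(
    suite <- run_model_suite(b$panel, co, modes = "weighted",
                             subgroups = c("all", "women")),
    "too small")
  expect_false("weighted_women" %in% names(suite$fits))
})
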