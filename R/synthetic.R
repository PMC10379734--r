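# Synthetic genotype/phenotype cohorts with the statistical structure the
# downstream analysis assumes: HWE (or F-perturbed) genotypes at given
# effect-allele frequencies, haplotype-level LD pairs, categorical social
# covariates at configured prevalences, and a bounded integer depression
# score driven by additive SNP + covariate effects plus Gaussian noise.

.derive_seed <- function(seed, k, attempt = 0L) {
  ((as.numeric(seed) %% 1e6) * 1009 + k * 9973 + attempt * 131 + 1) %%
    2147483629
}

#' Default covariate effects of the synthetic phenotype model
#'
#' Per-unit effects, in BDI points, of each social/demographic predictor
#' on the latent depression score.  Defaults are on the scale of the
#' conditional (multivariable) effects typical of a young-adult
#' higher-education cohort: women score about one point higher, each
#' year of age lowers the score by 0.3 points, ethnic groups differ by
#' 1--3 points from the mixed-ancestry reference, above-average family
#' income lowers the score, high parental care lowers and high parental
#' protection raises it; rearing in a full family carries no direct
#' effect and maltreatment a small one.
#'
#' @return Named numeric vector.
#' @export
default_covariate_effects <- function() {
  c(sex_woman = 1.1, age = -0.30,
    ethnicity_Russian = -1.5, ethnicity_Tatar = -2.7,
    ethnicity_Udmurt = -1.9,
    income_average = -1.9, full_family = 0, maltreatment = 1.2,
    maternal_care_high = -2.65, maternal_protection_high = 1.52,
    paternal_care_high = -1.07, paternal_protection_high = 1.43)
}

#' Default covariate prevalences of the synthetic cohort
#'
#' Category probabilities matching the margins of the reference cohort:
#' 79.25% women; ethnic composition Russian/Tatar/Udmurt/mixed =
#' 357/340/234/134 out of 1065; 10.57% lower-than-average income; 83.72%
#' reared in a full family; 9.78% reporting maltreatment; and PBI "high"
#' category prevalences of 68.33% (maternal care), 53.99% (maternal
#' protection), 52.95% (paternal care) and 46.91% (paternal protection).
#'
#' @return Named list (`woman`, `ethnicity`, `income_lower`,
#'   `full_family`, `maltreatment`, `pbi_high`).
#' @export
default_covariate_prevalences <- function() {
  list(woman = 0.7925,
       ethnicity = c(mixed = 134, Russian = 357, Tatar = 340,
                     Udmurt = 234) / 1065,
       income_lower = 0.1057,
       full_family = 0.8372,
       maltreatment = 0.0978,
       pbi_high = c(maternal_care = 728, maternal_protection = 575,
                    paternal_care = 564, paternal_protection = 500) / 1065)
}

#' Simulation configuration
#'
#' Assembles and validates the generative model for a synthetic cohort.
#'
#' @param n_individuals cohort size (>= 2).
#' @param variants variant table (as in [genotype_panel()]; `eaf`
#'   required).  Defaults to the 32-variant candidate panel.
#' @param ld_pairs data.frame `variant_a`, `variant_b`, `target_r2`
#'   (haplotype-frequency r2 in `[0, 1)`); pair members are drawn from a
#'   two-locus haplotype distribution and may not appear twice.
#' @param hwe_violations data.frame `variant_id`, `f` (inbreeding
#'   coefficient; P(het) = 2pq(1-f)).
#' @param missing_rate independent per-genotype missingness probability.
#' @param true_snp_betas named per-allele effects (BDI points) on the
#'   latent phenotype; unnamed variants get 0.
#' @param covariate_effects named vector as
#'   [default_covariate_effects()].
#' @param covariate_prevalences list as
#'   [default_covariate_prevalences()].
#' @param noise_sd SD of the Gaussian phenotype noise (default 6.5,
#'   chosen so the marginal depression SD is about 7 BDI points under
#'   the default effects).
#' @param mean_depression target mean of the latent score; fixes the
#'   model intercept analytically (ignored when `intercept` is given).
#' @param intercept optional explicit intercept.
#' @param age_range uniform age bounds in years.
#' @param pbi_sd named SDs of the four raw PBI scales.
#' @param seed integer RNG seed; every draw is a pure function of it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1065,
                       variants = candidate_panel_variants(),
                       ld_pairs = candidate_ld_pairs()[,
                         c("variant_a", "variant_b", "target_r2")],
                       hwe_violations = NULL,
                       missing_rate = 0.002,
                       true_snp_betas = NULL,
                       covariate_effects = default_covariate_effects(),
                       covariate_prevalences =
                         default_covariate_prevalences(),
                       noise_sd = 6.5,
                       mean_depression = 8.3,
                       intercept = NULL,
                       age_range = c(18, 25),
                       pbi_sd = c(maternal_care = 6,
                                  maternal_protection = 7,
                                  paternal_care = 6,
                                  paternal_protection = 7),
                       seed = 1L) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(hwe_violations)) {
    hwe_violations <- if ("hwe_f" %in% names(variants)) {
      data.frame(variant_id = variants$variant_id[variants$hwe_f != 0],
                 f = variants$hwe_f[variants$hwe_f != 0],
                 stringsAsFactors = FALSE)
    } else data.frame(variant_id = character(), f = numeric())
  }
  if (is.null(true_snp_betas)) {
    true_snp_betas <- if ("beta" %in% names(variants))
      setNames(variants$beta, variants$variant_id)
    else setNames(rep(0, nrow(variants)), variants$variant_id)
  }
  if (is.null(ld_pairs))
    ld_pairs <- data.frame(variant_a = character(),
                           variant_b = character(), target_r2 = numeric())

  stopifnot(n_individuals >= 2)
  if (anyNA(variants$eaf) || any(variants$eaf < 0 | variants$eaf > 1))
    stop("all variants need eaf in [0, 1]")
  if (any(ld_pairs$target_r2 < 0 | ld_pairs$target_r2 >= 1))
    stop("target_r2 must lie in [0, 1)")
  paired <- c(ld_pairs$variant_a, ld_pairs$variant_b)
  if (anyDuplicated(paired))
    stop("a variant may appear in at most one LD pair")
  if (!all(paired %in% variants$variant_id))
    stop("LD pair names unknown variants")
  if (!all(hwe_violations$variant_id %in% variants$variant_id))
    stop("hwe_violations names unknown variants")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  eth <- covariate_prevalences$ethnicity
  if (abs(sum(eth) - 1) > 1e-6)
    stop("ethnicity prevalences must sum to 1 (got ", sum(eth), ")")
  pr <- c(covariate_prevalences$woman, eth,
          covariate_prevalences$income_lower,
          covariate_prevalences$full_family,
          covariate_prevalences$maltreatment,
          covariate_prevalences$pbi_high)
  if (any(pr < 0 | pr > 1)) stop("prevalences must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  structure(list(
    n_individuals = as.integer(n_individuals), variants = variants,
    ld_pairs = ld_pairs, hwe_violations = hwe_violations,
    missing_rate = missing_rate, true_snp_betas = true_snp_betas,
    covariate_effects = covariate_effects,
    covariate_prevalences = covariate_prevalences,
    noise_sd = noise_sd, mean_depression = mean_depression,
    intercept = intercept, age_range = age_range, pbi_sd = pbi_sd,
    seed = as.integer(seed)), class = "sim_config")
}

# one unlinked variant: genotype classes under HWE perturbed by F
.draw_variant_dosage <- function(n, p, f, seed) {
  q <- 1 - p
  probs <- c(q^2 + p * q * f, 2 * p * q * (1 - f), p^2 + p * q * f)
  if (any(probs < -1e-12))
    stop("inbreeding coefficient f = ", f,
         " infeasible at eaf = ", p)
  probs <- pmax(probs, 0)
  set.seed(.derive_seed(seed, 1L))
  sample(0:2, n, replace = TRUE, prob = probs)
}

# a two-locus pair: random union of gametes from a haplotype
# distribution with D chosen to hit the target haplotype r2
.draw_pair_dosages <- function(n, p_a, p_b, target_r2, seed,
                               ids = c("a", "b")) {
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  if (denom == 0) {
    if (target_r2 > 0)
      stop("target r2 ", target_r2, " unattainable: a locus is ",
           "monomorphic (maximum attainable r2 = 0)")
    d <- 0
  } else {
    d <- sqrt(target_r2 * denom)
  }
  h <- c(ab = (1 - p_a) * (1 - p_b) + d, aB = (1 - p_a) * p_b - d,
         Ab = p_a * (1 - p_b) - d, AB = p_a * p_b + d)
  if (any(h < -1e-12)) {
    d_max <- min(p_a * (1 - p_b), (1 - p_a) * p_b)
    stop("target r2 = ", target_r2, " infeasible for eaf pair (",
         p_a, ", ", p_b, "); maximum attainable r2 = ",
         signif(d_max^2 / denom, 4))
  }
  h <- pmax(h, 0)
  set.seed(.derive_seed(seed, 2L))
  gam <- matrix(sample(4L, 2L * n, replace = TRUE, prob = h), ncol = 2)
  # haplotype index -> allele at locus A (3,4 carry A) and B (2,4 carry B)
  dos_a <- rowSums(gam >= 3L)
  dos_b <- rowSums(gam == 2L | gam == 4L)
  out <- cbind(dos_a, dos_b)
  colnames(out) <- ids
  out
}

.apply_missing <- function(x, rate, seed) {
  if (rate <= 0) return(x)
  set.seed(.derive_seed(seed, 3L))
  x[runif(length(x)) < rate] <- NA_integer_
  x
}

#' Simulate a genotype panel
#'
#' Unlinked variants are drawn under Hardy--Weinberg proportions at the
#' configured effect-allele frequency, optionally perturbed by an
#' inbreeding coefficient (`P(het) = 2pq(1-f)`); LD pairs are drawn as
#' random unions of gametes from a two-locus haplotype distribution
#' whose D is set to achieve the target haplotype-frequency r2;
#' missingness is applied independently.  Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A [genotype_panel()]; `variants$eaf` carries the configured
#'   (true) frequencies.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  v <- config$variants
  n <- config$n_individuals
  dos <- matrix(NA_integer_, n, nrow(v),
                dimnames = list(NULL, v$variant_id))
  fmap <- setNames(rep(0, nrow(v)), v$variant_id)
  fmap[config$hwe_violations$variant_id] <- config$hwe_violations$f
  paired <- c(config$ld_pairs$variant_a, config$ld_pairs$variant_b)
  for (k in seq_len(nrow(v))) {
    id <- v$variant_id[k]
    if (id %in% paired) next
    dos[, k] <- .draw_variant_dosage(n, v$eaf[k], fmap[id],
                                     .derive_seed(config$seed, k))
  }
  if (nrow(config$ld_pairs) > 0)
    for (j in seq_len(nrow(config$ld_pairs))) {
      pr <- config$ld_pairs[j, ]
      ka <- match(pr$variant_a, v$variant_id)
      kb <- match(pr$variant_b, v$variant_id)
      pair <- .draw_pair_dosages(n, v$eaf[ka], v$eaf[kb], pr$target_r2,
                                 .derive_seed(config$seed, 5000L + j))
      dos[, ka] <- pair[, 1]
      dos[, kb] <- pair[, 2]
    }
  dos <- .apply_missing(dos, config$missing_rate,
                        .derive_seed(config$seed, 9001L))
  cols <- c("variant_id", "locus_label", "chrom", "pos",
            "effect_allele", "non_effect_allele", "eaf")
  genotype_panel(v[, cols], dos, sprintf("S%04d", seq_len(n)))
}

#' Simulate cohort covariates
#'
#' Draws sex, ethnicity, income, family and maltreatment indicators
#' from the configured category probabilities; age uniformly on the
#' configured range; and raw PBI scores from normals positioned so the
#' dichotomized "high" categories hit the configured prevalences (scores
#' are rounded to integers and clamped to the instrument ranges, 0--36
#' for care and 0--39 for protection).
#'
#' @param config a [sim_config()].
#' @return A `cohort_table` with `depression` still missing.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  pv <- config$covariate_prevalences
  set.seed(.derive_seed(config$seed, 20011L))
  cut <- pbi_default_cutoffs()
  dat <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    depression = NA_integer_,
    sex = ifelse(runif(n) < pv$woman, "woman", "man"),
    age = runif(n, config$age_range[1], config$age_range[2]),
    ethnicity = sample(names(pv$ethnicity), n, replace = TRUE,
                       prob = pv$ethnicity),
    income = ifelse(runif(n) < pv$income_lower,
                    "lower-than-average", "average-and-higher"),
    full_family = as.integer(runif(n) < pv$full_family),
    maltreatment = as.integer(runif(n) < pv$maltreatment),
    stringsAsFactors = FALSE)
  bounds <- c(maternal_care = 36, maternal_protection = 39,
              paternal_care = 36, paternal_protection = 39)
  for (sc in names(cut)) {
    # rounding maps the continuous threshold to ceil(cutoff) - 0.5
    t_star <- ceiling(cut[[sc]]) - 0.5
    mu <- t_star + qnorm(pv$pbi_high[[sc]]) * config$pbi_sd[[sc]]
    raw <- round(rnorm(n, mu, config$pbi_sd[[sc]]))
    dat[[sc]] <- pmin(bounds[[sc]], pmax(0, raw))
  }
  as_cohort_table(dat)
}

.analytic_effect_mean <- function(config) {
  pv <- config$covariate_prevalences
  eff <- config$covariate_effects
  v <- config$variants
  beta <- config$true_snp_betas[v$variant_id]
  beta[is.na(beta)] <- 0
  snp <- sum(beta * 2 * v$eaf)
  eth <- pv$ethnicity
  cov <- eff[["sex_woman"]] * pv$woman +
    eff[["age"]] * mean(config$age_range) +
    eff[["ethnicity_Russian"]] * eth[["Russian"]] +
    eff[["ethnicity_Tatar"]] * eth[["Tatar"]] +
    eff[["ethnicity_Udmurt"]] * eth[["Udmurt"]] +
    eff[["income_average"]] * (1 - pv$income_lower) +
    eff[["full_family"]] * pv$full_family +
    eff[["maltreatment"]] * pv$maltreatment +
    sum(eff[paste0(names(pv$pbi_high), "_high")] * pv$pbi_high)
  unname(snp + cov)
}

#' Simulate the depression phenotype
#'
#' Latent score = intercept + sum of per-allele SNP effects + covariate
#' linear terms + Gaussian noise; the observed BDI score is the latent
#' value rounded and clipped to `[0, 63]`.  Missing dosages enter the
#' generative sum at their expectation (`2 * eaf`).
#'
#' @param panel [genotype_panel()] from [simulate_genotypes()].
#' @param cohort `cohort_table` from [simulate_covariates()].
#' @param config the same [sim_config()].
#' @return The cohort with `depression` filled in.
#' @export
simulate_phenotype <- function(panel, cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(panel$sample_ids, cohort$sample_id))
    stop("panel and cohort sample ids are not aligned")
  n <- nrow(cohort)
  v <- panel$variants
  beta <- config$true_snp_betas[v$variant_id]
  beta[is.na(beta)] <- 0
  x <- panel$dosages
  for (k in seq_len(ncol(x)))
    x[is.na(x[, k]), k] <- 2 * v$eaf[k]
  snp_term <- as.vector(x %*% beta)
  eff <- config$covariate_effects
  eth_eff <- setNames(rep(0, 4), c("mixed", "Russian", "Tatar", "Udmurt"))
  eth_eff[c("Russian", "Tatar", "Udmurt")] <-
    eff[c("ethnicity_Russian", "ethnicity_Tatar", "ethnicity_Udmurt")]
  cov_term <- eff[["sex_woman"]] * (cohort$sex == "woman") +
    eff[["age"]] * cohort$age +
    eth_eff[as.character(cohort$ethnicity)] +
    eff[["income_average"]] * (cohort$income == "average-and-higher") +
    eff[["full_family"]] * cohort$full_family +
    eff[["maltreatment"]] * cohort$maltreatment +
    eff[["maternal_care_high"]] * (cohort$maternal_care_cat == "high") +
    eff[["maternal_protection_high"]] *
      (cohort$maternal_protection_cat == "high") +
    eff[["paternal_care_high"]] * (cohort$paternal_care_cat == "high") +
    eff[["paternal_protection_high"]] *
      (cohort$paternal_protection_cat == "high")
  intercept <- config$intercept
  if (is.null(intercept))
    intercept <- config$mean_depression - .analytic_effect_mean(config)
  set.seed(.derive_seed(config$seed, 30011L))
  latent <- intercept + snp_term + unname(cov_term) +
    rnorm(n, 0, config$noise_sd)
  cohort$depression <- as.integer(pmin(63, pmax(0, round(latent))))
  cohort$depression_missing <- FALSE
  cohort
}

#' Simulate a complete cohort bundle
#'
#' @param config a [sim_config()].
#' @return List of class `cohort_bundle` with elements `panel`,
#'   `cohort` and `truth` (the config).
#' @export
simulate_cohort <- function(config) {
  panel <- simulate_genotypes(config)
  cohort <- simulate_covariates(config)
  cohort <- simulate_phenotype(panel, cohort, config)
  structure(list(panel = panel, cohort = cohort, truth = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", nrow(x$cohort), " individuals, ",
      n_variants(x$panel), " variants\n", sep = "")
  invisible(x)
}

#' Simulate the reference study cohort
#'
#' Convenience constructor for the study-scale synthetic dataset: the
#' full 32-variant candidate panel (30 association variants plus the two
#' Hardy--Weinberg violators), the three intra-locus LD pairs at their
#' target r2 values, covariate margins and phenotype model at their
#' defaults, and n = 1065 individuals.
#'
#' With `condition_on_design = TRUE` (the default), per-variant draws
#' are redrawn (deterministically, from seeds derived from `seed`) until
#' the realized data exhibit the designed QC structure: the two spiked
#' violators fail the HWE exact test at `hwe_alpha` while every other
#' variant passes, every variant clears the MAF and call-rate gates, and
#' each LD pair's EM-estimated r2 falls within 0.05 of its target and at
#' or above `proxy_r2_threshold`.  This samples from the generative law
#' conditioned on the design targets, so the QC ledger of the bundle is
#' reproducible by construction; set it to `FALSE` for unconditioned
#' draws.
#'
#' @param seed integer seed.
#' @param n cohort size.
#' @param condition_on_design logical, see above.
#' @param hwe_alpha,maf_min,call_rate_min,proxy_r2_threshold the QC
#'   thresholds the conditioning targets.
#' @param max_attempts per-variant redraw cap.
#' @return A `cohort_bundle`.
#' @export
simulate_study_cohort <- function(seed = 1L, n = 1065,
                                  condition_on_design = TRUE,
                                  hwe_alpha = 0.05, maf_min = 0.05,
                                  call_rate_min = 0.98,
                                  proxy_r2_threshold = 0.2,
                                  max_attempts = 200L) {
  config <- sim_config(n_individuals = n, seed = seed)
  if (!condition_on_design) return(simulate_cohort(config))

  v <- config$variants
  fmap <- setNames(rep(0, nrow(v)), v$variant_id)
  fmap[config$hwe_violations$variant_id] <- config$hwe_violations$f
  paired <- c(config$ld_pairs$variant_a, config$ld_pairs$variant_b)
  dos <- matrix(NA_integer_, n, nrow(v),
                dimnames = list(NULL, v$variant_id))

  ok_single <- function(x, p, want_violation) {
    cr <- mean(!is.na(x))
    eaf <- mean(x, na.rm = TRUE) / 2
    hp <- hwe_exact_test(sum(x == 2, na.rm = TRUE),
                         sum(x == 1, na.rm = TRUE),
                         sum(x == 0, na.rm = TRUE))
    cr > call_rate_min && min(eaf, 1 - eaf) > maf_min &&
      if (want_violation) hp < hwe_alpha else hp >= hwe_alpha
  }
  for (k in seq_len(nrow(v))) {
    id <- v$variant_id[k]
    if (id %in% paired) next
    for (att in seq_len(max_attempts)) {
      s <- .derive_seed(seed, k, att)
      x <- .draw_variant_dosage(n, v$eaf[k], fmap[id], s)
      x <- .apply_missing(x, config$missing_rate,
                          .derive_seed(seed, k + 40000L, att))
      if (ok_single(x, v$eaf[k], fmap[id] > 0)) break
      if (att == max_attempts)
        stop("could not realize design targets for ", id)
    }
    dos[, k] <- x
  }
  for (j in seq_len(nrow(config$ld_pairs))) {
    pr <- config$ld_pairs[j, ]
    ka <- match(pr$variant_a, v$variant_id)
    kb <- match(pr$variant_b, v$variant_id)
    for (att in seq_len(max_attempts)) {
      pair <- .draw_pair_dosages(n, v$eaf[ka], v$eaf[kb], pr$target_r2,
                                 .derive_seed(seed, 5000L + j, att))
      pair <- .apply_missing(pair, config$missing_rate,
                             .derive_seed(seed, 45000L + j, att))
      r2 <- .ld_r2_em(pair[, 1], pair[, 2])
      if (abs(r2 - pr$target_r2) <= 0.05 && r2 >= proxy_r2_threshold &&
          ok_single(pair[, 1], v$eaf[ka], FALSE) &&
          ok_single(pair[, 2], v$eaf[kb], FALSE)) break
      if (att == max_attempts)
        stop("could not realize LD design target for pair ",
             pr$variant_a, "-", pr$variant_b)
    }
    dos[, ka] <- pair[, 1]
    dos[, kb] <- pair[, 2]
  }
  cols <- c("variant_id", "locus_label", "chrom", "pos",
            "effect_allele", "non_effect_allele", "eaf")
  panel <- genotype_panel(v[, cols], dos, sprintf("S%04d", seq_len(n)))
  cohort <- simulate_covariates(config)
  cohort <- simulate_phenotype(panel, cohort, config)
  structure(list(panel = panel, cohort = cohort, truth = config),
            class = "cohort_bundle")
}
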