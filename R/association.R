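#' Per-SNP covariate-adjusted additive regression
#'
#' For each panel variant, ordinary least squares of the depression
#' score on the effect-allele dosage plus covariates (sex, age and
#' ethnicity by default; ethnicity enters as a factor against the
#' `ethnicity_ref` reference level).  The per-allele coefficient, its
#' standard error and the t-test p-value of the dosage term are
#' reported.  Individuals missing that variant's genotype (or any model
#' variable) are excluded for that variant only.
#'
#' @param panel a [genotype_panel()].
#' @param cohort a `cohort_table` with a `depression` column.
#' @param covariates character vector of cohort columns to adjust for
#'   (use `character(0)` for an unadjusted model).
#' @param ethnicity_ref reference level when `ethnicity` is a covariate.
#' @return data.frame of class `assoc_results`: `variant_id`,
#'   `effect_allele`, `non_effect_allele`, `eaf`, `beta`, `se`, `p`,
#'   `n_used`, `status` (`"ok"` or `"degenerate"` when the dosage has no
#'   variance after exclusions, in which case `beta` is `NA`, not 0).
#' @export
fit_snp_regression <- function(panel, cohort,
                               covariates = c("sex", "age", "ethnicity"),
                               ethnicity_ref = "mixed") {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss) > 0L)
    stop("cohort lacks covariate column(s): ",
         paste(miss, collapse = ", "))
  idx <- match(panel$sample_ids, cohort$sample_id)
  if (anyNA(idx))
    stop("panel sample(s) absent from cohort: ",
         paste(panel$sample_ids[is.na(idx)][1:5], collapse = ", "))
  dat <- cohort[idx, , drop = FALSE]
  if ("ethnicity" %in% covariates)
    dat$ethnicity <- stats::relevel(factor(dat$ethnicity),
                                    ref = ethnicity_ref)
  v <- panel$variants
  out <- data.frame(variant_id = v$variant_id,
                    effect_allele = v$effect_allele,
                    non_effect_allele = v$non_effect_allele,
                    eaf = unname(observed_eaf(panel)),
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n_used = NA_integer_, status = "ok",
                    stringsAsFactors = FALSE)
  rhs <- paste(c("dosage", covariates), collapse = " + ")
  fml <- as.formula(paste("depression ~", rhs))
  for (k in seq_len(nrow(v))) {
    d <- dat
    d$dosage <- panel$dosages[, k]
    d <- d[complete.cases(d[, c("depression", "dosage", covariates)]), ]
    out$n_used[k] <- nrow(d)
    if (nrow(d) < length(covariates) + 3 || var(d$dosage) == 0) {
      out$status[k] <- "degenerate"
      next
    }
    fit <- lm(fml, data = d)
    cf <- summary(fit)$coefficients
    if (!"dosage" %in% rownames(cf)) {
      out$status[k] <- "degenerate"
      next
    }
    out$beta[k] <- cf["dosage", 1]
    out$se[k] <- cf["dosage", 2]
    out$p[k] <- cf["dosage", 4]
  }
  class(out) <- c("assoc_results", "data.frame")
  out
}

#' Mann--Whitney screen of binary social factors
#'
#' Tests each binary factor's effect on the outcome with the two-sided
#' Mann--Whitney U (Wilcoxon rank-sum) test: exact when both groups have
#' at most `exact_limit` observations and there are no ties, otherwise
#' the normal approximation with tie and continuity correction.
#'
#' @param cohort a `cohort_table`.
#' @param factors character vector of binary cohort columns (two-level
#'   factors or 0/1 indicators), e.g. `sex`, `income`, `maltreatment`
#'   or the dichotomized PBI categories.
#' @param outcome outcome column, default `depression`.
#' @param exact_limit exact-distribution group-size limit.
#' @param alpha,m family-wise error rate and number of tests; the
#'   significance flag compares p against [correction_threshold()].
#' @return data.frame of class `screen_results` with group labels,
#'   sizes, means, SDs, the U statistic, the two-sided p-value and
#'   `significant_after_correction`.
#' @export
mannwhitney_screen <- function(cohort, factors, outcome = "depression",
                               exact_limit = 8, alpha = 0.05,
                               m = length(factors)) {
  thr <- correction_threshold(alpha, m)
  rows <- lapply(factors, function(f) {
    if (!f %in% names(cohort)) stop("cohort lacks factor column: ", f)
    g <- cohort[[f]]
    if (is.numeric(g)) g <- factor(g, levels = sort(unique(g[!is.na(g)])))
    g <- droplevels(factor(g))
    if (nlevels(g) != 2)
      stop("factor ", f, " is not binary (levels: ",
           paste(levels(g), collapse = ", "), ")")
    y <- cohort[[outcome]]
    keep <- !is.na(y) & !is.na(g)
    y <- y[keep]; g <- g[keep]
    y1 <- y[g == levels(g)[1]]
    y2 <- y[g == levels(g)[2]]
    if (length(y1) == 0 || length(y2) == 0)
      stop("factor ", f, " has an empty group")
    use_exact <- length(y1) <= exact_limit && length(y2) <= exact_limit &&
      !anyDuplicated(y)
    wt <- suppressWarnings(
      wilcox.test(y1, y2, exact = use_exact, correct = TRUE))
    pval <- wt$p.value
    if (is.nan(pval)) pval <- 1  # zero-variance data: no evidence
    data.frame(factor = f,
               level1 = levels(g)[1], level2 = levels(g)[2],
               n1 = length(y1), n2 = length(y2),
               mean1 = mean(y1), sd1 = sd(y1),
               mean2 = mean(y2), sd2 = sd(y2),
               U = unname(wt$statistic), p = pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant_after_correction <- out$p < thr$threshold
  attr(out, "threshold") <- thr
  class(out) <- c("screen_results", "data.frame")
  out
}

#' Per-test multiple-testing threshold
#'
#' The Bonferroni bound `alpha / m` over `m` tests, reported both at
#' full precision and rounded (half-up) to two significant figures for
#' display.
#'
#' @param alpha family-wise error rate in `(0, 1)`.
#' @param m number of tests (>= 1).
#' @return List of class `correction_threshold` with elements
#'   `threshold` (full precision), `displayed` (2 significant figures),
#'   `alpha` and `m`.
#' @examples
#' correction_threshold(0.05, 8)  # 0.00625, displayed 0.0063
#' @export
correction_threshold <- function(alpha = 0.05, m) {
  if (m < 1 || m != round(m)) stop("m must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  thr <- alpha / m
  # round half-up to 2 significant figures
  d <- 1 - floor(log10(thr))
  displayed <- floor(thr * 10^d + 0.5) / 10^d
  structure(list(threshold = thr, displayed = displayed,
                 alpha = alpha, m = as.integer(m)),
            class = "correction_threshold")
}

#' @export
print.correction_threshold <- function(x, ...) {
  cat("per-test threshold ", x$alpha, "/", x$m, " = ", x$threshold,
      " (displayed ", x$displayed, ")\n", sep = "")
  invisible(x)
}
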