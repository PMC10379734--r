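.social_candidates <- c("income", "full_family", "maltreatment",
                        "maternal_care_cat", "maternal_protection_cat",
                        "paternal_care_cat", "paternal_protection_cat")

#' Fit one linear regression model
#'
#' Ordinary least squares of `outcome` on the listed predictor terms
#' (factors expand to dummies; `ethnicity` is releveled to
#' `ethnicity_ref`), on the complete cases of the variables involved.
#' Reports the coefficient table, R2, adjusted R2
#' (`1 - (1 - R2)(n - 1)/(n - k - 1)` with `k` non-intercept columns),
#' the overall F test against the intercept-only model, and a Gaussian
#' AIC computed as `n log(RSS/n) + 2(k + 2)` (intercept and residual
#' variance counted as parameters; only AIC differences are
#' meaningful).
#'
#' @param data data.frame holding `outcome` and all `terms` (e.g. a
#'   `cohort_table` with a `pgs` column merged in).
#' @param terms character vector of predictor column names.
#' @param outcome outcome column name.
#' @param ethnicity_ref reference level for `ethnicity`.
#' @return Object of class `model_fit`: list with `coefficients` (term,
#'   beta, se, p), `r2`, `adjusted_r2`, `f_statistic`, `model_p`,
#'   `aic`, `n_used`, `terms`, `outcome` and the underlying `lm`.
#' @export
fit_linear_model <- function(data, terms, outcome = "depression",
                             ethnicity_ref = "mixed") {
  if (length(terms) < 1) stop("at least one predictor term is required")
  miss <- setdiff(c(outcome, terms), names(data))
  if (length(miss) > 0L)
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, c(outcome, terms), drop = FALSE]), ,
            drop = FALSE]
  if ("ethnicity" %in% terms)
    d$ethnicity <- stats::relevel(factor(d$ethnicity), ref = ethnicity_ref)
  fml <- as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  fit <- lm(fml, data = d)
  al <- stats::alias(fit)$Complete
  if (!is.null(al) && nrow(al) > 0)
    stop("rank-deficient design; aliased term(s): ",
         paste(rownames(al), collapse = ", "))
  sm <- summary(fit)
  k <- length(coef(fit)) - 1L
  n <- nrow(d)
  if (n <= k + 1) stop("too few complete cases (", n, ") for ", k,
                       " predictor columns")
  rss <- sum(fit$residuals^2)
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  cf <- sm$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(cf), beta = cf[, 1],
                              se = cf[, 2], p = cf[, 4],
                              row.names = NULL,
                              stringsAsFactors = FALSE),
    r2 = unname(sm$r.squared), adjusted_r2 = unname(sm$adj.r.squared),
    f_statistic = unname(if (is.null(fstat)) NA_real_ else fstat[1]),
    model_p = model_p,
    aic = n * log(rss / n) + 2 * (k + 2),
    n_used = n, terms = terms, outcome = outcome, lm = fit),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", x$outcome, " ~ ",
      paste(x$terms, collapse = " + "), "\n", sep = "")
  cat(sprintf("  n = %d, r2 = %.4f, adj r2 = %.4f, model p = %.3g, AIC = %.2f\n",
              x$n_used, x$r2, x$adjusted_r2, x$model_p, x$aic))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Backward elimination by AIC
#'
#' Starting from the full term set, repeatedly removes the single
#' non-forced term whose removal most decreases the model AIC, stopping
#' when no removal decreases it; ties break toward the earlier position
#' in the declared term order.  All candidate models are fitted on the
#' complete cases of the full model, so AICs are comparable.
#'
#' @inheritParams fit_linear_model
#' @param forced terms never considered for removal.
#' @return The final `model_fit`, with the elimination path (a
#'   data.frame `step`, `removed`, `aic_before`, `aic_after`) attached
#'   as attribute `"path"`.
#' @export
backward_eliminate <- function(data, terms, forced = character(),
                               outcome = "depression",
                               ethnicity_ref = "mixed") {
  if (!all(forced %in% terms)) stop("forced terms must be a subset of terms")
  d <- data[complete.cases(data[, c(outcome, terms), drop = FALSE]), ,
            drop = FALSE]
  cur <- terms
  fit <- fit_linear_model(d, cur, outcome, ethnicity_ref)
  path <- data.frame(step = integer(), removed = character(),
                     aic_before = numeric(), aic_after = numeric(),
                     stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    removable <- setdiff(cur, forced)
    if (length(removable) == 0) break
    aics <- vapply(removable, function(tm)
      fit_linear_model(d, setdiff(cur, tm), outcome, ethnicity_ref)$aic,
      numeric(1))
    best <- which(aics == min(aics))[1]   # ties: earlier declared order
    if (aics[best] >= fit$aic) break
    step_i <- step_i + 1L
    path <- rbind(path, data.frame(step = step_i,
                                   removed = removable[best],
                                   aic_before = fit$aic,
                                   aic_after = aics[best],
                                   stringsAsFactors = FALSE))
    cur <- setdiff(cur, removable[best])
    fit <- fit_linear_model(d, cur, outcome, ethnicity_ref)
  }
  attr(fit, "path") <- path
  fit
}

#' Fit the four nested PGS models
#'
#' Model 1: PGS alone.  Model 2: sex, ethnicity and age.  Model 3: PGS
#' plus sex, age and ethnicity.  Model 4: Model 3 plus the social
#' candidate predictors (family income, rearing in a full family,
#' maltreatment and the four PBI categories), reduced by AIC backward
#' elimination with the Model 3 terms forced to stay.
#'
#' @param data cohort data.frame with a `pgs` column.
#' @param base_covariates demographic covariates (Model 2 terms).
#' @param social_candidates candidate pool for Model 4.
#' @param outcome outcome column.
#' @param ethnicity_ref reference ethnicity level.
#' @return Named list `model1`..`model4` of `model_fit` objects
#'   (`model4` carries its elimination path attribute).
#' @export
fit_nested_models <- function(data,
                              base_covariates = c("sex", "age",
                                                  "ethnicity"),
                              social_candidates = .social_candidates,
                              outcome = "depression",
                              ethnicity_ref = "mixed") {
  list(
    model1 = fit_linear_model(data, "pgs", outcome, ethnicity_ref),
    model2 = fit_linear_model(data, base_covariates, outcome,
                              ethnicity_ref),
    model3 = fit_linear_model(data, c("pgs", base_covariates), outcome,
                              ethnicity_ref),
    model4 = backward_eliminate(
      data, c("pgs", base_covariates, social_candidates),
      forced = c("pgs", base_covariates), outcome = outcome,
      ethnicity_ref = ethnicity_ref))
}

#' Run the full model suite
#'
#' Builds weighted and unweighted in-sample PGS from per-SNP
#' association results, scores the cohort, and fits the four nested
#' models in each requested condition (scoring mode x subgroup).  In
#' the women-only subgroup sex is constant and is dropped from the
#' covariates.  Subgroups too small to fit are skipped with a warning.
#'
#' @param panel QC'd [genotype_panel()].
#' @param cohort a `cohort_table`.
#' @param assoc optional `assoc_results`; computed with
#'   [fit_snp_regression()] when `NULL`.
#' @param modes scoring modes to run.
#' @param subgroups subset of `c("all", "women")`.
#' @param missing_policy passed to [score_individuals()].
#' @param social_candidates candidate social predictors for Model 4.
#' @return Object of class `model_suite`: list with `fits` (per
#'   condition, the four `model_fit`s), `adjusted_r2` (matrix, rows =
#'   models 1--4, columns = conditions), `assoc`, and `scores` per mode.
#' @export
run_model_suite <- function(panel, cohort, assoc = NULL,
                            modes = c("weighted", "unweighted"),
                            subgroups = c("all", "women"),
                            missing_policy = "mean_dosage",
                            social_candidates = .social_candidates) {
  if (is.null(assoc)) assoc <- fit_snp_regression(panel, cohort)
  scores <- lapply(setNames(modes, modes), function(md)
    score_individuals(panel, build_weights(assoc, mode = md),
                      missing_policy = missing_policy))
  fits <- list()
  for (md in modes) {
    dat <- merge(cohort, scores[[md]][, c("sample_id", "pgs")],
                 by = "sample_id")
    for (sg in subgroups) {
      d <- if (sg == "women") dat[dat$sex == "woman", , drop = FALSE]
           else dat
      covs <- if (sg == "women") c("age", "ethnicity")
              else c("sex", "age", "ethnicity")
      cond <- paste(md, sg, sep = "_")
      if (nrow(d) < length(covs) + length(social_candidates) + 10) {
        warning("subgroup ", sg, " too small (", nrow(d),
                " rows); skipped")
        next
      }
      fits[[cond]] <- fit_nested_models(
        d, base_covariates = covs,
        social_candidates = social_candidates)
    }
  }
  if (length(fits) == 0) stop("no condition could be fitted")
  adj <- vapply(fits, function(f)
    vapply(f, function(m) m$adjusted_r2, numeric(1)), numeric(4))
  rownames(adj) <- paste0("model", 1:4)
  structure(list(fits = fits, adjusted_r2 = adj, assoc = assoc,
                 scores = scores),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("<model_suite> adjusted r2 by condition:\n")
  print(round(x$adjusted_r2, 4))
  for (cond in names(x$fits)) {
    p <- attr(x$fits[[cond]]$model4, "path")
    if (nrow(p) > 0)
      cat("  ", cond, ": eliminated ",
          paste(p$removed, collapse = ", "), "\n", sep = "")
    else cat("  ", cond, ": no term eliminated\n", sep = "")
  }
  invisible(x)
}

#' Incremental variance-explained table
#'
#' @param suite a `model_suite`.
#' @return data.frame in long form: condition, model, adjusted_r2,
#'   r2, model_p, n_used.
#' @export
variance_explained_table <- function(suite) {
  rows <- lapply(names(suite$fits), function(cond)
    do.call(rbind, lapply(paste0("model", 1:4), function(mid) {
      m <- suite$fits[[cond]][[mid]]
      data.frame(condition = cond, model = mid,
                 r2 = m$r2, adjusted_r2 = m$adjusted_r2,
                 model_p = m$model_p, n_used = m$n_used,
                 stringsAsFactors = FALSE)
    })))
  do.call(rbind, rows)
}

#' Bar chart of adjusted r2 across models and conditions
#'
#' @param suite a `model_suite`.
#' @return A ggplot object.
#' @export
plot_variance_explained <- function(suite) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tab <- variance_explained_table(suite)
  ggplot2::ggplot(tab, ggplot2::aes(x = model, y = adjusted_r2,
                                    fill = condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "adjusted r²") +
    ggplot2::theme_minimal()
}
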