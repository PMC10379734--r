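#' Hardy--Weinberg exact test
#'
#' Exact two-sided test of Hardy--Weinberg proportions from genotype
#' counts: conditional on the observed allele counts, the probability of
#' every heterozygote count whose conditional probability does not
#' exceed that of the observed count is summed.
#'
#' @param n_hom_effect count of effect-allele homozygotes.
#' @param n_het count of heterozygotes.
#' @param n_hom_other count of non-effect-allele homozygotes.
#' @return Exact p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(10, 40, 50)
#' @export
hwe_exact_test <- function(n_hom_effect, n_het, n_hom_other) {
  counts <- c(n_hom_effect, n_het, n_hom_other)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("all genotype counts are zero")
  n_a <- 2 * n_hom_effect + n_het          # effect-allele count
  hs <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  # log conditional probability of each possible heterozygote count
  logp <- lfactorial(n) - lfactorial(hs) - lfactorial((n_a - hs) / 2) -
    lfactorial(n - (n_a + hs) / 2) + hs * log(2)
  logp <- logp - max(logp)
  p_h <- exp(logp) / sum(exp(logp))
  obs <- match(n_het, hs)
  min(1, sum(p_h[p_h <= p_h[obs] * (1 + 1e-12)]))
}

#' Hardy--Weinberg chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test against expected
#' proportions p^2, 2pq, q^2 (no continuity correction).  Offered as the
#' large-sample alternative to [hwe_exact_test()].
#'
#' @inheritParams hwe_exact_test
#' @return Asymptotic p-value.
#' @export
hwe_chisq_test <- function(n_hom_effect, n_het, n_hom_other) {
  n <- n_hom_effect + n_het + n_hom_other
  if (n < 1) stop("all genotype counts are zero")
  p <- (2 * n_hom_effect + n_het) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_hom_effect, n_het, n_hom_other)
  if (any(e == 0)) return(1)
  stat <- sum((o - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# EM haplotype-frequency r2 from two unphased dosage vectors
.ld_r2_em <- function(xa, xb, tol = 1e-12, max_iter = 1000L) {
  keep <- !is.na(xa) & !is.na(xb)
  xa <- xa[keep]; xb <- xb[keep]
  if (length(xa) < 2) stop("fewer than 2 individuals non-missing at both")
  p_a <- mean(xa) / 2
  p_b <- mean(xb) / 2
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    warning("monomorphic variant; r2 defined as 0")
    return(0)
  }
  n <- length(xa)
  # genotype table counts indexed by dosages (0..2, 0..2)
  tab <- table(factor(xa, 0:2), factor(xb, 0:2))
  # haplotype freqs: 1=ab 2=aB 3=Ab 4=AB (A/B = effect alleles)
  h <- c((1 - p_a) * (1 - p_b), (1 - p_a) * p_b,
         p_a * (1 - p_b), p_a * p_b)
  dh <- tab["1", "1"]                       # double heterozygotes
  for (it in seq_len(max_iter)) {
    # unambiguous haplotype counts from all non-double-het cells
    c_ab <- 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"]
    c_aB <- 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"]
    c_Ab <- 2 * tab["2", "0"] + tab["1", "0"] + tab["2", "1"]
    c_AB <- 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"]
    # E-step: split double hets between AB/ab and Ab/aB phases
    w <- h[4] * h[1]
    w2 <- h[3] * h[2]
    frac <- if (w + w2 > 0) w / (w + w2) else 0.5
    new_h <- c(c_ab + dh * frac, c_aB + dh * (1 - frac),
               c_Ab + dh * (1 - frac), c_AB + dh * frac) / (2 * n)
    if (max(abs(new_h - h)) < tol) { h <- new_h; break }
    h <- new_h
  }
  d <- h[4] - (h[3] + h[4]) * (h[2] + h[4])
  pa <- h[3] + h[4]; pb <- h[2] + h[4]
  denom <- pa * (1 - pa) * pb * (1 - pb)
  if (denom <= 0) return(0)
  unname(min(1, d^2 / denom))
}

#' Linkage-disequilibrium r2 between two panel variants
#'
#' The default estimator reconstructs maximum-likelihood haplotype
#' frequencies from unphased genotypes by expectation--maximization and
#' returns `r2 = D^2 / (pA qA pB qB)` (the estimator PLINK reports for
#' unphased data); `method = "genotype"` returns the squared Pearson
#' correlation of the dosage vectors instead.
#'
#' @param panel a [genotype_panel()].
#' @param variant_a,variant_b variant ids.
#' @param method `"em"` (haplotype-frequency r2) or `"genotype"`.
#' @return r2 in `[0, 1]`; monomorphic input gives 0 with a warning.
#' @export
ld_r2 <- function(panel, variant_a, variant_b,
                  method = c("em", "genotype")) {
  method <- match.arg(method)
  for (id in c(variant_a, variant_b))
    if (!id %in% panel$variants$variant_id)
      stop("variant not in panel: ", id)
  xa <- panel$dosages[, variant_a]
  xb <- panel$dosages[, variant_b]
  if (method == "em") return(.ld_r2_em(xa, xb))
  keep <- !is.na(xa) & !is.na(xb)
  if (var(xa[keep]) == 0 || var(xb[keep]) == 0) {
    warning("monomorphic variant; r2 defined as 0")
    return(0)
  }
  cor(xa[keep], xb[keep])^2
}

#' Variant-level quality control
#'
#' Applies the exclusion cascade in fixed order: call rate, minor allele
#' frequency, Hardy--Weinberg, then LD proxy pruning among variants
#' sharing a `locus_label`.  For a flagged proxy pair, an explicit
#' `proxy_keep` list decides which member survives; otherwise the member
#' with the smaller association p-value from a preliminary
#' covariate-adjusted pass over `cohort` is kept (ties and missing
#' p-values fall back to panel order).
#'
#' @param panel a [genotype_panel()].
#' @param cohort optional `cohort_table`, needed only when a flagged
#'   proxy pair is not resolved by `proxy_keep`.
#' @param call_rate_min keep variants with call rate above this.
#' @param maf_min keep variants with minor allele frequency above this.
#' @param hwe_alpha drop variants with HWE p below this.
#' @param hwe_method `"exact"` or `"chisq"`.
#' @param proxy_r2_threshold r2 at or above which an intra-locus pair is
#'   pruned.
#' @param proxy_keep character; preferred member per pruned pair.
#'   Naming both members of a flagged pair is an error.
#' @param ld_method passed to [ld_r2()].
#' @return List with `panel` (the filtered panel) and `report` (a
#'   `qc_report` data.frame with one row per input variant: `call_rate`,
#'   `eaf`, `maf`, `hwe_p`, `status`, `proxy_partner`, `proxy_r2`).
#' @export
run_qc <- function(panel, cohort = NULL, call_rate_min = 0.98,
                   maf_min = 0.05, hwe_alpha = 0.05,
                   hwe_method = c("exact", "chisq"),
                   proxy_r2_threshold = 0.2, proxy_keep = NULL,
                   ld_method = "em") {
  hwe_method <- match.arg(hwe_method)
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1,
            hwe_alpha >= 0, hwe_alpha <= 1,
            proxy_r2_threshold >= 0, proxy_r2_threshold <= 1)
  v <- panel$variants
  hwe_fun <- if (hwe_method == "exact") hwe_exact_test else hwe_chisq_test
  rep <- data.frame(variant_id = v$variant_id,
                    locus_label = v$locus_label,
                    call_rate = unname(variant_call_rate(panel)),
                    eaf = unname(observed_eaf(panel)),
                    hwe_p = NA_real_, status = "kept",
                    proxy_partner = NA_character_, proxy_r2 = NA_real_,
                    stringsAsFactors = FALSE)
  rep$maf <- pmin(rep$eaf, 1 - rep$eaf)

  rep$status[rep$call_rate <= call_rate_min] <- "dropped_callrate"
  alive <- rep$status == "kept"
  rep$status[alive & rep$maf <= maf_min] <- "dropped_maf"
  alive <- rep$status == "kept"
  for (k in which(alive)) {
    cnt <- genotype_counts(panel, rep$variant_id[k])
    rep$hwe_p[k] <- hwe_fun(cnt[1], cnt[2], cnt[3])
  }
  rep$status[alive & !is.na(rep$hwe_p) & rep$hwe_p < hwe_alpha] <-
    "dropped_hwe"

  # proxy pruning among surviving variants sharing a locus label
  alive_ids <- rep$variant_id[rep$status == "kept"]
  assoc <- NULL
  for (locus in unique(rep$locus_label[rep$status == "kept"])) {
    ids <- rep$variant_id[rep$status == "kept" &
                            rep$locus_label == locus]
    if (length(ids) < 2) next
    for (i in seq_along(ids)[-length(ids)])
      for (j in seq((i + 1), length(ids))) {
        a <- ids[i]; b <- ids[j]
        if (rep$status[rep$variant_id == a] != "kept" ||
            rep$status[rep$variant_id == b] != "kept") next
        r2 <- ld_r2(panel, a, b, method = ld_method)
        if (r2 < proxy_r2_threshold) next
        in_keep <- c(a, b) %in% proxy_keep
        if (all(in_keep))
          stop("proxy_keep names both members of flagged pair ",
               a, "-", b)
        if (any(in_keep)) {
          drop_id <- c(a, b)[!in_keep]
        } else {
          if (is.null(cohort))
            stop("proxy pair ", a, "-", b, " at r2 = ", signif(r2, 3),
                 " needs either proxy_keep or a cohort for the ",
                 "preliminary association pass")
          if (is.null(assoc))
            assoc <- fit_snp_regression(panel, cohort)
          pa <- assoc$p[assoc$variant_id == a]
          pb <- assoc$p[assoc$variant_id == b]
          drop_id <- if (isTRUE(pb < pa)) a else b
        }
        keep_id <- setdiff(c(a, b), drop_id)
        krow <- rep$variant_id == drop_id
        rep$status[krow] <- "dropped_proxy"
        rep$proxy_partner[krow] <- keep_id
        rep$proxy_r2[krow] <- r2
      }
  }
  kept <- rep$variant_id[rep$status == "kept"]
  class(rep) <- c("qc_report", "data.frame")
  list(panel = subset_variants(panel, kept), report = rep)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", nrow(x), " variants: ",
      paste(names(table(x$status)), table(x$status),
            sep = " = ", collapse = ", "), "\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
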