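#' Build a scoring weight set from association results
#'
#' Orients every variant toward its risk-increasing allele: a
#' non-negative beta scores the effect allele with weight `|beta|`; a
#' negative beta scores the non-effect (alternative) allele with weight
#' `|beta|`, so that all weights are non-negative and every term raises
#' the predicted depression score.  Unweighted mode applies the same
#' allele orientation with every weight set to 1.
#'
#' @param assoc `assoc_results` from [fit_snp_regression()] (or any
#'   data.frame with `variant_id`, `effect_allele`, `non_effect_allele`,
#'   `beta`); undefined betas are an error.
#' @param mode `"weighted"` or `"unweighted"`.
#' @param provenance `"in_sample"` or `"external"`.
#' @param source_label free-text provenance label.
#' @return data.frame of class `weight_set` (`variant_id`,
#'   `scoring_allele`, `weight`) with attributes `mode`, `provenance`,
#'   `source_label`.
#' @export
build_weights <- function(assoc, mode = c("weighted", "unweighted"),
                          provenance = "in_sample",
                          source_label = provenance) {
  mode <- match.arg(mode)
  if (nrow(assoc) == 0L) stop("no association results to build from")
  if (anyNA(assoc$beta))
    stop("undefined beta for: ",
         paste(assoc$variant_id[is.na(assoc$beta)], collapse = ", "))
  if (any(assoc$beta == 0))
    warning("beta exactly 0 for ",
            paste(assoc$variant_id[assoc$beta == 0], collapse = ", "),
            "; scoring allele orientation is arbitrary")
  neg <- assoc$beta < 0
  out <- data.frame(
    variant_id = assoc$variant_id,
    scoring_allele = ifelse(neg, assoc$non_effect_allele,
                            assoc$effect_allele),
    weight = if (mode == "weighted") abs(assoc$beta)
             else rep(1, nrow(assoc)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$variant_id)) stop("duplicate variant_id")
  structure(out, mode = mode, provenance = provenance,
            source_label = source_label,
            class = c("weight_set", "data.frame"))
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize external summary-statistic weights to a panel
#'
#' Aligns each external (published) effect to the panel's allele
#' orientation: matching alleles keep the beta; swapped alleles negate
#' it; alleles matching only after strand complementation are
#' complemented first and then the same rules apply.  Strand-ambiguous
#' variants (A/T or C/G) are dropped by default because strand cannot be
#' inferred from the alleles; unresolvable or absent variants are
#' dropped.  The oriented signed betas are then passed through the
#' [build_weights()] recoding, so the returned weights are non-negative.
#'
#' @param raw data.frame from [read_weights()].
#' @param panel a [genotype_panel()].
#' @param mode `"weighted"` or `"unweighted"`.
#' @param drop_ambiguous drop A/T and C/G variants (default `TRUE`).
#' @param source_label provenance label for the weight set.
#' @return List with `weights` (a `weight_set`, provenance
#'   `"external"`) and `log` (data.frame recording the action taken for
#'   every input row: `kept`, `flipped`, `strand_complemented`,
#'   `strand_complemented_flipped`, `dropped_ambiguous`,
#'   `dropped_absent`, `dropped_unresolvable`).
#' @export
harmonize_external_weights <- function(raw, panel,
                                       mode = c("weighted", "unweighted"),
                                       drop_ambiguous = TRUE,
                                       source_label = "external") {
  mode <- match.arg(mode)
  v <- panel$variants
  log <- data.frame(variant_id = raw$variant_id,
                    action = NA_character_,
                    beta_in = raw$beta, beta_out = NA_real_,
                    stringsAsFactors = FALSE)
  oriented <- data.frame(variant_id = character(),
                         effect_allele = character(),
                         non_effect_allele = character(),
                         beta = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(raw))) {
    id <- raw$variant_id[i]
    ea <- toupper(raw$effect_allele[i])
    nea <- toupper(raw$non_effect_allele[i])
    k <- match(id, v$variant_id)
    if (is.na(k)) { log$action[i] <- "dropped_absent"; next }
    if (drop_ambiguous && identical(unname(.complement[ea]), nea)) {
      log$action[i] <- "dropped_ambiguous"; next
    }
    pea <- v$effect_allele[k]; pnea <- v$non_effect_allele[k]
    beta <- raw$beta[i]
    if (ea == pea && nea == pnea) {
      act <- "kept"
    } else if (ea == pnea && nea == pea) {
      beta <- -beta; act <- "flipped"
    } else {
      cea <- unname(.complement[ea]); cnea <- unname(.complement[nea])
      if (identical(cea, pea) && identical(cnea, pnea)) {
        act <- "strand_complemented"
      } else if (identical(cea, pnea) && identical(cnea, pea)) {
        beta <- -beta; act <- "strand_complemented_flipped"
      } else {
        log$action[i] <- "dropped_unresolvable"; next
      }
    }
    log$action[i] <- act
    log$beta_out[i] <- beta
    oriented <- rbind(oriented, data.frame(
      variant_id = id, effect_allele = pea, non_effect_allele = pnea,
      beta = beta, stringsAsFactors = FALSE))
  }
  if (nrow(oriented) == 0L)
    stop("no scorable variants after harmonization")
  list(weights = build_weights(oriented, mode = mode,
                               provenance = "external",
                               source_label = source_label),
       log = log)
}

#' Score individuals with a weight set
#'
#' Computes, for every individual, the weighted sum of scoring-allele
#' dosages: when a variant's scoring allele is the panel's effect
#' allele the dosage enters as `x`, and when it is the non-effect
#' allele as `2 - x`.  Missing genotypes are handled per
#' `missing_policy`: `"mean_dosage"` substitutes the variant's cohort
#' mean scoring-allele dosage (the convention of standard scoring
#' software); `"skip"` omits the term.
#'
#' @param panel a [genotype_panel()].
#' @param weights a `weight_set`.
#' @param missing_policy `"mean_dosage"` or `"skip"`.
#' @return data.frame of class `score_vector`: `sample_id`, `pgs`,
#'   `n_variants_used` (under `"mean_dosage"`, every matched variant
#'   counts as used; under `"skip"`, only non-missing genotypes do).
#' @export
score_individuals <- function(panel, weights,
                              missing_policy = c("mean_dosage", "skip")) {
  missing_policy <- match.arg(missing_policy)
  v <- panel$variants
  idx <- match(weights$variant_id, v$variant_id)
  absent <- is.na(idx)
  if (all(absent)) stop("no weight variant is present in the panel")
  if (any(absent))
    warning("weight variant(s) absent from panel, excluded: ",
            paste(weights$variant_id[absent], collapse = ", "))
  w <- weights[!absent, , drop = FALSE]
  idx <- idx[!absent]
  d <- panel$dosages[, idx, drop = FALSE]
  is_ea <- w$scoring_allele == v$effect_allele[idx]
  is_nea <- w$scoring_allele == v$non_effect_allele[idx]
  if (any(!is_ea & !is_nea)) {
    bad <- w$variant_id[!is_ea & !is_nea]
    warning("scoring allele matches neither panel allele, excluded: ",
            paste(bad, collapse = ", "))
    keep <- is_ea | is_nea
    if (!any(keep)) stop("no weight variant is present in the panel")
    w <- w[keep, , drop = FALSE]; d <- d[, keep, drop = FALSE]
    is_nea <- is_nea[keep]
  }
  storage.mode(d) <- "double"
  d[, is_nea] <- 2 - d[, is_nea]
  miss <- is.na(d)
  if (missing_policy == "mean_dosage") {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0          # variant missing in everyone
    for (k in which(colSums(miss) > 0)) d[miss[, k], k] <- mu[k]
    n_used <- rep(nrow(w), nrow(d))
  } else {
    d[miss] <- 0
    n_used <- nrow(w) - rowSums(miss)
  }
  pgs <- as.vector(d %*% w$weight)
  structure(data.frame(sample_id = panel$sample_ids, pgs = pgs,
                       n_variants_used = as.integer(n_used),
                       stringsAsFactors = FALSE),
            weight_mode = attr(weights, "mode"),
            missing_policy = missing_policy,
            class = c("score_vector", "data.frame"))
}
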