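#' Genotype panel container
#'
#' Bundles a variant table with an effect-allele dosage matrix.  Dosages
#' count copies of each variant's effect allele (0, 1, 2) with `NA` as
#' the missing sentinel; rows are individuals, columns variants.
#'
#' @param variants data.frame with columns `variant_id`, `locus_label`,
#'   `chrom`, `pos`, `effect_allele`, `non_effect_allele` and optionally
#'   `eaf` (effect-allele frequency, `NA` allowed).
#' @param dosages integer matrix, `length(sample_ids)` rows by
#'   `nrow(variants)` columns, entries in `{0, 1, 2, NA}`.
#' @param sample_ids character vector of unique individual identifiers.
#' @return An object of class `genotype_panel`: a list with elements
#'   `variants`, `dosages` (dimnames set from ids) and `sample_ids`.
#' @examples
#' v <- data.frame(variant_id = "rs1", locus_label = "GENE", chrom = "1",
#'                 pos = 100L, effect_allele = "A", non_effect_allele = "G",
#'                 eaf = 0.25)
#' genotype_panel(v, matrix(c(0L, 1L, 2L), ncol = 1), c("s1", "s2", "s3"))
#' @export
genotype_panel <- function(variants, dosages, sample_ids) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("variant_id", "locus_label", "chrom", "pos",
           "effect_allele", "non_effect_allele")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0L)
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"eaf" %in% names(variants)) variants$eaf <- NA_real_
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  sample_ids <- as.character(sample_ids)

  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id in panel: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in panel")
  if (nrow(dosages) != length(sample_ids) ||
      ncol(dosages) != nrow(variants))
    stop("dosage matrix is ", nrow(dosages), " x ", ncol(dosages),
         " but panel has ", length(sample_ids), " samples and ",
         nrow(variants), " variants")
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(dosages[bad]), collapse = ", "))
  if (any(!is.na(variants$eaf) &
          (variants$eaf < 0 | variants$eaf > 1)))
    stop("eaf outside [0, 1]")
  if (any(variants$effect_allele == variants$non_effect_allele))
    stop("effect and non-effect allele identical for: ",
         paste(variants$variant_id[
           variants$effect_allele == variants$non_effect_allele],
           collapse = ", "))
  if (any(variants$pos <= 0)) stop("positions must be positive (1-based)")

  dimnames(dosages) <- list(sample_ids, variants$variant_id)
  rownames(variants) <- NULL
  structure(list(variants = variants, dosages = dosages,
                 sample_ids = sample_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", length(x$sample_ids), " individuals x ",
      nrow(x$variants), " variants\n", sep = "")
  cat("  call rate: ",
      sprintf("%.4f", mean(!is.na(x$dosages))), "\n", sep = "")
  print(head(x$variants, 5))
  if (nrow(x$variants) > 5) cat("  ... and", nrow(x$variants) - 5, "more\n")
  invisible(x)
}

#' Number of samples / variants in a panel
#' @param panel a `genotype_panel`.
#' @return Integer count.
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' @rdname n_samples
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Subset a panel by variant id
#' @param panel a `genotype_panel`.
#' @param variant_ids character; ids to keep, in the order given.
#' @return A `genotype_panel` restricted to the requested variants.
#' @export
subset_variants <- function(panel, variant_ids) {
  idx <- match(variant_ids, panel$variants$variant_id)
  if (anyNA(idx))
    stop("variant(s) not in panel: ",
         paste(variant_ids[is.na(idx)], collapse = ", "))
  genotype_panel(panel$variants[idx, , drop = FALSE],
                 panel$dosages[, idx, drop = FALSE],
                 panel$sample_ids)
}

#' Flip the effect allele of selected variants
#'
#' Re-orients dosages toward the current non-effect allele: dosage
#' becomes `2 - x`, alleles swap, and `eaf` becomes `1 - eaf`.  Applying
#' the same flip twice is the identity.
#'
#' @param panel a `genotype_panel`.
#' @param variant_ids variants to flip.
#' @return The re-oriented `genotype_panel`.
#' @export
flip_effect_allele <- function(panel, variant_ids) {
  idx <- match(variant_ids, panel$variants$variant_id)
  if (anyNA(idx))
    stop("variant(s) not in panel: ",
         paste(variant_ids[is.na(idx)], collapse = ", "))
  v <- panel$variants
  ea <- v$effect_allele[idx]
  v$effect_allele[idx] <- v$non_effect_allele[idx]
  v$non_effect_allele[idx] <- ea
  v$eaf[idx] <- 1 - v$eaf[idx]
  d <- panel$dosages
  d[, idx] <- 2L - d[, idx]
  genotype_panel(v, d, panel$sample_ids)
}

#' Per-variant observed effect-allele frequency and call rate
#' @param panel a `genotype_panel`.
#' @return Named numeric vector over variants.
#' @export
observed_eaf <- function(panel) {
  colMeans(panel$dosages, na.rm = TRUE) / 2
}

#' @rdname observed_eaf
#' @export
variant_call_rate <- function(panel) {
  colMeans(!is.na(panel$dosages))
}

#' Observed genotype counts for one variant
#' @param panel a `genotype_panel`.
#' @param variant_id a single variant id.
#' @return Integer vector `c(n_hom_effect, n_het, n_hom_other)`.
#' @export
genotype_counts <- function(panel, variant_id) {
  if (!variant_id %in% panel$variants$variant_id)
    stop("variant not in panel: ", variant_id)
  x <- panel$dosages[, variant_id]
  c(n_hom_effect = sum(x == 2L, na.rm = TRUE),
    n_het = sum(x == 1L, na.rm = TRUE),
    n_hom_other = sum(x == 0L, na.rm = TRUE))
}
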