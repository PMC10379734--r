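#' Default Parental Bonding Instrument cut-offs
#'
#' Dichotomization cut-offs for the PBI care and protection scales,
#' separately for maternal and paternal ratings.  Scores greater than or
#' equal to the cut-off are assigned to the "high" category.
#'
#' @return Named list with elements `maternal_care` (27.0),
#'   `maternal_protection` (13.5), `paternal_care` (24.0) and
#'   `paternal_protection` (12.5).
#' @export
pbi_default_cutoffs <- function() {
  list(maternal_care = 27.0, maternal_protection = 13.5,
       paternal_care = 24.0, paternal_protection = 12.5)
}

#' Dichotomize a PBI scale score
#'
#' @param score numeric PBI raw score(s).
#' @param cutoff scalar cut-off; scores `>= cutoff` are "high" (a score
#'   exactly at the boundary is assigned to "high").
#' @return Factor with levels `low`, `high`.
#' @export
categorize_pbi <- function(score, cutoff) {
  factor(ifelse(score >= cutoff, "high", "low"), levels = c("low", "high"))
}

.cohort_levels <- list(
  sex = c("man", "woman"),
  ethnicity = c("mixed", "Russian", "Tatar", "Udmurt"),
  income = c("lower-than-average", "average-and-higher")
)

.pbi_scales <- c("maternal_care", "maternal_protection",
                 "paternal_care", "paternal_protection")

#' Read a cohort phenotype table
#'
#' Reads a tab-delimited cohort file with one row per individual and
#' derives the four dichotomous PBI categories from the raw scale
#' scores.  Required columns: `sample_id`, `depression` (BDI-II total,
#' integer 0--63, may be missing), `sex` (`man`/`woman`), `age`,
#' `ethnicity` (`Russian`/`Tatar`/`Udmurt`/`mixed`), `income`
#' (`lower-than-average`/`average-and-higher`), `full_family` (0/1),
#' `maltreatment` (0/1), and the raw PBI scores `maternal_care`,
#' `maternal_protection`, `paternal_care`, `paternal_protection`.
#'
#' @param path file path of the TSV ('.' or empty cell = missing).
#' @param pbi_cutoffs cut-off list as from [pbi_default_cutoffs()].
#' @param age_range plausible age bounds; ages outside are rejected.
#' @return A data.frame of class `cohort_table`; PBI categories appear
#'   as factor columns `*_cat` with levels `low`/`high`; rows with a
#'   missing depression score are retained (flagged in the logical
#'   column `depression_missing`).
#' @export
read_cohort_table <- function(path, pbi_cutoffs = pbi_default_cutoffs(),
                              age_range = c(10, 90)) {
  dat <- read.table(path, header = TRUE, sep = "\t",
                    na.strings = c("NA", ".", ""),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(dat) == 0L) stop("cohort file has no data rows: ", path)
  as_cohort_table(dat, pbi_cutoffs = pbi_cutoffs, age_range = age_range)
}

#' Validate a data.frame as a cohort table
#'
#' @param dat data.frame with the columns documented in
#'   [read_cohort_table()].
#' @inheritParams read_cohort_table
#' @return A validated `cohort_table` with derived PBI categories.
#' @export
as_cohort_table <- function(dat, pbi_cutoffs = pbi_default_cutoffs(),
                            age_range = c(10, 90)) {
  req <- c("sample_id", "depression", "sex", "age", "ethnicity", "income",
           "full_family", "maltreatment", .pbi_scales)
  miss <- setdiff(req, names(dat))
  if (length(miss) > 0L)
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  dat$sample_id <- as.character(dat$sample_id)
  if (anyDuplicated(dat$sample_id)) stop("duplicate sample_id in cohort")

  for (col in c("sex", "ethnicity", "income")) {
    lev <- .cohort_levels[[col]]
    bad <- setdiff(unique(dat[[col]][!is.na(dat[[col]])]), lev)
    if (length(bad) > 0L)
      stop("unknown ", col, " level(s): ", paste(bad, collapse = ", "))
    dat[[col]] <- factor(dat[[col]], levels = lev)
  }
  for (col in c("full_family", "maltreatment")) {
    v <- dat[[col]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop(col, " must be 0/1")
    dat[[col]] <- as.integer(v)
  }
  dep <- dat$depression
  if (any(!is.na(dep) & (dep < 0 | dep > 63 | dep != round(dep))))
    stop("depression must be an integer in [0, 63]")
  dat$depression <- as.integer(dep)
  dat$depression_missing <- is.na(dat$depression)
  if (any(!is.na(dat$age) &
          (dat$age < age_range[1] | dat$age > age_range[2])))
    stop("age outside plausible range [", age_range[1], ", ",
         age_range[2], "]")
  for (sc in .pbi_scales)
    dat[[paste0(sc, "_cat")]] <- categorize_pbi(dat[[sc]], pbi_cutoffs[[sc]])
  class(dat) <- c("cohort_table", "data.frame")
  attr(dat, "pbi_cutoffs") <- pbi_cutoffs
  dat
}

#' Write a cohort table
#' @param cohort a `cohort_table`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_table <- function(cohort, path) {
  keep <- setdiff(names(cohort),
                  c("depression_missing", paste0(.pbi_scales, "_cat")))
  write.table(cohort[, keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a variant weights file
#'
#' Tab-delimited with header `variant_id`, `effect_allele`,
#' `non_effect_allele`, `beta`; betas are signed, as published.
#'
#' @param path file path.
#' @return data.frame preserving file order; empty body gives a 0-row
#'   data.frame.
#' @export
read_weights <- function(path) {
  dat <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "character"))
  req <- c("variant_id", "effect_allele", "non_effect_allele", "beta")
  miss <- setdiff(req, names(dat))
  if (length(miss) > 0L)
    stop("weights file lacks column(s): ", paste(miss, collapse = ", "))
  beta <- suppressWarnings(as.numeric(dat$beta))
  bad <- which(is.na(beta) | !is.finite(beta))
  if (length(bad) > 0L)
    stop("non-numeric or non-finite beta in weights file at row(s): ",
         paste(bad, collapse = ", "), " (",
         paste(dat$variant_id[bad], collapse = ", "), ")")
  dat$beta <- beta
  if (anyDuplicated(dat$variant_id))
    stop("duplicated variant_id in weights file: ",
         paste(unique(dat$variant_id[duplicated(dat$variant_id)]),
               collapse = ", "))
  if (any(nchar(dat$effect_allele) != 1L |
          nchar(dat$non_effect_allele) != 1L))
    stop("weights alleles must be single bases")
  dat
}

#' @rdname read_weights
#' @param weights data.frame as returned by [read_weights()].
#' @export
write_weights <- function(weights, path) {
  write.table(weights[, c("variant_id", "effect_allele",
                          "non_effect_allele", "beta")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- genotype readers --------------------------------------------------

.variants_sidecar <- function(path) paste0(path, ".variants.tsv")

#' Read genotypes into a panel
#'
#' Three dialects are supported: a minimal GT-only VCF 4.x, PLINK-text
#' `.ped`/`.map`, and the pipeline's native dosage TSV (written by
#' [write_genotypes()], which places variant metadata in a
#' `<path>.variants.tsv` sidecar).  All dosages are re-oriented to count
#' the designated effect allele.
#'
#' @param path file path (for `plink_text`, the `.ped` file; the `.map`
#'   is found by extension swap).
#' @param format one of `"vcf"`, `"plink_text"`, `"dosage_tsv"`.
#' @param effect_allele_policy `"minor_allele"` orients each variant
#'   toward its minor allele; `"from_weights"` orients toward the effect
#'   allele of `weights` (rows absent from the weights keep the parsed
#'   orientation).
#' @param weights optional data.frame from [read_weights()]; required
#'   under `effect_allele_policy = "from_weights"`.  An allele pair in
#'   the weights that matches the genotype data neither directly nor
#'   swapped is an error listing the offending ids.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path,
                           format = c("dosage_tsv", "vcf", "plink_text"),
                           effect_allele_policy = c("minor_allele",
                                                    "from_weights"),
                           weights = NULL) {
  format <- match.arg(format)
  effect_allele_policy <- match.arg(effect_allele_policy)
  panel <- switch(format,
                  dosage_tsv = .read_dosage_tsv(path),
                  vcf = .read_vcf(path),
                  plink_text = .read_plink_text(path))
  .apply_allele_policy(panel, effect_allele_policy, weights)
}

.apply_allele_policy <- function(panel, policy, weights) {
  if (policy == "from_weights") {
    if (is.null(weights))
      stop("effect_allele_policy = 'from_weights' needs a weights table")
    v <- panel$variants
    idx <- match(v$variant_id, weights$variant_id)
    hit <- which(!is.na(idx))
    wea <- weights$effect_allele[idx[hit]]
    wnea <- weights$non_effect_allele[idx[hit]]
    same <- wea == v$effect_allele[hit] & wnea == v$non_effect_allele[hit]
    swapped <- wea == v$non_effect_allele[hit] &
      wnea == v$effect_allele[hit]
    bad <- hit[!(same | swapped)]
    if (length(bad) > 0L)
      stop("weights alleles do not match genotype alleles for: ",
           paste(v$variant_id[bad], collapse = ", "))
    flip <- v$variant_id[hit[swapped]]
    if (length(flip) > 0L) panel <- flip_effect_allele(panel, flip)
  } else {
    eaf <- observed_eaf(panel)
    flip <- panel$variants$variant_id[!is.na(eaf) & eaf > 0.5]
    if (length(flip) > 0L) panel <- flip_effect_allele(panel, flip)
  }
  panel$variants$eaf <- unname(observed_eaf(panel))
  panel
}

.read_dosage_tsv <- function(path) {
  side <- .variants_sidecar(path)
  if (!file.exists(side))
    stop("variant metadata sidecar not found: ", side,
         " (write_genotypes() emits it alongside the dosage TSV)")
  variants <- read.table(side, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(pos = "integer"))
  dat <- read.table(path, header = TRUE, sep = "\t",
                    na.strings = c("NA", ".", ""),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (names(dat)[1] != "sample_id")
    stop("dosage TSV must start with a sample_id column")
  ids <- dat$sample_id
  m <- as.matrix(dat[, -1, drop = FALSE])
  if (!setequal(colnames(m), variants$variant_id))
    stop("dosage columns and variant sidecar disagree")
  m <- m[, variants$variant_id, drop = FALSE]
  genotype_panel(variants, m, ids)
}

#' Write a panel as the native dosage TSV
#'
#' Emits the dosage matrix (`sample_id` + one column per variant,
#' missing as '.') and a `<path>.variants.tsv` metadata sidecar; the
#' pair round-trips exactly through [read_genotypes()].
#'
#' @param panel a `genotype_panel`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(panel, path) {
  vcols <- c("variant_id", "locus_label", "chrom", "pos",
             "effect_allele", "non_effect_allele", "eaf")
  write.table(panel$variants[, vcols], .variants_sidecar(path),
              sep = "\t", quote = FALSE, row.names = FALSE)
  out <- data.frame(sample_id = panel$sample_ids,
                    panel$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

.read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record file
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt) | nchar(alt) != 1L | nchar(ref) != 1L
  if (any(multi))
    stop("multi-allelic or non-SNP record(s) rejected: ",
         paste(ifelse(is.na(fix[multi, "ID"]), "<no id>",
                      fix[multi, "ID"]), collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # unphased or phased diploid GT -> ALT-allele count
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(as.integer(a)), integer(1)))
  }
  m <- apply(gt, c(1, 2), count_alt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(
    variant_id = ids, locus_label = "",
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    effect_allele = alt, non_effect_allele = ref,
    eaf = NA_real_, stringsAsFactors = FALSE)
  genotype_panel(variants, t(m), colnames(gt))
}

.read_plink_text <- function(path) {
  map_path <- sub("\\.ped$", ".map", path)
  if (identical(map_path, path))
    stop("plink_text expects a .ped path with a sibling .map")
  if (!file.exists(map_path)) stop(".map file not found: ", map_path)
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  names(map)[1:4] <- c("chrom", "variant_id", "cm", "pos")
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  n_var <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_var)
    stop(".ped has ", ncol(ped), " columns; expected ",
         6 + 2 * n_var, " for ", n_var, " variants")
  ids <- ped[[2]]
  n <- nrow(ped)
  dos <- matrix(NA_integer_, n, n_var)
  eff <- character(n_var); noneff <- character(n_var)
  for (j in seq_len(n_var)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
    alleles <- sort(unique(c(a1, a2)))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) > 2L)
      stop("more than two alleles for variant ", map$variant_id[j], ": ",
           paste(alleles, collapse = ", "))
    if (length(alleles) == 0L)
      stop("variant ", map$variant_id[j], " is entirely missing")
    if (length(alleles) == 1L) alleles <- c(alleles, alleles[1])
    # provisional orientation: count the first (alphabetical) allele
    eff[j] <- alleles[1]
    noneff[j] <- alleles[2]
    if (eff[j] == noneff[j])
      noneff[j] <- setdiff(c("A", "C", "G", "T"), eff[j])[1]
    dos[, j] <- (a1 == eff[j]) + (a2 == eff[j])
    dos[is.na(a1) | is.na(a2), j] <- NA_integer_
  }
  variants <- data.frame(
    variant_id = map$variant_id, locus_label = "",
    chrom = as.character(map$chrom), pos = as.integer(map$pos),
    effect_allele = eff, non_effect_allele = noneff,
    eaf = NA_real_, stringsAsFactors = FALSE)
  genotype_panel(variants, dos, ids)
}
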