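#' Curated candidate SNP panel for depression
#'
#' The 32-variant candidate panel used throughout the package's worked
#' examples and its synthetic study cohort: depression-candidate SNPs in
#' hypothalamic--pituitary--adrenal axis, monoaminergic, oxytocin and
#' vasopressin, inflammatory-response, telomere-maintenance and
#' miRNA-binding genes, with effect-allele frequencies and per-allele
#' BDI-point effect estimates characteristic of a Volga--Ural young-adult
#' cohort.  The effect allele is the minor allele.  Thirty variants form
#' the association panel; two additional variants (`rs13316193` in
#' *OXTR*, `rs7322347` in *HTR2A*) are included as known Hardy--Weinberg
#' violators with positive inbreeding coefficients `hwe_f`, so that QC
#' exclusion logic can be exercised (their coordinates are approximate
#' and their effects set to zero; treat them as synthetic controls).
#'
#' Three intra-locus proxy pairs are carried by [candidate_ld_pairs()]:
#' `rs237911`--`rs2228485` (*OXTR*, r2 = 0.44),
#' `rs1041981`--`rs1800629` (*TNF*, r2 = 0.23), and
#' `rs1360780`--`rs3800373` (*FKBP5*, r2 = 0.55); the `keep` member of
#' each pair is the one retained when the pair is pruned.
#'
#' @return `candidate_panel_variants()`: data.frame with one row per
#'   variant (columns `variant_id`, `locus_label`, `chrom`, `pos`,
#'   `effect_allele`, `non_effect_allele`, `eaf`, `beta`, `hwe_f`).
#'   `candidate_ld_pairs()`: data.frame with columns `variant_a`,
#'   `variant_b`, `target_r2`, `keep`.
#' @export
candidate_panel_variants <- function() {
  tab <- c(
    "rs3093077   CRP     1  159709846 G T 0.079 -0.24",
    "rs33911258  AVPR1B  1  206118034 G A 0.167  0.01",
    "rs1800587   IL1A    2  112785383 A G 0.278  0.29",
    "rs16944     IL1B    2  112837290 A G 0.378 -0.26",
    "rs7632287   OXTR    3    8749760 A G 0.199 -0.16",
    "rs2254298   OXTR    3    8760542 A G 0.095 -0.13",
    "rs53576     OXTR    3    8762685 A G 0.473 -0.04",
    "rs2228485   OXTR    3    8768017 G A 0.208 -0.25",
    "rs237911    OXTR    3    8768322 G A 0.165 -0.04",
    "rs9818870   MRAS    3  138403280 T C 0.139  0.36",
    "rs1317082   TERC    3  169779797 G A 0.341 -0.01",
    "rs7726159   TERT    5    1282204 A C 0.337 -0.31",
    "rs41423247  NR3C1   5  143399010 C G 0.352 -0.04",
    "rs1041981   TNF     6   31573007 A C 0.248 -0.46",
    "rs1800629   TNF     6   31575254 A G 0.109  0.04",
    "rs3800373   FKBP5   6   35574699 C A 0.234 -0.01",
    "rs1360780   FKBP5   6   35639794 T C 0.280 -0.11",
    "rs13212041  HTR1B   6   77461407 C T 0.177  0.12",
    "rs10457441  MIR2113 6   98124244 C T 0.419  0.48",
    "rs2148710   FYN     6  111801023 T C 0.135  0.32",
    "rs2715157   PCLO    7   82839058 A G 0.438  0.67",
    "rs531564    MIR124  8    3445535 C G 0.151 -0.22",
    "rs2487999   OBFC1   10 103900068 T C 0.087  0.65",
    "rs1800955   DRD4    11    636784 C T 0.402 -0.26",
    "rs187238    IL18    11 112164265 G C 0.283 -0.73",
    "rs3803107   AVPR1A  12  63147054 T C 0.176  0.64",
    "rs1042615   AVPR1A  12  63150429 A G 0.403 -0.03",
    "rs10459194  MIR135  12  99039512 C T 0.302  0.52",
    "rs2230912   P2RX7   12 121184393 G A 0.170 -0.01",
    "rs1042173   SLC6A4  17  30197993 T G 0.454  0.32")
  v <- read.table(text = paste(tab, collapse = "\n"),
                  stringsAsFactors = FALSE,
                  col.names = c("variant_id", "locus_label", "chrom",
                                "pos", "effect_allele",
                                "non_effect_allele", "eaf", "beta"))
  v$chrom <- as.character(v$chrom)
  v$pos <- as.integer(v$pos)
  v$hwe_f <- 0
  hwe <- data.frame(
    variant_id = c("rs13316193", "rs7322347"),
    locus_label = c("OXTR", "HTR2A"),
    chrom = c("3", "13"),
    pos = c(8755899L, 46843380L),
    effect_allele = c("T", "T"),
    non_effect_allele = c("C", "C"),
    eaf = c(0.30, 0.40),
    beta = c(0, 0),
    # inbreeding coefficients sized so the deviation is detected at
    # cohort scale (n ~ 1000): one gross, one moderate violator
    hwe_f = c(0.21, 0.09),
    stringsAsFactors = FALSE)
  rbind(v, hwe)
}

#' @rdname candidate_panel_variants
#' @export
candidate_ld_pairs <- function() {
  data.frame(
    variant_a = c("rs237911", "rs1041981", "rs1360780"),
    variant_b = c("rs2228485", "rs1800629", "rs3800373"),
    target_r2 = c(0.44, 0.23, 0.55),
    keep = c("rs2228485", "rs1800629", "rs3800373"),
    stringsAsFactors = FALSE)
}
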