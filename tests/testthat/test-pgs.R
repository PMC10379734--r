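test_that("negative betas recode onto the alternative allele", {
  assoc <- data.frame(
    variant_id = c("rs2715157", "rs187238"),
    effect_allele = c("A", "G"), non_effect_allele = c("G", "C"),
    beta = c(0.67, -0.73), stringsAsFactors = FALSE)
  w <- build_weights(assoc, mode = "weighted")
  expect_equal(w$scoring_allele, c("A", "C"))
  expect_equal(w$weight, c(0.67, 0.73))
  expect_true(all(w$weight >= 0))

  uw <- build_weights(assoc, mode = "unweighted")
  expect_equal(uw$scoring_allele, c("A", "C"))
  expect_equal(uw$weight, c(1, 1))

  assoc$beta[1] <- 0
  expect_warning(w0 <- build_weights(assoc), "arbitrary")
  expect_equal(w0$weight[1], 0)
  expect_equal(w0$scoring_allele[1], "A")

  assoc$beta[1] <- NA
  expect_error(build_weights(assoc), "rs2715157")
})

test_that("external weights harmonize by swap, strand and ambiguity rules", {
  v <- data.frame(
    variant_id = c("rs16944", "rs_identity", "rs_strand", "rs_amb",
                   "rs_bad"),
    locus_label = "", chrom = "1", pos = 1:5 * 10L,
    effect_allele = c("A", "A", "A", "C", "A"),
    non_effect_allele = c("G", "C", "G", "G", "C"),
    eaf = 0.3, stringsAsFactors = FALSE)
  panel <- genotype_panel(v, matrix(1L, 2, 5), c("s1", "s2"))
  raw <- data.frame(
    variant_id = c("rs16944", "rs_identity", "rs_strand", "rs_amb",
                   "rs_bad", "rs_gone"),
    effect_allele = c("G", "A", "T", "C", "A", "A"),
    non_effect_allele = c("A", "C", "C", "G", "G", "C"),
    beta = c(0.26, 0.5, 0.4, 0.3, 0.2, 0.1),
    stringsAsFactors = FALSE)
  h <- harmonize_external_weights(raw, panel)
  log <- h$log
  # swapped alleles: beta negated to panel orientation, then recoded
  # onto the panel non-effect allele with positive weight
  expect_equal(log$action[log$variant_id == "rs16944"], "flipped")
  expect_equal(log$beta_out[log$variant_id == "rs16944"], -0.26)
  w <- h$weights
  expect_equal(w$scoring_allele[w$variant_id == "rs16944"], "G")
  expect_equal(w$weight[w$variant_id == "rs16944"], 0.26)
  # identical orientation passes through unchanged
  expect_equal(log$action[log$variant_id == "rs_identity"], "kept")
  expect_equal(w$weight[w$variant_id == "rs_identity"], 0.5)
  expect_equal(w$scoring_allele[w$variant_id == "rs_identity"], "A")
  # T/C raw vs A/G panel resolves via strand complement
  expect_equal(log$action[log$variant_id == "rs_strand"],
               "strand_complemented")
  # C/G raw is strand-ambiguous and dropped under the default policy
  expect_equal(log$action[log$variant_id == "rs_amb"],
               "dropped_ambiguous")
  # alleles irreconcilable with the panel pair
  expect_equal(log$action[log$variant_id == "rs_bad"],
               "dropped_unresolvable")
  expect_equal(log$action[log$variant_id == "rs_gone"],
               "dropped_absent")
  expect_false(any(c("rs_amb", "rs_bad", "rs_gone") %in% w$variant_id))

  # empty intersection is fatal
  expect_error(
    harmonize_external_weights(raw[raw$variant_id == "rs_gone", ], panel),
    "no scorable")
})

test_that("harmonizing weights already in panel orientation is identity", {
  p <- make_tiny_panel(5, 8, seed = 44, missing_rate = 0)
  v <- p$variants
  raw <- data.frame(variant_id = v$variant_id,
                    effect_allele = v$effect_allele,
                    non_effect_allele = v$non_effect_allele,
                    beta = seq(-0.4, 0.3, length.out = 8))
  h <- harmonize_external_weights(raw, p, drop_ambiguous = FALSE)
  expect_true(all(h$log$action == "kept"))
  expect_equal(h$log$beta_out, raw$beta)
})

test_that("re-orientation arithmetic of a single scoring term", {
  v <- data.frame(variant_id = "rsX", locus_label = "", chrom = "11",
                  pos = 1L, effect_allele = "G", non_effect_allele = "C",
                  eaf = 0.3)
  p <- genotype_panel(v, matrix(c(2L, 1L, 0L), 3, 1), c("a", "b", "c"))
  w <- structure(data.frame(variant_id = "rsX", scoring_allele = "C",
                            weight = 0.73),
                 mode = "weighted", class = c("weight_set", "data.frame"))
  s <- score_individuals(p, w)
  expect_equal(s$pgs, 0.73 * (2 - c(2, 1, 0)))
})

test_that("scoring equals the brute-force loop on random panels", {
  for (rep_i in 1:20) {
    n <- sample(2:50, 1)
    m <- sample(1:32, 1)
    p <- make_tiny_panel(n, m, seed = 100 + rep_i, missing_rate = 0.15)
    set.seed(200 + rep_i)
    v <- p$variants
    pick <- sample(m, max(1, floor(m * 0.8)))
    use_nea <- runif(length(pick)) < 0.5
    w <- structure(
      data.frame(variant_id = v$variant_id[pick],
                 scoring_allele = ifelse(use_nea,
                                         v$non_effect_allele[pick],
                                         v$effect_allele[pick]),
                 weight = round(runif(length(pick), 0, 1), 3),
                 stringsAsFactors = FALSE),
      mode = "weighted", class = c("weight_set", "data.frame"))
    for (pol in c("mean_dosage", "skip")) {
      got <- score_individuals(p, w, missing_policy = pol)
      want <- brute_score(p, w, pol)
      expect_equal(got$pgs, want$pgs, tolerance = 1e-12)
      if (pol == "skip")
        expect_equal(got$n_variants_used, want$n_used)
    }
  }
})

test_that("zero and absent weights behave as documented", {
  p <- make_tiny_panel(10, 4, seed = 7, missing_rate = 0)
  v <- p$variants
  w0 <- structure(data.frame(variant_id = v$variant_id,
                             scoring_allele = v$effect_allele,
                             weight = 0),
                  mode = "weighted",
                  class = c("weight_set", "data.frame"))
  expect_true(all(score_individuals(p, w0)$pgs == 0))

  # adding a zero-weight variant never changes a score
  w1 <- w0; w1$weight <- c(0.5, 0.2, 0.9, 0.1)
  base <- score_individuals(p, w1)$pgs
  w2 <- rbind(w1[1:3, ], data.frame(variant_id = v$variant_id[4],
                                    scoring_allele = v$effect_allele[4],
                                    weight = 0))
  attributes(w2)$mode <- "weighted"
  class(w2) <- c("weight_set", "data.frame")
  w3 <- w1; w3$weight[4] <- 0
  expect_equal(score_individuals(p, w3)$pgs,
               score_individuals(p, w2)$pgs)

  # weights entirely absent from the panel are fatal
  wbad <- w1; wbad$variant_id <- paste0("zz", 1:4)
  expect_error(score_individuals(p, wbad), "no weight variant")

  # partially absent: warned and excluded
  wpart <- w1; wpart$variant_id[1] <- "zz1"
  expect_warning(s <- score_individuals(p, wpart), "zz1")
  expect_equal(s$n_variants_used, rep(3L, 10))
})

test_that("unweighted scores are integers under skip with complete data", {
  b <- quick_bundle(seed = 23, n = 80, n_var = 8)
  a <- fit_snp_regression(b$panel, b$cohort)
  uw <- build_weights(a, mode = "unweighted")
  s <- score_individuals(b$panel, uw, missing_policy = "skip")
  expect_true(all(s$pgs == round(s$pgs)))
  expect_true(all(s$n_variants_used == 8L))
})
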