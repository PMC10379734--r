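# Independent brute-force oracles and small fixture builders.

# random panel with arbitrary alleles and missingness
make_tiny_panel <- function(n, m, seed, missing_rate = 0.1) {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m, replace = TRUE)
  nea <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")
  v <- data.frame(variant_id = sprintf("v%03d", seq_len(m)),
                  locus_label = sample(c("L1", "L2", "L3"), m, TRUE),
                  chrom = "1", pos = seq_len(m) * 100L,
                  effect_allele = ea, non_effect_allele = nea,
                  eaf = runif(m, 0.05, 0.5), stringsAsFactors = FALSE)
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  d[matrix(runif(n * m) < missing_rate, n, m)] <- NA_integer_
  genotype_panel(v, d, sprintf("s%03d", seq_len(n)))
}

# per-individual, per-variant loop equivalent of score_individuals()
brute_score <- function(panel, weights, policy) {
  v <- panel$variants
  n <- length(panel$sample_ids)
  w <- weights[weights$variant_id %in% v$variant_id, , drop = FALSE]
  # oriented dosage of the scoring allele, individual i variant j
  orient <- function(i, j) {
    k <- which(v$variant_id == w$variant_id[j])
    x <- panel$dosages[i, k]
    if (w$scoring_allele[j] == v$effect_allele[k]) x else 2 - x
  }
  col_mean <- vapply(seq_len(nrow(w)), function(j)
    mean(vapply(seq_len(n), orient, numeric(1), j = j), na.rm = TRUE),
    numeric(1))
  pgs <- numeric(n); used <- integer(n)
  for (i in seq_len(n)) {
    s <- 0; u <- 0L
    for (j in seq_len(nrow(w))) {
      x <- orient(i, j)
      if (is.na(x)) {
        if (policy == "mean_dosage") {
          s <- s + w$weight[j] * col_mean[j]
          u <- u + 1L
        }
      } else {
        s <- s + w$weight[j] * x
        u <- u + 1L
      }
    }
    pgs[i] <- s; used[i] <- u
  }
  list(pgs = pgs, n_used = used)
}

# HWE exact p by enumerating all genotype-count triples with the same
# allele count and conditioning multinomial HWE probabilities on it
hwe_enum_oracle <- function(a, b, c) {
  n <- a + b + c
  na <- 2 * a + b
  cfgs <- expand.grid(het = 0:n)
  cfgs <- cfgs[cfgs$het <= na & (na - cfgs$het) %% 2 == 0 &
                 (na - cfgs$het) / 2 + cfgs$het <= n, , drop = FALSE]
  probs <- vapply(cfgs$het, function(h) {
    aa <- (na - h) / 2
    bb <- n - aa - h
    stats::dmultinom(c(aa, h, bb), prob = c(0.25, 0.5, 0.25))
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[cfgs$het == b]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# exact two-sided Mann-Whitney p by exhaustive group-assignment
# enumeration (tie-free data)
mw_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  u_obs <- r_obs - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) {
    sum(rank(pooled)[ii]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * (length(y)) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# small complete-data simulation bundle for model-level tests
quick_bundle <- function(seed, n = 400, n_var = 10) {
  v <- candidate_panel_variants()
  v <- v[v$hwe_f == 0, ][seq_len(n_var), ]
  cfg <- sim_config(n_individuals = n, variants = v, ld_pairs = NULL,
                    hwe_violations = data.frame(variant_id = character(),
                                                f = numeric()),
                    missing_rate = 0, seed = seed)
  simulate_cohort(cfg)
}
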