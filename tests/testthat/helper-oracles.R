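# Independent brute-force oracles used to cross-check the package's
# implementations on small instances.

# term-by-term complex summation of the fat modulation factor
oracle_modulation <- function(te_ms, shifts_ppm, amps, field_T,
                              water_ppm = 4.7) {
  total <- 0 + 0i
  for (p in seq_along(shifts_ppm)) {
    df <- (shifts_ppm[p] - water_ppm) * 42.576 * field_T
    total <- total + amps[p] * exp(1i * 2 * pi * df * te_ms / 1000)
  }
  total
}

# pairwise concordance AUC (ties count one half), O(n^2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + (x > y) + 0.5 * (x == y)
  }
  total / (length(pos) * length(neg))
}

# Spearman as the Pearson correlation of average ranks
oracle_spearman <- function(x, y) {
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Obuchowski estimate by exhaustive enumeration of level-pair concordances,
# weighted by the number of subject pairs in each level pair
oracle_obuchowski <- function(pred, truth) {
  lev <- sort(unique(truth))
  num <- 0; den <- 0
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (j <= i) next
      lo <- pred[truth == lev[i]]
      hi <- pred[truth == lev[j]]
      conc <- 0
      for (a in lo) for (b in hi) conc <- conc + (b > a) + 0.5 * (a == b)
      num <- num + conc
      den <- den + length(lo) * length(hi)
    }
  }
  num / den
}

# a small quantified cohort with perfectly known estimate columns, for
# model and report tests
toy_quantified_cohort <- function(n = 60, seed = 42, noise_sd = 0) {
  withr::with_seed(seed, {
    co <- simulate_cohort(cohort_spec(n_subjects = n), seed = seed)
    for (m in c("triple", "multi", "mrs")) {
      co[[paste0(m, "_pdff_pct")]] <-
        pmax(co$true_pdff_pct + rnorm(n, sd = noise_sd), 0)
    }
    co
  })
}
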