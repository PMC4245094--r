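test_that("spearman_rho matches the rank formula and flags degeneracy", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) on untied data
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)),
               1 - 6 * sum((1:4 - c(1, 3, 2, 4))^2) / (4 * 15))
  withr::with_seed(7, {
    for (rep in 1:20) {
      x <- sample(1:6, 15, replace = TRUE)  # heavy ties
      y <- x + sample(1:4, 15, replace = TRUE)
      expect_equal(spearman_rho(x, y), oracle_spearman(x, y),
                   tolerance = 1e-12)
    }
  })
  expect_warning(out <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("empirical ROC equals the pairwise concordance oracle", {
  expect_equal(roc_empirical(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_empirical(rep(1, 8), rep(0:1, 4))$auc, 0.5)
  expect_equal(roc_empirical(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc,
               oracle_auc(c(3, 1, 2, 4), c(0, 0, 1, 1)))
  withr::with_seed(8, {
    for (rep in 1:40) {
      n <- sample(6:30, 1)
      scores <- sample(1:8, n, replace = TRUE)  # forces ties
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      roc <- roc_empirical(scores, labels)
      expect_equal(roc$auc, oracle_auc(scores, labels), tolerance = 1e-12)
      expect_true(all(diff(roc$points$fpr) >= 0))
      expect_true(all(diff(roc$points$tpr) >= 0))
    }
  })
  expect_error(roc_empirical(1:4, rep(1, 4)), "Both classes")
})

test_that("smoothed ROC limits to the empirical curve and the normal model", {
  withr::with_seed(9, {
    x0 <- rnorm(60); x1 <- rnorm(60, mean = 1)
    scores <- c(x0, x1); labels <- rep(0:1, each = 60)
    emp <- roc_empirical(scores, labels)$auc
    tiny <- roc_smoothed(scores, labels, bandwidth = 1e-9)$auc
    expect_equal(tiny, emp, tolerance = 1e-6)
    # widely separated normals: AUC near the closed form (about 1)
    far <- roc_smoothed(c(rnorm(50), rnorm(50, 8)), rep(0:1, each = 50))
    expect_gt(far$auc, 0.99)
    same <- roc_smoothed(rnorm(200), rep(0:1, 100))
    expect_equal(same$auc, 0.5, tolerance = 0.08)
  })
  expect_error(roc_smoothed(rnorm(20), rep(0:1, 10), bandwidth = -1),
               "positive")
  expect_error(roc_smoothed(1:6, c(1, 0, 0, 0, 0, 0)), "at least 5")
})

test_that("Youden threshold maximises J over the operating points", {
  sep <- roc_empirical(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  thr <- youden_threshold(sep)
  expect_equal(thr$youden_j, 1)
  expect_gt(thr$threshold, 3); expect_lte(thr$threshold, 10)
  expect_equal(thr$youden_j, thr$sensitivity + thr$specificity - 1,
               tolerance = 1e-12)

  withr::with_seed(10, {
    scores <- round(rnorm(40), 1)
    labels <- as.integer(scores + rnorm(40) > 0)
    if (length(unique(labels)) == 2) {
      roc <- roc_empirical(scores, labels)
      thr <- youden_threshold(roc)
      # exhaustive check over every finite threshold
      p <- roc$points[is.finite(roc$points$threshold), ]
      expect_equal(thr$youden_j, max(p$tpr - p$fpr), tolerance = 1e-12)
    }
    ident <- roc_empirical(rep(1:5, 2), rep(0:1, each = 5))
    expect_lt(abs(youden_threshold(ident)$youden_j), 0.21)
  })

  # two known normals: the smoothed Youden cut lands near the midpoint
  withr::with_seed(11, {
    scores <- c(rnorm(400), rnorm(400, 2))
    labels <- rep(0:1, each = 400)
    thr <- youden_threshold(roc_smoothed(scores, labels))
    expect_lt(abs(thr$threshold - 1), 0.35)
  })
})

test_that("DeLong paired comparison is calibrated and degenerate-safe", {
  withr::with_seed(12, {
    s <- rnorm(60); l <- rep(0:1, 30)
    expect_equal(compare_roc_paired(s, s, l)$p_value, 1)
    # power: strong vs uninformative marker
    hits <- replicate(30, {
      lab <- rep(0:1, each = 100)
      strong <- lab * 2 + rnorm(200)
      rand <- rnorm(200)
      compare_roc_paired(strong, rand, lab)$p_value < 0.01
    })
    expect_gte(mean(hits), 0.95)
    # null: two equally informative correlated markers
    pvals <- replicate(400, {
      lab <- rep(0:1, each = 50)
      base <- lab + rnorm(100)
      a <- base + rnorm(100, sd = 0.4)
      b <- base + rnorm(100, sd = 0.4)
      compare_roc_paired(a, b, lab)$p_value
    })
    expect_gt(mean(pvals < 0.05), 0.015)
    expect_lt(mean(pvals < 0.05), 0.10)
  })
})

test_that("DeLong test agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    for (rep in 1:5) {
      lab <- rep(0:1, each = 40)
      a <- lab + rnorm(80)
      b <- 0.5 * lab + rnorm(80)
      ours <- compare_roc_paired(a, b, lab)
      ref <- pROC::roc.test(pROC::roc(lab, a, quiet = TRUE),
                            pROC::roc(lab, b, quiet = TRUE),
                            method = "delong", paired = TRUE)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
    }
  })
})

test_that("Obuchowski AUC reduces to and extends the two-class AUC", {
  pred <- c(1, 2, 3, 4, 5, 6)
  truth <- c(1, 1, 2, 2, 3, 3)
  expect_equal(obuchowski_auc(pred, truth)$auc, 1)
  expect_equal(obuchowski_auc(pred, truth)$auc,
               oracle_obuchowski(pred, truth))
  # hand-built 3-level set with discordances
  pred2 <- c(3, 1, 2, 5, 4, 2)
  truth2 <- c(1, 1, 2, 2, 3, 3)
  expect_equal(obuchowski_auc(pred2, truth2)$auc,
               oracle_obuchowski(pred2, truth2), tolerance = 1e-12)
  withr::with_seed(14, {
    for (rep in 1:20) {
      n <- sample(9:30, 1)
      truth <- sample(1:4, n, replace = TRUE)
      if (length(unique(truth)) < 2) next
      pred <- truth + rnorm(n)
      ob <- obuchowski_auc(pred, truth)
      expect_equal(ob$auc, oracle_obuchowski(pred, truth), tolerance = 1e-12)
      if (length(unique(truth)) == 2) {
        expect_equal(ob$auc,
                     roc_empirical(pred, truth == max(truth))$auc,
                     tolerance = 1e-12)
      }
    }
    # independence: AUC near 1/2
    ind <- obuchowski_auc(rnorm(600), sample(1:3, 600, replace = TRUE))
    expect_equal(ind$auc, 0.5, tolerance = 0.06)
    expect_gt(ind$se, 0)
  })
  expect_error(obuchowski_auc(1:4, rep(1, 4)), "2 distinct")
})

test_that("two-class Obuchowski equals the empirical AUC exactly", {
  withr::with_seed(15, {
    for (rep in 1:10) {
      n <- sample(8:24, 1)
      truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      pred <- sample(1:6, n, replace = TRUE)
      expect_equal(obuchowski_auc(pred, truth)$auc,
                   roc_empirical(pred, truth)$auc, tolerance = 1e-12)
    }
  })
})

test_that("group summaries use interpolation quantiles; rank-sum test works", {
  co <- tibble::tibble(grade = factor(rep("mild", 4)), v = c(1, 2, 3, 4))
  gs <- group_summaries(co, "v")
  expect_equal(gs$median, 2.5)
  expect_equal(gs$q25, 1.75)
  expect_equal(gs$q75, 3.25)

  expect_gt(group_test(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.99)
  expect_lt(group_test(1:10, 21:30), 0.001)
  expect_error(group_test(1, 1:3), "at least 2")
})

test_that("steatosis regression recovers exact linear structure", {
  co <- toy_quantified_cohort(n = 60)
  co$mrs_pdff_pct <- 30 * co$histo_pct / 100  # PDFF% = 30 * histology share
  fit <- suppressWarnings(fit_steatosis_models(co, "mrs"))
  td <- suppressWarnings(generics::tidy(fit))
  expect_equal(td$estimate[td$term == "histology"], 30, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  expect_equal(generics::glance(fit)$obuchowski_auc, 1)

  # an added irrelevant covariate cannot reduce R^2
  fit2 <- suppressWarnings(fit_steatosis_models(co, "mrs", "nash_fibrosis"))
  expect_gte(fit2$r_squared, fit$r_squared - 1e-12)
  td2 <- suppressWarnings(generics::tidy(fit2))
  expect_true(any(grepl("^fibrosis", td2$term)))
  expect_error(fit_steatosis_models(co[, 1:5], "triple"), "column")
})
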