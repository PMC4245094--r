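test_that("cohort simulation is a pure function of spec and seed", {
  spec <- cohort_spec(n_subjects = 25)
  a <- simulate_cohort(spec, seed = 3)
  b <- simulate_cohort(spec, seed = 3)
  expect_identical(a, b)
  c <- simulate_cohort(spec, seed = 4)
  expect_false(identical(a, c))
})

test_that("degenerate grade mixture yields only that grade", {
  spec <- cohort_spec(n_subjects = 4, grade_proportions = c(1, 0, 0, 0))
  co <- simulate_cohort(spec, seed = 1)
  expect_true(all(co$grade == "none"))
  expect_true(all(co$histo_pct < 5))
})

test_that("grade frequencies converge to the spec proportions", {
  spec <- cohort_spec(n_subjects = 2000)
  co <- simulate_cohort(spec, seed = 9)
  freq <- as.numeric(table(co$grade) / nrow(co))
  expect_true(all(abs(freq - spec$grade_proportions) < 0.03))
})

test_that("histology percentage is consistent with its grade and 5% scored", {
  co <- simulate_cohort(cohort_spec(n_subjects = 300), seed = 2)
  expect_true(all(co$histo_pct %% 5 == 0))
  expect_identical(as.character(grade_steatosis(co$histo_pct)),
                   as.character(co$grade))
  expect_true(all(co$true_pdff_pct >= 0 & co$true_pdff_pct <= 60))
})

test_that("grade-conditional PDFF medians converge to the spec anchors", {
  spec <- cohort_spec(n_subjects = 5000)
  co <- simulate_cohort(spec, seed = 6)
  med <- tapply(co$true_pdff_pct, co$grade, median)
  expect_true(all(abs(med / spec$grade_pdff_medians - 1) < 0.05))
})

test_that("histology and true PDFF are rank-coupled within grade", {
  co <- simulate_cohort(cohort_spec(n_subjects = 4000), seed = 8)
  mild <- co[co$grade == "mild", ]
  expect_gt(cor(mild$histo_pct, mild$true_pdff_pct, method = "spearman"), 0.3)
})

test_that("cohort_spec validates its probability vectors", {
  expect_error(cohort_spec(grade_proportions = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(cohort_spec(n_subjects = 0), "at least 1")
  expect_error(cohort_spec(grade_pdff_medians = c(5, 4, 10, 20)),
               "increasing")
  expect_error(cohort_spec(fibrosis_stage_probs = rep(0.2, 4)), "5")
})

test_that("gradient-echo simulation reduces to the forward model without noise", {
  tis <- tissue_state(0.8, 0.2, 18)
  ser <- simulate_gre_series(tis, multi_echo_protocol(), snr = Inf)
  expect_equal(ser$roi_mean, gre_signal(tis, multi_echo_protocol()),
               tolerance = 1e-9)
  a <- simulate_gre_series(tis, triple_echo_protocol(), snr = 30, seed = 5)
  b <- simulate_gre_series(tis, triple_echo_protocol(), snr = 30, seed = 5)
  expect_identical(a$roi_mean, b$roi_mean)
})

test_that("zero-signal magnitudes have the Rayleigh mean", {
  tis <- tissue_state(0, 0)
  sims <- withr::with_seed(11, {
    replicate(3000, simulate_gre_series(tis, multi_echo_protocol(),
                                        snr = 5, noise_sigma = 2)$roi_mean)
  })
  expect_equal(mean(sims), 2 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("Rician bias at the first echo is under 1% for SNR >= 50", {
  tis <- tissue_state(0.9, 0.1, 20)
  truth <- gre_signal(tis, triple_echo_protocol())[1]
  sims <- withr::with_seed(12, {
    replicate(4000, simulate_gre_series(tis, triple_echo_protocol(),
                                        snr = 50)$roi_mean[1])
  })
  expect_lt(abs(mean(sims) - truth) / truth, 0.01)
})

test_that("PRESS spectrum has the protocol shape and exponential TE scaling", {
  tis <- tissue_state(0.7, 0.3)
  ser <- simulate_spectrum_series(tis, snr = Inf)
  expect_equal(sum(ser$records$role == "multi_te"), 8L)
  expect_equal(ser$records$te_ms[ser$records$role == "multi_te"],
               seq(40, 110, 10))
  expect_equal(sum(ser$records$role == "single_echo"), 1L)
  expect_equal(ser$n_points, 1024L)
  # fat-free voxel: FID equals the analytic water line
  w <- simulate_press_spectrum(tissue_state(1, 0), te_ms = 40, snr = Inf,
                               linewidth_hz = 45)
  t_s <- (0:1023) / 2000
  expect_equal(w$fid, exp(-40 / 25) * exp(-pi * 45 * t_s) + 0i,
               tolerance = 1e-12)
  # doubling TE scales a single-peak fat FID by exp(-dTE / T2)
  fat_only <- fat_spectrum(1.3, 1)
  s1 <- simulate_press_spectrum(tissue_state(0, 1, fat_t2_ms = 60), 40,
                                fat_only, snr = Inf)
  s2 <- simulate_press_spectrum(tissue_state(0, 1, fat_t2_ms = 60), 80,
                                fat_only, snr = Inf)
  expect_equal(s2$fid, s1$fid * exp(-40 / 60), tolerance = 1e-12)
  expect_error(simulate_press_spectrum(tis, 40, linewidth_hz = -1),
               "positive")
  expect_error(simulate_press_spectrum(tis, 40, n_points = 32), "64")
})

test_that("cohort CSV round-trips losslessly and validates on read", {
  co <- simulate_cohort(cohort_spec(n_subjects = 12), seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(co))

  empty <- co[0, ]
  write_cohort_csv(empty, path)
  expect_equal(nrow(read_cohort_csv(path)), 0L)

  bad <- co
  bad$fibrosis_stage <- as.character(bad$fibrosis_stage)
  bad$fibrosis_stage[3] <- "F7"
  write_cohort_csv(bad, path)
  expect_error(read_cohort_csv(path), "Row 3")

  bad2 <- co
  bad2$histo_pct[2] <- 12
  write_cohort_csv(bad2, path)
  expect_error(read_cohort_csv(path), "Row 2")
})
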