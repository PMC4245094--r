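test_that("echo_series validates against its protocol", {
  expect_error(echo_series(c(1, 2), triple_echo_protocol()), "one value per")
  expect_error(echo_series(c(-1, 1, 1), triple_echo_protocol()),
               "non-negative")
  ser <- echo_series(c(3, 2, 1), triple_echo_protocol(), noise_sigma = 0.1)
  expect_equal(attr(ser, "roi_area_mm2"), 900)
})

test_that("ROI extraction averages the mask exactly", {
  proto <- triple_echo_protocol()
  vols <- lapply(c(2, 4, 6), function(v) array(v, dim = c(4, 4, 2)))
  mask <- array(FALSE, dim = c(4, 4, 2)); mask[1:2, 1:2, 1] <- TRUE
  ser <- extract_roi_mean(vols, mask, proto)
  expect_equal(ser$roi_mean, c(2, 4, 6))

  single <- array(FALSE, dim = c(4, 4, 2)); single[3, 2, 2] <- TRUE
  vols2 <- lapply(1:3, function(k) array(seq_len(32) * k, dim = c(4, 4, 2)))
  ser2 <- extract_roi_mean(vols2, single, proto)
  expect_equal(ser2$roi_mean, vols2[[1]][3, 2, 2] * 1:3)

  checker <- array(c(7, 3), dim = c(4, 4, 1))  # alternating 7/3
  allmask <- array(TRUE, dim = c(4, 4, 1))
  ser3 <- extract_roi_mean(list(checker, checker, checker), allmask, proto)
  expect_equal(ser3$roi_mean, rep(5, 3))

  expect_error(extract_roi_mean(vols, array(FALSE, dim = c(4, 4, 2)), proto),
               "empty")
  expect_error(extract_roi_mean(vols[1:2], mask, proto), "one volume per")
})

test_that("background noise estimate inverts the Rayleigh mean", {
  sig <- 1.7
  bg <- withr::with_seed(3, sqrt(rnorm(20000, sd = sig)^2 +
                                 rnorm(20000, sd = sig)^2))
  expect_equal(estimate_noise_sigma(bg), sig, tolerance = 0.03)
  expect_error(estimate_noise_sigma(numeric(0)), "non-empty")
})

test_that("noise-floor correction implements the second-moment relation", {
  proto <- triple_echo_protocol()
  ser <- echo_series(c(1, 0.8, 0.6), proto, noise_sigma = 0)
  expect_equal(noise_floor_correct(ser)$roi_mean, ser$roi_mean)
  sigma <- 0.3
  ser2 <- echo_series(c(1, sigma * sqrt(2), 0.1), proto, noise_sigma = sigma)
  corr <- noise_floor_correct(ser2)
  expect_equal(corr$roi_mean[2], 0)
  expect_equal(corr$roi_mean[1], sqrt(1 - 2 * sigma^2))
  expect_error(noise_floor_correct(echo_series(c(1, 1, 1), proto)),
               "unknown")
})

test_that("the second-moment relation de-biases Rician magnitudes at SNR 5", {
  s <- 1; snr <- 5; sigma <- s / snr
  m <- withr::with_seed(4, {
    sqrt(rnorm(20000, mean = s, sd = sigma)^2 + rnorm(20000, sd = sigma)^2)
  })
  # E[m^2] = s^2 + 2 sigma^2: the corrected signal estimate beats the raw mean
  corrected <- sqrt(mean(m^2) - 2 * sigma^2)
  expect_lt(abs(corrected - s), abs(mean(m) - s))
})

test_that("noiseless echo series are recovered exactly", {
  grid <- expand.grid(pdff = c(0, 0.05, 0.1, 0.2, 0.3, 0.5),
                      t2star = c(10, 20, 40))
  for (proto in list(triple_echo_protocol(), multi_echo_protocol())) {
    for (k in seq_len(nrow(grid))) {
      p <- grid$pdff[k]
      tis <- tissue_state(1 - p, p, grid$t2star[k])
      ser <- simulate_gre_series(tis, proto, snr = Inf)
      est <- fit_echo_model(ser)
      expect_lt(abs(est$pdff - p), 1e-6)
      expect_lt(abs(est$t2star_ms - grid$t2star[k]), 1e-4)
      expect_true(est$converged)
      # the reported PDFF is exactly the density ratio
      expect_equal(est$pdff,
                   pdff_from_densities(est$fat_density, est$water_density),
                   tolerance = 1e-9)
    }
  }
})

test_that("a fat-dominant voxel is recovered from the second basin", {
  tis <- tissue_state(0.2, 0.8, 25)
  ser <- simulate_gre_series(tis, multi_echo_protocol(), snr = Inf)
  expect_lt(abs(fit_echo_model(ser)$pdff - 0.8), 1e-6)
})

test_that("estimated PDFF is monotone in the fat density", {
  ests <- vapply(seq(0, 0.6, by = 0.1), function(f) {
    ser <- simulate_gre_series(tissue_state(1, f, 20),
                               multi_echo_protocol(), snr = Inf)
    fit_echo_model(ser)$pdff
  }, numeric(1))
  expect_true(all(diff(ests) >= -1e-9))
})

test_that("protocol wrappers check their label and agree at high SNR", {
  tis <- tissue_state(0.85, 0.15, 22)
  tri <- simulate_gre_series(tis, triple_echo_protocol(), snr = 1000, seed = 1)
  mul <- simulate_gre_series(tis, multi_echo_protocol(), snr = 1000, seed = 2)
  expect_error(estimate_pdff_triple(mul), "protocol")
  expect_error(estimate_pdff_multi(tri), "protocol")
  et <- estimate_pdff_triple(tri)
  em <- estimate_pdff_multi(mul)
  expect_equal(et$method_label, "triple")
  expect_equal(em$method_label, "multi")
  expect_lt(abs(et$pdff - em$pdff), 0.01)
  expect_lt(abs(et$pdff - 0.15), 0.01)
  row <- generics::tidy(et)
  expect_equal(row$pdff_pct, 100 * et$pdff)
})

test_that("degenerate series are rejected", {
  expect_error(fit_echo_model(echo_series(c(0, 0, 0), triple_echo_protocol())),
               "All-zero")
})
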