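single_peak_priors <- function(freq_hz, window_hz = 15) {
  tibble::tibble(label = "water", frequency_hz = freq_hz,
                 window_hz = window_hz, damping_lo_hz = 5,
                 damping_hi_hz = 200, is_water = TRUE)
}

test_that("a single damped sinusoid is recovered exactly", {
  t_s <- (0:511) / 2000
  truth <- list(f = -120, d = 37, a = 2.4)
  fid <- truth$a * exp((1i * 2 * pi * truth$f - pi * truth$d) * t_s)
  fit <- fit_peaks(fid, 2000, single_peak_priors(-115))
  expect_equal(fit$frequency_hz, truth$f, tolerance = 1e-6)
  expect_equal(fit$damping_hz, truth$d, tolerance = 1e-6)
  expect_equal(fit$area, truth$a, tolerance = 1e-6)
  expect_true(attr(fit, "converged"))
})

test_that("well-separated peaks keep their 2:1 area ratio", {
  t_s <- (0:1023) / 2000
  fid <- 2 * exp((1i * 2 * pi * 0 - pi * 40) * t_s) +
    1 * exp((1i * 2 * pi * (-430) - pi * 40) * t_s)
  priors <- tibble::tibble(label = c("water", "fat"),
                           frequency_hz = c(3, -427), window_hz = 13,
                           damping_lo_hz = 5, damping_hi_hz = 200,
                           is_water = c(TRUE, FALSE))
  fit <- fit_peaks(fid, 2000, priors)
  expect_equal(fit$area[1] / fit$area[2], 2, tolerance = 1e-4)
})

test_that("overlapping prior windows are rejected", {
  priors <- tibble::tibble(label = c("a", "b"), frequency_hz = c(0, 10),
                           window_hz = 8, damping_lo_hz = 5,
                           damping_hi_hz = 200, is_water = c(TRUE, FALSE))
  fid <- complex(real = rnorm(128), imaginary = rnorm(128))
  expect_error(fit_peaks(fid, 2000, priors), "overlap")
  expect_error(fit_peaks(fid[1:32], 2000, single_peak_priors(0)), "64")
})

test_that("pure noise yields fat areas consistent with zero", {
  # Amplitudes projected onto the prior basis (fixed frequencies, nominal
  # damping) exceed 3x their uncertainty only in the far tail (~1% per
  # peak), so nearly all of 20 noise draws must be clean. The adaptive
  # nonlinear fit would chase noise inside its windows and inflate areas,
  # which is why detection is judged on the fixed-basis projection.
  pri <- mrs_priors()
  clean <- withr::with_seed(5, {
    vapply(1:20, function(i) {
      fid <- complex(real = rnorm(1024, sd = 0.05),
                     imaginary = rnorm(1024, sd = 0.05))
      pr <- hepafat:::project_amplitudes(fid, 2000, pri$frequency_hz,
                                         rep(45, 4))
      fat_area <- Mod(pr$amplitude)[!pri$is_water]
      fat_se <- sqrt(pmax(diag(pr$cov), 0))[!pri$is_water]
      all(fat_area < 3 * fat_se)
    }, logical(1))
  })
  expect_gte(sum(clean), 17)
})

test_that("T2 decay fitting inverts exact exponentials", {
  te <- seq(40, 110, 10)
  fit <- fit_t2_decay(data.frame(te_ms = te, area = 100 * exp(-te / 25)))
  expect_equal(fit$density, 100, tolerance = 1e-6)
  expect_equal(fit$t2_ms, 25, tolerance = 1e-6)
  expect_false(fit$t2_at_bound)

  flat <- fit_t2_decay(data.frame(te_ms = te, area = rep(7, 8)))
  expect_true(flat$t2_at_bound)

  expect_error(fit_t2_decay(data.frame(te_ms = c(40, 50), area = c(1, 2))),
               "at least 3")
  expect_error(fit_t2_decay(data.frame(te_ms = te, area = rep(0, 8))),
               "at least 3")
})

test_that("single-echo correction undoes the decay it models", {
  expect_equal(correct_single_echo(5, 0, 30), 5)
  expect_equal(correct_single_echo(exp(-1), 40, 40), 1, tolerance = 1e-12)
  expect_error(correct_single_echo(1, 40, -3), "positive")
  # consistency: extrapolated density equals the corrected single area
  te <- seq(40, 110, 10)
  areas <- 3.2 * exp(-te / 55)
  fit <- fit_t2_decay(data.frame(te_ms = te, area = areas))
  expect_equal(correct_single_echo(areas[1], te[1], fit$t2_ms), fit$density,
               tolerance = 1e-9)
})

test_that("hidden-peak correction is the multiplicative measurable share", {
  sp <- default_fat_spectrum()
  expect_equal(hidden_fat_correction(0.914, sp), 1, tolerance = 1e-12)
  expect_equal(hidden_fat_correction(0, sp), 0)
  # multiplicative: f(kx) = k f(x)
  expect_equal(hidden_fat_correction(5 * 0.2, sp),
               5 * hidden_fat_correction(0.2, sp), tolerance = 1e-12)
  # no hidden peaks: identity
  vis <- fat_spectrum(c(1.3, 2.1), c(0.8, 0.2))
  expect_equal(hidden_fat_correction(0.37, vis), 0.37, tolerance = 1e-12)
  expect_error(hidden_fat_correction(-1), "non-negative")
})

test_that("noiseless spectra yield the true fat fraction end to end", {
  for (p in c(0.05, 0.15)) {
    ser <- simulate_spectrum_series(tissue_state(1 - p, p), snr = Inf)
    est <- estimate_pdff_mrs(ser)
    expect_lt(abs(est$pdff - p), 2e-3)
    expect_equal(est$method_label, "mrs")
    expect_equal(est$water_t2_ms, 25, tolerance = 0.05)
    expect_true(est$converged)
  }
  # fat-free liver
  est0 <- estimate_pdff_mrs(simulate_spectrum_series(tissue_state(1, 0),
                                                     snr = Inf))
  expect_lt(est0$pdff, 0.005)
})

test_that("a water-free pathological record is rejected", {
  ser <- simulate_spectrum_series(tissue_state(0, 1), snr = Inf)
  expect_error(estimate_pdff_mrs(ser), "water density")
})

test_that("the series must contain a single-echo record", {
  ser <- simulate_spectrum_series(tissue_state(0.9, 0.1), snr = Inf)
  mt_only <- spectrum_series(
    te_ms = ser$records$te_ms[ser$records$role == "multi_te"],
    fids = ser$records$fid[ser$records$role == "multi_te"],
    role = rep("multi_te", 8), sweep_hz = ser$sweep_hz
  )
  expect_error(estimate_pdff_mrs(mt_only), "single-echo")
})

test_that("spectrum series round-trip through CSV + sidecars", {
  ser <- simulate_spectrum_series(tissue_state(0.8, 0.2), snr = 80, seed = 31)
  dir <- withr::local_tempdir()
  write_spectrum_series(ser, dir)
  back <- read_spectrum_series(dir)
  expect_equal(back$sweep_hz, ser$sweep_hz)
  expect_equal(back$n_points, ser$n_points)
  expect_equal(back$records$te_ms, ser$records$te_ms)
  expect_equal(back$records$role, ser$records$role)
  for (i in seq_len(nrow(ser$records))) {
    expect_equal(back$records$fid[[i]], ser$records$fid[[i]])
  }
  expect_error(read_spectrum_series(withr::local_tempdir()), "No spectrum")
})

test_that("duplicate echo times within a role are rejected", {
  fids <- replicate(2, complex(real = rnorm(128)), simplify = FALSE)
  expect_error(spectrum_series(c(40, 40), fids), "unique")
})
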