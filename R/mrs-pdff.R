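#' Multi-TE spectrum series
#'
#' A subject's PRESS acquisition: complex free-induction decays at several
#' echo times (used to estimate per-peak T2) plus a high-average single-echo
#' record (used for the fat-fraction measurement). All records share the
#' sampling grid.
#'
#' @param te_ms Echo times, ms, one per record.
#' @param fids List of complex vectors, all the same length.
#' @param role `"multi_te"` or `"single_echo"` per record.
#' @param n_averages Averages per record.
#' @param sweep_hz Spectral window, Hz.
#' @param tr_ms Repetition time(s), ms.
#' @return A list of class `spectrum_series` with a `records` tibble.
#' @export
spectrum_series <- function(te_ms, fids, role = rep("multi_te", length(te_ms)),
                            n_averages = rep(1L, length(te_ms)),
                            sweep_hz = 2000, tr_ms = 2000) {
  if (length(te_ms) != length(fids) || length(te_ms) != length(role)) {
    abort("`te_ms`, `fids` and `role` must have one entry per record.")
  }
  n_points <- unique(vapply(fids, length, integer(1)))
  if (length(n_points) != 1L) abort("All FIDs must have the same length.")
  if (!all(role %in% c("multi_te", "single_echo"))) {
    abort("`role` must be 'multi_te' or 'single_echo'.")
  }
  for (r in unique(role)) {
    if (anyDuplicated(te_ms[role == r])) {
      abort(sprintf("Echo times within role '%s' must be unique.", r))
    }
  }
  records <- tibble::tibble(te_ms = as.numeric(te_ms), role = role,
                            n_averages = as.integer(n_averages),
                            tr_ms = rep_len(tr_ms, length(te_ms)),
                            fid = fids)
  records <- dplyr::arrange(records, .data$role != "multi_te", .data$te_ms)
  structure(list(records = records, sweep_hz = sweep_hz,
                 n_points = as.integer(n_points)),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("<spectrum_series> %d records, %d points over %g Hz\n",
              nrow(x$records), x$n_points, x$sweep_hz))
  cat(sprintf("  multi-TE (ms): %s\n",
              paste(x$records$te_ms[x$records$role == "multi_te"],
                    collapse = ", ")))
  se <- x$records$te_ms[x$records$role == "single_echo"]
  if (length(se)) cat(sprintf("  single-echo (ms): %s\n", paste(se, collapse = ", ")))
  invisible(x)
}

#' Write or read a spectrum series as CSV records with JSON sidecars
#'
#' Each record is stored as `rec-NN.csv` with columns `(t_s, re, im)` and a
#' `rec-NN.json` sidecar carrying `te_ms`, `role`, `n_averages`, `tr_ms`,
#' `sweep_hz` and `n_points`, so a directory fully round-trips one subject's
#' acquisition.
#'
#' @param series A [spectrum_series()].
#' @param dir Directory (created if missing).
#' @return `read_spectrum_series()` returns a [spectrum_series()];
#'   `write_spectrum_series()` returns `dir` invisibly.
#' @export
write_spectrum_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t_s <- (seq_len(series$n_points) - 1) / series$sweep_hz
  for (i in seq_len(nrow(series$records))) {
    rec <- series$records[i, ]
    stem <- file.path(dir, sprintf("rec-%02d", i))
    fid <- rec$fid[[1]]
    readr::write_csv(data.frame(t_s = t_s, re = Re(fid), im = Im(fid)),
                     paste0(stem, ".csv"))
    jsonlite::write_json(
      list(te_ms = rec$te_ms, role = rec$role, n_averages = rec$n_averages,
           tr_ms = rec$tr_ms, sweep_hz = series$sweep_hz,
           n_points = series$n_points),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_spectrum_series
#' @export
read_spectrum_series <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "^rec-[0-9]+\\.json$",
                              full.names = TRUE))
  if (length(sidecars) == 0) abort(sprintf("No spectrum records found in %s.", dir))
  meta <- lapply(sidecars, jsonlite::read_json, simplifyVector = TRUE)
  fids <- lapply(sidecars, function(sc) {
    df <- readr::read_csv(sub("\\.json$", ".csv", sc), show_col_types = FALSE,
                          progress = FALSE)
    complex(real = df$re, imaginary = df$im)
  })
  spectrum_series(
    te_ms = vapply(meta, `[[`, numeric(1), "te_ms"),
    fids = fids,
    role = vapply(meta, `[[`, character(1), "role"),
    n_averages = vapply(meta, function(m) as.integer(m$n_averages), integer(1)),
    sweep_hz = meta[[1]]$sweep_hz,
    tr_ms = vapply(meta, `[[`, numeric(1), "tr_ms")
  )
}

#' Prior knowledge for liver spectrum peak fitting
#'
#' The fitted resonances of a non-water-suppressed liver spectrum: water at
#' 4.7 ppm plus three measurable fat resonances at 2.1, 1.3 and 0.9 ppm (the
#' small 2.75 ppm resonance is unresolvable at 40--50 Hz linewidths and is
#' absorbed by the 2.1 ppm line). Frequencies are constrained to
#' `window_ppm` around the priors and dampings to `[5, 200]` Hz.
#'
#' @param field_T Field strength, tesla.
#' @param window_ppm Half-width of the frequency window, ppm.
#' @param water_shift_ppm Water position, ppm.
#' @return A tibble with columns `label`, `frequency_hz`, `window_hz`,
#'   `damping_lo_hz`, `damping_hi_hz` and `is_water`.
#' @export
mrs_priors <- function(field_T = 3, window_ppm = 0.1, water_shift_ppm = 4.7) {
  shifts <- c(water = water_shift_ppm, fat_21 = 2.1, fat_13 = 1.3, fat_09 = 0.9)
  tibble::tibble(
    label = names(shifts),
    frequency_hz = ppm_to_hz(unname(shifts), field_T, water_shift_ppm),
    window_hz = window_ppm * .gamma_mhz_t * field_T,
    damping_lo_hz = 5,
    damping_hi_hz = 200,
    is_water = names(shifts) == "water"
  )
}

#' Time-domain peak fitting of one FID
#'
#' Least-squares fit of a sum of exponentially damped complex sinusoids
#' with prior-knowledge constraints, in the spirit of AMARES: each peak has
#' a frequency confined to a window around its prior and a Lorentzian
#' damping bounded in `[damping_lo_hz, damping_hi_hz]`. The complex
#' amplitudes are solved exactly by linear projection at every step
#' (variable projection), so only frequencies and dampings are iterated.
#' The peak *area* is the modulus of the amplitude at `t = 0`.
#'
#' @param fid Complex FID of length >= 64.
#' @param sweep_hz Sampling bandwidth, Hz.
#' @param priors A prior table as [mrs_priors()]; windows must not overlap.
#' @return A tibble of class `peak_fit` with columns `label`,
#'   `frequency_hz`, `area`, `area_se`, `damping_hz`, `phase`; attributes
#'   `residual_norm` and `converged`.
#' @export
#' @examples
#' tis <- tissue_state(0.8, 0.2)
#' rec <- simulate_press_spectrum(tis, te_ms = 40, snr = Inf)
#' fit_peaks(rec$fid, 2000, mrs_priors())
fit_peaks <- function(fid, sweep_hz, priors = mrs_priors()) {
  n <- length(fid)
  if (n < 64) abort("FID must have at least 64 points.")
  K <- nrow(priors)
  lo <- priors$frequency_hz - priors$window_hz
  hi <- priors$frequency_hz + priors$window_hz
  ord <- order(lo)
  if (any(lo[ord][-1] < hi[ord][-K])) {
    abort("Prior frequency windows overlap; peaks would be unidentifiable.")
  }
  t_s <- (seq_len(n) - 1) / sweep_hz

  make_basis <- function(f, d) {
    vapply(seq_len(K),
           function(k) exp((1i * 2 * pi * f[k] - pi * d[k]) * t_s),
           complex(n))
  }
  solve_amp <- function(B) {
    G <- Conj(t(B)) %*% B
    list(G = G, c = solve(G, Conj(t(B)) %*% fid))
  }
  resid_fun <- function(par) {
    B <- make_basis(par[seq_len(K)], par[K + seq_len(K)])
    r <- fid - B %*% solve_amp(B)$c
    c(Re(r), Im(r))
  }

  start <- c(priors$frequency_hz, rep(50, K))
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = c(lo, priors$damping_lo_hz),
    upper = c(hi, priors$damping_hi_hz),
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-12,
                                         maxiter = 200)
  )
  f_hat <- fit$par[seq_len(K)]
  d_hat <- fit$par[K + seq_len(K)]
  B <- make_basis(f_hat, d_hat)
  sol <- solve_amp(B)
  r <- fid - B %*% sol$c
  residual_norm <- sqrt(sum(Mod(r)^2))
  # amplitude covariance conditional on the nonlinear parameters
  sigma2 <- sum(Mod(r)^2) / max(1, 2 * n - 4 * K)
  area_se <- sqrt(pmax(Re(diag(solve(sol$G))), 0) * sigma2)

  out <- tibble::tibble(
    label = priors$label,
    frequency_hz = f_hat,
    area = Mod(as.vector(sol$c)),
    area_se = area_se,
    damping_hz = d_hat,
    phase = Arg(as.vector(sol$c)),
    is_water = priors$is_water
  )
  attr(out, "residual_norm") <- residual_norm
  attr(out, "converged") <- fit$info %in% 1:4
  class(out) <- c("peak_fit", class(out))
  out
}

#' Mono-exponential T2 fit of peak areas over echo time
#'
#' Nonlinear least squares of `A(TE) = rho exp(-TE / T2)` over `rho > 0`
#' and `T2` in `[5, 500]` ms, returning the extrapolated TE = 0 proton
#' density and the relaxation time. A fit that runs into the upper T2 bound
#' (no measurable decay) is flagged with `t2_at_bound`.
#'
#' @param areas_by_te A data frame with columns `te_ms` and `area` (>= 3
#'   rows with positive areas), or a numeric vector of areas with `te_ms`
#'   supplied separately.
#' @param te_ms Echo times when `areas_by_te` is a plain vector.
#' @return A list with `density`, `t2_ms`, `t2_at_bound` and `converged`.
#' @export
#' @examples
#' te <- seq(40, 110, 10)
#' fit_t2_decay(data.frame(te_ms = te, area = 100 * exp(-te / 25)))
fit_t2_decay <- function(areas_by_te, te_ms = NULL) {
  if (is.data.frame(areas_by_te)) {
    te <- areas_by_te$te_ms
    a <- areas_by_te$area
  } else {
    te <- te_ms
    a <- areas_by_te
  }
  keep <- is.finite(a) & a > 0
  if (sum(keep) < 3) {
    abort("Need at least 3 echo times with positive areas for a T2 fit.")
  }
  te <- te[keep]; a <- a[keep]
  # log-linear start
  b <- coef(lm(log(a) ~ te))
  t2_0 <- min(max(-1 / b[2], 5), 500)
  if (!is.finite(t2_0)) t2_0 <- 100
  rho_0 <- exp(b[1])
  fit <- minpack.lm::nls.lm(
    par = c(rho = rho_0, t2 = t2_0),
    fn = function(p) p[1] * exp(-te / p[2]) - a,
    lower = c(1e-12, 5), upper = c(Inf, 500),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 200)
  )
  list(density = unname(fit$par[1]), t2_ms = unname(fit$par[2]),
       t2_at_bound = unname(fit$par[2]) > 500 - 1e-6,
       converged = fit$info %in% 1:4)
}

#' Correct a single-echo peak area back to TE = 0
#'
#' Undoes the T2 decay of one measured area: `area * exp(te / T2)`.
#'
#' @param area_at_te Measured area at echo time `te_ms`.
#' @param te_ms Echo time, ms.
#' @param t2_ms The peak's T2, ms (positive).
#' @return The TE = 0 proton density.
#' @export
correct_single_echo <- function(area_at_te, te_ms, t2_ms) {
  if (any(t2_ms <= 0)) abort("`t2_ms` must be positive.")
  area_at_te * exp(te_ms / t2_ms)
}

#' Restore the hidden fat signal
#'
#' The fat resonances under the water peak cannot be measured without water
#' suppression; the total fat density is recovered multiplicatively from the
#' measurable share of the spectral model:
#' `total = measurable / sum(measurable amplitudes)`.
#'
#' @param measurable_fat_density Summed T2-corrected density of the
#'   measurable fat peaks (>= 0).
#' @param spectrum A [fat_spectrum()].
#' @return The total fat proton density.
#' @export
#' @examples
#' hidden_fat_correction(0.914, default_fat_spectrum())
hidden_fat_correction <- function(measurable_fat_density,
                                  spectrum = default_fat_spectrum()) {
  if (any(measurable_fat_density < 0)) {
    abort("`measurable_fat_density` must be non-negative.")
  }
  msum <- measurable_fraction(spectrum)
  if (msum <= 0) abort("The spectrum has no measurable amplitude.")
  measurable_fat_density / msum
}

# Phase-coherent signed area: the modulus estimate |c| is positively biased
# for weak peaks, which flattens T2 decays; projecting every amplitude onto
# the water phase of the same record gives areas with zero-mean noise.
# nominal liver fat T2 at 3 T (literature value), used only when the data
# cannot support any fat T2 fit
.nominal_fat_t2_ms <- 60

coherent_areas <- function(fit) {
  phase_w <- fit$phase[fit$is_water][1]
  fit$area * cos(fit$phase - phase_w)
}

# Solve the complex amplitudes of a fixed set of damped sinusoids by linear
# least squares. Frequencies and dampings are physical properties of the
# voxel and do not change along the TE train, so once they are known from
# the high-SNR single-echo record the per-TE areas are a linear problem.
project_amplitudes <- function(fid, sweep_hz, f_hz, d_hz) {
  n <- length(fid)
  t_s <- (seq_len(n) - 1) / sweep_hz
  B <- vapply(seq_along(f_hz),
              function(k) exp((1i * 2 * pi * f_hz[k] - pi * d_hz[k]) * t_s),
              complex(n))
  G <- Conj(t(B)) %*% B
  Ginv <- solve(G)
  cc <- Ginv %*% (Conj(t(B)) %*% fid)
  r <- fid - B %*% cc
  sigma2 <- sum(Mod(r)^2) / max(1, 2 * n - 2 * length(f_hz))
  list(amplitude = as.vector(cc),
       cov = Re(Ginv) * sigma2)
}

# Per-peak areas along the TE train, with the nonlinear basis fixed from a
# reference fit and all areas phase-referenced to its water phase. The
# pooled fat area uses the full amplitude covariance: overlapping peaks
# have anticorrelated amplitude errors, so the sum is far better
# determined than the individual areas.
series_areas <- function(fids, te_ms, sweep_hz, ref_fit) {
  phase_ref <- ref_fit$phase[ref_fit$is_water][1]
  fat <- !ref_fit$is_water
  res <- lapply(seq_along(fids), function(i) {
    pr <- project_amplitudes(fids[[i]], sweep_hz, ref_fit$frequency_hz,
                             ref_fit$damping_hz)
    area <- Re(pr$amplitude * exp(-1i * phase_ref))
    list(
      areas = tibble::tibble(label = ref_fit$label, area = area,
                             area_se = sqrt(pmax(diag(pr$cov), 0)),
                             te_ms = te_ms[i]),
      pooled = tibble::tibble(te_ms = te_ms[i], area = sum(area[fat]),
                              area_se = sqrt(max(sum(pr$cov[fat, fat]), 0)))
    )
  })
  list(areas = dplyr::bind_rows(lapply(res, `[[`, "areas")),
       pooled = dplyr::bind_rows(lapply(res, `[[`, "pooled")))
}

#' MRS proton-density fat fraction
#'
#' The full spectroscopy pipeline: fit water and the measurable fat peaks in
#' each multi-TE record, fit each peak's mono-exponential T2 over echo time,
#' correct the 40-average single-echo areas back to TE = 0 with those T2
#' values, sum the fat densities, restore the hidden fat share, and form
#' `PDFF = fat / (fat + water)`.
#'
#' Because the hidden fat resonances lie inside the water line, the fitted
#' water area absorbs part of the fat signal. When `water_decontaminate` is
#' `TRUE` (default), a second pass subtracts the modelled hidden-fat FID
#' (hidden amplitudes of the spectral model, density-weighted fat T2 and
#' damping from the first pass) from every record and refits, so the water
#' density is free of that contamination.
#'
#' @param series A [spectrum_series()] containing the multi-TE records and a
#'   single-echo record.
#' @param spectrum A [fat_spectrum()].
#' @param priors Peak priors as [mrs_priors()].
#' @param water_decontaminate Subtract the modelled hidden-fat signal from
#'   the records before the final water fit.
#' @param field_T Field strength, tesla.
#' @return A `fat_fraction_estimate` with `method_label = "mrs"`, carrying
#'   `water_t2_ms` and the per-peak T2 table in `peak_t2`.
#' @export
estimate_pdff_mrs <- function(series, spectrum = default_fat_spectrum(),
                              priors = mrs_priors(), water_decontaminate = TRUE,
                              field_T = 3) {
  stopifnot(inherits(series, "spectrum_series"))
  recs <- series$records
  mt <- recs[recs$role == "multi_te", ]
  se <- recs[recs$role == "single_echo", ]
  if (nrow(se) == 0) abort("Series has no single-echo record.")
  if (nrow(mt) < 3) abort("Series needs at least 3 multi-TE records.")
  se <- se[1, ]

  run_pass <- function(mt_fids, se_fid) {
    # nonlinear parameters from the 40-average single-echo record (highest
    # SNR), then linear per-TE areas with that basis held fixed
    se_fit <- fit_peaks(se_fid, series$sweep_hz, priors)
    se_area_coh <- coherent_areas(se_fit)
    se_water_area <- se_area_coh[se_fit$is_water]
    sa <- series_areas(mt_fids, mt$te_ms, series$sweep_hz, se_fit)
    areas <- sa$areas
    labels <- priors$label
    t2 <- setNames(rep(NA_real_, length(labels)), labels)
    dens <- setNames(rep(0, length(labels)), labels)
    flags <- TRUE

    # A weak resonance (area comparable to its fitted uncertainty across the
    # multi-TE records) cannot support its own T2 fit: the exp(+TE/T2)
    # extrapolation would amplify a noise-determined T2. Weak fat peaks
    # borrow the T2 of the pooled measurable fat signal instead.
    peak_strength <- function(lb) {
      a <- areas[areas$label == lb, ]
      mean(a$area) / max(mean(a$area_se), .Machine$double.xmin)
    }
    pooled <- sa$pooled
    pooled_strength <- mean(pooled$area) /
      max(mean(pooled$area_se), .Machine$double.xmin)
    pooled_t2 <- if (pooled_strength >= 3) {
      tryCatch(fit_t2_decay(pooled)$t2_ms, error = function(e) NA_real_)
    } else NA_real_

    for (lb in labels) {
      is_water <- priors$is_water[priors$label == lb]
      a <- areas[areas$label == lb, c("te_ms", "area")]
      se_area <- se_area_coh[se_fit$label == lb]
      # skip fat peaks with negligible signal (e.g. fat-free liver)
      if (!is_water &&
          max(abs(a$area)) < 1e-8 * max(se_water_area, max(abs(a$area)))) next
      if (is_water || peak_strength(lb) >= 5) {
        t2fit <- tryCatch(fit_t2_decay(a), error = function(e) NULL)
        if (is.null(t2fit)) { flags <- FALSE; next }
        flags <- flags && t2fit$converged && !t2fit$t2_at_bound
        t2[lb] <- t2fit$t2_ms
      } else if (is.finite(pooled_t2)) {
        t2[lb] <- pooled_t2
      } else {
        # the data cannot support any fat T2 fit (near-zero fat signal);
        # fall back on the nominal liver fat T2 at 3 T
        t2[lb] <- .nominal_fat_t2_ms
      }
      dens[lb] <- max(correct_single_echo(se_area, se$te_ms, t2[lb]), 0)
    }
    water_density <- unname(dens["water"])
    measurable <- sum(dens[!priors$is_water])
    total_fat <- hidden_fat_correction(measurable, spectrum)
    fat_t2 <- t2[!priors$is_water]
    fat_dens <- dens[!priors$is_water]
    w <- if (sum(fat_dens) > 0) fat_dens / sum(fat_dens) else
      rep(1 / length(fat_dens), length(fat_dens))
    fat_damp <- se_fit$damping_hz[!se_fit$is_water]
    list(water_density = water_density, measurable = measurable,
         total_fat = total_fat, t2 = t2, dens = dens,
         fat_t2_mean = sum(w * ifelse(is.na(fat_t2), 60, fat_t2)),
         fat_damp_mean = sum(w * fat_damp),
         se_fit = se_fit, converged = flags && attr(se_fit, "converged"))
  }

  pass1 <- run_pass(mt$fid, se$fid[[1]])
  result <- pass1
  if (water_decontaminate && pass1$total_fat > 0) {
    hid <- spectrum[spectrum$role == "hidden", ]
    df_hz <- ppm_to_hz(hid$chemical_shift_ppm, field_T,
                       attr(spectrum, "water_shift_ppm"))
    t_s <- (seq_len(series$n_points) - 1) / series$sweep_hz
    hidden_fid <- function(te) {
      out <- complex(series$n_points)
      for (h in seq_len(nrow(hid))) {
        out <- out + pass1$total_fat * hid$relative_amplitude[h] *
          exp(-te / pass1$fat_t2_mean) *
          exp((1i * 2 * pi * df_hz[h] - pi * pass1$fat_damp_mean) * t_s)
      }
      out
    }
    mt_clean <- lapply(seq_len(nrow(mt)),
                       function(i) mt$fid[[i]] - hidden_fid(mt$te_ms[i]))
    se_clean <- se$fid[[1]] - hidden_fid(se$te_ms)
    result <- run_pass(mt_clean, se_clean)
  }

  # the protocol never suppresses water, so a liver record always carries a
  # dominant water line; a near-absent one signals a pathological input
  if (!is.finite(result$water_density) || result$water_density <= 0 ||
      result$water_density < 0.05 * (result$water_density + result$total_fat)) {
    abort("Fitted water density is zero or negligible; cannot form a fat fraction.")
  }
  pdff <- pdff_from_densities(result$total_fat, result$water_density)
  new_fat_fraction_estimate(
    pdff = pdff, t2star_ms = NA_real_,
    water_density = result$water_density, fat_density = result$total_fat,
    residual_norm = attr(result$se_fit, "residual_norm"),
    method_label = "mrs", converged = result$converged,
    extra = list(
      water_t2_ms = unname(result$t2["water"]),
      peak_t2 = tibble::tibble(label = names(result$t2),
                               t2_ms = unname(result$t2),
                               density = unname(result$dens))
    )
  )
}
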