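#' Quantify a simulated cohort with the three MR methods
#'
#' For every subject, simulates the acquisitions its tissue state implies
#' (triple-echo and multi-echo gradient-echo ROI series, the PRESS spectrum
#' series) and runs the matching estimator, appending per-method columns to
#' the cohort: `<method>_pdff_pct`, `<method>_t2star_ms` (imaging),
#' `mrs_water_t2_ms`, and `<method>_converged`. A subject whose estimation
#' fails is flagged (`converged = FALSE`, estimate `NA`) rather than
#' aborting the run.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param methods Any of `"triple"`, `"multi"`, `"mrs"`.
#' @param snr Acquisition signal-to-noise ratio.
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @param spectrum A [fat_spectrum()].
#' @return The cohort with estimate columns appended.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec(n_subjects = 3), seed = 1)
#' quantify_cohort(co, methods = "triple", seed = 2)
quantify_cohort <- function(cohort, methods = c("triple", "multi", "mrs"),
                            snr = 50, seed = NULL,
                            spectrum = default_fat_spectrum()) {
  methods <- match.arg(methods, several.ok = TRUE)
  with_seed(seed, {
    for (m in methods) {
      est <- purrr::map(seq_len(nrow(cohort)), function(i) {
        subject <- cohort[i, ]
        tryCatch({
          if (m == "mrs") {
            series <- simulate_spectrum_series(subject, spectrum, snr = snr)
            estimate_pdff_mrs(series, spectrum)
          } else {
            protocol <- if (m == "triple") triple_echo_protocol() else
              multi_echo_protocol()
            series <- simulate_gre_series(subject, protocol, snr = snr,
                                          spectrum = spectrum)
            if (m == "triple") estimate_pdff_triple(series, spectrum) else
              estimate_pdff_multi(series, spectrum)
          }
        }, error = function(e) NULL)
      })
      ok <- !vapply(est, is.null, logical(1))
      pdff <- vapply(est, function(e) if (is.null(e)) NA_real_ else e$pdff,
                     numeric(1))
      cohort[[paste0(m, "_pdff_pct")]] <- 100 * pdff
      if (m == "mrs") {
        cohort$mrs_water_t2_ms <- vapply(est, function(e) {
          if (is.null(e)) NA_real_ else e$water_t2_ms
        }, numeric(1))
      } else {
        cohort[[paste0(m, "_t2star_ms")]] <- vapply(est, function(e) {
          if (is.null(e)) NA_real_ else e$t2star_ms
        }, numeric(1))
      }
      cohort[[paste0(m, "_converged")]] <- ok &
        vapply(est, function(e) !is.null(e) && isTRUE(e$converged), logical(1))
    }
    cohort
  })
}

methods_in_cohort <- function(cohort) {
  intersect(c("triple", "multi", "mrs"),
            sub("_pdff_pct$", "",
                grep("_pdff_pct$", names(cohort), value = TRUE)))
}

#' Diagnostic-accuracy evaluation of a quantified cohort
#'
#' The statistical layer in one call: Spearman correlation of each method's
#' PDFF with the histology percentage; empirical and smoothed ROC with the
#' Youden threshold at each grade cutpoint (any / at-least-moderate /
#' severe steatosis); grade-wise medians and IQRs with pairwise rank-sum
#' tests; univariable and NASH/fibrosis-adjusted linear models with their
#' Obuchowski AUCs; and DeLong comparisons between methods at each
#' cutpoint. A cutpoint with a missing class is marked `skipped`.
#'
#' @param cohort A quantified cohort tibble (from [quantify_cohort()] or
#'   [read_cohort_csv()] after quantification).
#' @param methods Methods to evaluate; defaults to those present.
#' @return A list of class `hepafat_report` with tibbles `correlations`,
#'   `accuracy`, `group_medians`, `group_tests`, `model_coefficients`,
#'   `model_summaries` and `roc_comparisons`.
#' @export
evaluate_cohort <- function(cohort, methods = methods_in_cohort(cohort)) {
  if (length(methods) == 0) {
    abort("Cohort has no '<method>_pdff_pct' columns; quantify it first.")
  }
  cutpoints <- c("mild", "moderate", "severe")
  grade <- grade_steatosis(cohort$histo_pct)

  correlations <- purrr::map_dfr(methods, function(m) {
    v <- cohort[[paste0(m, "_pdff_pct")]]
    keep <- !is.na(v)
    tibble::tibble(method = m,
                   rho = spearman_rho(v[keep], cohort$histo_pct[keep]),
                   n = sum(keep))
  })

  accuracy <- purrr::map_dfr(methods, function(m) {
    v <- cohort[[paste0(m, "_pdff_pct")]]
    purrr::map_dfr(cutpoints, function(cp) {
      keep <- !is.na(v)
      labels <- binary_labels(grade[keep], cp)
      if (length(unique(labels)) < 2) {
        warn(sprintf("Cutpoint '%s' skipped for method '%s': only one class present.",
                     cp, m))
        return(tibble::tibble(method = m, cutpoint = cp, skipped = TRUE,
                              auc = NA_real_, auc_smoothed = NA_real_,
                              threshold = NA_real_, sensitivity = NA_real_,
                              specificity = NA_real_, youden_j = NA_real_))
      }
      emp <- roc_empirical(v[keep], labels)
      # the smoothed curve needs at least 5 subjects per class; fall back
      # to the empirical operating points for the threshold otherwise
      smo <- if (min(table(labels)) >= 5) roc_smoothed(v[keep], labels) else NULL
      thr <- youden_threshold(if (is.null(smo)) emp else smo)
      tibble::tibble(method = m, cutpoint = cp, skipped = FALSE,
                     auc = emp$auc,
                     auc_smoothed = if (is.null(smo)) NA_real_ else smo$auc,
                     threshold = thr$threshold,
                     sensitivity = thr$sensitivity,
                     specificity = thr$specificity,
                     youden_j = thr$youden_j)
    })
  })

  group_medians <- purrr::map_dfr(methods, function(m) {
    dplyr::mutate(group_summaries(dplyr::mutate(cohort, grade = grade),
                                  paste0(m, "_pdff_pct")),
                  method = m, .before = 1)
  })

  grade_pairs <- utils::combn(steatosis_grades(), 2)
  group_tests <- purrr::map_dfr(methods, function(m) {
    v <- cohort[[paste0(m, "_pdff_pct")]]
    purrr::map_dfr(seq_len(ncol(grade_pairs)), function(k) {
      a <- v[grade == grade_pairs[1, k] & !is.na(v)]
      b <- v[grade == grade_pairs[2, k] & !is.na(v)]
      tibble::tibble(method = m, grade_a = grade_pairs[1, k],
                     grade_b = grade_pairs[2, k],
                     p_value = if (length(a) >= 2 && length(b) >= 2) {
                       group_test(a, b)
                     } else NA_real_)
    })
  })

  fits <- purrr::map(methods, function(m) {
    list(uni = tryCatch(fit_steatosis_models(cohort, m, "none"),
                        error = function(e) NULL),
         multi = tryCatch(fit_steatosis_models(cohort, m, "nash_fibrosis"),
                          error = function(e) NULL))
  })
  names(fits) <- methods
  model_coefficients <- purrr::map_dfr(methods, function(m) {
    dplyr::bind_rows(
      if (!is.null(fits[[m]]$uni)) {
        dplyr::mutate(tidy(fits[[m]]$uni), method = m, model = "univariable")
      },
      if (!is.null(fits[[m]]$multi)) {
        dplyr::mutate(tidy(fits[[m]]$multi), method = m, model = "multivariable")
      }
    )
  })
  model_summaries <- purrr::map_dfr(methods, function(m) {
    dplyr::bind_rows(
      if (!is.null(fits[[m]]$uni)) {
        dplyr::mutate(glance(fits[[m]]$uni), model = "univariable")
      },
      if (!is.null(fits[[m]]$multi)) {
        dplyr::mutate(glance(fits[[m]]$multi), model = "multivariable")
      }
    )
  })

  roc_comparisons <- if (length(methods) >= 2) {
    mp <- utils::combn(methods, 2)
    purrr::map_dfr(cutpoints, function(cp) {
      labels <- binary_labels(grade, cp)
      purrr::map_dfr(seq_len(ncol(mp)), function(k) {
        a <- cohort[[paste0(mp[1, k], "_pdff_pct")]]
        b <- cohort[[paste0(mp[2, k], "_pdff_pct")]]
        keep <- !is.na(a) & !is.na(b)
        if (length(unique(labels[keep])) < 2) {
          return(tibble::tibble(cutpoint = cp, method_a = mp[1, k],
                                method_b = mp[2, k], auc_a = NA_real_,
                                auc_b = NA_real_, p_value = NA_real_))
        }
        cmp <- compare_roc_paired(a[keep], b[keep], labels[keep])
        tibble::tibble(cutpoint = cp, method_a = mp[1, k], method_b = mp[2, k],
                       auc_a = cmp$auc_a, auc_b = cmp$auc_b,
                       p_value = cmp$p_value)
      })
    })
  } else {
    tibble::tibble()
  }

  structure(
    list(correlations = correlations, accuracy = accuracy,
         group_medians = group_medians, group_tests = group_tests,
         model_coefficients = model_coefficients,
         model_summaries = model_summaries,
         roc_comparisons = roc_comparisons),
    class = "hepafat_report"
  )
}

#' @export
print.hepafat_report <- function(x, ...) {
  cat("<hepafat_report>\n\nSpearman correlations with histology:\n")
  print(x$correlations)
  cat("\nDiagnostic accuracy (Youden thresholds on smoothed ROC):\n")
  print(x$accuracy)
  cat("\nGrade-wise medians (IQR):\n")
  print(x$group_medians)
  invisible(x)
}

# ---- file-based pipeline -------------------------------------------------

#' Run the simulation stage to disk
#'
#' Writes one synthetic study to `out_dir`: `cohort.csv`, the long-form
#' gradient-echo table `gre_echoes.csv` (`subject_id`, `protocol`, `te_ms`,
#' `roi_mean`, `noise_sigma`), one spectrum directory per subject under
#' `spectra/`, and a `manifest.json` recording the seed and artifact list.
#' Rerunning with the same spec and seed reproduces the files byte for
#' byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param snr Acquisition SNR (defaults to the spec's `noise_snr`).
#' @param spectrum A [fat_spectrum()].
#' @return The manifest, invisibly.
#' @export
run_simulation <- function(out_dir, spec = cohort_spec(), seed = 1,
                           snr = spec$noise_snr,
                           spectrum = default_fat_spectrum()) {
  if (spec$n_subjects < 1) abort("`n_subjects` must be at least 1.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    cohort <- simulate_cohort(spec)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    protos <- list(triple = triple_echo_protocol(), multi = multi_echo_protocol())
    echoes <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      purrr::map_dfr(names(protos), function(p) {
        ser <- simulate_gre_series(cohort[i, ], protos[[p]], snr = snr,
                                   spectrum = spectrum)
        tibble::tibble(subject_id = cohort$subject_id[i], protocol = p,
                       te_ms = ser$te_ms, roi_mean = ser$roi_mean,
                       noise_sigma = attr(ser, "noise_sigma"))
      })
    })
    readr::write_csv(echoes, file.path(out_dir, "gre_echoes.csv"))
    for (i in seq_len(nrow(cohort))) {
      series <- simulate_spectrum_series(cohort[i, ], spectrum, snr = snr)
      write_spectrum_series(series,
                            file.path(out_dir, "spectra", cohort$subject_id[i]))
    }
    manifest <- list(
      seed = seed, snr = snr, n_subjects = spec$n_subjects,
      files = c("cohort.csv", "gre_echoes.csv",
                file.path("spectra", cohort$subject_id))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
  })
}

#' Run the quantification stage on a simulated (or supplied) study directory
#'
#' Reads `cohort.csv`, `gre_echoes.csv` and the per-subject spectrum
#' directories written by [run_simulation()], estimates PDFF with each
#' requested method, and writes `cohort_quantified.csv`. A subject with a
#' missing or unreadable acquisition gets `NA` estimates and a `FALSE`
#' convergence flag; the run continues.
#'
#' @param dir Study directory.
#' @param methods Methods to run.
#' @param spectrum A [fat_spectrum()].
#' @return The quantified cohort tibble, invisibly.
#' @export
run_quantification <- function(dir, methods = c("triple", "multi", "mrs"),
                               spectrum = default_fat_spectrum()) {
  methods <- match.arg(methods, several.ok = TRUE)
  cohort <- read_cohort_csv(file.path(dir, "cohort.csv"))
  echoes <- if (any(methods %in% c("triple", "multi"))) {
    readr::read_csv(file.path(dir, "gre_echoes.csv"), show_col_types = FALSE,
                    progress = FALSE)
  } else NULL
  for (m in methods) {
    est <- purrr::map(cohort$subject_id, function(sid) {
      tryCatch({
        if (m == "mrs") {
          series <- read_spectrum_series(file.path(dir, "spectra", sid))
          estimate_pdff_mrs(series, spectrum)
        } else {
          rows <- echoes[echoes$subject_id == sid & echoes$protocol == m, ]
          if (nrow(rows) == 0) abort("no echoes for subject")
          protocol <- if (m == "triple") triple_echo_protocol() else
            multi_echo_protocol()
          ser <- echo_series(rows$roi_mean[order(rows$te_ms)], protocol,
                             noise_sigma = rows$noise_sigma[1])
          if (m == "triple") estimate_pdff_triple(ser, spectrum) else
            estimate_pdff_multi(ser, spectrum)
        }
      }, error = function(e) {
        warn(sprintf("Subject %s, method %s failed: %s", sid, m,
                     conditionMessage(e)))
        NULL
      })
    })
    cohort[[paste0(m, "_pdff_pct")]] <- 100 * vapply(est, function(e) {
      if (is.null(e)) NA_real_ else e$pdff
    }, numeric(1))
    if (m == "mrs") {
      cohort$mrs_water_t2_ms <- vapply(est, function(e) {
        if (is.null(e)) NA_real_ else e$water_t2_ms
      }, numeric(1))
    } else {
      cohort[[paste0(m, "_t2star_ms")]] <- vapply(est, function(e) {
        if (is.null(e)) NA_real_ else e$t2star_ms
      }, numeric(1))
    }
    cohort[[paste0(m, "_converged")]] <- vapply(est, function(e) {
      !is.null(e) && isTRUE(e$converged)
    }, logical(1))
  }
  write_cohort_csv(cohort, file.path(dir, "cohort_quantified.csv"))
  invisible(cohort)
}

#' Run the evaluation stage on a quantified study directory
#'
#' Reads `cohort_quantified.csv`, computes the [evaluate_cohort()] report,
#' and writes it as `report.json` plus one CSV per table under `report/`.
#'
#' @param dir Study directory containing `cohort_quantified.csv`.
#' @return The `hepafat_report`, invisibly.
#' @export
run_evaluation <- function(dir) {
  cohort <- read_cohort_csv(file.path(dir, "cohort_quantified.csv"))
  report <- evaluate_cohort(cohort)
  rep_dir <- file.path(dir, "report")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    if (nrow(report[[nm]]) > 0) {
      readr::write_csv(report[[nm]], file.path(rep_dir, paste0(nm, ".csv")))
    }
  }
  jsonlite::write_json(lapply(unclass(report), as.data.frame),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Run the whole study pipeline
#'
#' Simulation, quantification and evaluation in sequence; everything is a
#' pure function of `(spec, seed)`.
#'
#' @inheritParams run_simulation
#' @inheritParams run_quantification
#' @return The `hepafat_report`, invisibly.
#' @export
run_study <- function(out_dir, spec = cohort_spec(), seed = 1,
                      snr = spec$noise_snr,
                      methods = c("triple", "multi", "mrs"),
                      spectrum = default_fat_spectrum()) {
  run_simulation(out_dir, spec, seed, snr, spectrum)
  run_quantification(out_dir, methods, spectrum)
  run_evaluation(out_dir)
}
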