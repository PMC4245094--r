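#' Linear models of an MR fat fraction on histology steatosis
#'
#' Ordinary least squares of one method's fat fraction (in percent) on the
#' histology steatosis percentage expressed as a proportion, optionally
#' adjusted for steatohepatitis and fibrosis: the model asks how the MR
#' measurement responds to the biopsy reference and whether the
#' histological covariates shift it. A slope near 33 means a fully
#' steatotic liver (histology 100%) maps to a PDFF near 33% -- the MR fat
#' fraction runs well below the hepatocyte percentage because biopsy counts
#' affected cells while MR measures fat protons. Fibrosis enters with F0
#' as reference and stages 3 and 4 merged (`F3-4`), matching the sparse
#' upper stages of a NAFLD cohort. Alongside the coefficient table the fit
#' reports R-squared and, as the accompanying accuracy summary, the
#' Obuchowski AUC of the method's measured fat fraction against the
#' four-level steatosis grade (fitted values would be monotone in the
#' histology predictor and hence trivially concordant with the grade).
#'
#' @param cohort A cohort tibble containing `histo_pct`, the method's
#'   `<method>_pdff_pct` column, and (for the adjusted model) `nash_flag`
#'   and `fibrosis_stage`.
#' @param method `"triple"`, `"multi"` or `"mrs"`.
#' @param covariates `"none"` for the univariable model or
#'   `"nash_fibrosis"` for the adjusted one.
#' @return An object of class `steatosis_fit` with [tidy()] and [glance()]
#'   methods.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec(n_subjects = 40), seed = 1)
#' co$mrs_pdff_pct <- co$true_pdff_pct
#' fit_steatosis_models(co, "mrs")
fit_steatosis_models <- function(cohort, method = c("triple", "multi", "mrs"),
                                 covariates = c("none", "nash_fibrosis")) {
  method <- match.arg(method)
  covariates <- match.arg(covariates)
  col <- paste0(method, "_pdff_pct")
  if (!col %in% names(cohort)) {
    abort(sprintf("Cohort has no '%s' column; run the quantification first.", col))
  }
  df <- tibble::tibble(
    pdff_pct = cohort[[col]],
    histology = cohort$histo_pct / 100,
    histo_pct = cohort$histo_pct
  )
  if (covariates == "nash_fibrosis") {
    df$nash <- factor(ifelse(as.logical(cohort$nash_flag), "yes", "no"),
                      levels = c("no", "yes"))
    df$fibrosis <- fibrosis_model_factor(cohort$fibrosis_stage)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (covariates == "nash_fibrosis") {
    empty <- levels(df$fibrosis)[!levels(df$fibrosis) %in% unique(df$fibrosis)]
    if (length(empty) > 0) {
      warn(paste0("Dropping empty fibrosis level(s): ",
                  paste(empty, collapse = ", ")))
      df$fibrosis <- droplevels(df$fibrosis)
    }
    model <- lm(pdff_pct ~ histology + nash + fibrosis, data = df)
  } else {
    model <- lm(pdff_pct ~ histology, data = df)
  }
  grade <- grade_steatosis(df$histo_pct)
  ob <- if (length(unique(grade)) >= 2) {
    obuchowski_auc(df$pdff_pct, grade)
  } else {
    warn("Only one steatosis grade present; Obuchowski AUC is undefined.")
    list(auc = NA_real_, se = NA_real_, n_levels = 1L, pairwise = NULL)
  }
  structure(
    list(model = model, method = method, covariates = covariates,
         r_squared = summary(model)$r.squared,
         obuchowski = ob, n = nrow(df)),
    class = "steatosis_fit"
  )
}

#' @export
print.steatosis_fit <- function(x, ...) {
  cat(sprintf("<steatosis_fit '%s'%s> n = %d, R2 = %.3f, Obuchowski AUC = %.3f (SE %.3f)\n",
              x$method,
              if (x$covariates == "nash_fibrosis") " + NASH + fibrosis" else "",
              x$n, x$r_squared, x$obuchowski$auc, x$obuchowski$se))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_steatosis_models
#' @param x A `steatosis_fit`.
#' @param ... Unused.
#' @export
tidy.steatosis_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  ci <- confint(x$model, level = 0.95)
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    conf.low = unname(ci[, 1]),
    conf.high = unname(ci[, 2])
  )
}

#' @rdname fit_steatosis_models
#' @export
glance.steatosis_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    obuchowski_auc = x$obuchowski$auc,
    obuchowski_se = x$obuchowski$se,
    nobs = x$n,
    method = x$method,
    covariates = x$covariates
  )
}
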