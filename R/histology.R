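#' NASH-CRN steatosis grade from the histology percentage
#'
#' Bands the percentage of steatotic hepatocytes into the four NASH-CRN
#' grades: none (< 5%), mild (5 to < 33%), moderate (33 to 66%), severe
#' (> 66%). The published bands share their endpoints; here 5 is mild, 33
#' and 66 are moderate, and only > 66 is severe, so the bands are half-open
#' and exhaustive.
#'
#' @param percent Steatosis percentage(s) in `[0, 100]`.
#' @return An ordered factor with levels [steatosis_grades()].
#' @export
#' @examples
#' grade_steatosis(c(0, 4, 5, 33, 66, 70))
grade_steatosis <- function(percent) {
  if (any(is.na(percent)) || any(percent < 0 | percent > 100)) {
    abort("`percent` must lie in [0, 100] with no missing values.")
  }
  g <- ifelse(percent < 5, "none",
       ifelse(percent < 33, "mild",
       ifelse(percent <= 66, "moderate", "severe")))
  factor(g, levels = steatosis_grades(), ordered = TRUE)
}

#' @rdname grade_steatosis
#' @export
steatosis_grades <- function() c("none", "mild", "moderate", "severe")

#' Dichotomise steatosis grades at a cutpoint
#'
#' One-vs-rest ordinal dichotomisation: a subject is positive when its grade
#' is at or above the cutpoint, so `"mild"` flags any steatosis.
#'
#' @param grades A vector coercible to the grade levels.
#' @param cutpoint `"mild"`, `"moderate"` or `"severe"`.
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' binary_labels(c("none", "mild", "severe"), "moderate")
binary_labels <- function(grades, cutpoint = c("mild", "moderate", "severe")) {
  cutpoint <- match.arg(cutpoint)
  g <- factor(as.character(grades), levels = steatosis_grades(), ordered = TRUE)
  if (any(is.na(g))) abort("`grades` contains values outside the grade levels.")
  as.integer(g >= cutpoint)
}

#' Fibrosis stage levels (F0 through F4)
#' @return Character vector of the five stages.
#' @export
fibrosis_stages <- function() paste0("F", 0:4)

# merged fibrosis coding used by the multivariable models: F0 reference,
# F1, F2, F3-or-F4
fibrosis_model_factor <- function(stage) {
  s <- factor(as.character(stage), levels = fibrosis_stages())
  if (any(is.na(s))) abort("Fibrosis stage outside F0..F4.")
  out <- as.character(s)
  out[out %in% c("F3", "F4")] <- "F3-4"
  factor(out, levels = c("F0", "F1", "F2", "F3-4"))
}
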