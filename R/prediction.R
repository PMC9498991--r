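# Grade prediction by inversion of the fitted linear laws, and
# classification into the four observed response phenotypes.

new_grade_prediction <- function(continuous, source_endpoint,
                                 interval = NULL) {
  continuous <- min(max(continuous, 0), 5)
  structure(list(
    continuous_grade = continuous,
    rounded_grade = as.integer(floor(continuous + 0.5)),  # half-up
    source_endpoint = source_endpoint,
    interval = interval
  ), class = "rs_grade_prediction")
}

#' @export
print.rs_grade_prediction <- function(x, ...) {
  cat(sprintf("Predicted CTCAE grade %.2f (rounded %d) from %s\n",
              x$continuous_grade, x$rounded_grade, x$source_endpoint))
  if (!is.null(x$interval))
    cat(sprintf("  95%% interval: [%.2f, %.2f]\n",
                x$interval[1L], x$interval[2L]))
  invisible(x)
}

# Inverts a decreasing linear law value = intercept + slope * grade.
invert_linear_law <- function(value, fit, source_endpoint) {
  if (fit$law != "linear")
    abort_model("a linear fit (a1 = slope, a2 = intercept) is required")
  slope <- fit$params[["a1"]]; intercept <- fit$params[["a2"]]
  if (slope >= 0)
    abort_model("the law must be decreasing (slope < 0) to invert to grade")
  continuous <- (intercept - value) / abs(slope)
  interval <- NULL
  if (all(is.finite(fit$ci95))) {
    corners <- c(outer(fit$ci95["a1", ], fit$ci95["a2", ],
                       function(a1, a2) (a2 - value) / abs(a1)))
    corners <- corners[is.finite(corners)]
    if (length(corners) > 0L)
      interval <- c(min(max(min(corners), 0), 5),
                    min(max(max(corners), 0), 5))
  }
  new_grade_prediction(continuous, source_endpoint, interval)
}

#' Predict CTCAE grade from SF2
#'
#' Inverts the linear SF2-grade law: every drop of one slope unit in SF2
#' corresponds to one additional severity grade.  The continuous grade is
#' clamped to [0, 5] before rounding; the optional interval propagates the
#' 95% confidence bounds of the fitted slope and intercept.
#'
#' @param sf2 measured SF2 in percent.
#' @param fit linear `rs_fit_result` of SF2 against grade (defaults to the
#'   published coefficients 61.55 - 11.72 * grade via
#'   [default_sf2_grade_fit()]).
#' @return an `rs_grade_prediction`.
#' @export
grade_from_sf2 <- function(sf2, fit = default_sf2_grade_fit()) {
  invert_linear_law(sf2, fit, "sf2")
}

#' Predict CTCAE grade from pATMmax
#'
#' Inverts the linear pATMmax-grade law (41.72 - 6.78 * grade under the
#' default fit): every 6.78 fewer early pATM foci per cell correspond to
#' one additional severity grade.
#'
#' @param patmmax maximal early pATM foci per cell.
#' @param fit linear `rs_fit_result` of pATMmax against grade (defaults to
#'   [default_patm_grade_fit()]).
#' @return an `rs_grade_prediction`.
#' @export
grade_from_patmmax <- function(patmmax, fit = default_patm_grade_fit()) {
  invert_linear_law(patmmax, fit, "patmmax")
}

synthetic_linear_fit <- function(slope, intercept) {
  params <- c(a1 = slope, a2 = intercept)
  ci <- cbind(lower = params, upper = params)
  structure(list(law = "linear", params = params,
                 se = c(a1 = 0, a2 = 0), ci95 = ci, r2 = 1,
                 r2_adjusted = 1, sse = 0, rmse = 0, n = NA_integer_,
                 df = NA_integer_, complex_flag = FALSE,
                 formula = "f(x) = a1*x + a2"),
            class = "rs_fit_result")
}

#' Published SF2-grade law as a fit object (61.55 - 11.72 * grade)
#' @return an `rs_fit_result` usable with [grade_from_sf2()].
#' @export
default_sf2_grade_fit <- function() synthetic_linear_fit(-11.72, 61.55)

#' Published pATMmax-grade law as a fit object (41.72 - 6.78 * grade)
#' @return an `rs_fit_result` usable with [grade_from_patmmax()].
#' @export
default_patm_grade_fit <- function() synthetic_linear_fit(-6.78, 41.72)

#' Classify a cell line into the four response phenotypes
#'
#' The observed responses fall into four categories: `radioresistant`
#' (grade-0-like), `intermediate` (grades 1-4), `hyper_radiosensitive`
#' (grade-5-like: no nuclear ATM activity or grade-5 survival), and
#' `lig4_like` (normal DSB recognition -- early gamma-H2AX foci in the
#' radioresistant range -- but more than `lig4_residual_h2ax_min` residual
#' foci, a gross repair defect).  The LIG4 rule is checked first because a
#' LIG4-like line also shows grade-5 survival.
#'
#' @param record a cell-line record (one-row data.frame or named list) with
#'   at least the pATM and gamma-H2AX endpoints.
#' @param params a [ground_truth_params()] supplying the dose, DSB induction
#'   rate, grade-5 SF2 band and LIG4 threshold.
#' @return one of `"radioresistant"`, `"intermediate"`,
#'   `"hyper_radiosensitive"`, `"lig4_like"`.
#' @export
classify_phenotype <- function(record, params = ground_truth_params()) {
  if (is.na(record$h2ax_10min) || is.na(record$h2ax_24h))
    abort_missing_data("gamma-H2AX endpoints are required")
  pmx <- patmmax(record)
  max_early <- params$dose * params$dsb_per_gy
  sf2 <- record$sf2
  # grade-5 survival band: mutant anchor + 2 sd of the mutant-level noise
  mutant_sd <- params$noise$sf2_base +
    params$noise$sf2_prop * params$grade5_sf2_mean
  grade5_band <- params$grade5_sf2_mean +
    2 * mutant_sd * max(params$noise_scale, 1)
  if (record$h2ax_10min >= 0.8 * max_early &&
      record$h2ax_24h > params$lig4_residual_h2ax_min)
    return("lig4_like")
  if (pmx < 1 || (!is.na(sf2) && sf2 <= grade5_band))
    return("hyper_radiosensitive")
  pred <- grade_from_patmmax(pmx)
  if (pred$rounded_grade == 0L) "radioresistant" else "intermediate"
}
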