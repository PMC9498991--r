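# The coupled k0-k4 coefficient system.
#
# The five fitted inter-endpoint laws can be rewritten as solutions of a
# small system of first-order differential equations whose constants are
# determined entirely by the bounded endpoint values (the most radioresistant
# and most radiosensitive phenotypes observed in human fibroblasts):
#
#   dSF2/dgrade     = -k0          k0 = (max SF2 - min SF2) / 5
#   dSF2/dMN24h     = -k1 * SF2    k1 = ln(max SF2 / min SF2) / max MN24h
#   dSF2/dH2AX24h   = -k2 * SF2    k2 = ln(max SF2 / min SF2) / max H2AX24h
#   dpATMmax/dgrade = -k3          k3 = (max pATMmax - min pATMmax) / 5
#   dSF2/dpATMmax   = +k4          k4 = max SF2 / max pATMmax
#
# The grade inversions for MN and H2AX use the exact algebraic inversion of
# the linear and exponential closed forms,
#   MN24h(grade) = -(1/k1) * ln(1 - k0 * grade / max SF2),
# which keeps every chained identity (e.g. SF2(MN(grade)) = SF2(grade))
# exact; the same inversion applies to H2AX with k2.

RELATIONS <- c("sf2_of_grade", "sf2_of_mn", "sf2_of_h2ax", "patm_of_grade",
               "sf2_of_patm", "mn_of_grade", "h2ax_of_grade", "mn_of_h2ax",
               "patm_of_mn", "patm_of_h2ax")

#' Derive the k0-k4 coefficients from bounded endpoint values
#'
#' @param max_sf2,min_sf2 maximal and minimal SF2 in percent (`min_sf2 > 0`).
#' @param max_mn24h maximal residual micronuclei per 100 cells (> 0).
#' @param max_h2ax24h maximal residual gamma-H2AX foci per cell (> 0).
#' @param max_patmmax,min_patmmax maximal and minimal pATMmax foci per cell.
#' @return an `rs_coefficient_set` holding the six bounds and the five
#'   derived coefficients: `k0` (percent SF2 per grade), `k1` (per
#'   micronucleus/100 cells), `k2` (per focus), `k3` (foci per grade), `k4`
#'   (percent SF2 per focus).
#' @export
derive_coefficients <- function(max_sf2, min_sf2, max_mn24h, max_h2ax24h,
                                max_patmmax, min_patmmax = 0) {
  if (min_sf2 <= 0) abort_domain("min_sf2 must be > 0 (log undefined)")
  if (max_mn24h <= 0 || max_h2ax24h <= 0 || max_patmmax <= 0)
    abort_domain("maximal endpoint values must be > 0")
  if (max_sf2 <= min_sf2 || max_patmmax <= min_patmmax)
    abort_domain("each max must exceed the corresponding min")
  structure(list(
    max_sf2 = max_sf2, min_sf2 = min_sf2, max_mn24h = max_mn24h,
    max_h2ax24h = max_h2ax24h, max_patmmax = max_patmmax,
    min_patmmax = min_patmmax,
    k0 = (max_sf2 - min_sf2) / 5,
    k1 = log(max_sf2 / min_sf2) / max_mn24h,
    k2 = log(max_sf2 / min_sf2) / max_h2ax24h,
    k3 = (max_patmmax - min_patmmax) / 5,
    k4 = max_sf2 / max_patmmax
  ), class = "rs_coefficient_set")
}

#' Default coefficient set from the fitted-law bounds
#'
#' Bounds chosen so that the derived coefficients equal the fitted-law
#' constants: `max_sf2 = 61.55` and `min_sf2` at grade 5 of the linear law
#' give `k0 = 11.72`; `max_mn24h` and `max_h2ax24h` are set from the
#' exponential decays so that `k1 = 0.107` and `k2 = 0.216`; the pATM
#' bounds `41.72` and `7.82` (the fitted law at grades 0 and 5) give
#' `k3 = 6.78`.  Using `min_patmmax = 0` instead (no pATM foci in the ATM
#' mutants) is equally defensible and changes only `k3`.
#'
#' @return an `rs_coefficient_set`.
#' @export
default_coefficient_set <- function() {
  max_sf2 <- 61.55
  min_sf2 <- 61.55 - 5 * 11.72
  derive_coefficients(
    max_sf2 = max_sf2, min_sf2 = min_sf2,
    max_mn24h = log(max_sf2 / min_sf2) / 0.107,
    max_h2ax24h = log(max_sf2 / min_sf2) / 0.216,
    max_patmmax = 41.72, min_patmmax = 41.72 - 5 * 6.78
  )
}

#' @export
print.rs_coefficient_set <- function(x, ...) {
  cat("Coefficient set:\n")
  cat(sprintf("  SF2 in [%.4g, %.4g]%%, pATMmax in [%.4g, %.4g] foci\n",
              x$min_sf2, x$max_sf2, x$min_patmmax, x$max_patmmax))
  cat(sprintf("  k0 = %.4g %%/grade, k1 = %.4g /MN, k2 = %.4g /focus,\n",
              x$k0, x$k1, x$k2))
  cat(sprintf("  k3 = %.4g foci/grade, k4 = %.4g %%/focus\n", x$k3, x$k4))
  invisible(x)
}

#' Closed-form prediction of one endpoint from another
#'
#' Evaluates the closed-form relation named by `relation` under a
#' coefficient set.  Grades live in [0, 5]; counts are non-negative; the
#' logarithmic grade inversions require `1 - k0 * grade / max_sf2 > 0`.
#'
#' @param relation one of `sf2_of_grade`, `sf2_of_mn`, `sf2_of_h2ax`,
#'   `patm_of_grade`, `sf2_of_patm`, `mn_of_grade`, `h2ax_of_grade`,
#'   `mn_of_h2ax`, `patm_of_mn`, `patm_of_h2ax`.
#' @param x the predictor value (vectorised).
#' @param coeffs an `rs_coefficient_set`.
#' @return predicted endpoint value(s).
#' @export
predict_endpoint <- function(relation = RELATIONS, x,
                             coeffs = default_coefficient_set()) {
  relation <- match.arg(relation)
  k <- coeffs
  if (relation %in% c("sf2_of_grade", "patm_of_grade", "mn_of_grade",
                      "h2ax_of_grade")) {
    if (any(x < 0 | x > 5))
      abort_domain("grade must lie in [0, 5]")
  } else if (any(x < 0)) {
    abort_domain("endpoint counts must be >= 0")
  }
  switch(relation,
    sf2_of_grade  = k$max_sf2 - k$k0 * x,
    sf2_of_mn     = k$max_sf2 * exp(-k$k1 * x),
    sf2_of_h2ax   = k$max_sf2 * exp(-k$k2 * x),
    patm_of_grade = k$max_patmmax - k$k3 * x,
    sf2_of_patm   = k$k4 * x,
    mn_of_grade   = {
      arg <- 1 - k$k0 * x / k$max_sf2
      if (any(arg <= 0)) abort_domain("log argument must be > 0")
      -log(arg) / k$k1
    },
    h2ax_of_grade = {
      arg <- 1 - k$k0 * x / k$max_sf2
      if (any(arg <= 0)) abort_domain("log argument must be > 0")
      -log(arg) / k$k2
    },
    mn_of_h2ax    = (k$k2 / k$k1) * x,
    patm_of_mn    = (k$max_sf2 / k$k4) * exp(-k$k1 * x),
    patm_of_h2ax  = (k$max_sf2 / k$k4) * exp(-k$k2 * x)
  )
}

central_diff <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)

#' Numerically verify the global differential system
#'
#' Differentiates each closed form by central differences (step `1e-5` of
#' the domain span) over an evaluation grid and reports the maximal
#' absolute residual against the right-hand side of each of the five
#' equations of the global system.
#'
#' @param coeffs an `rs_coefficient_set`.
#' @param n_grid number of interior grid points per domain.
#' @return named numeric vector of maximal absolute residuals for
#'   `dsf2_dgrade`, `dsf2_dmn`, `dsf2_dh2ax`, `dpatm_dgrade`, `dsf2_dpatm`.
#' @export
check_ode_consistency <- function(coeffs = default_coefficient_set(),
                                  n_grid = 101L) {
  k <- coeffs
  grid_in <- function(lo, hi) {
    h <- 1e-5 * (hi - lo)
    seq(lo + 2 * h, hi - 2 * h, length.out = n_grid)
  }
  res <- c(
    dsf2_dgrade = {
      g <- grid_in(0, 5); h <- 1e-5 * 5
      max(abs(central_diff(function(z)
        predict_endpoint("sf2_of_grade", z, k), g, h) + k$k0))
    },
    dsf2_dmn = {
      m <- grid_in(0, k$max_mn24h); h <- 1e-5 * k$max_mn24h
      max(abs(central_diff(function(z)
        predict_endpoint("sf2_of_mn", z, k), m, h) +
          k$k1 * predict_endpoint("sf2_of_mn", m, k)))
    },
    dsf2_dh2ax = {
      x <- grid_in(0, k$max_h2ax24h); h <- 1e-5 * k$max_h2ax24h
      max(abs(central_diff(function(z)
        predict_endpoint("sf2_of_h2ax", z, k), x, h) +
          k$k2 * predict_endpoint("sf2_of_h2ax", x, k)))
    },
    dpatm_dgrade = {
      g <- grid_in(0, 5); h <- 1e-5 * 5
      max(abs(central_diff(function(z)
        predict_endpoint("patm_of_grade", z, k), g, h) + k$k3))
    },
    dsf2_dpatm = {
      p <- grid_in(0, k$max_patmmax); h <- 1e-5 * k$max_patmmax
      max(abs(central_diff(function(z)
        predict_endpoint("sf2_of_patm", z, k), p, h) - k$k4))
    }
  )
  res
}

#' Audit the internal consistency of bound-derived and fitted coefficients
#'
#' Compares each bound-derived coefficient against its fitted-law
#' counterpart (e.g. `k0` against the absolute slope of the linear SF2-grade
#' law, `k4` against the fitted proportionality constant and against
#' `k0 / k3`), reporting relative differences and flagging those above
#' `tolerance`.  The published coefficient system is not perfectly
#' self-consistent -- the fitted proportionality constant (1.422), the bound
#' ratio max SF2 / max pATMmax (about 1.49) and k0/k3 (about 1.73) disagree
#' -- and the audit reports the discrepancies without privileging any value.
#'
#' @param coeffs an `rs_coefficient_set` (bound-derived).
#' @param fitted named list of `rs_fit_result`s, with any of the elements
#'   `sf2_grade` (linear), `sf2_mn` (exponential), `sf2_h2ax` (exponential),
#'   `patm_grade` (linear), `sf2_patm` (proportional).
#' @param tolerance relative difference above which a row is flagged
#'   (default 0.10).
#' @return data.frame with columns `quantity`, `derived`, `fitted`,
#'   `rel_diff`, `flagged`.
#' @export
audit_internal_consistency <- function(coeffs, fitted, tolerance = 0.10) {
  rows <- list()
  add <- function(quantity, derived, fit_val) {
    rel <- abs(derived - fit_val) / abs(fit_val)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, derived = derived, fitted = fit_val,
      rel_diff = rel, flagged = rel > tolerance, stringsAsFactors = FALSE)
  }
  if (!is.null(fitted$sf2_grade))
    add("k0 vs |slope(SF2~grade)|", coeffs$k0,
        abs(fitted$sf2_grade$params[["a1"]]))
  if (!is.null(fitted$sf2_mn))
    add("k1 vs |decay(SF2~MN24h)|", coeffs$k1,
        abs(fitted$sf2_mn$params[["b"]]))
  if (!is.null(fitted$sf2_h2ax))
    add("k2 vs |decay(SF2~H2AX24h)|", coeffs$k2,
        abs(fitted$sf2_h2ax$params[["b"]]))
  if (!is.null(fitted$patm_grade))
    add("k3 vs |slope(pATMmax~grade)|", coeffs$k3,
        abs(fitted$patm_grade$params[["a1"]]))
  if (!is.null(fitted$sf2_patm)) {
    a1 <- fitted$sf2_patm$params[["a1"]]
    add("k4 vs fitted proportionality", coeffs$k4, a1)
    add("k0/k3 vs fitted proportionality", coeffs$k0 / coeffs$k3, a1)
  }
  do.call(rbind, rows)
}
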