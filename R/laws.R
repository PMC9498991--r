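# Candidate inter-endpoint laws and model selection.
#
# Endpoint pairs are fitted by least squares with the current simple laws
# (linear, proportional through the origin, exponential, power, quadratic --
# the "curvilinear" option).  Exponential and power fits are true nonlinear
# least squares on the natural scale, initialised from the log-linearised
# regression, so the reported SSE is on the data scale.  If no law reaches
# the acceptability threshold the link is declared "complex" and must be
# deduced by crossed resolution from the other established links.

LAWS <- c("linear", "proportional", "exponential", "power", "quadratic")

new_fit_result <- function(law, params, se, fitted, y, n_par, formula_txt) {
  n <- length(y)
  df <- n - n_par
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  r2_adj <- if (n - n_par - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - n_par - 1)
            else r2
  tq <- if (df > 0) stats::qt(0.975, df) else NA_real_
  ci95 <- cbind(lower = params - tq * se, upper = params + tq * se)
  rownames(ci95) <- names(params)
  structure(list(
    law = law, params = params, se = se, ci95 = ci95,
    r2 = r2, r2_adjusted = r2_adj, sse = sse,
    rmse = if (df > 0) sqrt(sse / df) else NA_real_,
    n = n, df = df, complex_flag = FALSE, formula = formula_txt
  ), class = "rs_fit_result")
}

#' @export
print.rs_fit_result <- function(x, ...) {
  cat(sprintf("%s fit: %s\n", x$law, x$formula))
  for (nm in names(x$params))
    cat(sprintf("  %s = %.6g  (95%% CI %.6g, %.6g)\n", nm, x$params[nm],
                x$ci95[nm, "lower"], x$ci95[nm, "upper"]))
  cat(sprintf("  adj r^2 = %.4f, SSE = %.6g, RMSE = %.6g%s\n",
              x$r2_adjusted, x$sse, x$rmse,
              if (x$complex_flag) "  [complex link]" else ""))
  invisible(x)
}

check_xy <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) abort_data("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_n)
    abort_insufficient(sprintf("at least %d complete (x, y) pairs required",
                               min_n))
  list(x = x, y = y)
}

fit_linear_law <- function(x, y) {
  if (stats::var(x) == 0) abort_fit("rank-deficient design: x is constant")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))  # exact fits warn
  params <- c(a1 = unname(cf["x"]), a2 = unname(cf["(Intercept)"]))
  new_fit_result("linear", params, c(a1 = unname(se["x"]),
                                     a2 = unname(se["(Intercept)"])),
                 stats::fitted(fit), y, 2L, "f(x) = a1*x + a2")
}

fit_quadratic_law <- function(x, y) {
  if (length(unique(x)) < 3L)
    abort_fit("rank-deficient design: need >= 3 distinct x for quadratic")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  params <- c(a1 = unname(cf[3L]), a2 = unname(cf[2L]), a3 = unname(cf[1L]))
  new_fit_result("quadratic", params,
                 c(a1 = unname(se[3L]), a2 = unname(se[2L]),
                   a3 = unname(se[1L])),
                 stats::fitted(fit), y, 3L, "f(x) = a1*x^2 + a2*x + a3")
}

fit_nls_law <- function(x, y, law) {
  if (any(y <= 0))
    abort_domain(paste0(law, " law requires y > 0"))
  if (law == "power" && any(x <= 0))
    abort_domain("power law requires x > 0")
  # log-linearised initial values
  if (law == "exponential") {
    init_fit <- stats::lm(log(y) ~ x)
    form <- y ~ a * exp(b * x)
    txt <- "f(x) = a*exp(b*x)"
  } else {
    init_fit <- stats::lm(log(y) ~ log(x))
    form <- y ~ a * x^b
    txt <- "f(x) = a*x^b"
  }
  start <- list(a = exp(unname(stats::coef(init_fit)[1L])),
                b = unname(stats::coef(init_fit)[2L]))
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort_fit(paste0(law, " fit failed: ",
                                         conditionMessage(e))))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) cf * 0)
  se[!is.finite(se)] <- 0
  new_fit_result(law, c(a = unname(cf["a"]), b = unname(cf["b"])),
                 c(a = unname(se["a"]), b = unname(se["b"])),
                 stats::fitted(fit), y, 2L, txt)
}

#' Fit a through-origin proportional law
#'
#' Single-parameter least squares `y = a1 * x`, `a1 = sum(x*y) / sum(x^2)`.
#'
#' @param x,y numeric vectors (a single point already determines the
#'   parameter).
#' @return an `rs_fit_result` with parameter `a1`.
#' @export
fit_proportional <- function(x, y) {
  xy <- check_xy(x, y, min_n = 1L)
  x <- xy$x; y <- xy$y
  sxx <- sum(x^2)
  if (sxx == 0) abort_fit("cannot fit a proportional law: all x are 0")
  a1 <- sum(x * y) / sxx
  fitted <- a1 * x
  df <- length(x) - 1L
  se <- if (df > 0) sqrt(sum((y - fitted)^2) / df / sxx) else 0
  new_fit_result("proportional", c(a1 = a1), c(a1 = se), fitted, y, 1L,
                 "f(x) = a1*x")
}

#' Fit one candidate law to an endpoint pair
#'
#' @param x,y numeric vectors (equal length, >= 3 complete pairs; y > 0 for
#'   the exponential and power laws, x > 0 additionally for power).
#' @param law one of `"linear"`, `"proportional"`, `"exponential"`,
#'   `"power"`, `"quadratic"`.
#' @return an `rs_fit_result`: parameters with 95% confidence bounds
#'   (t-quantiles on the parameter covariance), adjusted r-squared
#'   (`1 - (1 - r2) * (n - 1) / (n - p - 1)`), SSE and RMSE
#'   (`sqrt(SSE / (n - p))`), all on the natural data scale.
#' @export
fit_law <- function(x, y, law = LAWS) {
  law <- match.arg(law)
  xy <- check_xy(x, y)
  switch(law,
         linear = fit_linear_law(xy$x, xy$y),
         proportional = fit_proportional(xy$x, xy$y),
         exponential = fit_nls_law(xy$x, xy$y, "exponential"),
         power = fit_nls_law(xy$x, xy$y, "power"),
         quadratic = fit_quadratic_law(xy$x, xy$y))
}

n_params <- function(law) switch(law, proportional = 1L, linear = 2L,
                                 exponential = 2L, power = 2L,
                                 quadratic = 3L)

#' Fit all applicable laws and select the best one
#'
#' Fits every candidate law whose domain requirements the data meet, returns
#' the fit with the lowest RMSE (ties broken toward fewer parameters), and
#' flags the link as "complex" when even the best adjusted r-squared falls
#' below the acceptability threshold -- in that case the relation between
#' the two endpoints has to be deduced from the other established links
#' (crossed resolution) rather than from a direct law.
#'
#' @param x,y numeric vectors.
#' @param laws candidate set (default: all five).
#' @param r2_threshold acceptability threshold for the adjusted r-squared
#'   (default 0.70).
#' @return the best `rs_fit_result`, with `complex_flag` set accordingly and
#'   an `all_fits` attribute holding every attempted fit.
#' @export
select_best_law <- function(x, y, laws = LAWS, r2_threshold = 0.70) {
  xy <- check_xy(x, y)
  fits <- list()
  for (law in laws) {
    f <- tryCatch(fit_law(xy$x, xy$y, law), rs_error = function(e) NULL)
    if (!is.null(f)) fits[[law]] <- f
  }
  if (length(fits) == 0L) abort_fit("no candidate law could be fitted")
  rmse <- vapply(fits, function(f) f$rmse, numeric(1))
  npar <- vapply(names(fits), n_params, integer(1))
  ord <- order(rmse, npar)
  best <- fits[[ord[1L]]]
  best$complex_flag <- best$r2_adjusted < r2_threshold
  attr(best, "all_fits") <- fits
  best
}
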