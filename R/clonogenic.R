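# Linear-quadratic fitting of clonogenic survival data.
#
# Cell survival after dose D is modelled as S = exp(-(alpha*D + beta*D^2)).
# Taking -log S makes the model linear in (alpha, beta), so the fit is an
# exact non-negative least-squares problem solved by an active-set sweep of
# the 2x2 normal equations; the dose-0 point only calibrates the plating
# efficiency and is excluded from the regression (S = 1 there by
# construction).

#' Build a clonogenic survival assay object
#'
#' @param doses doses in Gy (distinct, >= 0; should include 0 so that the
#'   plating efficiency can be derived).
#' @param seeded cells seeded per dose.
#' @param colonies colonies scored per dose (only colonies with more than 50
#'   cells count as survivors; the threshold is implicit in the counts).
#' @return an `rs_survival_assay`.
#' @export
survival_assay <- function(doses, seeded, colonies) {
  if (length(doses) != length(seeded) || length(doses) != length(colonies))
    abort_data("doses, seeded and colonies must have equal length")
  if (any(doses < 0)) abort_data("doses must be >= 0")
  if (anyDuplicated(doses)) abort_data("doses must be distinct")
  if (any(colonies < 0) || any(seeded < 1))
    abort_data("colony counts must be >= 0 and seeded cells >= 1")
  if (any(colonies > seeded))
    abort_data("more colonies than seeded cells")
  pe <- if (any(doses == 0)) colonies[doses == 0] / seeded[doses == 0]
        else NA_real_
  structure(list(doses = doses, seeded = seeded, colonies = colonies,
                 plating_efficiency = pe),
            class = "rs_survival_assay")
}

#' Read a survival assay from CSV (columns dose_gy, seeded, colonies)
#' @param path CSV file path.
#' @return an `rs_survival_assay`.
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: '", path, "'"))
  df <- utils::read.csv(path)
  need <- c("dose_gy", "seeded", "colonies")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    abort_format(paste0("missing mandatory column(s): ",
                        paste(miss, collapse = ", ")))
  survival_assay(df$dose_gy, df$seeded, df$colonies)
}

#' Plating efficiency from the unirradiated point
#'
#' @param colonies0 colonies scored at 0 Gy.
#' @param seeded0 cells seeded at 0 Gy.
#' @return fraction in [0, 1].
#' @export
compute_plating_efficiency <- function(colonies0, seeded0) {
  if (seeded0 < 1) abort_data("seeded0 must be >= 1")
  if (colonies0 < 0) abort_data("colonies0 must be >= 0")
  if (colonies0 > seeded0)
    abort_data("more colonies than seeded cells (PE > 1 is impossible)")
  colonies0 / seeded0
}

#' Surviving fraction at one dose point
#'
#' @param colonies colonies scored.
#' @param seeded cells seeded.
#' @param pe plating efficiency (> 0).
#' @return `colonies / (seeded * pe)`.
#' @export
surviving_fraction <- function(colonies, seeded, pe) {
  if (any(pe <= 0)) abort_data("plating efficiency must be > 0")
  colonies / (seeded * pe)
}

#' Fit the linear-quadratic survival model
#'
#' Least squares of `-log(S) = alpha*D + beta*D^2` with both parameters
#' constrained to be non-negative.  The problem is convex; the constrained
#' optimum is found by solving the unconstrained normal equations and, if a
#' coefficient comes out negative, refitting along each boundary.
#'
#' @param doses doses in Gy (any 0-dose points are dropped from the
#'   regression).
#' @param survival surviving fractions in (0, 1] at those doses.
#' @return an `rs_lq_fit`: list with `alpha` (1/Gy), `beta` (1/Gy^2),
#'   `sf2` (percent, `100 * exp(-2*alpha - 4*beta)`), and `residual_sse`
#'   (on the -log S scale).
#' @export
fit_lq <- function(doses, survival) {
  if (length(doses) != length(survival))
    abort_data("doses and survival must have equal length")
  if (any(is.na(survival)) || any(survival <= 0))
    abort_data("surviving fractions must be > 0 (log undefined at 0)")
  if (any(survival > 1 + 1e-12))
    abort_data("surviving fractions must be <= 1")
  keep <- doses > 0
  d <- doses[keep]; s <- survival[keep]
  if (length(d) < 3L)
    abort_insufficient("at least 3 positive-dose points are required")
  z <- -log(s)
  # normal equations for z ~ alpha*d + beta*d^2 (no intercept)
  s2 <- sum(d^2); s3 <- sum(d^3); s4 <- sum(d^4)
  t1 <- sum(d * z); t2 <- sum(d^2 * z)
  det <- s2 * s4 - s3^2
  cand <- list()
  if (det > 0)
    cand <- c(cand, list(c((s4 * t1 - s3 * t2) / det,
                           (s2 * t2 - s3 * t1) / det)))
  cand <- c(cand, list(c(t1 / s2, 0), c(0, t2 / s4), c(0, 0)))
  best <- NULL; best_sse <- Inf
  for (ab in cand) {
    if (any(ab < 0)) next
    sse <- sum((z - ab[1] * d - ab[2] * d^2)^2)
    if (sse < best_sse) { best <- ab; best_sse <- sse }
  }
  alpha <- best[1]; beta <- best[2]
  structure(list(alpha = alpha, beta = beta,
                 sf2 = 100 * exp(-2 * alpha - 4 * beta),
                 residual_sse = best_sse),
            class = "rs_lq_fit")
}

#' Fit an assembled survival assay
#'
#' Derives the plating efficiency from the 0 Gy point, normalises colony
#' counts to surviving fractions, and fits the LQ model.
#'
#' @param assay an `rs_survival_assay`.
#' @return an `rs_lq_fit` (see [fit_lq()]) with `plating_efficiency` added.
#' @export
fit_lq_assay <- function(assay) {
  pe <- assay$plating_efficiency
  if (is.null(pe) || is.na(pe)) {
    if (!any(assay$doses == 0))
      abort_data("assay has no 0 Gy point and no plating efficiency")
    pe <- compute_plating_efficiency(assay$colonies[assay$doses == 0],
                                     assay$seeded[assay$doses == 0])
  }
  sf <- surviving_fraction(assay$colonies, assay$seeded, pe)
  sf <- pmin(sf, 1)   # Poisson noise can push counts above seeded * PE
  # zero-colony points carry no log-scale information; drop them (labs seed
  # more cells at high doses precisely to avoid empty plates)
  keep <- sf > 0 | assay$doses == 0
  fit <- fit_lq(assay$doses[keep], sf[keep])
  fit$plating_efficiency <- pe
  fit
}

#' @export
print.rs_lq_fit <- function(x, ...) {
  cat(sprintf("LQ fit: alpha = %.4g /Gy, beta = %.4g /Gy^2, SF2 = %.2f%%\n",
              x$alpha, x$beta, x$sf2))
  invisible(x)
}
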