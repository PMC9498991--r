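# Synthetic cohort generator.
#
# Emulates a 200-line fibroblast collection from radiotherapy patients with
# the statistical structure the downstream analyses assume.  Each record is
# generated from a latent noiseless chain anchored on the fitted
# inter-endpoint laws:
#
#   SF2(grade)      = 61.55 - 11.72 * grade          (percent; grade-0 lines
#                                                     anchored at 62.1, the
#                                                     radioresistant mean)
#   MN_24h          = -ln(SF2 / 62.2)  / k1,  k1 = 0.107
#   H2AX_24h        = -ln(SF2 / 62.56) / k2,  k2 = 0.216
#   pATMmax(grade)  = 41.72 - 6.78 * grade           (foci per cell)
#   early gamma-H2AX = dose * dsb_per_gy * pATMmax / 41.72, capped at the
#                      physical induction rate (about 40 DSB/Gy/cell)
#
# Endpoint-specific measurement noise is added on top of the latent values
# and clamped at physical bounds.  Homozygous ATM mutants have no pATM (and
# nil or tiny gamma-H2AX) foci; LIG4 mutants recognise DSBs normally (normal
# early foci and pATM) but leave > 30 residual gamma-H2AX foci.

#' CTCAE grade frequency distribution
#'
#' Defaults to the semi-gaussian shape of radiotherapy overreaction
#' frequencies: about 65, 17, 10, 5, 2.5, and 0.5 percent of treated
#' patients for grades 0 to 5.
#'
#' @param p numeric vector of 6 probabilities for grades 0-5.
#' @return validated probability vector of class `"rs_grade_distribution"`.
#' @export
grade_distribution <- function(p = c(0.65, 0.17, 0.10, 0.05, 0.025, 0.005)) {
  p <- as.numeric(p)
  if (length(p) != 6L || anyNA(p) || any(p < 0) || any(p > 1))
    abort_parameter("grade distribution needs 6 probabilities in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    abort_parameter("grade probabilities must sum to 1 (within 1e-9)")
  structure(p, names = paste0("p", 0:5), class = "rs_grade_distribution")
}

#' Ground-truth parameters of the synthetic cohort
#'
#' The defaults are the published study conditions: the fitted law
#' coefficients, the per-grade SF2 anchors (62.1 percent for radioresistant
#' controls, 3.3 percent for the hyper-radiosensitive mutants), the DSB
#' induction rate of 40 per Gy per cell at 2 Gy, and the grade frequency
#' distribution.  Noise standard deviations emulate triplicate measurement
#' error (see the methods vignette for the calibration rationale); with
#' `noise_scale = 0` the generator reproduces the laws exactly.
#'
#' @param sf2_intercept,sf2_slope linear SF2-grade law (percent, percent per
#'   grade).
#' @param grade0_sf2_mean,grade5_sf2_mean SF2 anchors for grade-0 lines and
#'   grade-5 mutants (percent).
#' @param k1 exponential decay of SF2 per residual micronucleus/100 cells.
#' @param k2 exponential decay of SF2 per residual gamma-H2AX focus.
#' @param sf2_max_mn,sf2_max_h2ax amplitudes of the two exponential laws.
#' @param patm_intercept,patm_slope linear pATMmax-grade law (foci, foci per
#'   grade).
#' @param dsb_per_gy DSBs physically induced per Gy per cell.
#' @param dose irradiation dose in Gy.
#' @param lig4_residual_h2ax_min,lig4_residual_h2ax threshold and latent mean
#'   of residual gamma-H2AX foci in the LIG4-mutated phenotype.
#' @param noise list of per-endpoint noise standard deviations; most are of
#'   the form `sd = base + prop * latent`, emulating measurement error that
#'   scales with the endpoint level: `sf2_base` + `sf2_prop` (percent;
#'   calibrated against the decreasing per-grade SF2 standard errors of the
#'   radioresistant-to-radiosensitive range), `patm` (foci), `mn_base` +
#'   `mn_prop` (micronuclei, a counting-statistics scale), `h2ax_base` +
#'   `h2ax_prop` (foci), `h2ax_early` (foci), `mn_spont` (micronuclei),
#'   `pe` (fraction).
#' @param noise_scale multiplier applied to every noise sd (0 = noiseless).
#' @param mn_line_sd between-line biological dispersion of residual
#'   micronuclei (micronuclei per 100 cells), beyond counting noise.
#'   Default 0; see the vignette for what raising it emulates.
#' @param grade_dist a [grade_distribution()].
#' @param atm_fraction_of_grade5 fraction of grade-5 lines with the ATM
#'   phenotype (the rest are LIG4-like).
#' @param atm_h2ax_mode `"nil"` or `"tiny"`: whether gamma-H2AX foci in ATM
#'   mutants are scored as absent or as tiny non-nil counts.
#' @param slow_kinetics_fraction fraction of radiosensitive (grade >= 3)
#'   lines whose pATM focus count peaks at 1 h rather than 10 min.
#' @param sf2_design per-grade numbers of lines receiving a clonogenic assay
#'   (SF2 and plating efficiency); mirrors a stratified assay subset.  Use
#'   `Inf` to measure SF2 on every line.
#' @param beta_alpha_ratio beta/alpha ratio (per Gy) used when synthesising
#'   clonogenic assays from an SF2 value.
#' @param plating_efficiency mean plating efficiency of the collection.
#' @param mn_spont_mean mean spontaneous micronuclei per 100 cells
#'   (grade-independent).
#' @return a classed parameter list (`"rs_ground_truth"`).
#' @export
ground_truth_params <- function(
    sf2_intercept = 61.55, sf2_slope = -11.72,
    grade0_sf2_mean = 62.1, grade5_sf2_mean = 3.3,
    k1 = 0.107, k2 = 0.216,
    sf2_max_mn = 62.2, sf2_max_h2ax = 62.56,
    patm_intercept = 41.72, patm_slope = -6.78,
    dsb_per_gy = 40, dose = 2,
    lig4_residual_h2ax_min = 30, lig4_residual_h2ax = 35,
    noise = list(), noise_scale = 1, mn_line_sd = 0,
    grade_dist = grade_distribution(),
    atm_fraction_of_grade5 = 0.8,
    atm_h2ax_mode = c("nil", "tiny"),
    slow_kinetics_fraction = 0.5,
    sf2_design = c(10, 1, 6, 6, 6, 7),
    beta_alpha_ratio = 1 / 6,
    plating_efficiency = 0.25,
    mn_spont_mean = 2) {
  noise_defaults <- list(sf2_base = 0.5, sf2_prop = 0.06, patm = 1.5,
                         mn_base = 0.5, mn_prop = 0.1,
                         h2ax_base = 0.2, h2ax_prop = 0.05,
                         h2ax_early = 2, mn_spont = 1, pe = 0.05)
  bad <- setdiff(names(noise), names(noise_defaults))
  if (length(bad) > 0L)
    abort_parameter(paste0("unknown noise component(s): ",
                           paste(bad, collapse = ", ")))
  noise <- utils::modifyList(noise_defaults, noise)
  if (any(unlist(noise) < 0) || noise_scale < 0 || mn_line_sd < 0)
    abort_parameter("noise standard deviations must be >= 0")
  if (dose <= 0) abort_parameter("dose must be > 0")
  if (dsb_per_gy <= 0) abort_parameter("dsb_per_gy must be > 0")
  if (atm_fraction_of_grade5 < 0 || atm_fraction_of_grade5 > 1)
    abort_parameter("atm_fraction_of_grade5 must be in [0, 1]")
  if (length(sf2_design) != 6L || any(sf2_design < 0))
    abort_parameter("sf2_design needs 6 non-negative per-grade counts")
  structure(list(
    sf2_intercept = sf2_intercept, sf2_slope = sf2_slope,
    grade0_sf2_mean = grade0_sf2_mean, grade5_sf2_mean = grade5_sf2_mean,
    k1 = k1, k2 = k2, sf2_max_mn = sf2_max_mn, sf2_max_h2ax = sf2_max_h2ax,
    patm_intercept = patm_intercept, patm_slope = patm_slope,
    dsb_per_gy = dsb_per_gy, dose = dose,
    lig4_residual_h2ax_min = lig4_residual_h2ax_min,
    lig4_residual_h2ax = lig4_residual_h2ax,
    noise = noise, noise_scale = noise_scale, mn_line_sd = mn_line_sd,
    grade_dist = grade_distribution(grade_dist),
    atm_fraction_of_grade5 = atm_fraction_of_grade5,
    atm_h2ax_mode = match.arg(atm_h2ax_mode),
    slow_kinetics_fraction = slow_kinetics_fraction,
    sf2_design = sf2_design, beta_alpha_ratio = beta_alpha_ratio,
    plating_efficiency = plating_efficiency,
    mn_spont_mean = mn_spont_mean
  ), class = "rs_ground_truth")
}

#' Sample CTCAE grades from a grade distribution
#'
#' @param n number of grades to draw.
#' @param dist a [grade_distribution()].
#' @param seed optional integer seed (the RNG state is restored on exit when
#'   a seed is given).
#' @return integer vector of length `n` with values in 0-5.
#' @export
sample_grades <- function(n, dist = grade_distribution(), seed = NULL) {
  if (n < 0) abort_parameter("n must be >= 0")
  dist <- grade_distribution(dist)
  if (n == 0L) return(integer(0))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  sample.int(6L, size = n, replace = TRUE, prob = as.numeric(dist)) - 1L
}

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Latent (noiseless) SF2 in percent for a grade/genotype combination.
latent_sf2 <- function(grade, genotype, p) {
  if (genotype %in% c("atm_homozygous", "lig4_mutated")) p$grade5_sf2_mean
  else if (grade == 0L) p$grade0_sf2_mean
  else p$sf2_intercept + p$sf2_slope * grade
}

#' Simulate one cell-line record
#'
#' Draws a single record for the given grade and genotype from the latent
#' law chain plus endpoint noise, using the current RNG stream.  Callers
#' wanting reproducibility should `set.seed()` first (as
#' [simulate_cohort()] does per record).
#'
#' @param grade CTCAE grade 0-5.
#' @param genotype one of [GENOTYPES] (`"other_syndrome"` is treated like
#'   `"wildtype_like"` for endpoint generation).
#' @param params a [ground_truth_params()].
#' @param id record identifier.
#' @param measure_sf2 whether the clonogenic endpoints (sf2, plating
#'   efficiency) are observed for this line.
#' @return a named list with the cell-line record fields.
#' @export
simulate_record <- function(grade, genotype = "wildtype_like",
                            params = ground_truth_params(), id = "CL001",
                            measure_sf2 = TRUE) {
  if (length(grade) != 1L || is.na(grade) || grade < 0 || grade > 5 ||
      grade != as.integer(grade))
    abort_parameter("grade must be a single integer in 0..5")
  if (!genotype %in% GENOTYPES)
    abort_parameter(paste0("unknown genotype '", genotype, "'"))
  p <- params
  ns <- lapply(p$noise, function(s) s * p$noise_scale)
  grade <- as.integer(grade)
  is_atm <- genotype == "atm_homozygous"
  is_lig4 <- genotype == "lig4_mutated"
  is_mutant <- is_atm || is_lig4
  max_early <- p$dose * p$dsb_per_gy

  # latent chain
  sf2_lat <- latent_sf2(grade, genotype, p)
  mn_lat <- -log(sf2_lat / p$sf2_max_mn) / p$k1
  mn_lat <- max(mn_lat, 0)
  h2ax24_lat <- if (is_atm) 0 else if (is_lig4) p$lig4_residual_h2ax
    else max(-log(sf2_lat / p$sf2_max_h2ax) / p$k2, 0)
  patm_lat <- if (is_atm) 0 else if (is_lig4) p$patm_intercept
    else p$patm_intercept + p$patm_slope * grade
  early_lat <- if (is_atm) 0 else if (is_lig4) max_early
    else clamp(max_early * patm_lat / p$patm_intercept, 0, max_early)

  # observed = latent + endpoint noise, clamped at physical bounds
  sf2_sd <- ns$sf2_base + ns$sf2_prop * sf2_lat
  sf2 <- clamp(sf2_lat + stats::rnorm(1L, 0, sf2_sd), 0.1, 100)
  mn_sd <- ns$mn_base + ns$mn_prop * mn_lat
  mn24 <- clamp(mn_lat + stats::rnorm(1L, 0, mn_sd) +
                  (if (p$mn_line_sd > 0)
                     stats::rnorm(1L, 0, p$mn_line_sd * p$noise_scale)
                   else 0), 0)
  h2ax_sd <- ns$h2ax_base + ns$h2ax_prop * h2ax24_lat
  h2ax24 <- if (is_atm && p$atm_h2ax_mode == "nil") 0 else
    clamp(h2ax24_lat + stats::rnorm(1L, 0, h2ax_sd) +
            (if (is_atm) 0.3 else 0), 0)
  if (is_lig4 && p$noise_scale > 0)
    h2ax24 <- max(h2ax24, p$lig4_residual_h2ax_min + 0.1)
  early_sd <- if (is_atm) 0 else ns$h2ax_early
  h2ax10 <- if (is_atm && p$atm_h2ax_mode == "nil") 0 else
    clamp(early_lat + stats::rnorm(1L, 0, early_sd) +
            (if (is_atm) 0.3 else 0), 0, max_early)
  h2ax1h_lat <- h2ax24_lat + 0.5 * (early_lat - h2ax24_lat)
  h2ax1h <- if (is_atm && p$atm_h2ax_mode == "nil") 0 else
    clamp(h2ax1h_lat + stats::rnorm(1L, 0, ns$h2ax_early) +
            (if (is_atm) 0.3 else 0), 0, max_early)

  patmmax_obs <- if (is_atm) 0 else
    clamp(patm_lat + stats::rnorm(1L, 0, ns$patm), 0)
  # kinetic split: radioresistant lines peak at 10 min (1 h systematically
  # lower); a configurable fraction of radiosensitive lines peak at 1 h
  slow <- grade >= 3L && !is_atm &&
    stats::runif(1L) < p$slow_kinetics_fraction
  other <- patmmax_obs * stats::runif(1L, 0.4, 0.9)
  if (slow) { patm10 <- other; patm1h <- patmmax_obs }
  else      { patm10 <- patmmax_obs; patm1h <- other }

  mn_spont <- clamp(p$mn_spont_mean + stats::rnorm(1L, 0, ns$mn_spont), 0)
  pe <- clamp(p$plating_efficiency + stats::rnorm(1L, 0, ns$pe), 0.02, 1)

  list(id = as.character(id), genotype = genotype, ctcae_grade = grade,
       sf2 = if (measure_sf2) sf2 else NA_real_,
       plating_efficiency = if (measure_sf2) pe else NA_real_,
       mn_spont = mn_spont, mn_24h = mn24,
       h2ax_10min = h2ax10, h2ax_1h = h2ax1h, h2ax_24h = h2ax24,
       patm_10min = patm10, patm_1h = patm1h)
}

#' Simulate a full cohort
#'
#' Draws `n` grades from the configured grade distribution, assigns the
#' grade-5 lines an ATM or LIG4 phenotype, simulates every record from a
#' per-record child stream derived from the master seed, and marks the
#' clonogenic (SF2) assay subset according to `params$sf2_design` (a
#' stratified per-grade assay plan; lines beyond the per-grade quota carry
#' `NA` SF2, mirroring collections where the survival assay is run on a
#' representative subset only).
#'
#' @param n cohort size (>= 1).
#' @param params a [ground_truth_params()].
#' @param seed integer master seed.
#' @return an `rs_cohort`; `provenance` records `params` and `seed`.
#' @export
simulate_cohort <- function(n = 200, params = ground_truth_params(),
                            seed = 1L) {
  if (n < 1) abort_parameter("n must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  grades <- sample.int(6L, size = n, replace = TRUE,
                       prob = as.numeric(params$grade_dist)) - 1L
  genotypes <- rep("wildtype_like", n)
  g5 <- which(grades == 5L)
  if (length(g5) > 0L)
    genotypes[g5] <- ifelse(
      stats::runif(length(g5)) < params$atm_fraction_of_grade5,
      "atm_homozygous", "lig4_mutated")
  # stratified clonogenic assay subset
  measure <- logical(n)
  for (g in 0:5) {
    idx <- which(grades == g)
    quota <- min(length(idx), params$sf2_design[g + 1L])
    if (quota > 0) measure[idx[seq_len(quota)]] <- TRUE
  }
  child_seeds <- sample.int(.Machine$integer.max - 1L, n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(child_seeds[i])
    recs[[i]] <- simulate_record(grades[i], genotypes[i], params,
                                 id = sprintf("CL%04d", i),
                                 measure_sf2 = measure[i])
  }
  df <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  cohort(df, provenance = list(generator = "simulate_cohort", seed = seed,
                               n = n, params = unclass(params)))
}

#' Synthesise a clonogenic survival assay from an SF2 value
#'
#' Chooses non-negative linear-quadratic parameters consistent with
#' `S(2 Gy) = sf2 / 100` under the configured beta/alpha ratio, then draws
#' colony counts as Poisson with mean `seeded * PE * S(D)` (the dose-0 point
#' carries the plating efficiency).  With `noiseless = TRUE` the expected
#' (real-valued) colony counts are returned instead, so that a
#' [fit_lq()] round trip recovers alpha and beta to numerical precision.
#'
#' @param sf2 surviving fraction at 2 Gy, percent in (0, 100].
#' @param params a [ground_truth_params()] (beta/alpha ratio, default PE).
#' @param doses vector of doses in Gy (should include 0).
#' @param seeded_cells cells seeded per dose (recycled).
#' @param pe plating efficiency; defaults to `params$plating_efficiency`.
#' @param noiseless return expected counts instead of Poisson draws.
#' @return an `rs_survival_assay`: list with `doses`, `seeded`, `colonies`,
#'   `plating_efficiency`, and the generating `alpha`, `beta`.
#' @export
simulate_survival_assay <- function(sf2, params = ground_truth_params(),
                                    doses = c(0, 1, 2, 4, 6),
                                    seeded_cells = 1000, pe = NULL,
                                    noiseless = FALSE) {
  if (length(sf2) != 1L || is.na(sf2) || sf2 <= 0 || sf2 > 100)
    abort_parameter("sf2 must be a percent in (0, 100]")
  if (any(doses < 0)) abort_parameter("doses must be >= 0")
  seeded <- rep_len(seeded_cells, length(doses))
  if (any(seeded < 1)) abort_parameter("seeded_cells must be >= 1")
  if (is.null(pe)) pe <- params$plating_efficiency
  r <- params$beta_alpha_ratio
  s2 <- sf2 / 100
  alpha <- -log(s2) / (2 + 4 * r)   # alpha * 2 + beta * 4 = -log(S(2))
  beta <- r * alpha
  surv <- exp(-(alpha * doses + beta * doses^2))
  mu <- seeded * pe * surv
  colonies <- if (noiseless) mu else stats::rpois(length(mu), mu)
  structure(list(doses = doses, seeded = seeded, colonies = colonies,
                 plating_efficiency = pe, alpha = alpha, beta = beta),
            class = "rs_survival_assay")
}
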