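# End-to-end pipeline: simulate -> fit laws -> derive coefficients ->
# discriminate -> predict -> report.  All artifacts are deterministic given
# the seed; JSON artifacts embed the seed and a hash of the configuration.

# FNV-1a 32-bit hash of a string (hex); small stable config fingerprint.
# All arithmetic kept inside double precision (h < 2^32 exceeds integer
# range, and h * prime would exceed 2^53, so the multiply is split).
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = " ")))
  prime <- 16777619
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * prime) %% 65536) * 65536 + h0 * prime) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Pipeline configuration
#'
#' @param seed master seed for the synthetic cohort.
#' @param cohort_size number of cell lines to simulate.
#' @param params a [ground_truth_params()].
#' @param output_dir directory for the report bundle.
#' @param stages named logical toggles: `survival` (clonogenic laws),
#'   `coefficients`, `discrimination`, `prediction`.
#' @return an `rs_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, cohort_size = 200,
                            params = ground_truth_params(),
                            output_dir = "radiosens-output",
                            stages = list()) {
  if (cohort_size < 1) abort_parameter("cohort_size must be >= 1")
  stage_defaults <- list(survival = TRUE, coefficients = TRUE,
                         discrimination = TRUE, prediction = TRUE)
  bad <- setdiff(names(stages), names(stage_defaults))
  if (length(bad) > 0L)
    abort_parameter(paste0("unknown stage toggle(s): ",
                           paste(bad, collapse = ", ")))
  structure(list(seed = as.integer(seed), cohort_size = cohort_size,
                 params = params, output_dir = output_dir,
                 stages = utils::modifyList(stage_defaults, stages)),
            class = "rs_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `seed`, `cohort_size`, `output_dir`, `stages` and
#' `ground_truth` (arguments to [ground_truth_params()]).
#'
#' @param path YAML file.
#' @return an `rs_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: '", path, "'"))
  y <- yaml::read_yaml(path)
  gt <- if (is.null(y$ground_truth)) ground_truth_params()
        else do.call(ground_truth_params, y$ground_truth)
  pipeline_config(
    seed = if (is.null(y$seed)) 1L else y$seed,
    cohort_size = if (is.null(y$cohort_size)) 200 else y$cohort_size,
    params = gt,
    output_dir = if (is.null(y$output_dir)) "radiosens-output"
                 else y$output_dir,
    stages = if (is.null(y$stages)) list() else y$stages)
}

#' Fit the five standard inter-endpoint laws on a cohort
#'
#' Reproduces the standard fit report: a linear SF2-grade law, exponential
#' SF2-MN24h and SF2-H2AX24h laws, a linear pATMmax-grade law and a
#' proportional SF2-pATMmax law, all on per-cell-line values.  Records are
#' excluded where an endpoint does not carry the information the law
#' models: ATM-homozygous lines from the gamma-H2AX law (their foci are nil
#' by convention although their survival is minimal) and LIG4-mutated lines
#' from the gamma-H2AX and pATM-based laws (normal DSB recognition and ATM
#' activity despite grade-5 survival make them a category of their own).
#'
#' @param cohort an `rs_cohort`.
#' @param include_sf2_laws fit the four SF2-based laws (requires measured
#'   SF2 values).
#' @return named list of `rs_fit_result`s: `sf2_grade`, `sf2_mn`,
#'   `sf2_h2ax`, `sf2_patm` (when `include_sf2_laws`) and `patm_grade`,
#'   plus an `exclusions` attribute with the per-law record counts.
#' @export
fit_endpoint_laws <- function(cohort, include_sf2_laws = TRUE) {
  df <- cohort$records
  df$patmmax <- pmax(df$patm_10min, df$patm_1h, na.rm = TRUE)
  not_lig4 <- df$genotype != "lig4_mutated"
  not_atm <- df$genotype != "atm_homozygous"
  has_sf2 <- !is.na(df$sf2)
  fits <- list()
  used <- list()
  if (include_sf2_laws) {
    s <- df[has_sf2, ]
    fits$sf2_grade <- fit_law(s$ctcae_grade, s$sf2, "linear")
    used$sf2_grade <- nrow(s)
    fits$sf2_mn <- fit_law(s$mn_24h, s$sf2, "exponential")
    used$sf2_mn <- nrow(s)
    sh <- df[has_sf2 & not_atm & not_lig4, ]
    fits$sf2_h2ax <- fit_law(sh$h2ax_24h, sh$sf2, "exponential")
    used$sf2_h2ax <- nrow(sh)
    sp <- df[has_sf2 & not_lig4, ]
    fits$sf2_patm <- fit_proportional(sp$patmmax, sp$sf2)
    used$sf2_patm <- nrow(sp)
  }
  pg <- df[not_lig4, ]
  fits$patm_grade <- fit_law(pg$ctcae_grade, pg$patmmax, "linear")
  used$patm_grade <- nrow(pg)
  attr(fits, "exclusions") <- used
  fits
}

#' Derive a coefficient set from fitted laws
#'
#' Bounds are taken from the fitted laws themselves (intercepts as maxima,
#' the linear laws at grade 5 as minima, and the exponential-decay maxima
#' chosen so that k1 and k2 equal the fitted decays), so the derived
#' coefficients reproduce the fit report.
#'
#' @param fits output of [fit_endpoint_laws()]; missing SF2 laws fall back
#'   to the published defaults.
#' @return an `rs_coefficient_set`.
#' @export
coefficients_from_fits <- function(fits) {
  defaults <- default_coefficient_set()
  if (!is.null(fits$sf2_grade)) {
    max_sf2 <- fits$sf2_grade$params[["a2"]]
    min_sf2 <- max_sf2 + 5 * fits$sf2_grade$params[["a1"]]
    if (min_sf2 <= 0) min_sf2 <- 0.1   # degenerate steep fit
  } else {
    max_sf2 <- defaults$max_sf2; min_sf2 <- defaults$min_sf2
  }
  k1 <- if (!is.null(fits$sf2_mn)) abs(fits$sf2_mn$params[["b"]])
        else defaults$k1
  k2 <- if (!is.null(fits$sf2_h2ax)) abs(fits$sf2_h2ax$params[["b"]])
        else defaults$k2
  max_patm <- fits$patm_grade$params[["a2"]]
  min_patm <- max(max_patm + 5 * fits$patm_grade$params[["a1"]], 0)
  derive_coefficients(
    max_sf2 = max_sf2, min_sf2 = min_sf2,
    max_mn24h = log(max_sf2 / min_sf2) / k1,
    max_h2ax24h = log(max_sf2 / min_sf2) / k2,
    max_patmmax = max_patm, min_patmmax = min_patm)
}

fit_to_row <- function(name, fit) {
  p <- fit$params
  list(endpoints = name, fitting_function = fit$formula,
       params = as.list(p),
       ci95 = apply(fit$ci95, 1L, as.list),
       r2_adjusted = fit$r2_adjusted, sse = fit$sse, rmse = fit$rmse,
       n = fit$n, complex = fit$complex_flag)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, fits the inter-endpoint laws, derives and audits the
#' coefficient system, computes the per-grade and binary discrimination
#' reports, predicts grades and phenotypes per record, and writes the
#' report bundle to `config$output_dir`: `cohort.csv`, `fits.json`,
#' `coefficients.json`, `discrimination.json`, `predictions.csv`,
#' `summary.txt` and `manifest.json` (seed + configuration hash).
#'
#' @param config an [pipeline_config()].
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  hash <- fnv1a_hash(unclass(config)[c("seed", "cohort_size", "params",
                                       "stages")])
  meta <- list(seed = config$seed, config_hash = hash)
  write_json <- function(x, f)
    jsonlite::write_json(c(meta, x), out(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  results <- list()

  co <- simulate_cohort(config$cohort_size, config$params, config$seed)
  write_cohort_csv(co, out("cohort.csv"))
  results$cohort <- co

  fits <- fit_endpoint_laws(co, include_sf2_laws = config$stages$survival)
  write_json(list(fits = lapply(names(fits), function(n)
    fit_to_row(n, fits[[n]]))), "fits.json")
  results$fits <- fits

  if (config$stages$coefficients) {
    coeffs <- coefficients_from_fits(fits)
    audit <- audit_internal_consistency(coeffs, fits)
    ode <- check_ode_consistency(coeffs)
    write_json(list(coefficients = unclass(coeffs),
                    audit = audit, ode_max_residual = as.list(ode)),
               "coefficients.json")
    results$coefficients <- coeffs
    results$audit <- audit
  }

  if (config$stages$discrimination) {
    endpoints <- c("sf2", "mn_24h", "h2ax_24h", "patmmax")
    disc <- lapply(endpoints, function(e) {
      g <- tryCatch(grade_discrimination(co, e)$table,
                    rs_error = function(err) conditionMessage(err))
      b <- tryCatch(binary_discrimination(co, e),
                    rs_error = function(err) conditionMessage(err))
      list(endpoint = e, by_grade = g, binary = b)
    })
    write_json(list(discrimination = disc), "discrimination.json")
    results$discrimination <- disc
  }

  if (config$stages$prediction) {
    df <- co$records
    preds <- lapply(seq_len(nrow(df)), function(i) {
      rec <- df[i, ]
      pm <- patmmax(rec)
      gp <- grade_from_patmmax(pm)
      gs <- if (!is.na(rec$sf2)) grade_from_sf2(rec$sf2) else NULL
      data.frame(
        id = rec$id, ctcae_grade = rec$ctcae_grade,
        patmmax = pm,
        grade_from_patmmax = gp$continuous_grade,
        grade_from_patmmax_rounded = gp$rounded_grade,
        grade_from_sf2 = if (is.null(gs)) NA_real_ else gs$continuous_grade,
        grade_from_sf2_rounded = if (is.null(gs)) NA_integer_
                                 else gs$rounded_grade,
        phenotype = classify_phenotype(rec, config$params),
        stringsAsFactors = FALSE)
    })
    preds <- do.call(rbind, preds)
    utils::write.csv(preds, out("predictions.csv"), row.names = FALSE)
    results$predictions <- preds
  }

  summary_lines <- c(
    sprintf("radiosens pipeline (seed %d, config %s)", config$seed, hash),
    sprintf("cohort: %d lines, SF2 measured on %d",
            nrow(co$records), sum(!is.na(co$records$sf2))),
    if (!is.null(fits$sf2_grade))
      sprintf("SF2(grade) = %.2f %+.2f*grade (adj r2 %.3f)",
              fits$sf2_grade$params[["a2"]], fits$sf2_grade$params[["a1"]],
              fits$sf2_grade$r2_adjusted),
    sprintf("pATMmax(grade) = %.2f %+.2f*grade (adj r2 %.3f)",
            fits$patm_grade$params[["a2"]], fits$patm_grade$params[["a1"]],
            fits$patm_grade$r2_adjusted))
  writeLines(summary_lines, out("summary.txt"))

  manifest <- list(files = list.files(config$output_dir))
  write_json(manifest, "manifest.json")
  invisible(results)
}
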