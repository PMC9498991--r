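# Cohort container, record validation, and CSV interchange.
#
# A cohort is a plain data.frame of one row per fibroblast cell line plus a
# provenance list (generator parameters and seed, or the source file).  All
# endpoint values are per-cell-line means: micronuclei per 100 cells, nuclear
# foci per cell, SF2 in percent.

#' Known genotype categories
#'
#' `wildtype_like` covers all lines without an identified homozygous repair
#' defect (CTCAE grades 0-4), `atm_homozygous` the ataxia-telangiectasia
#' lines (no nuclear ATM kinase activity, hence no pATM and essentially no
#' gamma-H2AX foci), `lig4_mutated` the ligase-IV defective phenotype (normal
#' DSB recognition, grossly impaired repair), and `other_syndrome` any other
#' radiosensitivity syndrome.
#'
#' @export
GENOTYPES <- c("wildtype_like", "atm_homozygous", "lig4_mutated",
               "other_syndrome")

# Fixed CSV column dialect.  Order is the interchange contract; sem_* columns
# are optional standard errors of the mean over the triplicate experiments.
COHORT_COLUMNS <- c(
  "id", "genotype", "ctcae_grade", "sf2", "plating_efficiency",
  "mn_spont", "mn_24h", "h2ax_10min", "h2ax_1h", "h2ax_24h",
  "patm_10min", "patm_1h"
)
COHORT_SEM_COLUMNS <- c(
  "sem_sf2", "sem_mn_spont", "sem_mn_24h", "sem_h2ax_10min", "sem_h2ax_1h",
  "sem_h2ax_24h", "sem_patm_10min", "sem_patm_1h"
)
MANDATORY_COLUMNS <- c("id", "genotype", "ctcae_grade", "mn_spont", "mn_24h",
                       "h2ax_10min", "h2ax_1h", "h2ax_24h",
                       "patm_10min", "patm_1h")

#' Construct a single cell-line record
#'
#' Builds and validates one row of a cohort table.  `sf2` and
#' `plating_efficiency` may be `NA` (clonogenic assays are typically run on a
#' subset of a collection); all other endpoints are mandatory.
#'
#' @param id unique cell-line identifier.
#' @param genotype one of [GENOTYPES].
#' @param ctcae_grade integer CTCAE severity grade, 0 (no event) to 5 (death).
#' @param sf2 surviving fraction at 2 Gy, percent in (0, 100], or `NA`.
#' @param plating_efficiency fraction of unirradiated cells forming colonies,
#'   in (0, 1], or `NA`.
#' @param mn_spont,mn_24h spontaneous and 24 h post-irradiation micronuclei
#'   per 100 cells (non-negative).
#' @param h2ax_10min,h2ax_1h,h2ax_24h gamma-H2AX foci per cell at 10 min,
#'   1 h and 24 h post-irradiation (non-negative).
#' @param patm_10min,patm_1h pATM foci per cell at 10 min and 1 h
#'   post-irradiation; at least one must be present for [patmmax()].
#' @param ... optional `sem_*` standard errors (non-negative when present).
#' @return a one-row data.frame with the cohort column dialect.
#' @export
cell_line_record <- function(id, genotype, ctcae_grade, sf2 = NA_real_,
                             plating_efficiency = NA_real_,
                             mn_spont = 0, mn_24h = 0,
                             h2ax_10min = 0, h2ax_1h = 0, h2ax_24h = 0,
                             patm_10min = NA_real_, patm_1h = NA_real_, ...) {
  sems <- list(...)
  bad <- setdiff(names(sems), COHORT_SEM_COLUMNS)
  if (length(bad) > 0L)
    abort_parameter(paste0("unknown record field(s): ",
                           paste(bad, collapse = ", ")))
  rec <- data.frame(
    id = as.character(id), genotype = as.character(genotype),
    ctcae_grade = as.integer(ctcae_grade), sf2 = as.numeric(sf2),
    plating_efficiency = as.numeric(plating_efficiency),
    mn_spont = as.numeric(mn_spont), mn_24h = as.numeric(mn_24h),
    h2ax_10min = as.numeric(h2ax_10min), h2ax_1h = as.numeric(h2ax_1h),
    h2ax_24h = as.numeric(h2ax_24h), patm_10min = as.numeric(patm_10min),
    patm_1h = as.numeric(patm_1h), stringsAsFactors = FALSE
  )
  for (s in COHORT_SEM_COLUMNS)
    rec[[s]] <- if (is.null(sems[[s]])) NA_real_ else as.numeric(sems[[s]])
  validate_records(rec)
  rec
}

# Validates a data.frame of records; errors name the offending row and field.
validate_records <- function(df) {
  check <- function(bad, field) {
    idx <- which(bad)
    if (length(idx) > 0L)
      abort_validation(sprintf(
        "invalid value for '%s' in row %d (id '%s')",
        field, idx[1L], as.character(df$id[idx[1L]])))
  }
  check(is.na(df$id) | !nzchar(df$id), "id")
  check(!(df$genotype %in% GENOTYPES), "genotype")
  check(is.na(df$ctcae_grade) | df$ctcae_grade < 0L | df$ctcae_grade > 5L,
        "ctcae_grade")
  check(!is.na(df$sf2) & (df$sf2 <= 0 | df$sf2 > 100), "sf2")
  check(!is.na(df$plating_efficiency) &
          (df$plating_efficiency <= 0 | df$plating_efficiency > 1),
        "plating_efficiency")
  for (f in c("mn_spont", "mn_24h", "h2ax_10min", "h2ax_1h", "h2ax_24h",
              "patm_10min", "patm_1h"))
    check(!is.na(df[[f]]) & df[[f]] < 0, f)
  for (f in intersect(COHORT_SEM_COLUMNS, names(df)))
    check(!is.na(df[[f]]) & df[[f]] < 0, f)
  invisible(df)
}

#' Assemble a validated cohort
#'
#' @param records data.frame of cell-line records (rows as produced by
#'   [cell_line_record()] or the synthetic generator).
#' @param provenance free-form list of metadata (generator parameters, seed,
#'   or source file path).
#' @return an object of class `"rs_cohort"`: a list with elements `records`
#'   and `provenance`.
#' @export
cohort <- function(records, provenance = list()) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    abort_validation("a cohort requires a non-empty records data.frame")
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols) > 0L)
    abort_format(paste0("missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  for (s in COHORT_SEM_COLUMNS)
    if (is.null(records[[s]])) records[[s]] <- NA_real_
  records <- records[, c(COHORT_COLUMNS, COHORT_SEM_COLUMNS)]
  if (anyDuplicated(records$id))
    abort_validation(paste0("duplicated record id: ",
                            records$id[duplicated(records$id)][1L]))
  validate_records(records)
  rownames(records) <- NULL
  structure(list(records = records, provenance = provenance),
            class = "rs_cohort")
}

#' @export
print.rs_cohort <- function(x, ...) {
  tab <- table(factor(x$records$ctcae_grade, levels = 0:5))
  cat(sprintf("Radiosensitivity cohort: %d cell lines\n", nrow(x$records)))
  cat("  CTCAE grades 0-5:", paste(as.integer(tab), collapse = "/"), "\n")
  cat(sprintf("  SF2 measured on %d lines\n", sum(!is.na(x$records$sf2))))
  if (!is.null(x$provenance$seed))
    cat("  generated with seed", x$provenance$seed, "\n")
  invisible(x)
}

#' Maximal early pATM focus count
#'
#' The maximal number of pATM foci per cell reached at 10 min or 1 h after
#' 2 Gy.  It reflects the maximal nuclear ATM kinase activity, which is
#' reached at different times in different cell lines; taking the maximum of
#' the two sampling times removes that kinetic heterogeneity.
#'
#' @param record one-row data.frame (or list) with `patm_10min` / `patm_1h`.
#' @return maximal pATM foci per cell.
#' @export
patmmax <- function(record) {
  v <- c(record$patm_10min, record$patm_1h)
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    abort_missing_data("both patm_10min and patm_1h are missing")
  max(v)
}

# %.17g formatting round-trips IEEE doubles through text exactly.
format_cell <- function(x) {
  if (is.numeric(x)) ifelse(is.na(x), "", sprintf("%.17g", x))
  else ifelse(is.na(x), "", as.character(x))
}

#' Write a cohort endpoint table to CSV
#'
#' Comma-separated, UTF-8, dot decimal separator, one header row, fixed
#' column order.  Missing values are empty cells.  Numeric cells are written
#' with 17 significant digits so that a write/read round trip preserves every
#' value bit for bit.
#'
#' @param cohort an `rs_cohort` (or a bare records data.frame).
#' @param path output file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- if (inherits(cohort, "rs_cohort")) cohort$records else cohort
  cols <- c(COHORT_COLUMNS, COHORT_SEM_COLUMNS)
  for (cl in setdiff(cols, names(df)))
    df[[cl]] <- rep(NA_real_, nrow(df))
  lines <- paste(cols, collapse = ",")
  if (!is.null(df) && nrow(df) > 0L) {
    cells <- vapply(cols, function(cl) format_cell(df[[cl]]),
                    character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- c(lines, apply(cells, 1L, paste, collapse = ","))
  }
  ok <- tryCatch({
    writeLines(lines, con = path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(paste0("cannot write cohort CSV to '", path, "'"))
  invisible(path)
}

#' Read a cohort endpoint table from CSV
#'
#' Counterpart of [write_cohort_csv()].  The header must contain the
#' mandatory columns of the documented dialect; every row is validated on
#' input and violations are reported with their row and field.
#'
#' @param path CSV file path.
#' @return an `rs_cohort` with `provenance$source` set to `path`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    abort_io(paste0("file not found: '", path, "'"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    abort_format(paste0("missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  for (cl in setdiff(c(COHORT_COLUMNS, COHORT_SEM_COLUMNS), names(df)))
    df[[cl]] <- NA_real_
  num_cols <- setdiff(c(COHORT_COLUMNS, COHORT_SEM_COLUMNS),
                      c("id", "genotype", "ctcae_grade"))
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  df$ctcae_grade <- as.integer(df$ctcae_grade)
  cohort(df, provenance = list(source = path))
}
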