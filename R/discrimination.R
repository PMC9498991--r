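# One-way ANOVA discrimination of endpoint distributions across CTCAE
# grades, and under the binary radioresistant / radiosensitive grouping.

ENDPOINTS <- c("sf2", "mn_24h", "h2ax_24h", "patmmax")

endpoint_values <- function(records, endpoint) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  if (endpoint == "patmmax")
    pmax(records$patm_10min, records$patm_1h, na.rm = TRUE)
  else records[[endpoint]]
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square ratio with an F-distribution p-value, computed
#' via `stats::aov`.  Perfectly separated groups (zero within-group
#' variance but distinct means) return the smallest representable p-value
#' rather than 0.
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return list with `f` (F statistic), `p` (p-value), `df` (numerator,
#'   denominator), `group_sizes`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L)
    abort_insufficient("ANOVA needs at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    abort_insufficient("every group needs at least 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_along(groups), sizes))
  if (stats::var(y) == 0)
    abort_degenerate("all values identical across all groups")
  tab <- summary(stats::aov(y ~ g))[[1L]]
  f <- tab[1L, "F value"]
  p <- tab[1L, "Pr(>F)"]
  if (!is.finite(f)) {   # zero within-group variance: perfect separation
    f <- Inf
    p <- .Machine$double.xmin
  } else if (p == 0) {   # p-value underflow: report minimal representable
    p <- .Machine$double.xmin
  }
  list(f = f, p = p, df = c(tab[1L, "Df"], tab[2L, "Df"]),
       group_sizes = as.integer(sizes))
}

grade_groups <- function(cohort, endpoint, grades) {
  df <- cohort$records
  vals <- endpoint_values(df, endpoint)
  out <- lapply(grades, function(g) {
    v <- vals[df$ctcae_grade == g]
    v[!is.na(v)]
  })
  names(out) <- as.character(grades)
  short <- grades[vapply(out, length, integer(1)) < 2L]
  if (length(short) > 0L)
    abort_insufficient(sprintf(
      "fewer than 2 records with '%s' measured for grade %s",
      endpoint, paste(short, collapse = ", ")))
  out
}

#' Per-grade discrimination power of one endpoint
#'
#' Runs one-way ANOVA for the four standard comparisons of the mid-severity
#' range, where discrimination is hardest: grades {2,3,4}, {2,3}, {3,4} and
#' {2,4}.  Records with the endpoint missing are dropped per comparison.
#'
#' @param cohort an `rs_cohort`.
#' @param endpoint one of `"sf2"`, `"mn_24h"`, `"h2ax_24h"`, `"patmmax"`.
#' @return an `rs_discrimination_report`: endpoint, a comparison table with
#'   F statistics, p-values and group sizes.
#' @export
grade_discrimination <- function(cohort, endpoint) {
  comparisons <- list("2,3 and 4" = c(2, 3, 4), "2 and 3" = c(2, 3),
                      "3 and 4" = c(3, 4), "2 and 4" = c(2, 4))
  rows <- lapply(names(comparisons), function(lbl) {
    res <- one_way_anova(grade_groups(cohort, endpoint, comparisons[[lbl]]))
    data.frame(comparison = lbl, f = res$f, p = res$p,
               n = sum(res$group_sizes), stringsAsFactors = FALSE)
  })
  structure(list(endpoint = endpoint, table = do.call(rbind, rows)),
            class = "rs_discrimination_report")
}

#' @export
print.rs_discrimination_report <- function(x, ...) {
  cat(sprintf("Grade discrimination for %s (one-way ANOVA):\n", x$endpoint))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Binary radioresistant / radiosensitive discrimination
#'
#' Pools CTCAE grades 0-2 (radioresistant) against grades 3-5
#' (radiosensitive) and runs a one-way ANOVA on one endpoint.
#'
#' @param cohort an `rs_cohort`.
#' @param endpoint one of `"sf2"`, `"mn_24h"`, `"h2ax_24h"`, `"patmmax"`.
#' @return list with `f`, `p`, `group_sizes` (resistant, sensitive).
#' @export
binary_discrimination <- function(cohort, endpoint) {
  df <- cohort$records
  vals <- endpoint_values(df, endpoint)
  lo <- vals[df$ctcae_grade <= 2L]; lo <- lo[!is.na(lo)]
  hi <- vals[df$ctcae_grade >= 3L]; hi <- hi[!is.na(hi)]
  if (length(lo) < 2L || length(hi) < 2L)
    abort_insufficient(sprintf(
      "binary grouping needs >= 2 measured records on each side for '%s'",
      endpoint))
  res <- one_way_anova(list(radioresistant = lo, radiosensitive = hi))
  list(f = res$f, p = res$p, group_sizes = res$group_sizes)
}
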