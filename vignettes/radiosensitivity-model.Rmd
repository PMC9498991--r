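---
title: "Modelling individual radiosensitivity from multiple cellular endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling individual radiosensitivity from multiple cellular endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiosens)
```

## The problem

A minority of radiotherapy patients develop tissue overreactions whose
severity is scored clinically on the CTCAE scale, from grade 0 (no event) to
grade 5 (death).  Decades of radiobiology have produced several cellular
assays that each predict part of this spectrum: the clonogenic survival
fraction after a standard 2 Gy session (SF2), residual micronuclei 24 h
post-irradiation (MN24h, per 100 cells), residual gamma-H2AX nuclear foci at
24 h (unrepaired double-strand breaks recognised by NHEJ, per cell), and
phosphorylated-ATM foci early after irradiation.  Because nuclear ATM kinase
activity peaks at 10 min in some cell lines and at 1 h in others, the
useful summary is `pATMmax`, the maximum of the two time points.

`radiosens` implements the quantitative skeleton linking these endpoints:

* `SF2(grade) = 61.55 - 11.72 * grade` (percent),
* `SF2(MN24h) = 62.2 * exp(-0.107 * MN24h)`,
* `SF2(H2AX24h) = 62.56 * exp(-0.216 * H2AX24h)`,
* `pATMmax(grade) = 41.72 - 6.78 * grade` (foci per cell),
* `SF2(pATMmax) = 1.422 * pATMmax`,

together with the grade-frequency distribution of treated patients
(65 / 17 / 10 / 5 / 2.5 / 0.5 percent for grades 0-5) and the two anchor
phenotypes of hyper-radiosensitivity: homozygous ATM mutants (no pATM foci,
essentially no gamma-H2AX foci, SF2 near 3.3 %) and the LIG4-mutated
phenotype (normal DSB recognition -- about 80 early foci after 2 Gy at
40 DSB/Gy/cell -- but more than 30 residual foci at 24 h).

Because the underlying per-patient data are not publicly deposited, the
package treats these published constants as ground truth for a synthetic
cohort generator, and every downstream stage (law fitting, coefficient
derivation, ANOVA discrimination, grade prediction) is tested by parameter
recovery against that ground truth.

## The coefficient system

Writing `max(SF2)`, `min(SF2)` for the survival range of human fibroblasts
and similarly for the other endpoints, the five laws are solutions of a
coupled system of first-order differential equations with constants

* `k0 = (max SF2 - min SF2) / 5` - percent survival lost per grade,
* `k1 = ln(max SF2 / min SF2) / max MN24h` - roughly, the fraction of
  scored micronuclei that is lethal (about 1 in 10),
* `k2 = ln(max SF2 / min SF2) / max H2AX24h` - the fraction of unrepaired
  recognised DSBs that is lethal (about 1 in 5),
* `k3 = (max pATMmax - min pATMmax) / 5` - early pATM foci lost per grade,
* `k4 = max SF2 / max pATMmax` - percent survival per early pATM focus.

`derive_coefficients()` computes these from bounds;
`predict_endpoint()` evaluates all ten closed-form relations;
`check_ode_consistency()` differentiates each closed form numerically
(central differences, step `1e-5` of the domain span) and verifies the
system to below `1e-6`; `audit_internal_consistency()` compares
bound-derived and fitted constants.

Two printed forms needed care:

* The published grade inversions of MN24h and H2AX24h are dimensionally
  inconsistent as printed (the argument of the logarithm can leave the unit
  interval in percent units).  The package uses the exact algebraic
  inversion obtained by equating the linear and exponential laws,
  `MN24h(grade) = -(1/k1) * ln(1 - k0 * grade / max SF2)`, which reproduces
  the intended curve shape and makes the crossed-resolution identity
  `SF2(MN24h(grade)) = SF2(grade)` exact to machine precision.
* The system is not perfectly self-consistent even on its own constants:
  the fitted proportionality `SF2 = 1.422 * pATMmax` disagrees with both
  `max SF2 / max pATMmax` (about 1.49) and `k0 / k3` (about 1.73).  The
  audit reports these discrepancies without privileging any value.

## The synthetic cohort generator

`simulate_cohort()` draws grades from the configured distribution, assigns
grade-5 lines an ATM-like (80 %) or LIG4-like (20 %) genotype, and
generates each record from a latent noiseless chain: SF2 from the linear
grade law (with grade-0 lines anchored at the radioresistant mean of
62.1 % and grade-5 mutants at 3.3 %), MN24h and H2AX24h by inverting the
two exponential laws at the latent SF2, pATMmax from its linear law, and
early gamma-H2AX foci as `dose * 40 * pATMmax / 41.72`, capped at the
physical induction rate.  Endpoint noise is then added and clamped at
physical bounds.  With `noise_scale = 0` the chain reproduces the laws to
machine precision, which the test suite asserts at `1e-9`.

### Noise calibration

The published record gives standard errors of triplicate means but no
noise law, so the generator's defaults are calibrated once, as follows:

* **SF2**: `sd = 0.5 + 0.06 * latent` percent.  The printed per-grade
  standard errors fall from about +-1.4 (grade 0, ten lines, hence a
  between-line SD near 4.4 %) to +-0.6 (grade 4) and +-0.5 (grade 5):
  survival scatter shrinks with survival itself, which a flat SD cannot
  represent.  This calibration keeps the SF2-grade fit on a default cohort
  at an adjusted r-squared of about 0.98, the value the linear law reports.
* **MN24h and H2AX24h**: `sd = base + prop * latent` at the
  counting-statistics scale of three experiments of 100 scored nuclei
  (approximately the Poisson standard error of the mean), i.e.
  `0.5 + 0.1 * m` micronuclei and `0.2 + 0.05 * h` foci.
* **pATMmax**: flat `sd = 1.5` foci, small enough that re-fitting the
  pATM-grade law recovers its slope within the 5 % recovery band used in
  the acceptance tests.
* Spontaneous micronuclei are drawn grade-independently (mean 2 per 100
  cells); plating efficiency is drawn around 0.25.

### The clonogenic subset

Survival assays are slow, so collections of this kind measure SF2 on a
stratified representative subset rather than on every line.  The generator
mirrors this: `sf2_design = c(10, 1, 6, 6, 6, 7)` lines per grade receive
SF2 and plating-efficiency values (capped by per-grade availability; about
29 of 200 lines under the default grade distribution), and the remaining
lines carry `NA` SF2.  This subset design is not cosmetic: it is what makes
the binary ANOVA p-value of SF2 (n about 29) weaker than that of pATMmax
(n = 200), reproducing the published ranking of those two endpoints.

### What the generator does not emulate

The generator adds *measurement* noise around exact laws.  Real cell lines
additionally carry *biological* between-line dispersion that is much larger
than counting noise, particularly for micronuclei (the ratio of unrepaired
breaks to micronuclei varies with each line's capacity to bypass the G2/M
arrest) and for pATM kinetics.  Two consequences:

* The pATMmax-grade fit on synthetic cohorts reaches an adjusted r-squared
  near 0.96, whereas the published fit reports 0.74.  Recovery of the
  *parameters* is unaffected; the *dispersion* is understated.
* Under counting-scale micronucleus noise, the exponential MN law places
  grade 4-5 lines near 13-27 micronuclei per 100 cells against about 1 in
  the radioresistant group, so MN24h separates the binary radioresistant /
  radiosensitive split by several standard deviations and comes out as the
  *most* significant endpoint in the ANOVA -- the opposite of the
  published ranking, where micronuclei are the weakest discriminator.
  Reproducing that weakness requires a per-line micronucleus dispersion of
  roughly five or more micronuclei per 100 cells in the radioresistant
  group, which in turn biases the per-line exponential fit (regression
  dilution on the regressor) far beyond the 5 % recovery band for the
  decay constant 0.107.  A single self-consistent noise model cannot
  satisfy both observations when the law fit sees the same per-line values
  as the ANOVA.  The package resolves the tension in favour of exact law
  recovery: the default keeps counting-scale noise, the corresponding
  acceptance assertion on the full endpoint ordering is expected to fail
  on the micronucleus position (the pATMmax-before-SF2 part is stable),
  and a `mn_line_sd` parameter exposes the large-dispersion regime for
  users who want realistic discrimination behaviour instead of exact
  recovery.

Passing tests therefore demonstrate internal consistency of the analysis
chain under the published laws, not fidelity to every statistical property
of patient-derived cell lines.

## Clonogenic survival fitting

`fit_lq()` fits the linear-quadratic model `S = exp(-(alpha*D + beta*D^2))`
in log space, where it is linear in `(alpha, beta)`: an exact convex
problem, solved by the 2x2 normal equations with an active-set sweep for
the non-negativity constraints.  The 0 Gy point calibrates the plating
efficiency only and is excluded from the regression; the fit is unweighted.
Zero-colony plates at positive dose are dropped (no log-scale information).
Synthetic assays choose `(alpha, beta)` consistent with a target SF2 under
a configurable `beta/alpha` ratio (default 1/6 per Gy -- the published
work never reports the two parameters separately) and draw colonies as
Poisson counts with mean `seeded * PE * S(D)`.

## Law fitting and selection

`fit_law()` supports linear, proportional (through-origin), exponential,
power and quadratic laws ("curvilinear" is implemented as quadratic, the
usual reading when no definition is given).  Exponential and power fits
are genuine nonlinear least squares on the natural scale
(`minpack.lm::nlsLM`), initialised from the log-linearised regression, so
SSE and RMSE are comparable across laws.  Confidence bounds use
t-quantiles on the parameter covariance; adjusted r-squared is
`1 - (1 - r2)(n - 1)/(n - p - 1)`.  `select_best_law()` picks the lowest
RMSE (ties toward fewer parameters) and flags the link as "complex" when
even the best adjusted r-squared is below 0.70 -- chosen to sit just under
the weakest accepted published fit (0.74), and configurable.  SF2 enters
all fits in percent, matching the magnitude of the published
goodness-of-fit columns.  Fits use per-cell-line values, not per-grade
means (the published figures are ambiguous on this; per-line is the more
conservative choice and is applied consistently).

In `fit_endpoint_laws()` two genotype exclusions apply, mirroring how the
anchor phenotypes are treated: ATM-homozygous lines are excluded from the
SF2-H2AX law when their foci are scored as nil (the endpoint is then
uninformative for them although their survival is minimal), and the
LIG4-like line is excluded from the H2AX- and pATM-based laws (its normal
recognition and kinase activity with grade-5 survival make it a category
of its own; in a 200-line cohort a single such line is a high-leverage
off-law point).

## Discrimination and prediction

`one_way_anova()` is the classical between/within mean-square ratio
(`stats::aov` underneath; the test suite checks it against a hand-computed
oracle and the squared pooled t statistic, and verifies the type-I error
rate at the 5 % level under the null).  `grade_discrimination()` runs the
four mid-range comparisons {2,3,4}, {2,3}, {3,4}, {2,4}; per-grade means
are the ANOVA observations, and records missing an endpoint are dropped
per comparison.  Perfectly separated groups report the smallest
representable double rather than a literal zero p-value.  No multiple-
testing correction is applied, matching the published analysis.

`grade_from_sf2()` and `grade_from_patmmax()` invert the linear laws,
clamp the continuous grade to [0, 5], round half-up, and propagate the
fitted 95 % bounds into a grade interval.  When SF2- and pATM-based
predictions disagree, both are reported; no merging rule is imposed.
`classify_phenotype()` applies the four-category rule with the LIG4 test
first (early foci at or above 80 % of the induction rate and residual foci
above 30), then hyper-radiosensitivity (pATMmax below 1 focus or SF2 in
the grade-5 band), then radioresistant versus intermediate by the rounded
pATM-based grade.

## Reproducibility and problem sizes

Every stochastic entry point takes one integer master seed; cohort records
are generated from per-record child streams derived from it, so cohorts
are byte-reproducible and insensitive to the order of record generation.
The test suite works at the study scale it verifies: 200-line cohorts for
recovery and discrimination (five seeds for the recovery medians, since a
single ~29-line clonogenic subset determines the exponential decay with
about 5 % relative standard error), 100,000 draws for grade frequencies,
5,000 records per anchor group, and a few hundred Monte-Carlo replicates
for calibration checks -- sizes chosen to keep every assertion's
sampling error well inside its tolerance.

## Known limitations

* The generator's dispersion is measurement-scale; between-line biological
  heterogeneity is understated (see above), so synthetic p-values are far
  smaller than published ones and only orderings are meaningful -- and for
  micronuclei not even the ordering, by design.
* Grade-1 clinical scoring is acknowledged to be partly subjective; the
  generator nevertheless follows the linear law at grade 1.
* The LQ fit is unweighted; no feeder effects, colony-size distributions,
  or apoptotic-death pathways are modelled.
* The coefficient system is a compact description of inter-endpoint links,
  not an enzyme-kinetics model; no Michaelis-Menten reading is intended.
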