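# radiosens

Multi-endpoint modelling of individual radiosensitivity in R.

Some radiotherapy patients develop tissue overreactions, graded 0 (no
event) to 5 (death) on the CTCAE scale. Several cellular assays on skin
fibroblasts predict parts of this spectrum, and their readouts are
quantitatively linked:

- **SF2** — clonogenic surviving fraction at 2 Gy, from the
  linear-quadratic model S = exp(−(αD + βD²)); SF2(grade) = 61.55 − 11.72·grade (%)
- **MN24h** — residual micronuclei per 100 cells at 24 h;
  SF2 = 62.2·exp(−0.107·MN24h)
- **H2AX24h** — residual γH2AX foci per cell (unrepaired DSBs recognised
  by NHEJ); SF2 = 62.56·exp(−0.216·H2AX24h)
- **pATMmax** — maximal early pATM focus count (10 min or 1 h), the
  nuclear ATM kinase activity peak; pATMmax(grade) = 41.72 − 6.78·grade
  and SF2 = 1.422·pATMmax

These laws are solutions of a coupled first-order system with constants
k0–k4 fixed by the bounded endpoint values (e.g. k0 = ΔSF2/5,
k1 = ln(maxSF2/minSF2)/maxMN24h). The package provides:

- a seeded **synthetic cohort generator** emulating a 200-line fibroblast
  collection (grade frequencies 65/17/10/5/2.5/0.5 %, radioresistant and
  ATM/LIG4-mutant anchor phenotypes, stratified clonogenic subset),
- **LQ survival fitting** (exact non-negative least squares in log space),
- **law fitting and selection** (linear / proportional / exponential /
  power / quadratic, nonlinear LS on the natural scale, "complex"-link
  flagging),
- the **k0–k4 coefficient system** with closed-form predictions,
  numerical verification of the differential system, and a consistency
  audit,
- **one-way ANOVA discrimination** across grades and under the binary
  radioresistant (grades 0–2) / radiosensitive (grades 3–5) split,
- **grade prediction** by law inversion and four-category phenotype
  classification,
- an end-to-end **pipeline** (`run_pipeline()`, plus a thin CLI wrapper in
  `inst/cli/`).

## Worked example

```r
library(radiosens)

co <- simulate_cohort(200, seed = 42)
co
#> Radiosensitivity cohort: 200 cell lines
#>   CTCAE grades 0-5: 121/41/20/13/5/0
#>   SF2 measured on 28 lines
#>   generated with seed 42

fits <- fit_endpoint_laws(co)
fits$sf2_grade
#> linear fit: f(x) = a1*x + a2
#>   a1 = -12.0308  (95% CI -12.7046, -11.3571)
#>   a2 = 62.9141  (95% CI 61.3086, 64.5196)
#>   adj r^2 = 0.9796, SSE = 184.649, RMSE = 2.66494
```

The re-fitted slope and intercept recover the generating law
(−11.72, 61.55) within a few percent from the 28-line clonogenic subset;
every SF2 drop of one slope unit corresponds to one additional CTCAE
grade. Deriving the coefficient system from the fits:

```r
coefficients_from_fits(fits)
#> Coefficient set:
#>   SF2 in [2.76, 62.91]%, pATMmax in [7.536, 41.98] foci
#>   k0 = 12.03 %/grade, k1 = 0.1109 /MN, k2 = 0.2165 /focus,
#>   k3 = 6.889 foci/grade, k4 = 1.499 %/focus
```

k1 ≈ 0.11 says roughly one micronucleus in ten is a lethal event;
k2 ≈ 0.22 says about one unrepaired recognised DSB in five is. Grade
prediction and discrimination:

```r
rec <- co$records[co$records$ctcae_grade == 3, ][1, ]
grade_from_patmmax(patmmax(rec))
#> Predicted CTCAE grade 3.29 (rounded 3) from patmmax
classify_phenotype(rec)
#> [1] "intermediate"

b <- binary_discrimination(co, "patmmax")
sprintf("binary pATMmax: F = %.1f, p = %.3g", b$f, b$p)
#> "binary pATMmax: F = 248.4, p = 8.49e-37"
```

The full pipeline (cohort CSV, tabular fit report, coefficient and
discrimination JSON, per-record predictions, summary) is one call:

```r
run_pipeline(pipeline_config(seed = 1, cohort_size = 200,
                             output_dir = "radiosens-output"))
```

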