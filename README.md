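# kcurve

Age-dependent DLP-to-effective-dose conversion for pediatric brain CT.

## The problem

CT scanners report the dose-length product (DLP, mGy·cm), and the
effective dose (ED, mSv) — the risk-weighted quantity used for dose
management and risk communication — is usually estimated as

    ED = DLP × k

where *k* is a region- and age-specific conversion factor (mSv/mGy/cm).
The ICRP publishes pediatric brain-CT values of *k* only at 0, 1, 5 and
10 years (0.011, 0.0067, 0.0040 and 0.0032 mSv/mGy/cm), leaving the
conversion at every other age undefined. This matters in children:
automatic exposure control raises the DLP as the head grows while *k*
falls with age, so the two trends pull the ED in opposite directions.

`kcurve` implements and compares four practical ways to pick *k* at an
arbitrary age:

* **curve method** — fit the power law *y = a(x + b)^c* through the four
  ICRP anchors by unweighted nonlinear least squares and evaluate it at
  any age (the package's core);
* **linear method** — piecewise-linear interpolation between anchors,
  with extrapolation beyond 10 years from the 5- and 10-year values;
* **simple method** — the anchor of the nearest age (ties to the older
  anchor): 0 → 0 y, 1–2 → 1 y, 3–7 → 5 y, 8–14 → 10 y;
* **phantom-bin method** — the piecewise-constant ED/DLP ratio a
  Monte-Carlo dose-management system implies through its age-binned
  phantom selection (0–0.5, 0.5–2.5, 2.5–7.5, 7.5–12.5, 12.5–15 years).

Around the fit, the package provides batch conversion of dose-record
CSVs, per-age and per-age-group cohort summaries (median, mean, SD, CV)
for diagnostic-reference-level work, and a seeded synthetic cohort
generator so the whole pipeline is testable without patient data.
It is aimed at medical physicists and dose-survey analysts.

## Worked example

```r
library(kcurve)

fit <- fit_kcurve(brain_anchors())
fit
#> Power-law conversion-factor curve: y = a(x + b)^c
#>   a = 0.00745966, b = 0.346204, c = -0.366232
#>   fitted to 4 anchors (brain); residual SD 4.9e-05 mSv/mGy/cm
```

The fitted curve passes through the anchors to within 4e-05 mSv/mGy/cm
and decreases smoothly with age, with the annual decrease shrinking —
exactly the behaviour a conversion factor should have. Converting two
examinations (a 2.5-year-old with DLP 600 mGy·cm, a 5-month-old with
DLP 350 mGy·cm; ages are floored to integer years before the factor is
applied):

```r
rec <- data.frame(exam_id = c("e1", "e2"),
                  age_years = c(2.5, 0.4), dlp_mgycm = c(600, 350))
convert_records(rec, model = fit)
#>   exam_id age_years dlp_mgycm integer_age factor_curve ed_curve ...
#> 1      e1       2.5       600           2     0.005459    3.275
#> 2      e2       0.4       350           0     0.011001    3.850
```

For the 2.5-year-old the curve method gives 3.28 mSv while the simple
method gives 600 × 0.0067 = 4.02 mSv — a 23% over-estimate, because the
1-year factor is applied to a 2-year-old. The full method comparison at
integer ages comes from `factor_table(fit, bins = default_phantom_bins())`;
the relative factors (method / curve) show the simple method swinging
from 1.23 at 2 years to 0.83 at 3 years, and the linear method drifting
to 0.91 by 14 years.

A synthetic end-to-end run:

```r
cohort <- generate_cohort(cohort_config(seed = 5))   # 980 records
res <- run_summarize(cohort, scheme = "drl_group")
res$summary[res$summary$quantity == "dlp", c("label", "n", "median")]
#>   label   n   median
#>       0 150 309.7036
#>     1-4 350 343.5252
#>     5-9 270 416.0161
#>   10-14 210 473.5432
```

Median DLP rises with age group while the curve-method median ED falls —
the central qualitative finding this package reproduces.

A command-line front end covering fit/convert/summarize/simulate is
installed at `system.file("cli", "kcurve-cli.R", package = "kcurve")`.

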