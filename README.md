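# coda24

Compositional analysis of change in 24-hour movement behaviours.

## What this is for

Time-use epidemiologists ask how the composition of the day — sleep,
sedentary time (SED), light physical activity (LPA) and
moderate-to-vigorous physical activity (MVPA), together exhausting the
24 hours — shifts across a life transition such as retirement. Because
the four durations sum to a fixed total, they carry only relative
information and must be analysed on the simplex (compositional data
analysis), not as four independent outcomes. `coda24` provides the full
pipeline for a two-wave wrist-accelerometer study of this kind:

* **simplex mathematics** — closure, multiplicative zero replacement,
  perturbation and change compositions, compositional (geometric) means,
  sub-compositions, ternary coordinates with bootstrapped Mahalanobis
  confidence regions, and a log-contrast outlier screen;
* **balance coordinates** — the sequential binary partition
  (active {LPA, MVPA} vs passive {sleep, SED}; LPA vs MVPA; SED vs
  sleep) and its isometric log-ratio transform with exact inverse:
  for a split with $r$ positive and $s$ negative parts,
  $z = \sqrt{rs/(r+s)}\,\ln\big(g(\mathrm{pos})/g(\mathrm{neg})\big)$,
  with $g$ the geometric mean;
* **epoch processing** — non-wear detection (15-min blocks, 60-min
  window, SD < 13 mg or range < 50 mg on two of three axes), diary-guided
  sleep detection (arm-angle changes ≤ 5° for ≥ 5 min inside the logged
  bed window), ENMO intensity cut-points (30 and 100.6 mg),
  bedtime-to-bedtime day segmentation, the 10-h waking-wear valid-day
  rule and the ≥ 4-valid-days inclusion filter;
* **longitudinal models** — one linear mixed model per balance
  coordinate (`lme4`), time × gender × occupation fixed-effect levels,
  random intercept and time-slope per participant, Wald CIs;
* **synthetic data** — a seed-reproducible logistic-normal cohort
  generator anchored to published group means, and an epoch-stream
  generator that realizes any target day composition so the processing
  rules can be round-trip tested.

See `vignettes/movement-behavior-coda.Rmd` for the model, the
assumptions and every numerical default.

## Worked example

```r
library(coda24)

before <- c(sleep = 478, sed = 672, lpa = 239, mvpa = 50)  # minutes/day
after  <- c(sleep = 515, sed = 667, lpa = 217, mvpa = 42)

round(ilr_transform(before), 3)
#> active_vs_passive       lpa_vs_mvpa      sed_vs_sleep
#>            -1.646             1.106             0.241
round(perturb_diff(after, before), 4)
#>  sleep    sed    lpa   mvpa
#> 0.2822 0.2600 0.2378 0.2200
```

The balances say this person-day is strongly passive-dominated
(−1.646), has far more LPA than MVPA (+1.106) and slightly more SED
than sleep (+0.241). The change composition (a perturbation; equal
parts 0.25 would mean no change) shows sleep gaining at the expense of
LPA and, proportionally most of all, MVPA.

A small end-to-end run — simulate a 111-participant cohort (one fifth of
the published stratum sizes), plant six zero-MVPA days, impute, screen,
describe and model:

```r
cfg <- pipeline_config(seed = 1,
  cohort = list(n_per_stratum = c(62, 33, 11, 5), days_per_wave = 5),
  n_boot = 100)
res <- run_pipeline(cfg, out_dir = "coda24_demo")

res$log[c("n_simulated_participants", "n_zero_mvpa_days",
          "n_outliers_flagged", "n_included_participants")]
#> $n_simulated_participants  111
#> $n_zero_mvpa_days            6
#> $n_outliers_flagged          2
#> $n_included_participants   109

subset(res$describe$change, group %in% c("all", "women_manual"))
#>          group sleep sed  lpa mvpa
#> 1          all    32  19  -43   -9
#> 4 women_manual    55  76 -107  -24

attr(res$report, "fits")$z1_m1
#> fixed effects — coordinate 1 (active_vs_passive), model 1
#>        term estimate               ci      p
#>   intercept   -1.694 [-1.817, -1.571] <0.001
#>        time   -0.230 [-0.344, -0.116] <0.001
#>      gender   -0.125  [-0.389, 0.139]  0.355
#>  occupation    0.389   [0.193, 0.585] <0.001
```

The change block reads as minutes of a 1440-min day (sleep up, activity
down, most sharply among women retiring from manual work — the pattern
the default simulation encodes); the negative `time` coefficient says
the active-vs-passive balance fell after the transition. The output
directory holds the day compositions, group means/changes, ternary
confidence regions (JSON), the full 3 × 3 fixed-effects report and a run
log counting every exclusion.

A thin command-line wrapper with `simulate` / `process` / `describe` /
`model` / `run` verbs lives at `inst/cli/coda24.R`.

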