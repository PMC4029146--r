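# reirrad

Dose accumulation and outcome analysis for re-irradiation of recurrent
malignant glioma — and, more generally, for any paired-course CNS
radiotherapy cohort analysed from per-structure dose-volume histograms
(DVHs).

When a brain tumour recurs after a ~60 Gy primary course, selected patients
receive a second course (typically 36 Gy in 2 Gy fractions). The clinical
question is what the optic chiasm, brainstem, optic nerves and brain
accumulate across both courses when voxel-wise dose accumulation is
impossible (old plans, no co-registration, sometimes only printed DVHs).
`reirrad` implements the standard retrospective answer, aimed at radiation
oncologists and medical physicists doing plan-evaluation or pooled-cohort
work:

* **DVH handling** — cumulative ↔ differential conversion, resampling,
  a CSV dialect, and robust ingestion of digitised hardcopy curve points
  (sorting, clipping, running-minimum monotonicity repair).
* **Equivalent uniform dose** — for organs at risk the power-law
  gEUD = (Σᵢ vᵢ Dᵢᵏ)^(1/k) with k = 12 (serial structures: chiasm,
  brainstem, optic nerves) and k = 5 (brain); for tumour targets the
  log-cell-kill EUD = −(1/α)·ln(Σᵢ vᵢ e^(−α·Dᵢ)) with α = 0.4/Gy.
* **Cumulative dose with recovery** — per structure, the sum of the two
  per-course EUDs as a conservative upper bound, and a corrected sum
  r·EUD₁ + EUD₂ with recovery factor r = 0.5 modelling normal-tissue
  repair over the inter-treatment interval; cohort tables built
  patient-wise (median of sums) with row-wise handling of missing
  first-course data.
* **Equivalent-sphere geometry** — V = 4/3·π·r³ conversions and
  volume-based cohort dichotomisation.
* **Survival analysis** — Kaplan-Meier (median = smallest t with
  S(t) ≤ 0.5), two-group log-rank, univariate Cox with Efron ties,
  Mann-Whitney / paired Wilcoxon / Fisher's exact, and endpoint
  construction (post-recurrence survival, PFS, OS, inter-treatment
  interval at 30 days/month).
* **Synthetic cohort generator** — demographics, logistic-family DVHs,
  Weibull survival with a KPS effect and censoring, hardcopy-digitisation
  emulation; the fully seeded test substrate for the whole pipeline.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on DVHs and KM fits.

## Worked example

```r
library(reirrad)

# a structure receiving half its volume ~20 Gy and half ~60 Gy
dvh <- dvh_differential(dose_lo = c(0, 40), dose_hi = c(40, 80),
                        volume_fraction = c(0.5, 0.5))
dose_summary(dvh)
#> # A tibble: 1 x 4
#>   structure d_min d_mean d_max
#>   <chr>     <dbl>  <dbl> <dbl>
#> 1 structure  20.0     40  60.0
geud(dvh, k = 12)        # 56.63 Gy -- serial organ, hot spots dominate
survival_eud(dvh, 0.4)   # 21.73 Gy -- target, the cold half dominates

# conservative two-course accumulation with 50% recovery of course 1
cumulative_estimate(40, 10, recovery_r = 0.5)
#> # A tibble: 1 x 6
#>   metric course1_value course2_value sum_upper_bound corrected_sum recovery_r
#> 1 eud               40            10              50            30        0.5

# full synthetic run
run <- run_analysis(run_config(synthetic = cohort_config(n_patients = 58,
                                                         rng_seed = 1)))
glance(run$km_kps)       # KM median survival by KPS >= 70 vs < 70 (days)
run$dose_table           # per-course and cumulative dose table
run$volume_dichotomy     # group sizes and log-rank at the 2 cm (34 cc) cut
```

The gEUD value sits between mean (40 Gy) and maximum (60 Gy) dose as a
serial-organ summary should; the target EUD sits between minimum and mean,
pulled toward the under-dosed half. The corrected sum (30 Gy) counts only
half of the first course's 40 Gy as still biologically effective.

A thin CLI with `simulate` / `analyze` / `report` subcommands is installed
at `inst/cli/reirrad.R`.

## Documentation

The methods vignette (`vignettes/dose-accumulation.Rmd`) describes the
models, their assumptions, every tunable parameter with its default and
rationale, the synthetic generator's scope and limits, and the numerical
conventions (midpoint binning, ε-crossing min/max doses, half-up display
rounding).
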