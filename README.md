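# riceleafdyn

Diagnosing the nitrogen status of rice plants from the **dynamics** of
their leaves. Under nitrogen deficiency the youngest rice leaf expands more
slowly to a smaller final size, and the oldest leaf yellows (etiolates)
from the tip as nitrogen is remobilized — so the *rates of change* of leaf
shape and color, not single-time snapshots, carry the diagnostic signal.
`riceleafdyn` implements the full analysis for scanner images of single
leaves under four hydroponic ammonium-nitrate levels (N1 = 0, N2 = 57.20,
N3 = 85.70, N4 = 114.30 mg/L), scanned every 3 days from 20 to 44 days
after transplanting (DAT) at four leaf positions (the first incomplete
leaf FIL, and the 1st–3rd fully expanded leaves).

The package is written for plant-phenotyping researchers who want a tested,
fully reproducible version of this analysis — including a synthetic
scan generator with exact ground truth, because the original image archive
of such studies is rarely deposited.

## The analysis

For each leaf scan, shape and color characteristics are extracted:

- **shape**: leaf area `LA` (cm²), perimeter `LP` (cm, sub-pixel
  iso-contour length), and for the 3rd leaf the etiolated area `EA` and the
  etiolation degree `ED = EA / LA`;
- **color** (from the region mean RGB; whole blade for the FIL, distal
  third for expanded leaves): green mean `G`, chromatic coordinates
  `NRI = R/(R+G+B)` (NGI, NBI analogous), `ExR = 1.4·NRI − NGI`,
  `ExG = 2·NGI − NRI − NBI`, and the dark green color index
  `DGCI = [(Hue−60)/60 + (1−S) + (1−B)]/3`.

Blade expansion is compared across three growth laws — power `a·t^b`,
exponential `a·e^(bt)`, sigmoidal logistic `A/(1+e^(−k(t−t0)))` — by R² and
the least-squares AIC `n·ln(RSS/n) + 2p`. Dynamics are quantified per
plant and period as

    RGR = (ln W2 − ln W1)/(t2 − t1)   (shape)      ACR = (X2 − X1)/(t2 − t1)   (color)

over a 3-day scheme (P1…P7) and a 6-day scheme (P1′…P3′). One-way ANOVA
screens every characteristic × leaf position × period across the four
treatments (boundary F(3,30) = 2.92 at α = 0.05), and an RBF-kernel SVM
(libsvm via e1071) diagnoses the treatment class, evaluated by
resubstitution (training) and leave-one-out cross-validation for every
single period, every cumulative combination (P1P2, P1P2P3, …) and the
FIL + 3rd leaf combination.

## Worked example

```r
library(riceleafdyn)

# a synthetic two-season cohort: 4 N levels x 5 plants x 2 years,
# 9 scan days x 4 leaf positions, analytic ground-truth mode
cfg <- experiment_config(master_seed = 42)
ex  <- generate_experiment(cfg, render = FALSE)

# which growth law fits FIL expansion? (here: logistic, as for every level)
growth_fit_report(ex$features, "LA", "FIL")
#>          model     r2    aic selected      (N4 block)
#> 10       power 0.7674  34.90    FALSE
#> 11 exponential 0.6926  37.41    FALSE
#> 12    logistic 1.0000 -40.64     TRUE

# per-plant dynamics over the 3-day periods, screened by ANOVA
dyn3 <- dynamic_features(ex$features, build_interval_scheme(seq(20, 44, 3), 3))
sc   <- screen_features(dyn3)
head(sc[order(-sc$F), c("feature", "leaf_position", "period", "F", "p")], 5)
#>      feature leaf_position period        F            p
#> 195 ACR_DGCI           3rd     P6 173.2389 1.911185e-21
#> 186 ACR_DGCI           3rd     P5 159.6961 7.476087e-21
#> 185  ACR_NRI           3rd     P5 158.6500 8.343609e-21
#> 167  ACR_NRI           3rd     P3 146.7338 3.062318e-20
#> 168 ACR_DGCI           3rd     P3 146.6832 3.079921e-20

# diagnose the N level from the FIL's early-expansion dynamics
ds <- assemble_dataset(dyn3, c("P1", "P2", "P3"), "FIL")
loocv(ds)
#> <cv_result n=40 training 95.0% validation 70.0%>
```

The color-change rates of the 3rd (oldest) leaf separate the treatments
most strongly once etiolation is underway, while the FIL's expansion
dynamics already diagnose the nitrogen class at 70% leave-one-out accuracy
(chance = 25%) from the first nine days of scanning.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow — simulate, validate extraction against ground truth, fit growth
laws, build the dynamics tables, screen by ANOVA, evaluate the full
diagnosis grid, and verify end-to-end determinism — writing their tables
under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

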