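# protonInterplay

Simulation of the dosimetric interplay between intrafraction prostate motion
and layered proton dose delivery, comparing **double scattering (DS)** and
**uniform scanning (US)** techniques.

In DS delivery the range modulator wheel rotates continuously (600 RPM, one
energy sweep per 0.1 s), so the full spread-out Bragg peak (SOBP) covers the
target quasi-instantaneously; target motion can only blur the dose. In US
delivery the energy layers are delivered sequentially from the most distal
to the most proximal, with a 0.5 s beam-off gap between layers; a prostate
drifting during the fraction can move in or out of individual layers and
accumulate hot and cold spots. This package is for medical physicists and
methodologists who want a fully synthetic, reproducible test bed for that
interplay effect — no patient data, planning system, or DICOM input.

It provides:

* an analytic pristine Bragg peak and SOBP layer decomposition, with
  nonnegative-least-squares layer weights
  (`bragg_peak()`, `build_layer_set()`, `solve_layer_weights()`);
* separable per-layer and composed 3D dose grids for lateral fields
  (`build_field()`, ASCII NRRD persistence via `write_nrrd()`);
* a calibrated synthetic cohort of 10 Hz prostate displacement traces with
  drifts, transient excursions, persistent offsets and correlated SI/AP
  jitter (`generate_trace()`, `generate_cohort()`,
  `motion_components()`);
* per-second 4D dose accumulation of a rigidly moving CTV through the
  static (DS) or layer-indexed (US) dose matrices
  (`build_timeline()`, `accumulate_fraction()`, `simulate_course()`),
  implementing the accumulation
  `D_CTV(x0,y0,z0) = sum_t d_t(x,y,z) ∩ CTV(x0_t, y0_t, z0_t)`;
* DVH curves and the V100 / V95 / V110 / D100 / D95 / D5 metric panel with
  hot (V110 > 2%) and cold (D95 < 95%) flags
  (`compute_dvh()`, `dvh_metrics()`);
* cohort orchestration with paired DS-vs-US t-tests and Mean/STD/Max/Min
  summary tables at single-fraction and fraction-cumulative level
  (`simulate_interplay()`, `summary()`, `compare_techniques()`,
  `render_report()`).

## Worked example

Simulate the default study: 17 patients x 14 tracked fractions of 2 Gy at
2 Gy/min through a shared lateral plan (range 30.1 g/cm², modulation
8.4 g/cm² — 14 energy layers at 0.6 g/cm² spacing), every trace delivered
under both techniques:

```r
library(protonInterplay)
sim <- simulate_interplay(run_config(seed = 1))
summary(sim)                  # single-fraction level, 238 records/technique
summary(sim, "course")        # fraction-cumulative level, 17 records
plot(sim)                     # DVH overlay: static plan vs DS vs US courses
```

```
CTV DVH points, single fraction level (238 records per technique, 2.00 Gy/fraction):
         V100   V95 V110  D100   D95    D5
Mean DS  97.2  99.9  0.0  96.7 100.3 102.0
Mean US  89.7  99.8  0.0  96.3  99.7 102.8
STD DS    2.7   0.4  0.0   2.6   0.6   0.1
STD US   13.1   0.9  0.1   2.8   1.3   0.9
Max DS   99.7 100.0  0.0  99.7 100.8 102.3
Max US  100.0 100.0  1.4 100.4 101.5 107.1
Min DS   79.9  96.8  0.0  80.5  96.4 101.7
Min US   25.3  94.3  0.0  78.3  93.4 101.1
P value:
    V100      V95     V110     D100      D95       D5
3.51e-18 3.27e-04 1.58e-01 3.06e-05 6.48e-20 1.04e-25

CTV DVH points, course level (17 records per technique, 2.00 Gy/fraction):
        V100   V95 V110 D100   D95    D5
Mean DS 97.8 100.0    0 97.9 100.5 101.9
Mean US 97.8 100.0    0 97.9 100.5 102.0
STD DS   2.1   0.0    0  1.2   0.3   0.1
STD US   2.3   0.0    0  1.2   0.4   0.3
P value:
 V100   V95  V110  D100   D95    D5
0.978 0.332 1.000 0.425 0.838 0.158
```

Reading the tables: at the **single-fraction** level US shows the interplay
signature — wider spread (STD) in every metric, deeper cold minima
(Min D95 93.4 vs 96.4, Min V100 25.3 vs 79.9) and the only overdose
(Max V110 1.4 vs 0.0, rising to V110 of several percent on high-motion
cohorts) — while mean coverage stays similar for the two techniques.
At the **course** level fraction averaging washes most of this out: V110
returns to 0 for every patient, V95 to essentially 100, the DS and US means
coincide and no metric differs significantly any more. The SBRT variant
(`simulate_interplay(sbrt_config(run_config(seed = 1)))`) gives 85
single-fraction records of 7.25 Gy with a 224 s US delivery span
(217.5 s beam-on + 13 x 0.5 s switches).

The motion cohort itself can be inspected directly:

```r
mc <- motion_components(generate_cohort(seed = 1))
mc
#> Cohort intrafraction motion components (mm):
#>              lr   si   ap
#> systematic 0.26 0.50 0.50
#> random     0.63 1.26 1.71
#>   patients with >=10% of time beyond 3/5/7 mm: 12/2/0 of 17
```

against calibration targets of (0.3, 0.5, 0.6) mm systematic and
(0.7, 1.4, 1.9) mm random in (LR, SI, AP).

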