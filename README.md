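# nasoform

Nasal-bone morphometry from calibrated two-dimensional photogrammetry.

Rhinoplasty planning needs the dimensions and shape class of the nasal
bones, but the bone lies under skin and subcutaneous fat: measuring it
directly requires CT/MRI (ionizing radiation, cost) or dissection.
`nasoform` implements the surface-based alternative: landmarks are located
on standardized frontal, lateral and basilar photographs, converted to
millimetre measurements through an in-frame ruler, and used — together
with body covariates (age, sex, height, weight, BMI) — to predict the
hidden bone dimensions and morphology classes. It is aimed at
craniofacial anthropometry and facial-analysis researchers who need a
fully testable, self-contained reimplementation of that pipeline.

## What is inside

* **Landmark model** — a fixed catalog of 29 anthropometric points
  (9 midline: g, n, s, r, k, prn, sn, pg, gn; 10 bilateral pairs:
  en, ex, mf, al, mal, ac, zy, ch, po, or), per-view rosters and
  validation. Kyphion (k), the dorsal-hump apex, is optional.
* **Anthropometry** — Euclidean distances
  `d(w, u) = sqrt(sum_i (u_i - w_i)^2)`, interior angles at a vertex
  landmark (e.g. the nasofrontal angle g–n–prn), frontal symmetry
  ratios, and least-squares ruler calibration `mm/px = tick spacing /
  mean inter-tick pixel distance`.
* **Keypoint CNN** — a from-scratch 19-weight-layer convolutional
  network (16 conv 3x3 + 3 dense, 5 max-pool layers, sizes 3,5,3,5,3)
  mapping a 224x224x3 image to a 14x14x512 feature map, global average
  pooling, and sigmoid-bounded coordinate regression
  (`x_i, y_i` normalized to [0, 1], MSE loss, Adam, lr 0.001).
  Includes a loop-based reference convolution
  `F_ab = act(sum_ij w_ij x_{a+i, b+j} + bias)` and finite-difference
  gradient checking.
* **Morphology** — kyphion detection (maximum anterior deviation from
  the sellion–rhinion chord, threshold 0.5 mm), bone angles (NA, DPA,
  KA, RA), the lateral V/S rule (S iff a kyphion with angulation
  `|180 - KA| >= 4 deg` is present), the frontal A–E decision tree over
  the bone widths d3 (frontonasal), d4 (nasomaxillary), d5 (narrowest),
  and a back-propagation network (BPNN) with ReLU hidden layers and
  three heads (bone-dimension regression, 5-way frontal and 2-way
  lateral classification; update `W <- W - f * dE/dW`).
* **Metrics** — `MAE = mean |y - yhat|`, `R^2 = 1 - SS_res/SS_tot`,
  mean average precision over landmark categories (101-point
  interpolated PR area, fixed correctness radius), pooled means,
  Welch t and Kruskal–Wallis tests, percentage tables.
* **Synthetic data** — populations with the published group structure
  (sex-specific bone distances, BMI-dependent surface dimensions,
  frontal type frequencies 57.6/30.3/3.0/6.1/3.0%, kyphion prevalence
  24.2%) plus rendered three-view images with exact ground-truth
  landmarks and a calibration ruler, so every stage is testable offline.
* **CLI** — `inst/exec/nasoform` with subcommands `generate`,
  `measure`, `classify`, `train`, `detect`, `predict-bone`, `evaluate`,
  `report`.

## Worked example

```r
library(nasoform)

nrow(landmark_catalog())
#> [1] 29

pop <- sample_population(population_params(500, seed = 42))
summarize_classification(pop$frontal_type)
#>   label count fraction percent
#> 1     A   266    0.532    53.2
#> 2     B   164    0.328    32.8
#> 3     C     8    0.016     1.6
#> 4     D    40    0.080     8.0
#> 5     E    22    0.044     4.4

views <- render_subject_views(pop[1, ], render_config(), seed = 1)
mt <- measure_subject(lapply(views, `[[`, "landmarks"),
                      lapply(views, `[[`, "calibration"))
subset(mt, code %in% c("n-prn", "al-al", "g-n-prn"))
#>   subject_id    code      value   units     kind   provenance
#> 1     S00001   n-prn   4.158799      cm distance ground_truth
#> 5     S00001   al-al   3.630184      cm distance ground_truth
#> 8     S00001 g-n-prn 148.678404 degrees    angle ground_truth
pop$surf_n_prn[1]      # the generator's true dorsal length, recovered exactly
#> [1] 4.158799

cad <- cadaver_fixture()
summarize_classification(cad$subjects$lateral_shape)
#>   label count  fraction percent
#> 1     S     7 0.2121212    21.2
#> 2     V    26 0.7878788    78.8
pooled_mean(data.frame(n = c(18, 15), mean = c(23.79, 23.83)))  # N-R, mm
#> [1] 23.80818

fit <- train_bpnn(pop[1:400, ], bpnn_config(epochs = 150, seed = 1))
pred <- predict_bone_morphology(fit$model, pop[401:500, ])
r_squared(pop$bone_n_r[401:500], pred$bone_dims[, "bone_n_r"])
#> [1] 0.8629044
```

The measurement table reproduces the generator's surface dimensions
exactly (ground-truth landmarks, exact ruler scale); the V/S and A–E
percentages of the 33-cadaver reference fixture match the published
frequencies; and a BPNN trained on 400 subjects already explains ~86% of
the held-out variance in the bone length N–R (rising above 90% at the
2000-subject training size used in the acceptance suite).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline's headline quantities from scratch against the
installed package — the cadaver classification percentages, the pooled
bone-length and angle means, the 14x14x512 extractor shape, a
generate/measure round trip, and held-out BPNN bone recovery — logging
each to stderr and writing the acceptance JSON to `--out`.
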