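---
title: "Methods: nasal-bone morphometry from 2D photogrammetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nasal-bone morphometry from 2D photogrammetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models, conventions and numerical choices behind
`nasoform`, in the spirit of a methods section: what each stage assumes,
which parameters matter, what the synthetic generator does and does not
emulate, and where the design was genuinely open.

## 1. The measurement model

All geometry lives in image pixel coordinates: origin at the top-left,
x rightward, y downward, 0-based, sub-pixel positions allowed. Lateral
views obey an orientation contract — the subject faces +x, superior is
−y — shared by the renderer, the kyphion detector and every angle
formula. A lateral photograph shows only the camera-side (right) member
of each bilateral pair, so the lateral roster carries `po_R`/`or_R` but
not their left counterparts.

**Landmark roster.** The catalog closes "29 points including 10 pairs" as
9 midline points {g, n, s, r, k, prn, sn, pg, gn} and 10 pairs
{en, ex, mf, al, mal, ac, zy, ch, po, or}. The mid-alare pair (`mal`) is
required by the frontal mid-alar symmetry ratio; kyphion (`k`) is flagged
optional because a dorsal hump exists only in some subjects. Columella,
trichion and the lip points were left out: including them would break the
29-point closure, and the angle catalog was restricted to angles whose
operands are in the roster (nasofrontal, nasofacial, facial, nasomental,
middle/lower facial height, kyphion angle, and the four bone angles).

**Calibration.** A stainless ruler in frame fixes the scale. Ticks are fit
by least squares along their principal axis; `mm_per_px = tick spacing /
mean inter-tick pixel distance`. Fits with residual above 10% of a tick
spacing are rejected as non-collinear or irregular. Distances are
`pixel distance x mm_per_px`; angles are calibration-free (invariant under
translation, rotation and uniform scaling, which the tests verify).
Surface distances are reported in cm — the scale on which nasal surface
dimensions are conventionally tabulated — bone dimensions in mm.

## 2. The landmark network

The detector is a 19-weight-layer convolutional network implemented from
scratch (R orchestration over C++ im2col/pooling kernels; no deep-learning
framework exists in the target environment, and having our own
forward/backward passes is what makes oracle and gradient testing
possible). Architecture: five blocks of 3x3/stride-1 convolutions
(2,3,3,4,4 layers; 64,128,256,512,512 channels at full width) each
followed by max pooling with sizes 3,5,3,5,3. A stated stride of 1
everywhere cannot reduce 224 to 14, while the 14x14x512 feature map is
stated explicitly; the pools therefore use strides 2,2,2,2,1, treating the
feature-map shape as authoritative. Global average pooling feeds three
dense layers regressing two coordinates per landmark.

The output head is direct coordinate regression, sigmoid-bounded to
[0, 1] and trained with MSE — a softmax layer is not meaningful for
coordinates and is used only where it belongs, in the BPNN classification
heads. Images are normalized as `(pixel/255 − 0.5)/sigma` with `sigma`
the per-dataset pixel standard deviation (overridable). The reference
convolution is valid (unpadded): output side = input side − filter side + 1.

Training defaults mirror the published configuration (Adam, learning rate
0.001, 100 epochs, batch 100, validation split 0.2, dropout 0.25 after
each pooling stage). The test and acceptance suites use a width-scaled
network (`width_scale = 1/16`), 10 epochs, batch 10 and learning rate
0.01: at desk scale the binding constraint is optimizer steps per epoch,
not capacity, and these settings reach a ≥ 5x reduction of validation
landmark MAE below the untrained baseline within minutes on one CPU.

## 3. Morphology rules

**Kyphion.** The dorsal hump apex is the interior profile point of maximum
perpendicular deviation from the sellion–rhinion chord on the anterior
side; it is reported only when the deviation reaches `tau_k = 0.5` mm.
The rule is monotone: growing a hump never un-detects it.

**Lateral V/S.** A V-shaped dorsum runs straight from sellion to rhinion
(one angulation, at the dorsal profile angle); an S-shaped dorsum curves
through the kyphion, adding a second angulation. Classification: S iff a
kyphion is present *and* its angulation `|180 − KA| >= tau_a = 4 deg`.
The threshold encodes the one published kyphion-bearing V-shaped cadaver
as a sub-threshold hump rather than a measurement error — with the
default geometry any hump passing the 0.5 mm detection threshold also
passes 4 deg, so detection is the binding rule.

**Frontal A–E.** The published suture descriptions are qualitative; they
are operationalized as a fixed-order decision tree over
`w = d3/d4` (frontonasal width relative to the lower nasomaxillary
width), concavity `c = 1 − d5/min(d3, d4)`, and whether the
nasomaxillary border slope lies within ±10 deg of vertical:
E if `w >= 0.80`, not concave (`c < 0.15`) and vertical; D if wide and
concave; C if `w < 0.45` and not concave; B if concave; else A.
The thresholds are package defaults, fully exposed in
`frontal_type_thresholds()`, and were chosen once so that the five
generator templates are separable; they were not fit to data.

**Bone angles.** The nasion angle needs a superior profile continuation
above the nasion, whose construction is not standardized; the default is
one unit straight above `n`, overridable per profile. d3/d4/d5 follow the
naming "upper width (frontonasal suture), lower width (nasomaxillary
suture line), narrowest"; other orderings circulate and this one is fixed
as the package convention.

## 4. The BPNN

A fully connected trunk (ReLU, per-layer biases) with three heads:
linear regression of the six bone dimensions defined for every subject
(N–S, S–R, N–R, d3, d4, d5 — S–K and K–R exist only for hump carriers
and are excluded from the regression head), and softmax heads for the
frontal type and lateral shape. Loss: mean squared error plus the two
cross-entropies. Back-propagation is implemented in its standard form,
`W <- W − f * dE/dW`, with Adam as the default optimizer (matching the
reference training configuration) and plain SGD available. Features and
regression targets are z-scored on the training data; the scaling
constants ship inside the model. Defaults (hidden 128/64, lr 0.002, 400
epochs, a 0.2 lr step-down over the final 30%) are sized so the network
reaches the linear-Gaussian recovery ceiling below; the smaller trunk
first tried (32/16) plateaued around R² 0.985 on a task whose exact
solution is linear, a pure optimization shortfall.

## 5. The synthetic world

`sample_population()` states a world matching the published group
statistics:

* Bone distances: sex-specific Gaussians truncated at zero
  (N–S 5.56/5.89, S–K 14.54/14.08, K–R 4.61/4.52, S–R 18.85/18.22,
  N–R 23.79/23.83 mm for males/females; d4 17.08 ± 2.08 mm for both sexes —
  the reference study found no sex difference in bone widths).
* Surface dimensions (cm): normal-weight baselines with signed BMI
  slopes reproducing the direction of the published BMI contrasts,
  centred at the mixture-expected BMI so marginal means equal the
  configured means. Deviations are clamped at ±3.5 SD (symmetric, mean-
  preserving) so every subject fits the rendering frame.
* Profile angles: the per-sex "±" values printed next to the angle means
  are standard errors, not SDs — only `SE x sqrt(n)` reproduces the
  printed pooled SDs (9.54/5.73 pooling to 7.99 for the nasofrontal
  angle) — so the generator uses those as per-sex SDs.
* Frontal types: multinomial with probabilities 19/33, 10/33, 1/33,
  2/33, 1/33; each type draws (w, c, slope) from a template range with
  margins clear of the classifier thresholds, making the rule-based
  classifier exactly self-consistent with the labels. d3 and d5 are
  derived from d4 and the template, so their marginal moments are
  emergent rather than configured.
* Kyphion: prevalence 8/33; hump heights are log-normal with the
  sub-threshold (< 0.5 mm) mass fixed at 1/8, so S-shapes occur in 7 of
  8 hump carriers in expectation — the published 87.5%.

**Surface ↔ bone link.** Surface measures are linear-Gaussian in the
standardized bone dimensions: each measure carries a fixed share of its
variance from bone (0.85; 0.92 for the nasion–rhinion skin distance,
which loads solely on the bone length N–R as its direct skin
projection), the remainder being independent noise scaled by
`noise_scale` (0 gives a deterministic link). The loadings were chosen
*a priori* by computing the Bayes-optimal posterior R² of each bone
dimension given all nine measures — ~0.94 for N–R under the default
noise — so that parameter-recovery acceptance checks (R² ≥ 0.99
noiseless, ≥ 0.9 for N–R under noise) test the estimator against a
known ceiling rather than an accident of the draw.

**Renderer.** Landmark positions are an analytic placement of a
parametric face template: all catalog distances are honoured exactly,
as is the sampled nasofrontal angle (the glabella is otherwise
unconstrained). The nasomental angle of the drawn geometry is the value
implied by the n-prn / sn-prn / n-sn triangle, which cannot in general
equal an independently sampled angle; the record keeps the sampled value
for population statistics. When a sampled distance triple violates the
triangle inequality (≈ a few percent of subjects), sn-prn is minimally
raised and the repair is flagged in the view's `adjusted` field; tests
and acceptance checks skip flagged entries. The ruler is drawn with
ticks every 10 px and physical spacing `tick_px x mm_per_px` exactly,
so calibration consistency is exact by construction. The default scale
is 0.85 mm/px at 224 px (a whole face cannot fit a 224-px frame at a
finer scale). The skin kyphion is placed on the visible sellion–rhinion
skin chord; note the generated world keeps the published surface
nasion–rhinion distance (≈ 12.6 mm) distinct from the bone length N–R
(≈ 23.8 mm): the two are different printed quantities, so the skin `r`
marker is *not* drawn over the bone rhinion.

What the generator does **not** emulate: photorealistic appearance,
lighting, occlusion, head-pose error, soft-tissue thickness variation
(thickness figures enter only as the fixed 1 mm sellion offset), or
detector-style annotation noise. A green keypoint test therefore
establishes that the network can localize high-contrast schematic
landmarks — the learning mechanics — not photographic-grade accuracy;
the published accuracy tables for real faces depend on an unavailable
2000-image dataset and are out of scope.

## 6. Numerical choices and degenerate inputs

* Angles are interior, in degrees, range (0, 180]; coincident vertex
  points raise a geometry error. The middle/lower facial height angles,
  whose construction is otherwise unspecified, are defined as
  ∠(g, n, sn) and ∠(n, sn, gn).
* Report rounding is half-up at the printed precision (R's own
  `round()` is half-even); exact fractions are always retained.
* mAP: a detection is correct within a fixed radius (default 5 px,
  configurable) of the truth; matching is greedy by confidence, one
  match per truth; AP is the 101-point interpolated PR area; landmark
  codes are the categories. Categories without ground truth are skipped
  with a warning; uniform confidence rescaling cannot change the value.
* Welch t and Kruskal–Wallis delegate to R's `stats` implementations
  (the tests keep independent permutation and rank-formula oracles);
  degenerate samples (zero variance, all-identical values) raise typed
  errors rather than NaNs. No multiple-testing correction is applied,
  matching the reference analyses.
* Classification ties break toward the earlier class letter (A before
  B, V before S) via first-maximum argmax.
* The cadaver fixture resolves two internal inconsistencies of the
  printed tables: the male/female header counts (81/101) are only
  consistent with the pooled bone means if read as the cadaver counts
  18/15, and the lateral-shape sex counts (15+12) contradict the V=26
  marginal; the fixture uses the marginals, splits S as 4 male/3 female
  and assigns the single sub-threshold-hump V carrier to the male group.

## 7. Known limitations

* The CNN is CPU-bound R + C++; full-width, full-resolution training is
  out of desk-scale reach, which is why reduced-width training is the
  tested configuration.
* The lateral geometry is planar; out-of-plane rotation and projection
  effects are not modelled.
* Only the `nasoform19` backbone is implemented; comparison backbones
  (DenseNet, Inception, VGG, MobileNet, ConvNet) would need pretrained
  weights and are intentionally absent.
* The BPNN classification heads cannot beat the majority class for the
  lateral shape: hump height is simply not identifiable from the
  surface features the generator links, and the regression heads carry
  the scientifically recoverable signal.
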