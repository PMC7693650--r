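---
title: "Methods: synthetic 3D myocardial deformation analysis and neural-network classification"
author: "lvmda package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic 3D myocardial deformation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Three-dimensional myocardial deformation analysis (3D-MDA) converts dynamic
cardiac imaging into a time-resolved two-layer mesh of the left ventricle
(LV), from which standardized descriptors of wall architecture (thickness)
and deformation (strain amplitudes, timing, and rates) are extracted and
aggregated over the American Heart Association (AHA) segments. A
feed-forward neural network trained on these segmental features can then
discriminate hypertrophic cardiomyopathy (HCM) from mimicking hypertrophic
states: cardiac amyloidosis (CA), Anderson-Fabry disease (AFD) and
hypertensive cardiomyopathy (HTNcm).

Because clinical CMR-derived mesh cohorts are not publicly available, the
package pairs the analysis machinery with a synthetic dynamic LV phantom
whose deformation has analytic ground truth. Every downstream stage — strain
tensors, temporal metrics, AHA aggregation, classification — is therefore
testable against known values.

## The reference geometry

The LV is a truncated prolate-spheroid shell. The endocardial surface is an
ellipsoid of revolution with equatorial radius 25 mm, truncated at the base
plane; 10% of the apical pole is removed so no degenerate pole elements
arise. The default grid is 30 circumferential x 17 longitudinal nodes per
layer (510 nodes, matching the roughly 500-node layers used clinically), and
the two layers are joined by 480 transmural hexahedral elements. The long
axis points from apex to base (+z); the circumferential origin sits at the
anterior right-ventricular insertion with angle increasing counterclockwise
viewed from the base, which fixes a deterministic AHA sectoring (6/6/4
sectors over basal/mid/apical thirds). Because the truncated mesh has no
apical cap, 16 segments are the default for strain features; a 17th segment
(the most apical element ring) is available for thickness summaries only.

The wall thickness field defaults to 10 mm at the base and thins toward the
apex (a factor `1 - 0.35 s^2` along the normalized base-to-apex coordinate
`s`, recentred to the configured mean). The taper mirrors real ventricles
and also keeps the transmural offset below the apical curvature radius for
thick-walled subjects, which is what guarantees positive element Jacobians
across the cohort distributions.

## The motion model

The phantom is stretch-prescribed, not force-based: there are no fibers, no
pressures, and no material law. Per subject and cardiac phase the mid-wall
surface is deformed so that

- circumferential radii scale by `lambda_c(s, phi, t)`,
- meridian chords scale by `lambda_l(s, phi, t)`,
- both faces are offset along the deformed mid-surface normal by half the
  local wall thickness times the radial stretch `lambda_r`.

Under the (default) incompressibility option, `lambda_r` is prescribed per
element as the reciprocal of the element's in-plane stretch product, so the
deformation-gradient determinant measured by the strain engine equals one to
better than 1e-3 everywhere. Time dependence enters through a piecewise
raised-cosine activation `a(t)` with independent rise and decay
half-periods: `a(0) = 0`, a unique maximum `a(t_peak) = 1`, `a(1) = 0`, and
all stretch fields interpolate as `1 + (lambda_peak - 1) a(t)` over 30
phases of a 1000 ms cycle. At phase 0 (end-diastole) the displacements are
identically zero, which is the strain reference.

A geometric point worth stating explicitly: on a thick shell one cannot
independently prescribe the subendocardial in-plane stretches, the
subepicardial ones, and the transmural (radial) stretch — two surfaces give
only two degrees of freedom per station. The package prescribes the mid-wall
stretches and the radial offset exactly; the face strains *emerge* from
wall geometry, and they emerge with the clinically observed transmural
gradient (stronger subendocardial than subepicardial shortening) because
the endocardium sits at a smaller radius. User-facing amplitude parameters
are nevertheless subendocardial, matching how clinical tables are reported:
a damped per-node fixed-point calibration inverts the emergent map so the
recovered subendocardial amplitudes equal the configured values to well
within 0.1 strain-points. A `midwall` referencing mode bypasses the
calibration and is the natural way to target transmural radial amplitudes
via incompressibility.

Two safeguards keep extreme between-subject draws physical. First,
amplitude pairs are drawn jointly with the constraint that longitudinal
shortening may not exceed circumferential by more than 4 strain-points
(deeper violations are both clinically unobserved and geometrically
unrealizable near the truncated apex); second, the transmural offset is
capped by a discrete estimate of the deformed mid-surface curvature radius,
with the cap tightened automatically in the rare case an element Jacobian
still turns non-positive. Both mechanisms are inactive for typical
parameter values.

## Class phenotypes

The per-class generator defaults are calibrated to published global means
(and between-subject SDs) of the four hypertrophy etiologies:
subendocardial circumferential and longitudinal peak amplitudes, the
circumferential subendocardial time-to-peak fraction, and mean
end-diastolic wall thickness. HCM carries a basal-septal thickness bump
(Gaussian in angle and long-axis position, +5 mm, recentred so the global
mean stays at the drawn thickness); CA and HTNcm are concentric; CA
additionally has apical strain sparing, implemented as a linear apex-ward
amplitude factor (1.5 at the apex relative to the base, normalized to unit
mean so the global amplitude is unchanged). Segment-level heterogeneity is
multiplicative Gaussian jitter per AHA segment (SD 0.05 by default),
smoothed across segment borders because a discontinuous longitudinal
stretch field would integrate into jagged, potentially folded apex rings —
something no continuous myocardium does. Torsion is omitted: it adds no
testable target here, though the deformation map would accept it.

The segmental calibration itself is a package invention: the published
tables report only global distributions, so any segmental structure (bump
geometry, jitter scale, sparing slope) is chosen once as a plausible
clinical pattern and documented here, not fitted to data.

## The strain engine

Strain is Green-Lagrange based. Transmural quantities use the trilinear
hexahedral deformation gradient evaluated at the element centroid (single
quadrature point — the deformation is smooth at this resolution);
subendocardial and subepicardial quantities use 2D membrane tensors on the
endo/epi faces, where radial strain is undefined — hence the 11
direction-layer combinations: circumferential and longitudinal at three
layers, minimum principal at three layers, radial and maximum principal
transmural only. All reported strains are stretch-based engineering strains
`100 (sqrt(1 + 2 eta) - 1)` of material fibers (for directions, `eta = d' E
d`; for principal strains, the eigenvalues of `E`). This choice — rather
than raw tensor components — is what makes magnitudes like +40% radial
thickening and -27% minimum principal behave like length changes, matching
the scale of clinical reports; it is invariant to rigid motion by
construction.

Temporal metrics per element and combination: the signed peak-systolic
amplitude (minimum for shortening directions, maximum for radial/maximum
principal), time to peak as a percentage of the cycle (resolution one phase,
100/30 = 3.3%; no sub-frame interpolation), and peak systolic/diastolic
strain rates from central differences in %/s, split at the per-combination
peak phase with ties to the earliest phase. End-diastolic thickness is the
endo-to-epi face-centroid distance projected on the reference radial
direction. Global longitudinal shortening is the percent change of the
endocardial base-to-apex meridian arc length from end-diastole to its
minimum — the tables report such a summary without defining it, so this
construction is the package's own and is labelled as such.

## Features and classifier

Features are unweighted means over the elements of each AHA segment: 4
temporal metrics x 11 combinations + end-diastolic thickness, over 16
segments = 720 features per subject. (The original clinical description
mentions 917 features, a count not reproducible from any enumeration of its
stated taxonomy; the schema here is explicit, configurable, and serialized
alongside every feature table rather than silently patched.) The feature
container is a `SummarizedExperiment` (features x subjects) with the schema
in `rowData` and binary HCM labels in `colData`.

The classifier is the published architecture: two fully-connected hidden
layers of 30 and 5 tanh neurons, a single log-sigmoid output read as the
probability of HCM, cross-entropy loss, 100 epochs, decision threshold
strictly greater than 0.5 (an output of exactly 0.5 is non-HCM). The
original training algorithm, learning rate, initialization and
regularization are unpublished; the package fixes full-batch Adam
(learning rate 0.01, standard moments), uniform
`(-1/sqrt(fan-in), +1/sqrt(fan-in))` initialization with zero biases, and a
seed, so results are exactly reproducible even though they cannot replicate
an unstated original. Features are z-scored with training-set statistics
only (required to keep tanh units out of saturation, and asserted by test
to prevent leakage).

Evaluation is stratified 5-fold cross-validation: per-class round-robin
assignment after a seeded shuffle, so fold sizes differ by at most one per
class — with 85 HCM subjects each fold tests exactly 17. Stratification is a
deliberate choice (the smallest class has 18 subjects; unstratified folds
could go single-class). Per fold: standardize on the training portion,
train, score the held-out fifth; AUC is the mid-rank Mann-Whitney
statistic, which equals the trapezoidal area under the constructed ROC
curve; summaries are means with sample SD (n-1) over folds, and the median
ROC is the pointwise median of fold curves interpolated on a fixed
false-positive-rate grid. Single-marker baselines use the same AUC with the
orientation flipped when needed and a seeded class-stratified percentile
bootstrap (2000 resamples by default) for the confidence interval — the CI
method behind published marker tables is unstated, so this is fixed by
convention here.

## What passing tests do and do not show

The phantom emulates class-conditional amplitude/timing/architecture
patterns with analytic truth; it does not emulate image noise, tracking
failures, fibrous architecture, torsion, breathing artifacts, or the
correlation structure of real disease. Classifier performance on the
synthetic cohort (cross-validated AUC above 0.9, versus roughly 0.83 for
the best single thickness marker under the default phenotypes) demonstrates
that the protocol is implemented correctly and that the generator's class
separation is controllable — it is a property-level analog of the published
real-data result, not a reproduction of it. When all phenotypes are set
equal, the same protocol yields chance-level AUC, which is the
complementary control.

## Numerical choices and problem sizes

- Mid-wall calibration: damped fixed-point (step 0.05, tolerance 1e-9, max
  500 iterations), with the meridian feasibility projection described
  above. Residuals above 0.05 trigger a warning naming the cause.
- The smooth per-chord-to-node radial solve is a minimum-roughness
  least-squares system, precomputed once per geometry.
- Parameter draws use symmetric rejection windows (2.5 SD or the distance
  to the nearest physical bound, whichever is smaller) so configured means
  are never biased by truncation.
- Recovery runs in the tests and the acceptance script use 50 subjects per
  target; the classifier checks use the full 163-subject cohort
  (85/18/30/30). At the default resolution one subject costs well under a
  second to simulate and extract on one CPU.
- Seeds: every stochastic stage derives its seed from a single master seed
  and a stage/subject counter; identical configurations reproduce
  bit-identical manifests, feature tables and cross-validation results.

## Known limitations

- Subepicardial amplitudes are emergent, not prescribed; their ground truth
  is recorded from the construction's closed-form chord ratios, but they
  cannot be dialed independently of wall geometry.
- The printed radial transmural amplitude of real HCM cohorts is not
  consistent with pointwise incompressibility at the printed
  circumferential/longitudinal amplitudes on this shell; the default HCM
  phenotype keeps the subendocardial amplitudes at their printed values and
  lets radial follow incompressibility. The radial recovery target instead
  uses mid-wall referencing, where the incompressibility-implied radial
  amplitude is exact.
- Time-to-peak is quantized to one phase; cohort means inherit up to about
  half a phase of quantization error.
- The apical cap is absent by construction; apical-cap features are
  restricted to thickness.
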