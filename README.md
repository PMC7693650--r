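# lvmda

Synthetic 3D myocardial deformation analysis (3D-MDA) and neural-network
classification of left-ventricular hypertrophy etiologies, in R.

## The problem

Distinguishing hypertrophic cardiomyopathy (HCM) from its mimic states —
cardiac amyloidosis (CA), Anderson–Fabry disease (AFD) and hypertensive
cardiomyopathy (HTNcm) — is hard from single global markers: wall thickness,
ejection fraction or global strain each separate the classes only modestly.
3D-MDA converts dynamic cardiac imaging into a time-resolved two-layer
left-ventricular mesh from which *regional* architecture and deformation
features are extracted, and a small feed-forward neural network trained on
those features can discriminate HCM well.

Clinical mesh cohorts of this kind are not publicly available, so this
package provides the full analysis stack together with a synthetic dynamic
LV phantom with analytic ground truth:

- **`mesh_model`** — truncated prolate-spheroid two-layer LV mesh (510
  nodes/layer, 480 hexahedral elements), per-element local
  circumferential/longitudinal/radial frames, AHA 16/17-segment assignment,
  radial wall thickness.
- **`synthetic_cohort`** — class-conditional stretch-prescribed deformation
  over 30 cardiac phases with incompressible kinematics, calibrated to
  published global means of the four etiologies; seeded and fully
  reproducible.
- **`strain_engine`** — Green–Lagrange tensors from trilinear hexahedra and
  2D membrane faces; directional and principal strains per layer
  (stretch-based, in %); peak amplitude, time-to-peak (% of cycle), peak
  systolic/diastolic strain rates (%/s), end-diastolic thickness (mm).
- **`feature_builder`** — AHA-segmental means; 16 × (11 direction-layer
  combinations × 4 metrics + thickness) = 720 ordered features per subject,
  stored as a `SummarizedExperiment`; CSV round trip; cohort mean atlases
  and legacy-VTK export.
- **`classifier`** — the published architecture (30 and 5 tanh hidden
  neurons, log-sigmoid output, cross-entropy, 100 epochs, HCM iff output
  > 0.5) trained with full-batch Adam under stratified 5-fold
  cross-validation.
- **`evaluation`** — Mann–Whitney AUC, ROC curves with pointwise-median
  summary, confusion metrics, bootstrap single-marker baselines.

The strain of a fiber along unit direction `d` is
`100·(sqrt(1 + 2 dᵀE d) − 1)` with `E = (FᵀF − I)/2`; minimum/maximum
principal strains apply the same transform to the eigenvalues of `E`.

## Worked example

Simulate one noise-free HCM-like subject, extract strain, and compare with
the generator's analytic ground truth:

```r
library(lvmda)

ph <- classPhenotype("HCM", ampCirc = -0.178, ampLong = -0.152,
                     tPeak = 0.414, thickness = 11.3, segmentJitterSd = 0)
set.seed(1)
subj <- simulateSubject(ph)            # 30 phases, 1000 ms cycle
met  <- extractMetrics(subj)           # frames -> strain series -> metrics
g    <- globalSummary(met)
g[g$layer == "subendo", c("direction", "layer", "amp")]
#>   direction   layer       amp
#>        circ subendo -17.74908
#>        long subendo -15.15343
#>        minP subendo -17.74908
attr(g, "thickness")                   # mean ED wall thickness, mm
#> [1] 11.27778
longitudinalShortening(subjectDynamics(subj))
#> [1] -15.15846
```

The configured subendocardial circumferential amplitude (−17.8%) is
recovered to 0.05 strain-points; the residual is the one-phase sampling of
the activation peak. The subepicardial amplitudes come out smaller in
magnitude than the subendocardial ones — that transmural gradient is not a
parameter but emerges from wall geometry.

The full study-scale pipeline (163 subjects: 85 HCM, 18 CA, 30 AFD,
30 HTNcm) runs in about two minutes on one CPU:

```r
res <- runPipeline(pipelineConfig(seed = 11))
cvSummary(res$cv)
#>        metric      mean          sd
#> 1         auc 0.9984804 0.002082612
#> 2 sensitivity 0.9764706 0.032218974
#> 3 specificity 0.9866667 0.029814240
#> 4         ppv 0.9888889 0.024845200
#> 5         npv 0.9757353 0.033251233
#> 6    accuracy 0.9814394 0.016947848
round(res$baselines$globalEDThickness$auc, 3)  # best single-marker baseline
#> [1] 0.828
```

The network's cross-validated AUC clearly exceeds the global-thickness
threshold baseline, reproducing the qualitative ordering seen clinically
(regional ML model ≫ single markers) on a cohort whose class separation is
known by construction.

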