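# sliceomics

Slice-spacing-aware radiomics signatures for non-invasive prediction of
chromosomal 1p/19q co-deletion in lower-grade glioma (LGG).

## The problem

1p/19q co-deletion — combined loss of chromosome arms 1p and 19q — is a
diagnostic, prognostic and predictive biomarker in WHO grade II–III glioma,
normally determined by FISH on resected tissue (an arm is called "lost" when
its probe ratio falls below 0.75; the tumor is co-deleted when both arms are
lost). A radiomics signature predicts the status preoperatively from MRI:
quantitative shape, intensity-histogram and texture descriptors of the tumor
ROI feed a machine-learning classifier.

Clinical MR series differ widely in inter-slice spacing, and texture
matrices built from *adjacent voxels* are exactly the descriptors that
spacing perturbs. `sliceomics` implements the full experiment that isolates
this effect:

1. generate (or load) 3D volumes with ROI masks and labels;
2. create a **simulated-conventional (SC)** CE-T1 series from the thin-slice
   series by retaining one of every five 0.5 mm slices (bit-exact copies,
   2.5 mm inter-slice distance — no averaging, no blurring);
3. extract **107 radiomics features** per modality (14 shape, 18
   first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM), implemented
   from scratch with Rcpp kernels and verified against brute-force oracles;
4. build a **3D signature** (thin CE-T1 + T2 features) and an **SC
   signature** (SC CE-T1 + T2 features): training-SD scaling → LASSO
   (5-fold CV) → random forest (500 trees) with one importance-based
   feature-reduction pass;
5. evaluate accuracy/sensitivity/specificity/AUC, compare the paired ROC
   curves with the **DeLong test** (z = ΔAUC/√(v₁+v₂−2c), placement-value
   covariance), re-evaluate in IDH-mutant and WHO-grade subgroups;
6. map the regional contribution of image areas to individual features with
   **occlusion maps** (5×5 mask, stride 5) and compare thin vs SC maps.

No patient data ships with the package; a seedable synthetic cohort
generator (`generate_cohort`) supplies volumes whose co-deleted class has a
longer within-ROI spatial correlation length and more elongated ROIs —
echoing the clinically selected features (GLCM Correlation / IMC2, GLDM
Dependence Entropy, shape Major Axis Length).

## Worked example

```r
library(sliceomics)

ex <- run_experiment(experiment_config(cohort_config(seed = 3)))
ex
```

```
Slice-spacing radiomics experiment
 model    dataset  n accuracy sensitivity specificity   auc auc_lo auc_hi
    3D   training 78    1.000       1.000       1.000 1.000  1.000      1
    3D validation 18    0.944       0.833       1.000 0.986  0.948      1
    SC   training 78    1.000       1.000       1.000 1.000  1.000      1
    SC validation 18    0.778       0.500       0.917 0.764  0.493      1
DeLong 3D vs SC: training p = 1.000, validation p = 0.083
3D signature features: t1_3d_glcm_MCC, t1_3d_shape_Elongation, t1_3d_ngtdm_Complexity, ...
SC signature features: t1_sc_shape_Elongation, t1_sc_gldm_DependenceEntropy, ...
```

Reading this: each row reports one signature on one dataset — the 3D
signature (thin-slice CE-T1 + T2 features) classifies the 18 validation
cases with accuracy 0.944 and AUC 0.986 (95% DeLong CI 0.948–1, truncated
at 1), while the SC signature built from the thick-interval series reaches
accuracy 0.778 / AUC 0.764: the thin-versus-thick ordering the experiment
is designed to expose. The in-sample training rows are nearly separable for
a random forest, so validation rows carry the information. The DeLong p
quantifies the paired AUC difference on 18 cases (underpowered in a single
cohort, as its clinical counterpart was); the ordering is the stable
quantity — over 14 replicate cohorts the mean validation AUC is 0.927 (3D)
vs 0.809 (SC), with 3D ≥ SC in 85% of replicates. The selected features sit
in the planted signal families (correlation-structure texture and ROI
shape). Replicate the whole experiment over independent cohorts with
`replicate_experiment(cfg, 20)`.

Lower-level entry points: `extract_all(volume, mask)` for one 107-feature
vector, `downsample_to_sc()` / `downsample_mask()` for the slice-retention
simulator, `delong_test(labels, scores_a, scores_b)` for the ROC
comparison, `occlusion_map(volume, roi, "glcm_Correlation")` for feature
sensitivity maps, and `read_volume()` / `write_volume()` for NIfTI I/O.

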