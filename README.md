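# crsradiomics

CT-radiomics pipeline for predicting histopathologic response to
neoadjuvant chemotherapy (NACT) in high-grade serous ovarian carcinoma
(HGSOC). Response is graded on surgical omental specimens by the
three-tier chemotherapy response score and dichotomized into
non-complete (CRS1–2, label 0) and complete response (CRS3, label 1);
the package predicts this label *before* surgery from the pre-NACT CT
appearance of segmented omental tumor deposits.

The package is aimed at imaging researchers who want a fully inspectable,
leakage-safe reference implementation of this class of radiomics
workflow, together with synthetic data generators that make every stage
testable without access to patient data.

## What it computes

**Feature extraction.** From a CT volume (Hounsfield units) plus a binary
lesion mask: 107 three-dimensional radiomic features in seven classes —
shape (14), first-order (18), GLCM (24), GLRLM (16), GLSZM (16),
GLDM (14), NGTDM (5). Intensity and texture features are computed after
resegmentation to [−100, 400] HU and Freedman–Diaconis gray-level
quantization (bin width `2·IQR·n^(−1/3)`), at the original voxel sizes;
shape features come from the original mask (iso-surface mesh, covariance
principal axes, in-plane maximum diameters). HU-threshold
sub-segmentation splits lesions into hypodense / soft-tissue /
hyperdense components, and volumetry reports lesion volume and
percentage change between time points.

**Modeling.** Elastic Net logistic regression
(`mean deviance + λ(α‖β‖₁ + (1−α)‖β‖₂²/2)`, α = 0.5 by default) inside a
nested 5 × 5 cross-validation repeated over 100 random permutations of
the discovery cohort (500 model instances). A supervised redundancy
filter (drop the lower-AUC member of any feature pair with Spearman
|ρ| ≥ 0.90) and z-score standardization are embedded in the inner loop so
outer-test rows never influence any fitted quantity; λ minimizes the
inner-validation deviance and the decision threshold maximizes the
inner-validation G-mean.

**Signature.** Features are ranked by occurrence — the number of model
instances in which their coefficient is non-zero — and those selected in
more than 60% of instances (plus whole-tumor volume, forced in for
clinical recognition) form a compact interpretable signature, refitted
with identical data partitions and summarized by averaged coefficients.

**Evaluation.** External cohorts are scored by a majority-voting ensemble
of the five outer-fold models (each with its own standardization and
threshold). Metrics: AUC, accuracy, sensitivity, specificity,
G-mean = √(sensitivity·specificity), PPV and NPV, with Wilcoxon
signed-rank / rank-sum comparisons and Bonferroni–Holm adjustment.

**Synthetic data.** Lesion phantoms (ellipsoids with spatially correlated
HU texture plus hypodense/hyperdense inclusions) and feature-table
cohorts (informative features with known log-odds effects, redundant
rank-correlated copies, independent noise, intercept solved to hit a
target prevalence) emulate the study conditions: a discovery cohort of
61 patients at 41% prevalence and an external cohort of 48 at 21%.

## Worked example

```r
library(crsradiomics)

# a lesion phantom and its six-term signature
ph  <- generate_lesion_phantom(phantom_spec(seed = 7))
round(compute_signature(ph$volume, ph$mask), 3)
#> shape_Maximum2DDiameterColumn         shape_LeastAxisLength
#>                        36.878                        21.509
#>              shape_Elongation                     glcm_Idmn
#>                         0.779                         0.996
#>        glcm_DifferenceEntropy                    volume_cm3
#>                         2.783                        12.756
```

The lesion is moderately elongated (elongation 0.779), 12.8 cm³, with a
maximum coronal-plane diameter of 36.9 mm; its texture is locally
homogeneous (IDMN 0.996) with a difference entropy of 2.78 bits.

```r
# end-to-end on simulated cohorts (10 repetitions for a quick demo)
cfg <- pipeline_config(base_seed = 20220616,
                       cv = list(k_outer = 5, k_inner = 5, n_repetitions = 10))
res <- run_pipeline(cfg)
res$signature
#> <signature_report> 9 features selected from 50 model instances
#>     feature count  mean_coef sign
#>    noise_23    49  0.4765939    +
#>      inf_05    48  0.5111667    +
#>    noise_20    48 -0.5109767    -
#>   inf_03_r1    47  0.8832766    +
#>    noise_05    47 -0.4136073    -
#>    noise_15    40  0.4137405    +
#>   inf_02_r1    35  0.8394932    +
#>    noise_26    32  0.1980166    +
#>  volume_cm3    23  0.3705320    +
```

At n = 61 the stability selection recovers planted signals (`inf_*`
columns, sometimes represented by a redundant copy such as `inf_03_r1`)
but also admits noise features — an honest picture of what occurrence
counts can and cannot do at this sample size; recovery becomes reliable
at n = 200 (see the methods vignette). On the simulated external cohort
the ensemble outperformed the volume-only baseline in this run
(AUC 0.826 vs 0.655, G-mean 0.734 vs 0.667, NPV 0.931 vs 0.897).

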