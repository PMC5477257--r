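# GLCMSurv

Grey-level co-occurrence matrix (GLCM) texture analysis of CT regions of
interest, and the survival statistics to ask whether texture is a
prognostic imaging biomarker.

## The problem

Tumors — pancreatic ductal adenocarcinoma in particular — are spatially
heterogeneous, and that heterogeneity is visible as *texture* in routine
contrast-enhanced CT. Radiomics workflows quantify it: a radiologist
contours the tumor (and a reference region of normal tissue) on each
slice, and second-order statistics of the grey-level co-occurrence matrix
summarize how often pairs of intensity levels sit next to each other
inside the contour. The clinical question is whether those numbers,
measured once on a pre-operative scan, are associated with overall
survival after resection.

GLCMSurv implements this measurement chain and its statistical evaluation
as a tested, reusable R package, for imaging researchers who have CT
volumes (NIfTI), aligned binary ROI masks and a survival table — or who
want to validate the methodology on fully synthetic phantom cohorts.

## The model

For an ROI on a CT volume in Hounsfield units (HU):

1. keep in-mask voxels with HU in `[-10, 500]` (fat and stent exclusion;
   bounds inclusive);
2. take the axial slice with the largest filtered cross-section;
3. quantize HU to `G = 64` equal-width levels over `[-10, 500]`;
4. count co-occurrences `P_ij` of levels *i, j* over pixel pairs at
   offset δ = 1 along the four in-plane orientations, both pixels
   in-mask; symmetrize and normalize: `C_ij = P_ij / Σ P_ij`;
5. compute (sums over all level pairs):

   | feature | definition |
   |---|---|
   | uniformity | Σ C_ij² |
   | entropy | Σ C_ij log C_ij (natural log; non-positive as defined) |
   | dissimilarity | Σ C_ij \|i − j\| |
   | correlation | Σ (i − μx)(j − μy) C_ij / (σx σy) |
   | inverse difference normalized | Σ C_ij / (1 + \|i − j\|²/G²) |

   plus the mean in-mask HU and the cross-sectional area (mm²).

The statistical layer compares tumor vs normal tissue per feature
(Mann–Whitney), tests the association of each tumor feature with overall
survival (univariate Cox regression, Wald test, Breslow ties), evaluates
prognostic value (rank AUC with Youden threshold and Hanley–McNeil 95%
CI, outcome = survival ≥ cohort median), and draws median-split
Kaplan–Meier curves with log-rank tests. Subjects who died within
3 months of surgery are excluded before analysis.

## Worked example

No patient data ships with the package; the built-in phantom generator
produces CT-like volumes with controllable texture and linked survival.

```r
library(GLCMSurv)

## one phantom: darker textured tumor, brighter normal gland
ph <- generatePhantom(phantomSpec(seed = 42))
extractFeatures(ph$volume, ph$tumorMask)
#>   slice_index n_pixels size_mm2 mean_intensity uniformity entropy dissimilarity
#> 1           3      484    189.1          57.33    0.03896  -3.525         1.104
#>   correlation    idn
#> 1      0.5774 0.9995
```

The tumor's largest cross-section is slice 3 (484 pixels, 189 mm²); its
mean intensity sits near the configured 57 HU, entropy is negative by
construction, and dissimilarity ≈ 1.1 levels is the mean grey-level jump
between adjacent pixels.

```r
## a 30-subject cohort whose hazard rises 0.8 log-units per SD of
## tumor dissimilarity, written as NIfTI + CSV and analyzed end-to-end
dir <- tempfile()
co  <- generateCohort(phantomSpec(), cohortSpec(n = 30, seed = 42),
                      writeDir = dir)
res <- runPipeline(pipelineConfig(co$manifest, co$survivalFile,
                                  file.path(dir, "report")))

res$table4   # Cox regression: B / SE / Wald / p per tumor covariate
#>          feature n_missing         b       se     wald  p_value
#> 1     uniformity         0 -2.39e+01 8.67e+00  7.58412 0.005888
#> 2        entropy         0 -1.78e+00 5.66e-01  9.88791 0.001664
#> 3  dissimilarity         0  3.36e+00 1.04e+00 10.34278 0.001300
#> 4    correlation         0  2.37e+01 6.66e+00 12.63612 0.000378
#> 5            idn         0 -4.31e+03 1.28e+03 11.40479 0.000733
#> 6       size_mm2         0  4.70e-04 4.44e-03  0.01119 0.915769
#> 7 mean_intensity         0 -1.49e-02 2.20e-01  0.00457 0.946094
```

The planted texture–survival effect surfaces where it should: the driven
feature (dissimilarity) and the features correlated with it carry large
Wald statistics, while tumor size and mean intensity — which the
generator leaves independent of the hazard — do not. The ROC report tells
the same story:

```r
res$table5[res$table5$feature == "dissimilarity", ]
#>         feature sensitivity specificity   auc threshold ci_lower ci_upper
#> 3 dissimilarity       0.714       0.714 0.755     0.938    0.573    0.937
#>   direction p_value
#> 3        <=  0.0229
```

AUC 0.755 for predicting longer-than-median survival, with the Youden
threshold at 0.938 (lower dissimilarity → longer survival here, because
the planted effect is harmful: `direction` is `<=`). The output
directory also receives `features.csv`, the three report tables,
Kaplan–Meier and histogram figures for significant features, and a run
log of exclusions.

A thin command-line wrapper is installed at
`system.file("scripts", "ctpipeline.R", package = "GLCMSurv")`
(`simulate` and `run` verbs) for shell use.

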