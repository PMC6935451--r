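# thermoseg

Segmentation and classification of breast thermograms in R.

Frontal-view thermograms encode skin temperature as pseudo-colour, and
breast disease shows up as a localized hot region and as *bilateral
asymmetry* between the two breasts.  `thermoseg` implements the full
analysis chain for such images, for researchers in medical image
analysis who want a reproducible, fully testable desk-scale pipeline:

* **Curvature-based initialization** — the body silhouette is thresholded
  (0.25 after a 3×3 Gaussian denoise) and the signed curvature function
  `k = (x''y' − x'y'') / (x'² + y'²)^{3/2}` along the left/right margins
  locates the breast/chest-wall junction corners; a direct least-squares
  ellipse fitted to the arc between them, contracted radially, is the
  initial contour.
* **GVF snake segmentation** — a Gradient Vector Flow field
  (minimizing `∬ μ(|∇u|²+|∇v|²) + |∇f|²|(u,v)−∇f|²` over the edge map
  `f = w_l·I_s + w_e·|∇I_s|² + w_t·E_term`) drives a closed active
  contour with elasticity α = 0.20, rigidity β = 0.20, step γ = 1.00,
  force scale κ = 0.1, weights w_l = 0.01, w_e = 0.40, w_t = 0.01, up to
  5000 iterations with early stop.
* **155-dimension feature vector** — per breast: area, perimeter,
  roundness `R = 4πA/P²`, compactness `C = A/P²`; mean, median,
  variance, SD and entropy per colour channel; GLCM contrast,
  correlation, energy and homogeneity per channel; plus, for each of the
  31 left/right base pairs, the asymmetry distances `ED = √((V_r−V_l)²)`,
  `BD = √(|V_r·V_l|)`, `D = |V_r−V_l|` (8 + 30 + 24 + 93 = 155).
* **Classification under 2-fold cross-validation** — a small
  configurable convolutional network on the segmented image, and random
  forest / multilayer perceptron / naive Bayes on the feature vector,
  scored with TPR, PPV, FDR, F1/HM, SPC, NPV, ACC, FPR and rank AUC.
* **Segmentation agreement** — Zijdenbos Similarity Index
  `ZSI = 2|A₁∩A₂|/(|A₁|+|A₂|)` (the Dice coefficient; > 0.75 is
  conventionally excellent agreement).
* **Synthetic phantoms** — a seeded generator renders torso + breast
  temperature fields (with optional hot spots) through an invertible
  blue→green→red palette, with exact ground-truth masks, so the whole
  pipeline is testable with no image downloads.

## Worked example

```r
library(thermoseg)

# an abnormal phantom: hot spot in one breast
ph <- render_phantom(phantom_spec(seed = 42, hotspot = TRUE))
seg <- segment_breasts(ph)       # silhouette -> curvature -> ellipse -> snake
seg
#> <thermo_segmentation> 120x160 image; snake iterations L=100* R=100*
#>   left mask: 1862 px, right mask: 1888 px  (* = converged)

zsi(seg$left_mask, ph$left_mask)   # agreement with ground truth
#> [1] 0.9433357

fv <- extract_features(ph$image, seg$left_mask, seg$right_mask)
fv[, c("mu_R_left", "mu_R_right", "rel_D_mu_R")]
#> # A tibble: 1 × 3
#>   mu_R_left mu_R_right rel_D_mu_R
#>       <dbl>      <dbl>      <dbl>
#> 1    0.0156          0     0.0156
```

The hot spot leaves a red-channel trace only in the affected breast:
its in-mask red mean is 0.0156 against exactly 0 on the healthy side,
and the asymmetry feature `rel_D_mu_R` carries that difference.  On a
20-phantom dataset the classifiers separate the classes:

```r
ds <- make_dataset(10, 10, seed = 7)          # 10 normal + 10 abnormal
fx <- dataset_features(ds, masks = "segmented")
cv <- cross_validate(fx, classifier_spec("forest", seed = 1), seed = 2)
cv
#> <thermo_cv> forest, 20 samples, 2-fold (seed 2)
#> <confusion_matrix> TP=10 FP=0 TN=10 FN=0 (P=10, N=10)
#>  TPR PPV FDR F1 HM SPC NPV ACC FPR AUC
#>    1   1   0  1  1   1   1   1   0   1
```

Every sample is tested exactly once (train on one half, test on the
other, then switch); here the pooled confusion matrix is perfect, so all
indicators are 1 (error rates 0).  `tidy(cv)` gives per-fold rows and
`glance(cv)` a one-row summary; `autoplot(seg, ph$image)` and
`autoplot(cv)` draw the contour overlay and the indicator bars.

A thin command-line front end over the same functions lives in
`inst/scripts/thermoseg.R` (subcommands `simulate`, `segment`,
`features`, `classify`).

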