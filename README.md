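# mgmf

Multiscale Gaussian matched filtering with neural-network fusion for the
segmentation of vessel-like structures in X-ray coronary angiograms.

Coronary arteries appear in angiograms as dark tubes of varying caliber on
an unevenly illuminated, noisy background. `mgmf` implements the two-stage
approach used throughout the vessel-detection literature:

1. **Detection.** An oriented Gaussian matched-filter bank — templates
   $G(x,y) = -\exp(-x^2/2\sigma^2)$ of length $L$, width $T$, rotated to
   $\kappa$ orientations, zero-sum normalized — is applied at several
   scales $\sigma$. A small feed-forward network (default 11–3–8–1,
   logistic activations) fuses each pixel's per-scale responses into a
   vessel score in $(0,1)$.
2. **Segmentation.** The score map is binarized by one of ten classical
   thresholding methods (Otsu's between-class variance by default; also
   Ridler–Calvard, Kapur and Pal entropies, Tsai moments, histogram
   concavity, RATS, Niblack, Sauvola, White–Rohrer).

Detections are evaluated by the area under the ROC curve ($A_z$, trapezoidal
sweep) and masks by pixel accuracy. Because clinical angiogram sets with
expert outlines are rarely shareable, the package includes a synthetic
angiogram phantom generator with pixel-exact ground truth, and an
experiment driver that reproduces the whole protocol (split, train, detect,
threshold, evaluate) deterministically from one seed.

## Worked example

Generate a small phantom dataset, run the full experiment with a 3-scale
filter bank, and inspect the report:

```r
library(mgmf)

dir <- file.path(tempdir(), "phantoms")
generate_dataset(8, phantom_config(size = 128, n_vessels = 3, seed = 11), dir)

cfg <- pipeline_config(
  sigmas = c(1.5, 2.0, 2.5),
  training = training_config(epochs = 80, seed = 5, max_samples = 20000L)
)
report <- run_experiment(dir, cfg)

cat(sprintf("train A_z: %.4f\n", report$detection$train_az_pooled))
cat(sprintf("test  A_z: %.4f\n", report$detection$test_az_pooled))
print(report$single_scale, digits = 4)
head(report$threshold_accuracy[order(-report$threshold_accuracy$mean), 1:2], 4)
```

```
train A_z: 0.9866
test  A_z: 0.9807
  sigma test_az_pooled
1   1.5         0.9789
2   2.0         0.9801
3   2.5         0.9809
          method      mean
6      concavity 0.9632874
2 ridler_calvard 0.9577789
1           otsu 0.9577026
5        moments 0.9551392
```

The fused test $A_z$ (0.9807) meets the best single scale (0.9809 at
$\sigma = 2.5$) on this small run and exceeds every scale on the pooled
training half; the thresholding table ranks the ten binarizers by mean
per-image accuracy on the test responses. Larger studies (the default
`mgmf` preset with 11 scales on 300 px phantoms) show the fusion
consistently at or above the best single scale.

Individual stages are exported too: `gmf_response()` /
`multiscale_response()` for filtering, `train_network()` /
`predict_image()` for fusion, `segment()` for thresholding, `roc()` /
`auc()` / `accuracy()` for evaluation, `gmf_preset()` for the published
parameterizations. A thin command-line front end with `simulate`,
`detect`, `train`, `search`, `segment`, `evaluate` and `experiment`
subcommands ships at `system.file("cli", "mgmf.R", package = "mgmf")`.

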