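# fedhybrid

Federated hybrid spatial-geometric learning for benign/malignant
classification of multi-center breast-ultrasound-like images, implemented
end to end in base R.

Hospitals hold ultrasound archives that differ sharply in scanner quality
and case mix, and privacy usually forbids pooling the raw images. This
package simulates that setting and trains a classifier across centers
without moving any image:

* **Simulation** — seeded grayscale phantoms with one bright-rim lesion per
  image: benign lesions are smooth ellipses, malignant ones have irregular
  spiculated boundaries. Three centers are generated with sample sizes
  proportional to 437/210, 109/54 and 96/104 (benign/malignant) and
  progressively worse quality (speckle noise up, lesion contrast down).
* **Preprocessing** — resize to the network input size, stratified
  floor-rounded 60/20/20 split, and tenfold training-set augmentation
  (flips, small rotations and shifts, additive noise; a 437/210 cohort
  yields 389 training sources and 3890 augmented images).
* **Image-to-graph** — deterministic SLIC superpixels (about 120 segments),
  one node per segment (mean intensity + normalized centroid), exact
  k-nearest-neighbour edges (k = 16, so 120 nodes give 1920 directed edges)
  carrying the centroid distance as an edge attribute.
* **Model** — a two-branch network: a pre-activation residual CNN over the
  image and an edge-aware graph isomorphism network over the superpixel
  graph, fused by an MLP. All layers, including convolution and
  backpropagation, are hand-written in R on top of BLAS matrix products.
* **Federated training** — simulated federated averaging (size-weighted
  parameter means; a single client reproduces centralized training bit for
  bit) with a composite loss: cross entropy plus two hinge-embedding
  contrastive terms on the fused features, pushing away from the previous
  round's local model and pulling toward the current global model. Each
  center then fine-tunes its own copy, followed by batch-norm re-estimation
  on its training split.
* **Evaluation** — sensitivity, specificity, balanced accuracy, F1,
  trapezoidal ROC area (exactly the Mann-Whitney statistic), stepwise PR
  area, and decision-curve analysis with treat-all/treat-none references.

## Worked example

```r
library(fedhybrid)

centers <- generate_three_centers(seed = 1, scale = 0.15)  # 98 / 24 / 30 images
fit <- fedhybrid(centers,
                 net_config = hybrid_config(image_depth = 20),
                 config = fed_config(seed = 1),
                 augment = augment_params(copies = 2))
summary(fit)
```

Output of this exact run (about 2.5 minutes on one CPU):

```
Federated hybrid spatial-geometric classifier
  image branch: pre-activation ResNet, depth 20 (3 blocks/stage), feature 32
  graph branch: 4 edge-aware GIN blocks, width 32, mean pooling
  federated: 3 rounds x 2 local epochs over 3 centers, fine-tuned per center
  pooled test balanced accuracy: 0.894 (n = 28)

Per-center data sizes (train is post-augmentation):
        train val test
centerA   120  19   19
centerB    32   4    4
centerC    40   5    5

Per-center test metrics:
  centerA: bal.acc 1.000  sens 1.000  spec 1.000  F1 1.000  AUC-ROC 1.000  AUC-PR 1.000
  centerB: bal.acc 1.000  sens 1.000  spec 1.000  F1 1.000  AUC-ROC 1.000  AUC-PR 1.000
  centerC: bal.acc 0.333  sens 0.667  spec 0.000  F1 0.571  AUC-ROC 0.500  AUC-PR 0.756
```

Center C is the deliberately hardest center (speckle sigma 0.30, lesion
contrast 0.25) and has only five test images; the pooled balanced accuracy
is the headline number. `plot(fit$eval$pooled)` draws the ROC, PR and
decision-curve panels, and `predict(fit, new_samples, center = "centerA")`
scores new images with a center's fine-tuned model.

## Command-line workbench

A file-based pipeline (PNG / CSV / JSON / GraphML only) mirrors the
in-memory API:

```sh
Rscript -e 'fedhybrid::run_cli(commandArgs(TRUE))' simulate --config run.yaml
Rscript -e 'fedhybrid::run_cli(commandArgs(TRUE))' prepare  --config run.yaml
Rscript -e 'fedhybrid::run_cli(commandArgs(TRUE))' train    --mode federated
Rscript -e 'fedhybrid::run_cli(commandArgs(TRUE))' evaluate --subset test
```

Any configuration key can be overridden with dotted `key=value` arguments,
e.g. `fed.communication_rounds=5 phantoms.scale=0.2`.

## Testing

```r
testthat::test_dir("tests/testthat", package = "fedhybrid",
                   load_package = "installed")
```

The suite covers every module (layer gradients against finite differences,
convolution against a direct sliding-window oracle, KNN against exhaustive
search, federated aggregation against a brute-force weighted mean, metric
identities against closed forms and `pROC`) plus end-to-end acceptance
checks, including the full federated run above.

See `vignettes/federated-hybrid-ultrasound.Rmd` for the methods write-up
and the reasoning behind the numerical choices.
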