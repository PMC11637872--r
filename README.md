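# microdetect

Detection of diagnostic *feature cells* — stone cells, fibers, vessels,
cork cells, oil cells, starch granules — in microscopy images of powdered
medicinal herbs, for researchers who need a complete, reproducible,
CPU-only detection stack in R. Annotated micrograph collections in this
field are scarce, heavily class-imbalanced, and full of small,
edge-truncated, blurred cells; `microdetect` packages the whole pipeline
that copes with that:

* **Synthetic slide generator** — deterministic annotated "slides" with a
  configurable class-imbalance profile (the bundled `cell_profile`
  reproduces a reference annotation campaign: 9 classes, 11,060 images,
  12,840 boxes, per-class counts from 13 to 7555), YOLO-format labels.
* **Split-recombine augmentation** — two images are cut at the vertical
  midline and the four mixed-source recombinations are stitched with
  exactly remapped boxes; plus mirror / translate / 90°-rotate, and a
  driver that balances class box-counts by minority-biased resampling.
* **Channel attention** — squeeze-excitation (`ω = σ(W₂ δ(W₁ z))`, r = 16)
  and efficient channel attention (1-D convolution across the channel
  statistic, kernel size `k = ‖log₂(C)/2 + 1/2‖_odd`).
* **A three-scale anchor detector** — strides 8/16/32, three anchors per
  cell, squeeze-excitation in the shallow backbone, efficient channel
  attention on the neck outputs, trained with the three-part grid loss

  `L = α·Σ_obj[(x−x̂)² + (y−ŷ)² + (w−ŵ)² + (h−ĥ)²]
     + β·Σ_obj Σ_c (p(c)−p̂(c))²
     + γ·[Σ_obj (C−Ĉ)² + λ_noobj Σ_noobj Ĉ²]`,

  where the confidence target is `C = Pr(obj)·IoU` of the decoded box
  against its ground truth and `λ_noobj = 0.5`. Convolution kernels and
  backprop are implemented in the package (Rcpp/Armadillo); no deep
  learning framework is required.
* **Evaluation** — decoding, class-wise NMS, greedy matching, per-class
  P/R/AP, mAP@.5, mAP@.5:.95, Matthews correlation and ROC/AUC with a
  detection-adapted true-negative convention.
* **Protocol** — stratified 8:2 split, five-fold cross-validation
  producing models M1–M5, and 3-of-5 box-cluster majority voting.

## Worked example

```r
library(microdetect)

spec <- slide_spec(n_classes = 2, image_size = c(128, 128),
                   cells_per_image = c(1, 3), class_weights = c(0.65, 0.35),
                   blur_sigma = c(0, 1), seed = 11)
idx <- generate_dataset(spec, 100, "data")
idx
#> <dataset_index: 100 images, 2 classes, boxes per class [126, 62], status ok>

split <- split_dataset(idx, ratio = 0.8, seed = 3)
aug <- balance_dataset(split$train,
                       augmentation_policy(balance_ratio = 0.8, budget = 60,
                                           seed = 3),
                       out_dir = "data_aug")
aug
#> <dataset_index: 244 images, 2 classes, boxes per class [336, 273], status ok>

cfg <- detector_config(n_classes = 2, input_size = c(128, 128),
                       anchors = kmeans_anchors(split$train, c(128, 128)),
                       seed = 5)
model <- build_detector(cfg)
model <- train_detector(model, aug,
                        train_config(epochs = 8, lr = 0.002, batch_size = 4,
                                     weights = loss_weights(box = 0.5, cls = 1),
                                     seed = 2))

dets <- predict_dataset(model, split$test, score_thresh = 0.05)
report <- map_suite(dets, index_ground_truth(split$test))
report
#> <eval_report: mAP@.5 0.626, mAP@.5:.95 0.145, P 0.342, R 0.694>
```

The printed report means: averaged over the two classes, this single
8-epoch model's detections overlap the held-out ground truth at IoU ≥ 0.5
with an average precision of 0.63; under the stricter 0.50–0.95 IoU sweep
this drops to 0.15 (boxes are roughly, not perfectly, localized); at the
0.25 operating threshold 34% of emitted boxes are correct and 69% of true
cells are found. The five-fold voted ensemble below improves markedly on a
single model.

The five-fold + voting protocol is one call:

```r
res <- run_experiment(desk_experiment_config(seed = 1, out_dir = "exp"))
res$report          # voted-ensemble evaluation
res$per_model_map50 # the five fold models individually
```

A command-line wrapper covering generate / augment / evaluate / crossval
is installed at `inst/cli/microdetect`.

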