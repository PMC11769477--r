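# discwolf

Grey-wolf-optimized deep-feature classification for binary medical-image
labels — built for the herniated / non-herniated decision on lumbar disc
MRI slices, and fully testable without any MRI data.

## What it does

Given image slices (12-bit DICOM/IMA or 8-bit PNG) or a precomputed
feature matrix, the pipeline:

1. **Preprocesses** — rescales each pixel to 8 bits,
   `uint8 = round(255 · p / I_max)` (so 4095 → 255 for 12-bit input),
   normalizes by `X/255` into `[0, 1]`, replicates grayscale into three
   channels, and one-hot encodes labels.
2. **Extracts deep features** — a 50-layer residual backbone feeding
   flatten → FC-1024 → 2-unit output, trained with Adam on binary
   cross-entropy; the 1024-wide FC activation vector is the per-image
   descriptor. The residual backbone is represented structurally (exact
   shapes and variable counts: 10×10×2048 output, flatten 204,800,
   FC layer 209,716,224 variables, backbone 23,587,712); in-package
   inference uses a parameter-free pooling (`debug`) backbone or a
   feature CSV.
3. **Optimizes per-feature weights** with a grey wolf pack. Each wolf is
   a weight vector in `[0, 1]^d`; its fitness is the validation accuracy
   of the downstream classifier on column-weighted features. The three
   best wolves α, β, δ lead the update

   ```
   positions = (α + β + δ)/3 + a · (rand() − 0.5),   a: a₀ → 0 linearly
   ```

   and the best position ever seen is multiplied into the feature matrix.
4. **Classifies** with an SVM (linear, rbf, sigmoid or polynomial kernel)
   or an MLP (relu, identity, tanh or logistic activation, trained by
   back-propagation).
5. **Evaluates** with stratified 5-fold cross-validation:
   `Accuracy = (TP+TN)/(TP+TN+FP+FN)`, `Recall = TP/(TP+FN)`,
   `Precision = TP/(TP+FP)`, `F1 = 2·P·R/(P+R)`, support-weighted over
   both classes and averaged across folds. The optimizer and classifier
   see only training folds.

Seeded synthetic generators (`synthetic_features()`, `synthetic_images()`)
provide class-structured feature matrices with a known informative subset
and toy 12-bit slices, so every stage has a provable target.

## Worked example

```r
library(discwolf)

d <- synthetic_features(n_samples = 200, n_features = 32, n_informative = 8,
                        class_separation = 2, seed = 7)
g <- gwo_config(dimension = 32, population_size = 20, iterations = 30,
                validation_fraction = 0.5, seed = 7)
res <- gwo_optimize(d$features, d$labels, g)
res
#> <gwo_result 32-dim, 20 wolves x 30 iterations, best fitness 0.8600>
mean(res$best_position[d$informative])   # 0.581
mean(res$best_position[-d$informative])  # 0.406

report <- cross_validate(apply_weights(d$features, res$best_position), d$labels,
                         classifier_spec("svm", kernel = kernel_spec("linear")),
                         k = 5, seed = 7)
report
#> <metrics_report 5-fold cross-validation>
#>   accuracy precision recall     f1
#> 1    0.875    0.8828  0.875 0.8738
#> 2    0.775    0.7797  0.775 0.7729
#> 3    0.800    0.8143  0.800 0.7990
#> 4    0.850    0.8500  0.850 0.8500
#> 5    0.800    0.8040  0.800 0.8000
#> fold means:
#>  accuracy precision    recall        f1
#>    0.8200    0.8262    0.8200    0.8191
```

The optimizer's best fitness (0.86) is the wrapper accuracy on its
internal validation split. The learned weights rank the eight planted
informative columns above the 24 noise columns (mean 0.58 vs 0.41), and
the weighted features classify at 0.82 five-fold accuracy on a problem
whose class-mean separation is only 2σ. Support-weighted recall equals
accuracy in every row — the reporting convention's built-in identity.

The same run from the shell:

```sh
Rscript inst/cli/discwolf.R --input synthetic --family svm --kernel linear \
    --k 5 --seed 7 --gwo-population 20 --gwo-iterations 30 --out results/
```

writes `report.json`, `metrics.csv`, `best_position.json` and per-fold
confusion matrices; reruns with the same seed are byte-identical.

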