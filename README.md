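# emaclass

Automated four-class reading of IgA-class endomysial antibody (EmA)
immunofluorescence images for celiac disease serology.

The EmA test is read by experts from indirect immunofluorescence images of
umbilical-cord tissue sections: a positive serum lights up reticulin fibers
and vessel-wall outlines, a negative serum leaves a dim unstructured field,
IgA-deficient sera give a near-dark field, and weak or partial staining is
called equivocal. Expert reading is subjective and slow; `emaclass`
implements an observer-independent pipeline for this reading:

1. **Image reduction** — the green fluorescence channel is extracted (slides
   are acquired with red/blue suppressed) and edges are boosted with unsharp
   masking, `I' = clip(I + a (I - G_sigma * I))` with defaults
   `sigma = 1`, `a = 1`.
2. **Texture descriptor** — multi-scale rotation-invariant co-occurrence of
   adjacent local binary patterns. At each scale `(r, d)` in
   `{(1,2), (2,4), (4,8)}` the 4-neighbour LBP code
   `c(p) = sum_i 2^i [I(p + r e_i) >= I(p)]` is computed, and ordered code
   pairs `(c(p), c(p + a_theta))` are counted along the four directions
   `theta in {0, 45, 90, 135}` degrees (both displacement senses, so every
   valid centre contributes 8 pairs). The 4 x 16 x 16 = 1024 raw cells are
   pooled over the orbits of the 90-degree rotation action (rotating both
   codes, advancing `theta`, swapping the pair when the direction reverses),
   which yields exactly **272 invariant bins** per scale — the feature vector
   is 3 x 272 = 816 values, each scale block an L1-normalised distribution.
   On square images the vector is *exactly* invariant under 90/180/270-degree
   rotation.
3. **Classification** — one-vs-all RBF-kernel SVM ensemble (optionally tuned
   by inner 10-fold cross-validation over a `C x gamma` grid) or multi-class
   AdaBoost (SAMME) over depth-limited decision trees; class imbalance can be
   addressed by seeded random under-sampling of the negative majority class.
4. **Evaluation** — repeated stratified 70/30 splits (default 10), held-out
   predictions pooled into a confusion matrix; accuracy, classification
   error, per-class sensitivity/specificity/precision/F1, Cohen's kappa and
   one-vs-all ROC/AUC.

Because clinical EmA images are not publicly available, the package ships a
seeded synthetic generator that renders the four staining phenotypes
(rings + fibers, dim speckle, near-dark field, weak partial staining) at a
configurable class balance and contrast, so the whole pipeline is testable
end to end.

## Worked example

```r
library(emaclass)

# 40 images/class at full contrast, 64 x 64 px
spec <- dataset_spec(n_per_class = rep(40, 4), image_size = 64, seed = 0)
ds   <- generate_dataset(spec)

feats <- t(vapply(ds$images, extract_features, numeric(816)))
cfg   <- train_config(svm_C_grid = 10, svm_gamma_grid = 1/816,
                      n_repeats = 10, seed = 0)
ev    <- train_evaluate(labeled_dataset(feats, ds$labels), cfg)
ev
```

```
Repeated-split evaluation (10 repeats, pooled)
  per-repeat accuracy: 1.0000 +- 0.0000
EmA classification metrics (positive class: I )
  accuracy    1.0000   error 0.0000
  sensitivity 1.0000   specificity 1.0000
  F1          1.0000   kappa 1.0000
  one-vs-all AUC: I=1.0000  II=1.0000  III=1.0000  IV=1.0000
  confusion matrix (rows = truth):
     predicted
truth   I  II III  IV
  I   120   0   0   0
  II    0 120   0   0
  III   0   0 120   0
  IV    0   0   0 120
```

(each of the 10 repeats holds out 12 images per class, so 480 pooled
held-out predictions; at the generator's default full contrast the four
classes are cleanly separable and every held-out image is correctly
classified). Lowering `separability` toward 0 collapses the class-specific
texture parameters onto a shared set and accuracy falls to the 25 % chance
level.

For images on disk, the same run is:

```r
extract_feature_table("images/manifest.csv", out_csv = "features.csv")
ev <- train_evaluate("features.csv", cfg, do_undersample = TRUE)
```

or from a shell via the thin CLI (`inst/cli/emaclass.R`):

```sh
Rscript inst/cli/emaclass.R simulate --profile clinical --n 400 --seed 1 --out imgs
Rscript inst/cli/emaclass.R extract  --manifest imgs/manifest.csv --out features.csv
Rscript inst/cli/emaclass.R evaluate --features features.csv --seed 1 --out run
```

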