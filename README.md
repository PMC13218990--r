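# fgar — Fourier-guided attention encoders for histopathology feature extraction

`fgar` is an R package for people who want a *transferable feature
extractor* for haematoxylin–eosin (H&E) histopathology tiles rather than
an opaque end-to-end classifier: computational-pathology researchers
benchmarking descriptor families, and method developers studying
frequency-domain priors in vision transformers.

## The model

Diagnostic evidence in colorectal histopathology lives at two scales:
fine cellular texture (nuclear boundaries, chromatin — high spatial
frequencies) and broader tissue architecture (low frequencies).  The
encoder implemented here makes that prior explicit.  A tile is cut into
$P\times P$ patches and embedded as tokens

$$Z^0 = [z_{\mathrm{cls}};\,X_p] + E_{\mathrm{pos}},\qquad
N = (S/P)^2 \text{ patch tokens},$$

and each of $L$ encoder blocks applies, residually:

1. **spectral refinement** of the patch tokens laid out on their
   2-D grid,
   $$U = T + \mathrm{IFFT}\big(G(\mathrm{FFT}(\mathrm{LN}(T)))\big),$$
   where $G$ is a squeeze-and-excitation gate computed from per-channel
   spectral magnitude summaries — channels whose frequency content is
   informative get amplified, noisy ones suppressed;
2. **multi-head self-attention** over all $N+1$ tokens (pre-norm);
3. a **pre-norm GELU MLP** of hidden width `mlp_ratio * D`.

Training minimises cross-entropy
$\mathcal{L} = -\sum_c y_c \log \hat y_c$ with AdamW.  After training,
the final class token is exported as the tile's descriptor and scored by
a fixed roster of seven shallow classifiers (logistic regression, kNN
$k{=}9$, Gaussian naive Bayes, 10-tree random forest, linear SVM, RBF
SVM, two-hidden-layer ANN) — the transferability protocol used by the
EBHI-style benchmarks.  Five handcrafted descriptor families (colour
histogram, luminance histogram, HOG, LBP, GLCM) are included as
baselines, and the flags `use_fft`/`use_se` give the B0/B1/B2/full
ablation grid of the spectral block.

Everything is testable offline: a synthetic generator produces
two-class H&E-like tiles whose class signal lives mainly in the spatial
frequency spectrum (power-law texture slope β = 3.5 benign-like vs 1.5
malignant-like, Beer–Lambert stain colourisation).

## Worked example

```r
library(fgar)

## a small two-class synthetic H&E dataset (64 x 64 tiles)
ds <- generate_dataset(synth_spec(n_per_class = 200, seed = 42))

## a small frequency-aware encoder
cfg <- fga_config(image_size = 64, patch_size = 8, embed_dim = 64,
                  depth = 2, num_heads = 4, se_reduction = 8)
#> <fga_config> full | 64x64 px, P=8 (N=64), D=64, L=2, heads=4, C=2

## train end-to-end, then export class-token features
fit <- train_fga(fga_model(cfg, seed = 1), ds$images, ds$labels,
                 train_config(epochs = 15, batch_size = 32, seed = 1,
                              augment = FALSE))
#> <fga_fit> 15 epochs; best val acc 0.688 (epoch 5); final train loss 0.6829
feats <- fga_extract(fit$model, ds$images)

## score the features with downstream shallow classifiers
reports <- fit_and_evaluate(feats, ds$labels,
                            classifier_protocol()[c("knn", "ann")],
                            split_seed = 1)
print(reports$ann)
#> <fga_eval_report> accuracy 85.00% (n = 80)
#>        precision recall specificity    f1
#> class1     81.82     90          80 85.71
#> class2     88.89     80          90 84.21
```

Reading the numbers: training at the full-size protocol's learning rate
moves a tiny encoder only gently (the cross-entropy is still near
ln 2 = 0.693), yet the exported class-token features — whose SE gates
are driven by per-channel spectral statistics — already separate the
held-out tiles at 85% with a downstream ANN.  That gap between weak
end-to-end accuracy and strong transferred-feature accuracy is exactly
what the transferability protocol is designed to expose.

The report mirrors one row group of the benchmark tables: overall
accuracy plus class-wise precision/recall/specificity/F1 in percent
(class 1 = benign-like, class 2 = malignant-like; in the binary setting
the specificity of one class equals the recall of the other).

The same pipeline is scriptable:

```sh
Rscript inst/cli/fga.R synth   --out data --n 100 --size 64
Rscript inst/cli/fga.R train   --data data --out model.rds --config run.yaml
Rscript inst/cli/fga.R extract --checkpoint model.rds --data data --out feats.csv
Rscript inst/cli/fga.R eval    --features feats.csv --out metrics.csv
Rscript inst/cli/fga.R ablate  --data data --out ablation.csv --seeds 1,2,3
```

## Package layout

* `R/model.R`, `R/backprop.R` — the encoder, analytic gradients, AdamW
  (attention and GELU kernels in `src/`).
* `R/spectral.R` — patch-grid FFT/IFFT pair and SE gating (the tested
  spectral contracts).
* `R/training.R` — augmentation and the training loop.
* `R/feature_eval.R`, `R/classifiers.R` — the seven-classifier
  downstream protocol.
* `R/baselines.R` — handcrafted descriptor families.
* `R/synthetic.R` — the synthetic H&E texture generator.
* `R/cli.R`, `inst/cli/fga.R` — command-line entry points.
* `vignettes/fgar-methods.Rmd` — model, protocol and design notes.
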