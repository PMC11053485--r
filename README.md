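# scdr — supervised contrastive deep regression for image-based biomass prediction

`scdr` predicts continuous above-ground biomass (AGB, grams per plot or
g/m²) from RGB canopy images. It is written for crop-phenotyping work
where plots are photographed (drone or handheld) and the harvested,
weighed biomass is the regression target.

Plain deep regression treats every image independently and ignores the
structure continuous labels impose on a batch. `scdr` adds a supervised
contrastive term built for regression (SCDR): after two-view
augmentation, views $i, j$ form a **positive** pair when their labels
are close, $|\tilde y_i-\tilde y_j|\le\omega$, and a **negative** pair
when their labels are far apart but the model currently *confuses*
them, $|\hat y_i-\hat y_j|\le\omega$. A view with at least one negative
is an anchor $j$ with loss

$$
L^{j}=-\log\frac{\frac{1}{N_j^{+}}\sum_{i\in P_j^{+}}e^{v_j\cdot v_i/\tau}}
{\sum_{p\in P_j^{+}}e^{v_j\cdot v_p/\tau}+\sum_{q\in P_j^{-}}S_{j,q}\,e^{v_j\cdot v_q/\tau}},
$$

where the thrust $S_{j,q}=\min\!\big(\eta/(\mathrm{Sim}_l\,\mathrm{Sim}_f),\,S_{\max}\big)$
pushes a confused negative apart more strongly the *less* its label and
features already resemble the anchor's, damping the influence of
mislabelled pairs. Non-anchors contribute 0; the batch loss is the mean
over all $2N$ views, and training minimises
$L_{\mathrm{sum}}=\alpha L_{\mathrm{reg}}+\beta L_{\mathrm{scdr}}$
(defaults $\alpha=1,\beta=3,\tau=0.2,\eta=0.01$, focal-L1 regression).

The bundled backbone, **BioUMixer**, is a U-like hierarchical residual
fusion network: patch embedding, three stages of ConvNeXt-style
FeatureBlocks (BatchNorm, ×4 expansion, GELU, global response
normalization, DropPath) and sandwich-layout BioBlocks (FFN → depthwise
token mixer with parameter-free SimAM attention → FFN), SimAM +
strided-conv stage transitions, long-range additive skips pairing
same-kind blocks across the depth, and an MLP-Mixer head that emits the
embedding $v$ and the scalar prediction $\hat y$. Every module can be
toggled for ablation. The neural-network core (forward, analytic
backprop, Adam, cosine annealing) is implemented in vectorized R with
the depthwise convolution in C++, and is verified against
finite-difference gradients in the test suite.

Evaluation uses RMSE, MAE and MAPE (as a fraction). A seeded synthetic
canopy-scene generator (green foliage blobs and red fruit over soil,
with occlusion; label = grams per visible plant pixel plus noise) makes
the whole pipeline testable without any dataset download; real datasets
load through a CSV manifest with configurable column names.

## Worked example

```r
library(scdr)

data_dir <- file.path(tempdir(), "pepper_like")
generate_dataset(250, scene_params(), seed = 7, out_dir = data_dir)
samples   <- load_dataset(file.path(data_dir, "manifest.csv"), data_dir)
train_set <- Filter(function(s) s$split == "train", samples)
test_set  <- Filter(function(s) s$split == "test",  samples)

fit <- scdr_train(train_config(epochs = 10, seed = 1, verbose = TRUE), train_set)
ev  <- scdr_evaluate(fit, test_set)
print(ev$metrics)
```

This trains the `tiny` preset (64×64 inputs, ~0.5 M parameters) for 10
epochs on 200 synthetic scenes (a few minutes on one CPU core) and
prints, for the 50 held-out scenes:

```
epoch   1  lr 1.00e-03  l_reg 12.0844  l_scdr 1.0340  val MAE 1258.77
...
epoch  10  lr 1.00e-05  l_reg 0.3401  l_scdr 0.9706  val MAE 314.93
n = 50  RMSE = 388.0412  MAE = 304.4655  MAPE = 0.2086
```

`l_reg`/`l_scdr` are the regression and contrastive components of the
training loss (on standardized labels), validation and test MAE/RMSE
are in grams, and MAPE is a fraction (0.21 = 21% mean relative error).
Predictions correlate strongly with the true labels (Spearman 0.88
here); `ev$residuals` holds per-scene labels, predictions and
residuals. Setting `beta = 0` in `scdr_config()` gives the
pure-regression baseline; `scdr_ablate()` re-trains the five module
ablations (main module only, no skips, no FeatureBlocks, no BioBlocks,
full model) and tabulates RMSE/MAE/MAPE and parameter counts.

A command-line interface wrapping the same functions ships in
`inst/cli/scdr`:

```sh
Rscript inst/cli/scdr generate --n 250 --seed 7 --out data/
Rscript inst/cli/scdr train --config run.yaml --data data/ --out run/
Rscript inst/cli/scdr eval --checkpoint run/checkpoint.rds --data data/
```

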