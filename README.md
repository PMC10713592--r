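# cellgraphnet

Graph convolutional networks over **cell spatial organization** for
pathology, in pure R.

Modern pipelines segment and classify every nucleus in an H&E image
patch, yielding a table per patch: centroid, cell type, detection
confidence, major-axis orientation, and ten morphology features (area,
convex area, eccentricity, extent, filled area, major/minor axis length,
perimeter²/area, perimeter, solidity). `cellgraphnet` turns such tables
into directed k-nearest-neighbour cell graphs and trains small
edge-conditioned graph networks on them to predict patch, slide and
patient outcomes (histology subtype, malignant-transformation risk,
treatment response), then attributes each prediction back to individual
cells, features and cell–cell interactions. A synthetic tissue simulator
makes the entire pipeline runnable and testable without any images.

## The model

Each nucleus is a node with 11 globally standardized features; each node
points at its k = 8 nearest other nuclei. An edge (n → m) carries three
interaction features:

- **edge type** `t = type(n)·T + type(m)` — one of T² categories
  (6 cell types → 36, 4 types → 16);
- **parallelism** `a = |cos(θₙ − θₘ)|` — alignment of the two nuclear
  major axes;
- **closeness** `w = 1/‖pₙ − pₘ‖` — reciprocal centroid distance (px⁻¹).

One convolution layer computes, for every edge, a modulator
`mo = γ(w,a) ⊙ EM[t] + β(w,a)` (an edge-type embedding row, FiLM-modulated
by the continuous edge features, reshaped to x×c), forms the message
`X_m · mo`, averages messages over each node's out-edges, and adds a self
term `X_n · θ`:

    X′_n = X_n θ  +  mean over (n→m) of  X_m · mo(n,m)

with ReLU + dropout between layers. Final-layer node logits are averaged
over a task-specific nucleus subset (e.g. tumor nuclei only) and
softmaxed. The default 3-layer classification network (11 → 8 → 8 → 2,
36 edge types) has 7,224 trainable parameters — orders of magnitude
smaller than an image CNN. Interpretation computes, in one exact backward
pass, ∂L/∂f for a cross-entropy objective L with respect to every node
feature of every nucleus and the (w, a) of every edge; a positive
derivative means the feature works against the presumptive class.

The forward pass, backward pass, SGD/AdaDelta optimizers and attribution
are implemented in vectorised base R — at this parameter count no
compiled autodiff framework is needed, and every gradient is checked
against central finite differences in the test suite.

## Worked example

Two synthetic tissue classes that differ *only* in the median tumor
nuclear eccentricity (0.55 vs 0.85 — rounded vs elongated tumor nuclei):

```r
library(cellgraphnet)

specs <- preset_eccentricity_contrast()           # two synthetic_spec objects
ds <- generate_dataset(specs, n_patients = 20, slides_per_patient = 1,
                       patches_per_slide = 5,
                       split_fractions = c(0.6, 0.2, 0.2), seed = 7)
gr <- prepare_graphs(ds, lung_scheme(), k = 8,
                     counted_labels = "tumor", min_count = 20)
gr$train[[1]]
#> <cell_graph> 73 nodes, 584 edges (scheme 'lung')
#>   patch ADC_P001_S1_K001 | slide ADC_P001_S1 | patient ADC_P001 | label ADC

model <- new_cellgraph_net(config_histology(classes = c("ADC", "SCC")),
                           seed = 7, scaler = gr$scaler)
model
#> <cellgraph_net> 3 CSIGC layers (11 -> 8 -> 8 -> 2), subgroup pooling, 7224 parameters
#>   classes: ADC, SCC | scheme: lung

opt <- optimizer_spec("sgd", learning_rate = 1e-4, momentum = 0.9,
                      epochs = 50, batch_size = 8, seed = 7)
fit <- train(model, gr$train, gr$val, opt)
fit
#> <train_result> 50 epochs; best val accuracy 1.000 at epoch 33

preds <- predict_graphs(fit$model, gr$test)
ev <- evaluate(preds, level = "patch", positive_class = "SCC")
c(accuracy = ev$accuracy, auc = ev$auc)
#> accuracy      auc
#>    0.975    1.000
evaluate(preds, level = "slide", positive_class = "SCC")$accuracy
#> [1] 1
```

The patch-level accuracy is the fraction of held-out patch graphs whose
argmax class is correct; the slide accuracy aggregates patches by
majority vote. Attribution on a test graph shows that increasing tumor
eccentricity pushes the prediction away from the low-eccentricity class
(positive ∂L/∂ecc against presumptive class "ADC"):

```r
cm <- feature_contributions(fit$model, gr$test[[1]], k = "ADC")
round(colMeans(cm$node_feature_contributions), 4)[c("eccentricity", "area", "solidity")]
#> eccentricity         area     solidity
#>        1e-03       -1e-04        8e-04
```

`summarize_contributions()` pools such maps across a dataset into the
long table used for contribution boxplots by cell type and edge type.

A command-line front end (`exec/cellgraphnet`) exposes the same pipeline
as `simulate`, `build`, `train`, `predict`, `interpret` and `evaluate`
subcommands over files on disk.

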