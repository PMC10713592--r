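---
title: "Cell spatial graph networks: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell spatial graph networks: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Digital pathology pipelines can segment and classify every cell nucleus in
an H&E image patch, turning a tissue image into a table: one row per
nucleus with its centroid, cell type, detection confidence, the
orientation of its major axis, and ten morphology descriptors (area,
convex area, eccentricity, extent, filled area, major and minor axis
lengths, perimeter²/area, perimeter, solidity).  `cellgraphnet` consumes
such tables and asks how the *spatial organization* of those cells — who
is next to whom, how aligned and how tightly packed neighbouring nuclei
are — predicts patch-, slide- and patient-level outcomes, and which
individual cells and features drive the prediction.

# The model

## Graph construction

Each patch becomes a directed graph: every nucleus points at its k = 8
nearest other nuclei by Euclidean centroid distance.  Node features are
the 11-vector (confidence + 10 morphology), globally centered and scaled
by a mean/population-sd scaler fitted on the pooled *training* nuclei only
and then frozen — validation and test data never influence the scaling.
Each edge (n → m) carries three features:

* **edge type** `t = type(n) · T + type(m)`, one of T² categories for T
  cell types (36 for the 6-type lung scheme, 16 for the 4-type oral
  scheme);
* **parallelism** `a = |cos(θₙ − θₘ)|`, the structural concordance of the
  two nuclear major axes (1 = parallel, 0 = perpendicular).  Orientations
  are axial quantities — an axis at θ equals one at θ + π — and the
  reader normalizes them into [−π/2, π/2);
* **closeness** `w = 1 / ‖pₙ − pₘ‖`, in 1/pixels.

Distance ties in the kNN search break by ascending node index, and
duplicate centroids are an error rather than being jittered: silent
perturbation would make closeness arbitrary, and reproducibility matters
more than tolerance of degenerate inputs.  Orientation itself is *not* a
node feature; it enters only through edge parallelism, which keeps the
node representation rotation-insensitive.

## The edge-conditioned convolution layer

One layer maps node features X (N × x) to X′ (N × c).  For each edge the
categorical type selects a row of an embedding matrix `EM ∈ R^{T²×(x·c)}`,
which is then modulated elementwise by feature-wise linear modulation
(FiLM) driven by the two continuous edge features:

    mo(n,m) = γ(w, a) ⊙ EM[t] + β(w, a),   γ, β affine maps R² → R^{x·c}

reshaped to an x × c matrix.  The per-edge message is `X_m · mo(n,m)`
(the neighbour's features pushed through an interaction-specific linear
map); messages are averaged over each node's out-edges and added to a
self message `X_n · θ`.  Non-final layers apply ReLU and dropout (rate
0.2, training only); the final layer applies neither, so per-node outputs
are unconstrained logits.  Pooling averages final-layer logits over a
designated subset of nuclei (tumor nuclei for histology classification,
the epithelial strata for the oral risk task, or all nuclei for the
response task), and a softmax turns the pooled logits into class
probabilities.

Two readings of the per-edge message exist in this layer family: the
message can carry the *neighbour's* features (`X_m`, the convention of
edge-conditioned convolution and our default) or the source node's own
features (`X_n`).  Both are implemented behind
`task_config(message_source =)`; the gradient machinery covers both.

The final layer omitting ReLU is a deliberate choice: softmax over
nonnegative-only pooled logits is degenerate (it can never approach a
confident prediction for class probabilities below 1/K), and the
per-nucleus probability maps require unconstrained logits.

## Initialization

Embeddings and self-transforms start from zero-mean normals with
sd 1/√x (variance-preserving for width-x inputs).  The FiLM maps start at
the identity: γ ≡ 1, β ≡ 0, with zero weights on (w, a).  A consequence
worth knowing: at initialization the forward pass is *invariant* to
closeness and parallelism, so any predictive signal carried only by edge
features must be created by growing the FiLM weights from zero — such
tasks learn more slowly than tasks whose signal enters through node
features (see the orientation experiment below).

## Training and aggregation

Graph-level cross-entropy is minimized with either SGD (momentum 0.9,
learning rate 1e-4 for histology classification, 5e-4 for the risk task)
or AdaDelta for the response task, where the "scaling factor = 2" is read
as a multiplier of 2 on the AdaDelta update, with decay and epsilon at
conventional defaults (0.95, 1e-6) — the most natural reading of an
otherwise undefined term.  The checkpoint with the highest validation
accuracy is kept, earliest epoch on ties.  Batch size is not dictated by
the method; the default is 32 graphs, and the bundled recovery
experiments use 8 so that a 200-graph training set still yields ~25
updates per epoch.  Splits are slide-disjoint by construction and the
trainer *asserts* this rather than trusting its caller.

Patch predictions aggregate upward: slide labels by majority vote over
patch predictions (ties: higher mean probability, then lower class
index), patient scores by averaging the positive-class probability over
the patient's patches, then dichotomizing either at a fixed cutoff (0.5
for risk stratification) or at the sample median (response prediction).
With all scores equal, median dichotomization places everyone in the
negative group (every score ≤ its own median) — degenerate but
well-defined.  For the response task all patch graphs of a slide are
merged into one disconnected union graph before the forward pass; with
global mean pooling this equals the node-count-weighted mean of
per-patch outputs, a property the tests verify numerically.

## Interpretation

Per-nucleus class probabilities are the softmax of each pooled node's
final-layer logits; because the graph logits are the arithmetic mean of
those logits, graph-level supervision acts as weak supervision at the
cell level.  Feature attribution takes ∂L/∂f in one exact backward pass,
where L is the cross-entropy of the graph probabilities against a chosen
presumptive category and f ranges over every *derivable* input: all 11
standardized node features of every nucleus and the (w, a) pair of every
edge.  The categorical edge type is not derivable and is not attributed.
A positive derivative means increasing the feature increases the loss,
i.e. the feature works against the presumptive category.  Dropout is
disabled during interpretation so gradients are deterministic, and the
backward pass is verified against central finite differences at 1e-3
relative / 1e-6 absolute tolerance in the test suite.  Contributions are
reported on the standardized scale the model sees; the summary also emits
raw-scale values via the chain rule (divide by the scaler sd).  Whether
to plot per-cell values or per-graph averages is a free choice; we plot
per cell and per edge.

# The synthetic tissue simulator

The simulator exists so the full pipeline is testable without pathology
images.  Per patch it draws a Poisson nucleus count (default mean 60 in a
512 px field — a deliberately scaled-down stand-in for real patches,
chosen so a full train/evaluate/interpret cycle runs in minutes on one
CPU), places centroids by a hard-core process (uniform proposals rejected
within 10 px of an accepted point), assigns types from a mixture, and
derives morphology from an ideal ellipse: lognormal major axis (median
24 px, sdlog 0.15), logit-normal eccentricity (so a stated median is hit
exactly), minor axis `major·√(1−ecc²)`, area πab/4, Ramanujan perimeter,
and extent from the rotated ellipse's axis-aligned bounding box.
Orientations are isotropic or von-Mises-coherent around a shared
patch-level direction via the doubled-angle device, which makes mean edge
parallelism tunable from 2/π (isotropic) towards 1.

Two departures from a perfectly ideal ellipse are intentional.  Solidity
is drawn just below 1 (uniform on 0.93–0.995, with convex area =
area/solidity) and extent varies with orientation and eccentricity; for
exact ellipses both would be constants, and constant features are — by
contract — a fit error in the global scaler, so a pipeline of ideal
ellipses could never run end to end.  The simulator emulates the feature
*families* the analyses rely on (eccentricity contrasts, orientation
coherence, density) but not stain texture, segmentation noise,
inter-patient batch effects or realistic cell-type spatial clustering;
passing recovery tests on it demonstrates that the machinery works, not
that real tissue would be classified equally well.

Labels for the risk/response-style harnesses are generated as class
labels directly; censored survival times are out of scope (grouping
patients for any survival package is the caller's job).

# Recovery experiments and what they show

The bundled experiments use two classes × 30 patients × 1 slide × 5
patches (300 graphs; slide-level splits 200/50/50) with the ≥20-tumor-cell
patch filter, model seed fixed, SGD as above, batch 8.

* **Eccentricity contrast** (tumor eccentricity median 0.55 vs 0.85, all
  else identical): the classifier reaches perfect patch- and slide-level
  test accuracy within 50 epochs.
* **Orientation contrast** (isotropic vs coherent κ = 32): trained for
  150 epochs — longer than the eccentricity run because, as noted above,
  the parallelism signal must be created from identity-initialized FiLM
  weights.  Attribution then ranks parallelism far above closeness among
  edge features (by about three orders of magnitude in mean gradient).

A caveat the attribution experiment makes explicit: with internally
consistent ellipse morphology, an eccentricity contrast necessarily
moves every elongation-coupled feature — perimeter²/area (a scale-free,
strictly increasing function of eccentricity), extent, minor axis, area.
The standardized class gaps of eccentricity and perimeter²/area are
nearly equal by construction, so gradient descent spreads weight across
these collinear channels, and the mean-gradient ranking of
(cell type, feature) groups may place an eccentricity surrogate, or a
noisy rare-cell-type group, above (tumor, eccentricity) itself.  Worse,
once the classifier separates the classes essentially perfectly, the
dataset-mean gradient of any *single* collinear channel is dominated by
the few near-boundary graphs and becomes unstable across training seeds
— its rank and even its sign can flip while test accuracy stays at 1.
Attribution on collinear inputs identifies a feature family, not a
unique member of it; it is sharpest for signals with an exclusive input
channel, as the orientation experiment (parallelism is the only carrier
of coherence) demonstrates.

# Numerical and degenerate-input policy

* Duplicate centroids, empty pooling masks, out-degree-0 nodes,
  single-node graphs, constant features, non-finite losses and
  cross-split slide leakage are *errors*, never silently patched.
* kNN ties break by ascending index; argmax ties by lower class index;
  majority-vote ties by mean probability then lower index; boundary
  scores dichotomize to the negative group.
* All randomness (placement, mixtures, dropout, shuffling, per-epoch
  resampling, initialization) flows from explicit integer seeds; two
  runs with equal seeds are bit-identical, which the tests assert.
* Checkpoints and graph bundles serialize to JSON with 17 significant
  digits, which round-trips IEEE doubles exactly.

# Known limitations

* Pure-R training is practical for the ~10⁴-parameter networks this
  method uses and for desk-scale simulations, not for hundreds of
  thousands of real patches.
* The simulator's classes are spatially homogeneous fields; there is no
  within-patch region structure, so subgroup pooling is exercised but not
  stressed.
* AUC uses the rank statistic with average ranks (ties get half credit);
  ROC curves are step functions over unique score thresholds.
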