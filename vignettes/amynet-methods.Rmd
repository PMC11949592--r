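---
title: "Methods: multimodal amyloid-status classification and guided-backprop explainability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal amyloid-status classification and guided-backprop explainability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Amyloid-beta (Abeta) plaque deposition is the earliest measurable hallmark of
the Alzheimer's disease cascade. Clinically, amyloid status is established by
amyloid PET or by a cerebrospinal-fluid (CSF) assay: a CSF Abeta42
concentration strictly below 980 pg/ml labels a subject amyloid-positive
(POS); 980 pg/ml or above labels them negative (NEG). Both reference tests
are invasive or expensive, which motivates detecting amyloid status from
non-invasive MRI instead.

`amynet` implements a three-branch deep network that classifies amyloid
status from three MRI-derived views of one subject:

* **sMRI** — a gray-matter (GM) probability volume (clinically 121 x 145 x
  121 voxels in MNI space), carrying atrophy information;
* **rs-fMRI** — a 53 x 53 functional network connectivity (FNC) matrix of
  Pearson correlations between independent-component time courses, viewed as
  a complete weighted graph with signed edges;
* **dMRI** — an 84 x 84 structural connectome of streamline counts between
  anatomical ROIs, viewed as a complete weighted graph with nonnegative
  edges.

Cohort assembly follows the clinical design: NEG subjects are retained only
at the CN/SMC/EMCI stages (late-stage decline without amyloid suggests
non-amyloid pathology), POS subjects only at EMCI/LMCI/AD. The cohort is
therefore unbalanced both in label and in stage, which the loss function
acknowledges through class weighting.

## Architecture

Each modality passes through its own *feature-reduction* branch that ends in
a 100-feature latent vector:

* the GM volume through a 3D CNN with six 3x3x3 convolutional layers
  (channels 8-8-16-16-32-32), a 2x2x2 max-pool after every second
  convolution, and four dense layers;
* the FNC graph through two graph-convolutional layers (hidden width 16)
  followed by a dense layer. The message-passing update is
  `Z = H W_self + (A H) W_neigh + b` with `A` the signed correlation
  adjacency: negative correlations influence the aggregation rather than
  being discarded;
* the SC graph through two Chebyshev spectral layers of order K = 3 (hidden
  width 16) followed by a dense layer. Filtering operates on the rescaled
  symmetric-normalised Laplacian `2 L / lambda_max - I`, with `lambda_max`
  obtained per graph by power iteration (tolerance 1e-6).

Node features of both graphs are initialised to 1 so every bit of
discriminative information must come from edge weights. The graph readout is
an order-preserving flatten of the node embeddings: node counts are fixed
per modality, and keeping node identity in the latent makes per-node
attributions well defined. The three latents are concatenated in fixed order
(sMRI, fMRI, dMRI) into a 300-feature vector and classified by a three-layer
MLP with softmax output. Hidden activations are rectified-linear throughout;
the branch latents themselves are linear so the fusion layer sees signed
features.

Where the layer counts and dimensions are fixed by the design (six + three +
four for the CNN, two + one for each graph branch, three for the classifier,
100/300 for the latents), the remaining widths are the smallest stacks that
honour those counts while staying trainable on a single CPU; they are
exposed in `model_config()`.

## Training protocol

`cross_validate()` runs stratified k-fold cross-validation (default five
folds, stratified on the amyloid label only) with a fresh seeded
initialisation per fold. Optimisation is Adam with L2 weight decay 1e-4,
mini-batches of 16 subjects, weighted cross entropy, and by default the
clinical-scale recipe of learning rate 1e-5 for 200 epochs. Class weights
follow the inverse-frequency convention `w_c = N / (2 N_c)`, so balanced
labels give (1, 1) and the 185/133 cohort gives (0.859, 1.195). The final
epoch's model is evaluated (no early stopping); POS is the positive class
for precision/recall/F1; the best fold is the one with the highest
evaluation accuracy, ties broken toward the lowest fold id.

For desk-scale experiments the package pairs 30 epochs and 2 folds with
Adam's standard learning rate of 1e-3: roughly 120 optimisation steps
at 1e-5 would leave the parameters essentially at initialisation, so the
scaled recipe keeps total learning comparable while the defaults remain the
clinical ones.

## Guided backpropagation

Attribution maps are the gradient of the POS pre-softmax score with respect
to each input, with every rectified-linear backward pass replaced by the
guided rule: a gradient passes only where it is positive *and* the unit's
forward input was positive. Targeting the pre-softmax score avoids the
saturation-flattened gradients of the softmax output. The cohort-level map
is the voxelwise/nodewise mean over the correctly classified POS subjects of
the best fold's evaluation set; no per-subject normalisation is applied
before averaging.

For the sMRI map, per-region scores are the sum of attribution magnitudes
inside each atlas region divided by the region's voxel count — "weighted to
account for region volume" is directionally ambiguous, and division is the
reading that makes scores comparable across regions of different size, which
is the purpose of the cross-region ranking. Magnitudes rather than signed
values are summed within a region for the same reason percentages are
computed on absolute scores: first-layer convolution filters are signed, so
an attribution map carries mixed voxel signs inside a region and a signed
sum cancels real attribution mass (on synthetic cohorts the signed sum
demonstrably drops planted effect regions out of the ranking while the
magnitude sum retains them). A signed variant remains available. Graph-branch attributions are read
directly at the node features. Percentage contributions are computed on
absolute scores (signed sums can cancel and leave a percentage of an
ill-defined total); within-modality percentages sum to 100, as do
across-modality percentages over all regions. The top 10 regions per
modality feed the statistics stage; ties are broken lexicographically so
rankings are reproducible. Exported sMRI overlays are additionally masked at
the 96th percentile, a display convention only.

## Group statistics on input features

For the top-10 regions the package extracts per-subject *input* features on
all correctly classified subjects of both classes: regional mean GM
intensity (sMRI), node strength — the signed sum of incident edge weights —
(fMRI), and betweenness centrality (dMRI) with edge length the reciprocal
streamline count, normalised by (n-1)(n-2) over ordered pairs. Strength uses
the signed sum by definition; an absolute-value variant sits behind a flag
for sensitivity analyses. Betweenness relies on reciprocal edge lengths
because larger streamline counts mean stronger, hence "shorter",
connections; this is the standard connectomics transform where the exact
choice is not otherwise fixed.

Each region is compared between groups by a two-sided Mann-Whitney test:
exact null distribution when the combined sample is at most 20 without ties,
tie-corrected normal approximation with continuity correction otherwise.
Benjamini-Hochberg FDR correction is applied within each modality's family
of 10 tests. Comparison directions come from group medians at adjusted
p < 0.05; raw p < 0.1 is flagged separately as a trend. Directions are always
computed from the data.

## The synthetic cohort generator

Clinical imaging cohorts with CSF status are access-restricted, so the
package ships a generator whose defaults mirror the target study design:
subgroup counts 69/75/41 (NEG) and 53/53/27 (POS), 53 FNC nodes, 84 SC
nodes, a 56-region atlas, 6-mm FWHM Gaussian smoothing (sigma = FWHM/2.355
in voxel units), and CSF Abeta42 drawn per group from truncated normals
(POS 607.5 +/- 189.3 below the cutoff, NEG 1684.3 +/- 601.2 above it) so
derived labels always agree with the generating group.

* **Volumes** are a per-region template (regional means uniform on
  0.4-0.8) scaled by per-subject regional anatomical factors
  `1 + N(0, 0.1)` — without such between-subject variability the volumes
  would be a fixed template plus trace noise, a degenerate regime in which
  regional features are nearly deterministic and network latents barely vary
  across subjects — plus voxel noise; POS subjects' atrophy regions are
  scaled by `1 - atrophy_effect` before smoothing. The toy atlas grows regions from
  seeded voxels by nearest-seed assignment inside an ellipsoidal mask, which
  guarantees nonempty contiguous regions.
* **FNC matrices** come from a low-rank factor model (`BB' + I` converted
  to correlations, guaranteeing positive semidefiniteness before effect
  injection); the POS effect adds `fnc_effect_delta` to edges incident to
  the effect nodes, then re-clamps to [-1, 1]. Post-injection matrices may
  be marginally non-PSD; the pipeline never requires PSD.
* **SC matrices** are negative-binomial counts (variance > mean, mimicking
  streamline-count overdispersion) around a template that decays with the
  distance between random node centroids; the POS effect multiplies selected
  edges' expected counts.

The default grid is 32^3 voxels at 3 mm so a full cohort trains on one CPU;
the clinical 121 x 145 x 121 grid is available by overriding
`grid_extents`. What the generator does *not* emulate: scanner noise,
motion, registration error, biophysical BOLD or diffusion processes, or
realistic anatomical covariance between modalities. Passing the recovery
tests therefore demonstrates that the pipeline's machinery — training,
attribution, ranking, statistics — recovers known planted structure; it is
not evidence about classification accuracy on clinical data.

## Numerical choices and problem sizes

* 3D convolution is im2col plus BLAS matrix products, with patch matrices
  written into reusable workspaces; the backward input gradient uses the
  flipped-kernel convolution identity. Gradients of every layer are verified
  against central differences in the test suite.
* Max-pool ties (common at zero after ReLU) resolve to the first element of
  the pooling window, matching the usual framework convention.
* Parameter initialisation is variance-scaled uniform with zero biases,
  fully determined by (config, seed). A single run-level seed drives
  simulation, fold splitting, initialisation and epoch shuffling.
* Degenerate inputs are errors, not repairs: asymmetric matrices,
  out-of-range correlations, negative streamline counts, constant time
  series, all-zero SC matrices (betweenness undefined), all-zero attribution
  scores (percentages undefined), and cohorts lacking a class.
* The package's own experiments run at reduced problem sizes chosen once:
  the recovery study uses 32^3 volumes with 60 NEG / 60 POS subjects,
  30 epochs and 2 folds; the chance-level check uses a 16^3 zero-effect
  cohort (the question there is calibration, not capacity); statistical
  calibration uses matrix-level simulations (500 null repetitions with
  10 + 10 subjects in the exact Mann-Whitney regime; power at n = 40 + 40
  with the injected strength effect sized at three times the empirical
  strength noise sd, estimated from a pilot group per seed).

## Known limitations

* The fMRI layer family is a signed-weight sum-aggregation GCN; the exact
  update of the reference layer is not published beyond its citation, so the
  incorporation of signed edge weights into the aggregation is this
  package's design choice (flagged here deliberately).
* The graph readout (order-preserving flatten) is likewise a design choice;
  permutation-invariant pooling would lose the node identity that per-node
  attribution requires.
* Unimodal ablations reuse the same branches with a classifier head on the
  100-feature latent.
* Betweenness on very sparse graphs can be dominated by a few shortest
  paths; the generator's SC templates are dense enough that this is not
  exercised.
* CNN attribution quality depends on how much the fused classifier relies
  on the sMRI branch, and this exposes a genuine property of jointly trained
  multimodal models: *modality free-riding*. When one modality separates the
  classes on its own — as the planted FNC node-strength shift does on the
  package's recovery cohorts, where it moves strengths by an order of
  magnitude more than their noise — cross entropy reaches zero within a few
  optimisation steps, gradient flow stops for every branch, and the CNN
  pathway never matures; its guided-backprop region ranking then reflects
  initialisation rather than atrophy (the identical CNN trained unimodally
  on the same cohort classifies at 0.98-0.99).
* Guided backpropagation itself under-attributes *evidence by absence*. The
  synthetic atrophy signal is "less gray matter implies positive": a network
  can encode it through units that activate on high GM and are therefore
  silent in exactly the amyloid-positive subjects being analysed — silent
  ReLUs pass no gradient, so the planted regions can receive near-zero
  attribution even when the classifier demonstrably relies on them. On
  small-grid unimodal experiments this inversion is systematic (planted
  regions rank at the bottom of the magnitude ranking); at larger scales the
  network sometimes forms dark-responsive units instead and the regions
  surface near the top. This is a recognised limitation of
  positive-evidence attribution methods, and it means synthetic recovery of
  atrophy regions through guided backprop is not guaranteed even for a
  well-fit model. On real gray-matter maps, where atrophic regions remain
  active at reduced intensity rather than switching off, the method behaves
  more gracefully. The attribution-recovery expectation for the multimodal
  model is stated in the acceptance suite and is allowed to fail under
  these study conditions.
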