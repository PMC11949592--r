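# amynet — multimodal MRI deep learning for amyloid-beta status

`amynet` classifies amyloid-beta (Abeta) status — the earliest biomarker of
the Alzheimer's disease cascade, defined by a CSF Abeta42 concentration
strictly below 980 pg/ml — from three MRI-derived views of a subject's
brain, and then explains its decisions with guided backpropagation. It is
aimed at neuroimaging researchers who want a fully inspectable, CPU-scale
implementation of a multimodal connectome + volume classification pipeline,
including the post hoc attribution and statistics stages.

## The model

Three feature-reduction branches, one per modality, each ending in a
100-feature latent vector:

| Branch | Input | Architecture |
|---|---|---|
| sMRI | gray-matter volume (121x145x121 clinically; 32^3 desk-scale) | 3D CNN: 6 conv (3^3 kernels, channels 8-8-16-16-32-32), 3 max-pool, 4 dense |
| rs-fMRI | 53x53 FNC correlation matrix as a complete signed weighted graph | 2 graph-conv layers `Z = H W_self + (A H) W_neigh + b`, then dense |
| dMRI | 84x84 streamline-count connectome as a complete weighted graph | 2 Chebyshev spectral layers (K = 3, rescaled normalised Laplacian), then dense |

Node features of both graphs start at 1, so all discriminative information
enters through edge weights. The latents are concatenated (300 features) and
classified by a 3-layer MLP with softmax; training is stratified k-fold
cross-validation with Adam, L2 weight decay 1e-4, batches of 16 and weighted
cross entropy (`w_c = N / (2 N_c)`).

Post hoc, guided backpropagation (every ReLU backward passes a gradient only
where the gradient and the forward input are both positive) attributes the
POS pre-softmax score to input voxels and graph nodes; maps are averaged
over correctly classified POS subjects of the best fold, aggregated into
atlas regions (volume-weighted), ranked into top-10 tables, and the
corresponding *input* features (regional GM means, FNC node strength, SC
betweenness centrality) are compared between groups with Mann-Whitney tests
and Benjamini-Hochberg correction per modality.

Because the clinical data (ADNI) are access-restricted, the package ships a
synthetic-cohort generator that emulates the study design: atlas-structured
GM volumes with group-dependent regional atrophy, factor-model FNC matrices
with node-incident correlation shifts, overdispersed streamline counts with
edge effects, and CSF values sampled on the correct side of the 980 pg/ml
cutoff. See `vignette("amynet-methods")` for the model, every tunable
parameter, and what the synthetic cohorts do and do not demonstrate.

## Worked example

A desk-scale run: simulate a 120-subject cohort (60 NEG / 60 POS, 32^3
voxels, 30% atrophy in regions R01-R05, +0.3 FNC shift on 3 nodes, 2x
streamline factor on 5 edges), train 2 folds x 30 epochs, explain, test:

```r
library(amynet)
cfg <- run_config(
  out_dir = "demo-run",
  cohort = synthetic_cohort_spec(n_per_subgroup = rep(20, 6)),
  train_args = list(learning_rate = 1e-3, epochs = 30, n_folds = 2),
  seed = 1)
res <- cmd_all(cfg)
res$train$cv
```

which prints (about eleven minutes on one CPU):

```
totals: NEG 60 / POS 60
[train] multimodal mean accuracy 1.000 (best fold 1)
[explain] fold 1, 30 correctly classified POS subjects
[stats] 30 tests, 11 significant after FDR
cross-validation over 2 folds (best fold: 1)
  accuracy  1.000 +/- 0.000
  precision 1.000 +/- 0.000
  recall    1.000 +/- 0.000
  f1        1.000 +/- 0.000
```

The held-out accuracy of 1.0 reflects how strongly the planted group effects
separate the synthetic classes at this effect size — the three injected
contrasts are each individually decisive. `demo-run/` then contains
`metrics.json`, per-subject `predictions.csv`, the mean POS attribution maps
under `maps/`, the percentage-contribution table `contributions.tsv`, the
top-10 tables `top_*.tsv`, the group-statistics table `stats.tsv` (region,
contribution %, raw and FDR-adjusted p, comparison direction), and a
human-readable `report.md`. In `stats.tsv` the planted effects surface in
the input features of the top-ranked regions: the atrophy region `R02`
reaches the sMRI top-10 and tests `NEG > POS` (FDR-adjusted p = 3.0e-10,
less gray matter in the positive group), and the functional nodes test
`NEG < POS` in node strength (the +0.3 shift on the effect nodes' edges
raises every node's strength in the positive group). The vignette explains
why guided backprop does not reliably place all five planted atrophy
regions in the multimodal top-10 on cohorts this separable.

The same pipeline is scriptable from a shell, with the run described in a
YAML config (`cohort_spec` and `train_args` mirror `synthetic_cohort_spec()`
and `train_config()`; omitting `train_args` selects the clinical-scale
defaults of learning rate 1e-5 and 200 epochs):

```sh
cat > demo.yaml <<'YAML'
cohort_spec: {n_per_subgroup: [20, 20, 20, 20, 20, 20]}
train_args: {learning_rate: 0.001, epochs: 30, n_folds: 2}
YAML
Rscript inst/cli/amynet.R all --config demo.yaml --out demo-run --seed 1
```

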