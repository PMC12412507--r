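# graphdeconv

Cell-type deconvolution for bulk and spatial **proteomics** from a labeled
single-cell proteomics reference, using a graph neural network.

## The problem

Bulk proteomics and multicellular-resolution spatial proteomics measure
averaged protein abundance over many cells, hiding cellular composition.
Given single-cell proteomics data with known cell-type labels,
deconvolution estimates the fraction of each cell type in every bulk
sample or spatial spot. Count-based transcriptomics deconvolution models
(Poisson / negative-binomial) do not fit continuous protein intensities,
and reference and target usually come from different runs or technologies,
so batch effects must be removed rather than assumed away. This package is
for computational biologists who have a labeled single-cell proteomics
(CyTOF, FACS-based, CITE-seq ADT, LC-MS/MS) reference and bulk or spot
profiles to decompose.

## The method

1. **Mixup pseudo-bulks.** Labeled single cells are averaged into
   pseudo-bulk samples with known composition: a flat-Dirichlet
   composition, a multinomial allocation of `cells_per_sample` cells
   (15/50/200 presets), expression = mean of the chosen cells, label =
   realized count ratio, so `Y` rows sum to 1.
2. **Shared latent space and similarity graphs.** An `[input, 16, input]`
   autoencoder trained on reference + target yields latents `Z`; cosine
   kNN graphs (k = 10) are built within the reference, within the target,
   and jointly. Reference edges are re-weighted by label homophily
   `w_ij = cos(y_i, y_j)`: weight ×1.5 if `w_ij > 0.5`, else ×0.8.
3. **Multi-channel GraphSAGE with three losses.** C independent two-layer
   GraphSAGE channels (`h_v = σ(W_k · [h_v, mean_{u∈N(v)} h_u])`), layer
   outputs fused by learnable weights initialized at (0.7, 0.3), channels
   concatenated into `Z_GNN`. A softmax head predicts compositions
   (`p_i = softmax(MLP(z_i))`), a domain discriminator drives adversarial
   batch-effect removal through a gradient-reversal layer, and a cosine
   triplet loss shapes the embedding. Total loss
   `L = L_dec + α·L_tri + β·L_dom` (α = 0.01, β = 1, margin m = 0.3), Adam
   at 0.001, early stopping on validation CCC (patience 100, never before
   iteration 1500 at full scale).
4. **Two-pass prediction.** Predict target compositions, re-weight the
   target graph with those predictions, and predict again on the adjusted
   graph.

Evaluation uses Lin's concordance correlation coefficient
(`CCC = 2·cov / (σ_y² + σ_ŷ² + (μ_y − μ_ŷ)²)`), RMSE, and Pearson
correlation, per sample and per cell type.

## Worked example

The package ships a synthetic benchmark generator that emulates a labeled
single-cell pool measured in two runs with a strong batch effect
(log-normal archetypes per cell type, per-protein batch shift and scale):

```r
library(graphdeconv)

spec  <- synthetic_spec(seed = 1)              # 4 types, 200 proteins
bench <- make_benchmark_pair(spec)             # 2000 ref / 500 tgt pseudo-bulks
cfg   <- benchmark_config(seed = 1)            # desk-scale configuration

res    <- deconvolve(bench$ref, bench$tgt$expr, cfg)
report <- evaluate_deconv(res$proportions, bench$tgt$props)
print(res)
print(report)
print(head(round(res$proportions$values, 3), 3))
```

```
deconv_result: 500 target samples x 4 cell types (stopped at iteration 333, best 283)
metric_report: sample-wise mean CCC 0.9869, RMSE 0.0260, PCC 0.9932 (500 samples)
  cell-type-wise mean CCC 0.9906, RMSE 0.0277, PCC 0.9940 (4 types)
      type1 type2 type3 type4
pbt_1 0.036 0.042 0.068 0.854
pbt_2 0.143 0.229 0.089 0.539
pbt_3 0.039 0.198 0.174 0.590
```

The report says the 500 held-out target compositions were recovered with a
mean sample-wise concordance (CCC) of 0.987 and an average per-entry error
(RMSE) of 0.026 against truth the model never saw; each printed row is one
target pseudo-bulk's estimated composition and sums to 1. The run takes a
few minutes on one CPU.

A thin command-line front end covers the same pipeline from files:

```sh
exec/graphdeconv simulate --out bench --seed 1
exec/graphdeconv run --ref bench/ref_expr.csv --ref-props bench/ref_props.csv \
    --target bench/tgt_expr.csv --truth bench/tgt_truth.csv --out run1 --seed 1
exec/graphdeconv eval --pred run1/proportions.csv --truth bench/tgt_truth.csv
```

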