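# gatfuse

Multimodal drug-response prediction for cancer cell lines: a multi-channel
graph attention network with gated (adaptive) fusion, implemented in pure R.

## The problem

Pharmacogenomic screens measure the half-maximal inhibitory concentration
(IC50) of compounds against panels of cancer cell lines. Given a drug's
structure and a cell line's genomic profile, the task is to predict the
normalized IC50 of an untested pair — including the *cold-start* setting
where the cell line was never seen during training. The package is aimed at
computational methodologists who want a fully inspectable, CPU-scale
implementation of this model family, with a synthetic benchmark whose
ground truth is known.

## The model

Three modalities enter the network:

* the drug's **molecular graph** (atoms = nodes with 78 binary features,
  bonds = edges), encoded by a GCN backbone
  `Z⁽ˡ⁾ = ReLU(D̃^{-1/2} Ã D̃^{-1/2} Z⁽ˡ⁻¹⁾ W⁽ˡ⁾)`, `Ã = A + I`, that
  **retains every layer's embeddings**;
* the drug's **circular fingerprint** (2048 bits, radius 2);
* the cell line's **binary feature vector** (735 dimensions).

Each retained GCN layer ("channel") is refined by multi-head graph
attention (`e_ij = LeakyReLU(φᵀ[Wz_i ‖ Wz_j])`, softmax over neighbors;
8 heads then 1) and pooled through a **virtual super node** whose state is
updated across channels by a GRU; attention over the per-channel states
yields the drug embedding `h`. Conv+dense encoders embed the fingerprint
and cell vector into `X`. An **adaptive fusion gate**
`g = σ(W_g[h‖X] + b_g)` blends the two views as the convex combination
`H = h⊙g + X⊙(1−g)`; a final attention layer over the two views plus a
dense head with sigmoid output predict the normalized IC50 in [0, 1].

Training: MSE loss, Adam (lr 5e-4, weight decay 5e-4), dropout 0.3,
Xavier initialization, early stopping (patience 50 within 300 epochs).
Ablation variants are one flag away: `no_multichannel` (final-layer
channel only) and `concat_fusion` (concatenation replaces the gate).

## Worked example

```r
library(gatfuse)

ds    <- simulate_drug_response(seed = 1)      # 50 drugs x 40 cells = 2000 pairs
feats <- featurize_drugs(ds$drugs)             # graphs + fingerprints
split <- make_split(ds$responses, "mixed", seed = 1)
fit   <- gf_train(feats, ds$cells, split, gf_config(seed = 1))

glance(fit)
#> # A tibble: 1 x 8
#>   variant n_layers epochs_trained best_epoch best_val_loss best_val_rmse val_pcc n_parameters
#>   <chr>      <int>          <int>      <int>         <dbl>         <dbl>   <dbl>        <int>
#> 1 full           3            193        143       0.00270        0.0519   0.972      2884225

gf_evaluate(fit, part = "test")
#> # A tibble: 1 x 5
#>     pcc   rmse     n split_kind  seed
#>   <dbl>  <dbl> <int> <chr>      <int>
#> 1 0.959 0.0576   200 mixed          1
```

The test PCC of ~0.96 against a noise ceiling of ~0.97 (noise sd 0.05 on a
response spread of sd ~0.21) shows the model recovering nearly all of the
synthetic signal; `autoplot(fit)` and `autoplot(gf_evaluate(fit))` draw the
training curves and the predicted-vs-observed scatter. The cold-start
protocol (`make_split(..., "new_cell_line")`) holds entire cell lines out
of training and is harder, mirroring the usual mixed-vs-new-cell-line gap.

A thin command-line interface wraps the same functions
(`Rscript inst/cli.R simulate|featurize|train|evaluate|ablate ...`).

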