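# makl — multiple approximate kernel learning for pathway-level classification

`makl` classifies binary phenotypes from gene-expression matrices while
selecting the pathways the prediction relies on. Kernel methods capture
nonlinear expression–phenotype relationships but need an `N x N` kernel
matrix per pathway, which does not scale to modern cohorts. `makl` replaces
each pathway's Gaussian kernel with an explicit random Fourier feature block
and learns all blocks jointly with a logistic group Lasso, so the cost is
linear in the number of samples and whole pathways are kept or discarded as
units.

## Model

For each feature set (pathway) `p` with genes `F_p`:

1. estimate a kernel width `sigma_p` as the mean pairwise Euclidean distance
   over a training subsample of the set's columns;
2. draw `D` frequencies `delta_j ~ N(0, sigma_p^{-2} I)` (the Fourier
   transform of the Gaussian kernel) and offsets `b_j ~ U[0, 2pi)`;
3. map each sample `x` to
   `z_p(x) = D^{-1/2} [cos(delta_j' x + b_j), sin(delta_j' x + b_j)]_j`,
   an `2D`-vector with exactly unit norm, so `Z_p Z_p'` approximates the
   kernel matrix and has an exactly unit diagonal.

The concatenated design `Z = [Z_1 ... Z_P]` (width `2DP`) enters the group
Lasso

```
min_{b0, beta}  sum_i log(1 + exp(-s_i (b0 + Z_i beta)))
                + lambda sum_p w_p ||beta_p||_2 ,      s = 2y - 1,
```

solved by block coordinate descent with exact block soft-thresholding. The
block norms `eta_p = ||beta_p||_2` rank pathway relevance; `eta_p > 0`
defines selection. `lambda` is expressed as a multiplier of the closed-form
`lambda_max` and tuned by stratified 4-fold inner cross-validation over
`{0.9, 0.8, 0.7, 0.6}`, inside a replication harness (stratified 80/20
splits, train-statistic z-normalization, test AUROC, per-set selection
frequencies).

## Worked example

```r
library(makl)

# synthetic cohort: 500 samples x 500 genes, 20 pathways, 3 carrying a
# nonlinear (radial) signal, 5% label noise
data <- generate_dataset(synthetic_spec())
sets <- resolve_sets(data$sets, colnames(data$X))

sp <- split_80_20(data$y, seed = 11)
set.seed(22)
model <- makl_fit(data$X[sp$train, ], data$y[sp$train], sets,
                  D = 50, lambda_multiplier = 0.6)
model
#> makl_model: P = 20 sets, D = 50 , lambda multiplier = 0.6
#>   selected: 3 set(s) (top: SET03)

selected_sets(model)
#> [1] "SET03" "SET11" "SET19"
data$informative
#> [1] "SET03" "SET11" "SET19"

scores <- predict(model, data$X[sp$test, ], gene_names = colnames(data$X))
auroc(scores, data$y[sp$test])
#> [1] 0.8388
```

Exactly the three ground-truth pathways are selected, ranked by their block
norms; across 20 replications of the full protocol their selection
frequency is 1.0 while no decoy exceeds 0.10, with mean test AUROC around
0.87. A linear L1 logistic model on the same raw genes scores about 0.50:
the planted signal is radial, invisible to any linear score, which is the
point of the kernel blocks.

The full protocol, from the command line:

```sh
Rscript inst/cli/makl.R simulate --out fixture --seed 7
Rscript inst/cli/makl.R evaluate --expression fixture/expression.csv \
    --labels fixture/labels.csv --gmt fixture/sets.gmt \
    --D 50 --replications 20 --seed 1 --out results
```

which writes `replications.csv` (per replication: chosen multiplier, test
AUROC, number of selected sets, fraction of genes covered),
`selection_frequencies.csv`, and a reproducibility manifest.

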