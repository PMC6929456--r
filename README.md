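# relabeler

Post hoc correction of cell-type labels in single-cell RNA-seq data.

Cell types in scRNA-seq experiments are usually annotated by a mixture of
marker-gene knowledge, clustering and manual inspection. That process is
good but not perfect: a small fraction of cells typically ends up with the
wrong type. `relabeler` takes an expression matrix **X** (N cells × M
genes) together with an existing annotation **y** and asks, cell by cell,
whether the data support the assigned label — reassigning the cells that
look mislabelled to their most probable type. It is aimed at analysts who
already have an annotation from any upstream pipeline and want to fine-tune
it, and at method developers who need a controlled label-noise benchmark.

## Method

1. **Preprocessing.** Genes that are zero in more than 80% of cells are
   removed and values are transformed to log2(x + 1).
2. **Dimension reduction.** PCA on the column-centred matrix; the number of
   retained components is the smallest *d* whose cumulative explained
   variance reaches 70%, clamped to the range [10, 20]:

   M′ = 10 if d < 10, d if 10 ≤ d ≤ 20, 20 if d > 20.

3. **Mislabelling probabilities (AdaSampling).** A probabilistic classifier
   trained on a class-stratified bootstrap of (scores, y) predicts all N
   cells; the mislabelling probability of cell *i* labelled *k* is

   ε_i = 1 − P(ŷ_i = k | x_i).

   For L = 3 iterations, the next training set is resampled with each
   cell's inclusion weight proportional to 1 − ε_i within its class, so
   suspicious cells progressively drop out of training.
4. **Ensemble reclassification.** B = 10 final training sets are drawn with
   the converged weights, one base classifier is fitted per set, their
   class-probability matrices are averaged, and every cell is reassigned to
   the argmax class (ties conservatively keep the initial label).

The base classifier is either an RBF-kernel SVM trained one-against-one
with Platt-scaled probabilities combined by pairwise coupling, or a random
forest whose class probabilities are the fraction of its 100 trees voting
for each class.

Two metrics quantify agreement with a reference annotation: per-class
**mean accuracy** (the unweighted mean over cell types of the within-type
fraction of correct labels) and the **adjusted Rand index** computed from
the four pair-count categories *a, b, c, d* over all N(N−1)/2 cell pairs:

ARI = 2(ad − bc) / ((a + b)(b + d) + (a + c)(c + d)).

## Worked example

Simulate 5 cell types × 100 cells with 2000 genes, flip 10% of each type
to the next type, and correct the noisy annotation:

```r
library(relabeler)
set.seed(2026)
sim   <- simulate_cells(n_types = 5, cells_per_type = 100, n_genes = 2000)
noisy <- inject_label_noise(sim$labels, rho = 0.1)
mean_accuracy(noisy$labels, sim$labels)   # 0.9  (the injected baseline)

fit <- relabel(sim$expression, noisy$labels)
fit
#> Post hoc cell-type label correction
#>   500 cells, 5 cell types, 20 PCs
#>   base classifier: svm (3 AdaSampling iterations, ensemble of 10)
#>   relabelled 47 of 500 cells (9.4%)

mean_accuracy(fitted(fit), sim$labels)            # 0.994
adjusted_rand_index(fitted(fit), sim$labels)      # 0.9851 (baseline: 0.7732)
sum(fitted(fit)[noisy$flipped] == sim$labels[noisy$flipped])  # 47 of 50 restored
```

Of the 50 deliberately mislabelled cells, 47 are returned to their true
type and the corrected annotation reaches 99.4% mean accuracy against the
90% baseline. `summary(fit)` shows the label transition table and the
distribution of mislabelling probabilities; `plot(fit)` draws the cells in
PC1/PC2 with relabelled cells ringed; `write_result(fit, "out.csv")` saves
the per-cell table.

A command-line front end is installed with the package
(`system.file("exec", "relabeler", package = "relabeler")`) with
`run`, `simulate` and `evaluate` subcommands; see `?cli_main`.

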