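# gmq — graph-based local quality assessment of protein structure models

Computational protein structure models vary in accuracy from residue to
residue, and most practical uses of a model — interpreting mutagenesis,
locating functional sites, phasing low-resolution data — hinge on knowing
*which* residues to trust. `gmq` implements single-model, per-residue
(local) quality assessment for structural bioinformaticians: given one
model (a C&alpha; trace in PDB format) and its residue features, it
predicts for every residue a binary label — 1 if the modelled C&alpha; is
expected to lie within a chosen error cutoff (2–8 Å) of its native
position after global superposition, 0 otherwise.

## The model

The structure is represented as a residue graph *G*: nodes are C&alpha;
positions; edges join main-chain neighbours, residue pairs closer than a
neighbour cutoff (4.0–5.5 Å), and pairs sharing a neighbour. A
conditional random field over the maximal cliques *c* of *G* couples each
residue's features with the predicted labels of its spatial neighbours:

    P(Y | X) = (1/Z(X)) ∏_c Ψ_c(Y_c, X_c)

    log Ψ_c = Σ_{r∈c} Σ_{i=1..m} λ_{y_r, i} · x_{r,i}
            + Σ_{(r,s)∈c} w_class(r,s) · ω_pat(y_r, y_s)

with m = 25 structural and alignment features per residue, ω indexed by
the four pair patterns 00/01/10/11, and optional per-class edge weights
w for HH, BB, HB, CH/CB and CC secondary-structure pairs. Inference is
exact: sum-product message passing on a junction tree for marginals,
max-product for the most likely labelling; training is stochastic
gradient ascent of the conditional log-likelihood. A 1.0 Å cutoff
degenerates the graph to the chain ("linear" baseline), and a plain
logistic regression serves as the no-neighbourhood baseline.

## Worked example

Train on a small synthetic dataset (hairpin toys with planted CRF
parameters) and assess a held-out model:

```r
library(gmq)

spec <- synthetic_spec(n_models = 12, n_residues = 14, topology = "hairpin",
                       mu = c(0.5, -0.5, 0.4, -0.4),
                       omega_star = c(0.2, -0.2, -0.2, 0.2),
                       neighbor_cutoff = 5.5, seed = 42)
ds <- sample_crf_dataset(spec)

fit <- train_sgd(ds$instances[1:10], learning_rate = 0.015, epochs = 20,
                 seed = 1, neighbor_cutoff = 5.5)
print(fit)
#> CRFParameters: 4 features, Calpha cutoff 5.0 A, neighbour cutoff 5.5 A
#>   omega: 00=0.2864 01=-0.1832 10=-0.2869 11=0.1837
#>   w:     HH=1 BB=1 HB=1 CHB=1 CC=1
```

The learned pattern weights recover the planted structure: agreeing
neighbour labels (00, 11) score higher than disagreeing ones (01, 10).
Predicting a held-out model:

```r
pred <- predict_quality(ds$instances[[11]], fit)
data.frame(residue = 1:14, truth = ds$instances[[11]]$labels,
           map = pred$map, p1 = round(pred$p1, 3))[1:6, ]
#>   residue truth map    p1
#> 1       1     1   1 0.662
#> 2       2     0   1 0.800
#> 3       3     1   1 0.913
#> 4       4     1   1 0.983
#> 5       5     1   1 0.988
#> 6       6     1   1 0.996

accuracy(pred$map, ds$instances[[11]]$labels)
#> [1] 0.9285714
mcc(confusion_table(pred$map, ds$instances[[11]]$labels))
#> [1] NA
```

`map` is the most likely joint labelling, `p1` the exact per-residue
marginal probability of being within the cutoff. 13 of 14 residues are
labelled correctly; the MCC is `NA` — the explicit "undefined" marker —
because this all-positive prediction leaves both true-negative and
false-negative counts at zero.

For real models the same pipeline starts from files:
`read_model()` (PDB) → `assemble_features()` (external score TSV +
aligned FASTA MSA) → `make_labels()` against a native for training →
`cmd_train()` / `cmd_predict()` / `cmd_evaluate()`, also reachable from
a shell via `Rscript -e 'gmq::gmq_cli()' train --model ... --native ...`.
Cross-validation, neighbour-cutoff comparison and the 6^5-point
secondary-structure edge-weight grid search live in `cross_validate()`,
`compare_cutoffs()` and `grid_search_edge_weights()`.

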