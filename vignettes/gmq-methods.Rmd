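---
title: "Graph-based local quality assessment: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based local quality assessment: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmq)
```

## The problem

A computational model of a protein structure is only useful if its user
knows where it is right. *Local* quality assessment asks, for every
residue of a single model and without access to the native structure,
whether the modelled C&alpha; position is within some error cutoff (here
2–8 &Aring;, measured after optimal global superposition onto the
native). The premise of this package is that residue errors are not
independent: residues that are close in space tend to be right or wrong
together, because modelling errors arrive in fragments — a misplaced
helix, a shifted strand, a badly built loop.

## The model

A structure model becomes an undirected graph: nodes are C&alpha;
positions; edges join (i) consecutive residues on the chain, (ii) residue
pairs closer than a neighbour cutoff (4.0–5.5 &Aring; are the useful
values; 3.8 &Aring; is the typical consecutive C&alpha; spacing), and
(iii) pairs that share a neighbour, applied once. A conditional random
field over the binary label vector $Y$ given residue features $X$
factorises over the cliques $c$ of this graph:

$$
P(Y\mid X) \;=\; \frac{1}{Z(X)} \prod_{c \in C} \Psi_c(Y_c, X_c),
\qquad
\log \Psi_c \;=\; \sum_{r \in c} \sum_{i=1}^{m} \lambda_{y_r,i}\, x_{r,i}
\;+\; \sum_{(r,s) \in c} w_{\mathrm{class}(r,s)}\,
\omega_{\mathrm{pat}(y_r,y_s)} .
$$

The node term scores each residue's $m = 25$ features against its label;
the pairwise term scores the four label patterns 00, 01, 10, 11 of every
connected pair (ordered by ascending residue index), optionally weighted
per secondary-structure edge class (HH, BB, HB, CH/CB, CC). Inference —
marginals by sum-product, the most likely labelling by max-product — runs
exactly on a junction tree built from the maximal cliques; training is
stochastic gradient ascent on the conditional log-likelihood, whose
gradient is observed minus expected sufficient statistics.

## Design choices the formulation leaves open

**Label-conditioned node weights.** The potential above is written with a
single $\lambda_i$ per feature; a label-independent node term cancels
between numerator and normaliser, so the minimal identifiable form
conditions $\lambda$ on the label. We fix the label-0 row to zero
(reference category) and learn the label-1 row, exactly as in logistic
regression.

**Ownership against double counting.** Maximal cliques overlap; summing
the potential naively over cliques would count shared residues and edges
several times, making the likelihood depend on clique overlap rather
than on the graph. Every residue is therefore *owned* by exactly one
clique (the smallest containing it; lexicographic tie-break) and every
edge by exactly one clique containing both endpoints. The global energy
is then well defined and the four pattern counts over a 3-clique's three
connections come out exactly as the worked description demands.

**Triangulation.** A distance graph need not be chordal, and exact
message passing requires the running intersection property. We add fill
edges with the min-fill heuristic (deterministic lowest-index
tie-breaks). Fill edges exist only for inference validity: they carry no
pairwise potential, so the probability model is unchanged.

**MAP tie-breaking.** Ties are resolved toward label 1 (the "good"
label), earliest residue first, by sequentially clamping residues and
comparing maximal attainable scores with a 10<sup>-9</sup> slack. This
makes outputs bit-reproducible; the brute-force oracle in the test suite
applies the same rule.

**SGD hyperparameters.** The training method is stated but not its
settings. Defaults: learning rate 0.05 decaying as $1/\sqrt{\text{epoch}}$,
50 epochs, one model per update, L2 penalty 10<sup>-3</sup>, shuffling
reseeded per epoch. On dense toy graphs (~50 edges on 14 residues) a
0.05 step oscillates — the pairwise gradient scales with the edge count —
so experiments on such graphs use 0.01–0.015 and can enable Polyak
tail-averaging (`average_tail`), which returns the mean of the last few
epoch-end parameter vectors instead of the final iterate; all of this is
exposed configuration, not hidden constants.

**Secondary structure from C&alpha; only.** No assignment tool is
prescribed, and the pipeline must run on C&alpha;-only models, so the
default assigner uses d(i,i+3)/d(i,i+4) helix windows and d(i,i+2)
strand windows with smearing; a per-residue override file (e.g. DSSP
output mapped to {H,B,C}) takes precedence when provided.

**Other fixed readings.** "Closer than" is a strict inequality, for the
distance cutoff and the label cutoff alike. Superposition uses all
shared residues (no trimming). Z-scores use the population standard
deviation of the training residues; zero-variance features map to 0.
Contact order uses C&alpha;–C&alpha; ≤ 8 &Aring; and sequence separation
≥ 2 (the citation gives no parameters; these are the standard ones).
The mutation-score columns pair all rows of the alignment including the
target; gaps count in the conservation denominator but can never be the
most abundant type. Logistic-regression fitting uses quasi-Newton ascent
of the exact likelihood rather than literal first-order gradient ascent;
the test suite checks it against an independent IRLS implementation.

## Features

Of the 25 features, the externally produced scores (ANOLEA, DOPE, TAP,
PROCHECK, Verify3D, PRSS, SPAD, GA341, pG, ProQ) are ingested from TSV
files and never recomputed — re-implementing ten published scoring
programs is out of scope and the CRF is agnostic to feature provenance.
Computed here: contact order and its length-normalised version, model
length, the three alignment-column features (mean BLOSUM45 pair score,
gap fraction, conservation) and the log/ratio transforms
(Verify3D/L², log(Verify3D/L²), log(SPAD), log(lSPAD/(SPAD+1)), floored
at 10<sup>-6</sup> before the log). Missing columns are flagged and
mean-imputed, i.e. 0 after Z-scoring. Six features are local; the
5-feature subset used for the reduced model is a named view.

## What the synthetic world does and does not emulate

The generator produces C&alpha; traces with ideal helix geometry (rise
1.5 &Aring;, 100°/residue), zigzag strands (3.8 &Aring; spacing), turny
random-walk coils, and an antiparallel hairpin topology whose strands sit
4.8 &Aring; apart. Perturbed "models" displace contiguous regions by a
shared direction plus residue noise, mimicking fragment-sized errors.
CRF-sampled datasets draw labels from the pairwise field on the real
residue graph (exact forward sampling on the calibrated clique tree —
chosen over Gibbs sampling because it is exact at any size and needs no
burn-in; a brute-force inverse-CDF sampler serves as the independent
oracle up to 16 residues) and then draw features as label-conditioned
Gaussians N(&plusmn;&mu;, &sigma;²), whose posterior is exactly a CRF of
this form with &lambda;-difference 2&mu;/&sigma;².

Two properties of that world matter for reading the tests. First, on
chain-like folds the spatial edges added at 5.5 &Aring; are short-range
shortcuts of the chain and carry almost no extra information; only
topologies that fold back (the hairpin) give the full graph a real
advantage over the chain-only baseline, which is also where the method's
benefit is expected on real sheets. Second, the pairwise coupling has a
phase transition: on a ~7-neighbour graph, pattern weights much beyond
&plusmn;0.2 drive sampled label vectors to all-0 or all-1. The
neighbourhood-benefit experiment therefore plants sub-critical coupling
(&plusmn;0.2) on hairpins — patchy, spatially coherent labels — and weak
node features (&mu; = 0.3), the regime where neighbour pooling is the
dominant signal. A green test establishes that exact inference, training
and evaluation behave as specified in that regime; it says nothing about
accuracy on real threading or CASP models, which would require the
external model archives, native structures and the ten external scoring
programs.

## Numerical choices

Message passing runs in log space with group-wise log-sum-exp;
normalisation holds to 10<sup>-12</sup> on enumerable instances and
marginals match enumeration to well below 10<sup>-9</sup>. Brute-force
enumeration refuses more than 16 residues. All orderings (clique sort,
tie-breaks, fold assignment, epoch shuffles) are deterministic given the
seed; parameter files serialise doubles at 17 significant digits and
round-trip bit-exactly. MCC returns an explicit undefined marker (`NA`)
whenever a confusion-table margin is zero, rather than 0, matching how
degenerate all-positive predictors must be reported.

## Known limitations

Single chain, C&alpha; only, binary labels — no real-valued error
regression and no consensus (multi-model) mode. The full 7776-point
edge-weight grid with per-point retraining is exhaustive by
specification but computationally serious; `grid_search_edge_weights()`
accepts a sub-grid for anything interactive. The C&alpha;-only secondary
structure assigner is approximate near segment boundaries; plug DSSP
output via the override when full-atom coordinates exist. Maximal clique
enumeration is exponential on adversarial graphs, though residue graphs
at ≤ 5.5 &Aring; stay far from that regime.
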