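---
title: "Mining structural alerts for endocrine disruption with explainable random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining structural alerts for endocrine disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxalert)
```

## The problem

Endocrine-disrupting chemicals interfere with hormone-receptor signalling —
androgen (AR), estrogen (ER), aryl hydrocarbon (AhR), aromatase (ARO) and
peroxisome proliferator-activated (PPAR) receptors in the assays this
package targets. Screening chemicals one assay at a time is slow; a
machine-learning classifier trained on assay outcomes is fast but opaque.
What a toxicologist actually wants is a *structural alert*: a substructure
whose presence explains why a compound is predicted active, compact enough
to act on in molecular design.

`toxalert` implements an explainable workflow that produces such alerts:

1. **Curation** of binary-labelled SMILES tables (missing-data removal,
   salt/complex removal, duplicate and conflicting-label elimination, with
   a complete audit).
2. **Featurization** into 1024-bit extended-connectivity fingerprints
   (ECFP, radius 2) with full bit-to-environment bookkeeping.
3. **Modeling**: minority-class oversampling, an 80/20 stratified split,
   randomized hyperparameter search over the forest size and depth scored
   by k-fold cross-validated ROC-AUC, and a probability random forest.
4. **Local explanation**: a perturbation-based linear surrogate fit around
   each confidently predicted active, assigning each fingerprint bit a
   signed weight in [-1, 1].
5. **Alert mining**: mapping weighted bits back to substructures,
   filtering, and aggregating them into a ranked toxic-alert table.

A synthetic-molecule generator with *planted* alert substructures makes
every stage testable without any external download: when activity is caused
by a known fragment, the pipeline's output can be compared against that
ground truth.

## The fingerprint and its environment map

An ECFP assigns every atom an initial integer invariant (element, formal
charge, heavy-atom degree, implicit hydrogen count, ring membership), then
iteratively hashes it together with the sorted (bond order, neighbor
invariant) pairs, once per radius up to 2. Every (atom, radius) identifier
is folded into 1024 bits. Folding loses the mapping from bit to structure,
so `fingerprint()` records it at generation time: for every active bit, the
list of (center atom, radius) environments that set it. Environments whose
bond sets duplicate an already-emitted environment are dropped, and an atom
whose neighborhood stops growing stops emitting — a lone carbon therefore
sets exactly one bit. Collisions (several distinct environments on one bit)
are retained and later attributed *all* of them, since the bit's surrogate
weight cannot be divided between them honestly.

`fragment_for_bit()` turns an environment back into chemistry: the subgraph
of atoms and bonds within the radius, exported as a canonical fragment
SMILES. Bond orders come from the kekulized parent, so fragments of
aromatic rings appear in kekulé form; substructure containment checks
(`has_substructure()`) therefore match by element-colored topology by
default, with bond-order matching available as an option.

## The local surrogate

For one molecule `x`, `explain_instance()` draws `num_samples` perturbed
fingerprints, each bit sampled independently from its Bernoulli frequency
in the training matrix. The interpretable representation is agreement with
the instance (1 = same value), and each sample is weighted by the proximity
kernel exp(-D²/σ²), with D the Euclidean distance on that representation
and σ = 0.75·√1024 by default. A ridge regression (λ = 1, intercept
unpenalized) on the model's class-1 probabilities pre-fits all bits; the
`num_features` = 100 largest-magnitude coefficients are kept and refit; the
refit coefficients, clipped to [-1, 1], are the per-bit weights, and the
weighted R² of the refit is reported as local fidelity.

Two semantics matter downstream:

* A weight explains *agreement with the instance*. For a bit that is off
  in the molecule, a positive weight means "its absence supports the
  prediction". Only bits *active* in the molecule are mapped to fragments.
* One explanation is produced per molecule, for the predicted class.

## From explanations to alerts

Alert mining uses only molecules that are truly active, predicted active,
and predicted with probability ≥ 0.8 (`select_confident_actives()`) — the
alerts should summarize what the model gets *confidently right*, not its
mistakes. Each weighted active bit contributes one attribution per
environment; `molecule_verdict()` compares the positive and negative weight
sums (a molecule is a "disruptor" when the positive sum is strictly
larger); `aggregate_alerts()` drops attributions with weight ≤ 0.1, groups
by canonical fragment SMILES, counts occurrences as distinct
(molecule, fragment) pairs — so a bit collision cannot double-count one
motif in one molecule — and ranks by total weight.

Two points were genuinely open and are decided here as package policy:

* The 0.1 weight floor is applied to *individual attributions* before
  aggregation (an `floor_on = "total"` mode applies it to aggregated totals
  instead).
* The 0.8 confidence threshold applies to the forest's vote-fraction
  probability, and the predicted label for the filter comes from that
  probability at 0.5, not from the surrogate verdict; the verdict is
  reported alongside as a fidelity audit.

## The synthetic study conditions

`synthetic_spec()` defines the generative model the tests assume. Actives
are simple drug-like carriers (about 30 scaffolds, each optionally extended
by a short benign tail) decorated at a terminal carbon with one sampled
alert fragment; inactives are bare carriers. The default alert set is six
toxicophores repeatedly implicated in endocrine disruption: thiophosphate,
sulfamate ester, anilide, carbamate, sulfamide, thiocyanate. Labels flip
independently with probability `label_noise` (default 0); generation
verifies with SMARTS matching that every active contains its planted group
and no inactive contains any. The default study size is 250 actives + 250
inactives — large enough that a forest reaches cross-validated ROC-AUC
near 1 on clean data, small enough that the full pipeline runs in seconds.

What the generator deliberately does **not** emulate: realistic
chemistry-space diversity (the pool is small, so duplicates occur and are
exercised by curation), property-matched decoys, activity cliffs, or
assay noise structure beyond independent label flips. Passing the planted-
alert recovery test therefore shows the *mechanism* works — signal present
as a fragment is found and ranked first — not that real assay data are this
easy.

`inject_duplicates()` adds exact duplicates, conflicting-label duplicates
and counter-ion salts at known positions so that curation's removal counts
can be compared with the injection audit *exactly*.

## Numerical and protocol choices

* **Oversampling timing.** The default protocol oversamples the minority
  class *before* the 80/20 split, which leaks duplicated rows across the
  split and inflates internal validation scores; the package also provides
  the leakage-safe after-split mode (`upsample_timing = "after"`). The
  before/after ROC-AUC gap on noisy synthetic data (about +0.1 on average
  over 10 seeds) is itself one of the reported quantities.
* **Cross-validation** is hosted inside the 80% training portion,
  stratified; k = 5 by default, with k ∈ {3, 5, 10} stability (range
  < 0.05 on clean data) asserted in the tests.
* **Search budget.** The randomized search draws 20 configurations by
  default from trees ∈ [50, 500] and depth ∈ [1, 20]. Pipeline runs in the
  test and acceptance suites skip the search and use 300 trees of depth 19
  so each run stays within seconds; the search itself is tested separately.
* **Explainer sizes.** `num_samples` defaults to 5000 (neighborhood
  moments stable to within 3 binomial standard errors); batch runs in the
  tests use 1000, which the logistic-recovery check shows already ranks
  ten known coefficients with Spearman ≈ 0.95.
* **Determinism.** Every stochastic stage (generation, resampling, splits,
  forests, perturbation) flows from one pipeline seed; the same config
  reproduces the alert table byte for byte. Forests run single-threaded
  for exact reproducibility.
* **Degenerate inputs.** Zero-denominator metrics return 0 with a warning;
  a constant model yields a flagged, weightless explanation; an empty
  confident-active set yields a valid empty alert table.

## Known limitations

* Fragment SMILES are canonicalized per kekulized parent subgraph;
  chemically equivalent fragments extracted from differently kekulized
  contexts can in principle receive different strings. On the synthetic
  conditions this does not occur (canonical parents are fingerprinted),
  but it is a caveat for heterogeneous real data.
* The Tanimoto identity used for deduplication is implemented as canonical
  SMILES equality with an optional full pairwise fingerprint mode
  (`pairwise = TRUE`); at 2048 bits the two agree on all tested cases.
* Implicit hydrogen counts come from default valence rules covering the
  organic subset (B, C, N, O, Si, P, S, halogens); exotic elements get
  zero implicit hydrogens and a degree-based invariant only.
* Attribution weights are surrogate regression coefficients, not causal
  effects; a fragment can rank highly because it co-occurs with the true
  alert on the same molecules.
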