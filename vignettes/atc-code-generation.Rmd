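---
title: "Generating ATC codes from chemical structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating ATC codes from chemical structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The WHO Anatomical Therapeutic Chemical (ATC) classification assigns each
drug one or more hierarchical codes.  The first five characters encode four
levels: the anatomical main group (one letter), the therapeutic subgroup
(two digits), the pharmacological subgroup (one letter) and the chemical
subgroup (one letter) — `A02BC` is "alimentary tract / drugs for
acid-related disorders / drugs for peptic ulcer and GORD / proton pump
inhibitors".  Predicting these codes from chemical structure alone supports
the annotation of new compounds and the search for repurposing candidates,
without depending on interaction or side-effect databases that do not exist
for novel molecules.

`atcgen` treats the task as *generation* rather than classification: a
character-level encoder–decoder reads the SMILES string of a compound and
emits a 5-character code one character at a time.  The generative framing
handles the multilabel nature of the problem naturally — beam search
produces a ranked list of candidate codes, and a secondary *meta-model*
decides how many of them to accept per compound.

## Architectures

Both generators share the same interface: character tokenization of SMILES
and codes (two-letter element symbols are deliberately split, `"Cl"` →
`"C"`, `"l"`; spec-level atom-wise tokenization would be chemically nicer
but the conventional character-wise form is used), teacher-forced
cross-entropy training, and beam-search decoding.

**BiLSTM encoder–decoder.** The encoder runs a forward and a backward LSTM
over the embedded source characters.  Their final hidden states are
concatenated and passed through fully connected `tanh` layers to form the
initial hidden and cell states of a unidirectional LSTM decoder.  The
bridged state is *also* appended to the decoder input at every step as a
fixed context vector, in the spirit of the original RNN encoder–decoder:
design experiments showed that conditioning through the initial state alone
leaves the decoder free to drift toward marginal character frequencies,
while the per-step context feed makes the source summary available at every
emission and markedly improves generalization.  (A variant that also
concatenated the final *cell* states into the bridge was tried and
rejected: cell states are unbounded and saturate the `tanh` bridge.)

**Transformer encoder–decoder.** A standard pre-layer-norm transformer
(configurable layers, heads, feed-forward width).  The pre-LN arrangement
trains stably at small scale without a warm-up schedule.  Decoding re-runs
the decoder over the growing prefix; with targets of at most six tokens
this costs little and keeps the incremental-decoding interface uniform
across architectures.

**Multimodal fusion.** Molecular descriptors offer a complementary view of
the same structure.  For the BiLSTM, the standardized descriptor vector is
concatenated onto the combined encoder state before the bridge (so it
shapes both the decoder's initial state and the per-step context).  For the
transformer, the descriptor vector is concatenated to *every* encoder
memory position and each position is projected back to the model dimension
by a fully connected layer; per-position fusion was chosen over pooled
fusion so that cross-attention can still address individual source
positions after fusion.  In both cases the decoder interface is unchanged
from the unimodal model, and the descriptor dimensionality is recorded at
fit time and enforced at inference.

## The meta-model

Beam search yields up to ten ranked candidates per compound.  For each
training compound the package finds the *F1-optimal* number of candidates
to accept (`optimal_k()`: the smallest k in 1..10 maximizing the
per-compound F1 of exact matches; ties break toward small k, favouring
precision).  A feed-forward network with one hidden layer (default width
32) is then trained to predict that count from the vector of the ten
highest candidate log-probabilities.  Log-probabilities rather than
probabilities are used as inputs; compounds with fewer than ten distinct
candidates are padded with a sentinel of -1e9, which is clamped to -20
before entering the network (a finite "essentially impossible" value keeps
the optimisation well-conditioned).  At prediction time the per-compound
candidate list is truncated at the predicted count.

## Evaluation metrics

Two families are implemented (`compute_level_metrics()`,
`compute_exact_prf()`):

* **Exact-code precision/recall/F1** over complete 4-level codes,
  example-based: per-compound values averaged over compounds (a flag offers
  F1-of-means instead).  Example-based averaging is consistent with the
  meta-model's per-compound F1 objective.
* **Level-wise L-Precision / L-Recall**: level *n* is evaluated only on the
  compounds with at least one correct prediction at level *n*-1, and within
  a compound only on the predicted/actual codes already correct through
  level *n*-1.  Correctness at level *n* is prefix equality over the first
  1/3/4/5 characters.  Levels whose evaluation set is empty are reported as
  `NA` with an evaluated count of 0 — never as 0 — and are excluded from
  cross-seed averaging denominators.

Generated strings that do not match the ATC pattern are kept in the
predicted set and can only count as incorrect: unconstrained generation is
penalised, not silently repaired.

**A caution on sweeping k.** Exact recall and level-1 L-Recall are provably
non-decreasing in the number of generated candidates (candidate sets are
nested and their denominators fixed).  The deeper L-Recall levels are *not*
monotone in k, by construction: an extra candidate that is correct at level
*n*-1 but wrong at level *n* enlarges the actual-side survivor set
Y^n (the denominator) without adding matches, and compounds newly entering
the level-*n* evaluation set can join with low values.  The test suite
demonstrates this with a concrete fixture.  Plots of metrics against k
should therefore be read as trade-off curves, not as cumulative-gain
curves.

## Evaluation scenarios

* **New-drug split** (`new_drug_split()`): compounds are partitioned
  80/10/10 into train/validation/test, stratified on the single- versus
  multi-code indicator by largest-remainder apportionment, so no molecule
  appears in two partitions and the multi-code proportion is preserved to
  within one compound per partition.
* **Repurposing split** (`repurposing_split()`): the *code sets* are
  partitioned instead.  Single-code compounds go wholly to training; each
  multi-code compound's codes are shuffled and split with `ceiling(m/2)` to
  training and the rest to test (the odd code goes to training), so the
  model must generate held-out indications for molecules whose other
  indications it has seen.  Validation draws whole compounds from training
  (default 10%), stratified as above.

`run_experiment()` repeats split → train → generate → score over a list of
seeds (ten by default) and reports per-metric means and standard
deviations, with undefined level metrics excluded from the denominators.

## The synthetic grammar

Real dataset assembly (database merging, SMILES standardization, descriptor
computation) is supported, but all training-dependent tests run on a
synthetic grammar (`grammar_spec()`, `generate_dataset()`) built to make
every stage of the pipeline testable offline:

* source strings are random sequences over a 12-symbol alphabet with
  lengths 8–30, mimicking the scale of tokenized SMILES;
* the j-th code of a compound is read off source positions 4(j-1)+1..4j
  through fixed random permutations — one per level — so codes are exactly
  recoverable from the string and a sequence model can in principle reach
  100% accuracy on noise-free data;
* compounds carry 1–4 codes with default probabilities (0.70, 0.20, 0.06,
  0.04): most compounds have a single code, a minority several, matching
  the qualitative shape of curated ATC annotations;
* descriptor vectors (default 16 features, a desk-scale stand-in for the
  ~1100 descriptors of a full pipeline) noisily encode the first eight
  code-bearing positions plus pure-noise nuisance features;
* with `descriptor_only_signal = TRUE` the level-4 letter of every code is
  driven by a latent variable visible only through the last descriptor
  feature — a string-only model cannot beat chance at level 4, which is
  precisely the situation descriptor fusion is meant to exploit;
* `noise_rate` corrupts one level segment per code with the given
  probability, for robustness experiments.

What the grammar does *not* emulate: chemical validity, the skewed and
sparse class distribution of real ATC data, correlated descriptors, and
inter-database annotation conflicts.  Passing tests on the grammar
demonstrate that the machinery — tokenization, training, fusion, beam
search, count selection, metrics — works and that the architectures can
extract string- and descriptor-borne signal at desk scale; they do not
certify accuracy levels on real compound collections.

## Numerical and training choices

* Optimiser: Adam (lr 3e-3 default; 5e-3 for the BiLSTM and 2e-3 for the
  transformer in the bundled experiments), decoupled weight decay on
  matrices only, global gradient-norm clipping at 5, LSTM forget-gate bias
  initialised to 1, Glorot-uniform weight initialisation.
* Early stopping on validation loss (patience 10 by default; training loss
  is used when no validation set is supplied), with the step size halved
  each time the plateau persists for half the patience.
* Batches are length-bucketed (shuffle, stable sort by source length,
  shuffle batch order) to keep padding waste low; padded positions carry
  the previous LSTM state through and are masked out of the loss.
* Beam search uses total sequence log-probability with no length
  normalisation (targets are near-constant length); zero-probability
  continuations are pruned; beam width >= |vocabulary|^max_len makes the
  search exhaustive, which the tests exploit against an enumeration oracle.
* Descriptor pruning drops all-missing and constant columns, then walks
  columns in order keeping those whose absolute Pearson correlation with
  every kept column is at most 0.95 (a common cheminformatics default;
  keep-first makes the result deterministic).  Missing values are imputed
  with training-row medians; columns are centred and scaled by
  training-row mean and population standard deviation (zero spread scales
  by 1).
* SMILES standardization removes monatomic counterions, neutralizes
  charges and canonicalizes via Open Babel, behind a syntactic screen that
  rejects malformed inputs the toolkit would silently "repair"; one
  canonical dialect is used for all sources so string equality after
  standardization is chemically meaningful within that dialect.
* All randomness flows from explicit integer seeds through a single
  derivation function; training, splitting, sampling and experiments are
  bitwise reproducible for a fixed seed.

All backpropagation is hand-derived matrix code (no neural framework is
among the dependencies) and is verified against central finite differences
in the test suite for every parameter group of both architectures,
including the fusion layers.

## Problem sizes in the bundled checks

The training-based tests and the acceptance script use fixtures of 500
compounds with an 80/10/10 (or 70/10/20) split, 60–80 training epochs for
the BiLSTM and 25–40 for the transformer, and beams of width up to 10 —
sizes chosen so a full run completes comfortably on a single CPU while
leaving each property clearly resolvable.

## Known limitations

* The level-wise recall metrics are not monotone in the candidate count
  (see above); this is a property of the metric definitions, not of the
  implementation.
* The BiLSTM is the weaker of the two generators at the deeper levels on
  the synthetic grammar at these training budgets; the transformer's
  cross-attention reaches positional signal more easily.
* Atom-wise tokenization, grammar-constrained decoding, and pretrained
  chemical language models are deliberately out of scope.
* The meta-model conditions only on candidate log-probabilities, not on
  the compound itself; compounds with identical score profiles receive the
  same count.
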