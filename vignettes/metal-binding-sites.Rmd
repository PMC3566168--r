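---
title: "Identifying metal-binding cysteine and histidine residues: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying metal-binding cysteine and histidine residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and assumptions

`metalbindr` classifies individual cysteine and histidine residues in
electron transport proteins as metal-binding or not. The two residue types
are modelled separately, and the negative class for each model is the
non-binding residues of the *same* type — a histidine is never a negative
example for the cysteine model. This matters: the question the classifier
answers is "is *this* cysteine a ligand?", not "is this residue a
cysteine?", and mixing residue types would let the trivial identity signal
dominate.

The method assumes that metal coordination leaves two detectable signatures
in a 13-residue sequence window centred on the candidate: (i) an
evolutionary one — ligand positions and their immediate neighbourhood are
conserved, which a PSI-BLAST position-specific scoring matrix (PSSM)
captures; and (ii) a combinatorial one — specific residue pairs at specific
offsets (a second coordinating cysteine four positions upstream, a proline
kink next door) recur around true sites far more often than chance.

## Window extraction and encodings

Each candidate position yields a window of width `2w + 1` with `w = 6`.
Windows overhanging a terminus are padded with `X`; the padding symbol is
confined to a contiguous prefix/suffix and the centre is never padding.
Padding positions contribute an **all-zero row** to every encoding — a
deliberate neutral-contribution choice, distinct from every real residue's
row, since nothing is known beyond the terminus. Two annotated sites close
enough for their windows to overlap are extracted independently; neither
masks the other.

Four encodings produce a `13 × 20 = 260`-vector (columns always in the
PSI-BLAST amino-acid order `A R N D C Q E G H I L K M F P S T W Y V`):

| encoding   | row for residue *a* at window position *t*                          |
|------------|---------------------------------------------------------------------|
| `AA`       | one-hot indicator of *a*                                            |
| `BLOSUM62` | BLOSUM62 row of *a*, min–max rescaled to [0, 1] over the 20×20 block |
| `PAM250`   | PAM250 row of *a*, same rescaling                                   |
| `PSSM`     | logistic-squashed profile row of the underlying sequence position   |

Two of these involved genuine design decisions:

* **PSSM scaling.** Raw profile scores are integer log-odds, unbounded in
  principle. They are squashed with the logistic `1/(1 + e^(−x))` — the
  standard squashing for profile-encoded feature vectors, strictly
  increasing, mapping 0 to 0.5 and all real scores into (0, 1). It is
  exposed as the `scale_fun` hook of `encode_window()` should a different
  squashing be preferred. The package reads the log-odds block of
  PSI-BLAST's ASCII output (the first 20 numeric columns), not the
  weighted-percentage block.
* **Substitution-matrix scaling.** BLOSUM62 and PAM250 rows are rescaled by
  a *global* min–max over the whole 20×20 matrix (not per-row), so that all
  four encodings inhabit the same [0, 1] range and a single kernel
  bandwidth remains sensible across encodings. The matrices themselves come
  from Biostrings.

## Significant amino-acid pairs (SAAPs)

For every ordered pair of non-centre offsets `i < j` in `[-6, 6] \ {0}` and
every residue combination observed there, the miner counts `n` — windows
containing the pair — and `x` — positive windows containing it. Counting is
per-window membership (a window either has the pair or not); padding never
matches; the centre offset is excluded because it is constant within a
model's dataset. With `N` windows overall and `M` positives, the enrichment
p-value is the hypergeometric upper tail `P(X ≥ x)`: the probability that a
pair carried by `n` windows would land in at least `x` positives if
windows were exchangeable.

The upper-tail sum is the natural reading of an *enrichment* test; the
point-mass probability `P(X = x)` is also available
(`saap_pvalue(..., type = "point")`) since published per-pair p-values of
this kind are sometimes point masses and the distinction cannot always be
recovered from a printed table. Pairs with `p < α` (default `α = 0.05`,
chosen so that the weakest pairs a practitioner would still report, around
`p ≈ 2 × 10⁻²`, survive) are ranked ascending with a deterministic
lexicographic tie-break on `(offset1, aa1, offset2, aa2)`. No
multiple-testing correction is applied — the ranking feeds a selection
step that controls how many pairs are actually used, which is the
operative safeguard. Tail p-values are verified in the test suite against
an exhaustive subset-counting dynamic programme (exact in doubles up to
`N = 30`), an independent computational path from the distribution
functions used in the implementation.

## The RBF network

The classifier realises

$$g_j(q) = \sum_{i=1}^{k} w_{ij}\, \exp\!\left(-\frac{\lVert q - \mu_i \rVert^2}{2\sigma^2}\right)$$

with **every training vector as a centre** and a **fixed bandwidth
σ = 5**. The bandwidth convention — σ appearing as `2σ²` in the
denominator — is stated explicitly because "bandwidth 5" alone is
ambiguous across RBFN implementations; σ is an ordinary argument should a
different convention be needed. Targets are one-hot rows per class and the
weights solve a linear least-squares system:

* `ridge = 0`: the square kernel system `Φ W = T` is solved directly, and
  the network *interpolates* its training labels whenever the training
  points are distinct — a property the tests exercise exactly.
* `ridge = λ > 0` (default `1e-8`): the normal equations
  `(ΦᵀΦ + λI) W = Φᵀ T` are solved instead. The all-centres design matrix
  is square and can be numerically ill-conditioned (262 000 kernel entries
  all close to 1 when windows are similar), and the tiny ridge makes
  training robust to near-duplicate or duplicated rows without measurably
  moving predictions.

Prediction takes the argmax output node; an exact tie classifies as
non-binding, the conservative direction for a screening tool (a false
positive sends a curator to the bench; a tie carries no evidence).
Squared distances are computed by the usual inner-product expansion with
negative cancellation residues clamped to zero. Models serialise to a
self-describing JSON archive (format version, centres, weights, σ, λ,
residue type, feature specification, training accessions) written at 17
significant digits, so a round-trip is bit-exact.

## Evaluation protocol

Cross-validation is 10-fold, **stratified by label at the residue level**
and driven by a single recorded seed; fold sizes within each class differ
by at most one. (Whether folds should be stratified, or drawn at the
protein level, is genuinely open for this family of methods; residue-level
stratified is the default here because the positive class is small and an
unstratified split can leave folds with no positives at all.) Predictions
are pooled over folds into one confusion matrix, from which sensitivity
`TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, accuracy
and the Matthews correlation coefficient are computed. A zero denominator
reports the metric as `NA` with an `undefined` flag — never silently as 0.
Display rounding is one decimal for percentages and two for the MCC; full
precision is kept internally.

When SAAP features are used inside cross-validation, `run_cv()` defaults to
`saap_scope = "fold"`: the catalog is re-mined and re-ranked inside each
fold's *training* split, so the test fold never influences feature
construction. The traditional protocol — mining once on the full dataset
before splitting — is available as `saap_scope = "global"` with an explicit
catalog, because published results of this kind are usually produced that
way and reproducing them requires the leaky variant; the leak-free scope is
the default precisely because the global one overstates performance.
`run_cv()` records which rows were visible to mining in each fold, and the
tests assert the test fold is never among them.

Forward selection (`forward_select_saaps()`) adds ranked pairs one at a
time, records pooled CV accuracy after each addition, and returns the
prefix length `k*` maximising accuracy with ties broken towards the
*smallest* prefix — an uninformative catalog therefore selects `k* = 0`.
Pooled accuracy (rather than the mean of per-fold accuracies) is the
selection criterion; with stratified near-equal folds the two differ only
in weighting, and the pooled count is the quantity reported everywhere
else. `max_k` bounds the search; 25 — the length of a typical published
top-pair table — is used in the package's own validation runs.

Independent-test evaluation (`run_independent_test()`) refuses any
accession shared between training and test records, naming the offenders.

## The synthetic data generator

Real datasets of this kind require UniProt retrieval, BLAST-based
redundancy culling and PSI-BLAST profile computation against NR, none of
which belongs in a test suite. The generator (`synth_config()` /
`generate_synthetic()`) instead emulates the *statistical structure* the
method relies on, at the shape of a typical curated training set:

* **44 proteins** of 100–200 residues, i.i.d. background composition
  (uniform by default, configurable), carrying **80 positive** and **280
  negative** designed sites of one residue type on non-overlapping window
  slots.
* **Planted pairs**: by default the single pair (−4C, +1P), written into
  positive windows with probability 0.8 and negative windows with
  probability 0.05. Enrichment must be ≥ background by construction.
* **Profiles**: every position gets a conservation level `c ~ Beta(1, 4)`
  (mostly weakly conserved, emulating generic purifying selection).
  Within ±1 of a positive centre, conservation is raised to
  `1 − (1 − c)·e^(−s)` where `s` is `pssm_signal` (default 2): the
  coordination neighbourhood looks strongly conserved. The position's
  generating distribution is the conservation-weighted mixture of
  background and a point mass on the actual residue; a multinomial sample
  of `profile_depth = 25` pseudo-observations plus background pseudocounts
  yields the estimated frequencies, and integer scores
  `round(2·log(p̂/bg))`, clipped to [−10, 13], mimic PSI-BLAST's ASCII
  output. `pssm_signal = 0` therefore produces profiles with realistic
  sampling noise but **no class information** — the null configuration.
* **Conserved decoys**: 18% of designed negatives (`decoy_rate`) receive
  the same conservation boost as positives while carrying planted pairs
  only at the background rate. These model structurally conserved
  non-binding residues — disulfide cysteines, catalytic histidines — and
  are the reason profile features alone plateau around 90% accuracy on the
  default data while pair features push beyond it. Without decoys the
  profile encoding is perfectly separable and the selection step would
  have nothing to do; the 18% fraction was fixed during generator design
  so that the default conditions exhibit both regimes (a strong but
  imperfect profile signal, and a genuine incremental value of pair
  features), and it is an ordinary config knob.

All randomness flows through one seed; the same seed reproduces every file
byte for byte. `write_synthetic()` emits exactly the formats the toolkit
consumes (FASTA, annotation TSV, per-protein PSI-BLAST-dialect PSSM files,
JSON-lines manifest of every designed site).

What the generator does **not** emulate: homology and phylogenetic
correlation between proteins (every sequence is independent), realistic
residue composition and hydrophobicity patterns, genuine PSI-BLAST search
behaviour, multi-metal coordination geometry, or annotation noise. Passing
the synthetic end-to-end checks therefore demonstrates that the pipeline
recovers the signal classes it models — enriched pairs and localised
conservation — at realistic sizes and noise levels; it does not certify
accuracy figures on real proteins, which depend on retrieval and profile
construction outside the package's scope.

## Validation runs and problem sizes

The package's own validation (test suite plus `scripts/acceptance.R`) uses:
published confusion-count rows for the metric arithmetic; all valid
hypergeometric tuples up to `N = 30` against the subset-counting oracle;
100 random separated training sets for exact interpolation; 25 random
instances for the kernel-sum oracle at `1e-10`; 20 seeds of the default
strong-signal generator for end-to-end recovery (mine → select → train →
pooled 10-fold CV, expecting ≥ 90% accuracy with the planted pair inside
the selected prefix in ≥ 90% of seeds); and 50 + 200 seeds of the
`pssm_signal = 0` null for calibration. On the null, the ensemble-mean
pooled CV MCC must sit within ±0.1 of zero (a single 360-site
cross-validation has sampling noise of roughly ±0.07, so the mean across
seeds, not each seed, is the calibrated quantity), and the planted pair's
p-values must be uniform by a Kolmogorov–Smirnov test at the 1% level. The
KS check uses the standard randomisation device for discrete tests —
`P(X > x) + U·P(X = x)` — because a discrete tail p-value is conservative
by construction and no implementation could make the raw values exactly
uniform.

One published value deserves a note: the independent-test row for the
cysteine model (TP 22, FP 4, TN 25, FN 0) implies an accuracy of
47/51 = 92.2% at one-decimal rounding, while the source table prints
92.3%; all other printed values in those tables follow exactly from their
counts. The package reports the value its arithmetic produces.

## Preparing real data (recipe)

The package deliberately does not fetch or align anything. To build a real
dataset: retrieve electron transport proteins with experimentally verified
metal-binding annotations (protein-level evidence) from UniProt; cull
redundancy to < 20% pairwise identity with BLAST; write one FASTA plus an
annotation TSV (`protein_id  position  residue  metal`, 1-based positions);
and compute one profile per sequence with
`psiblast -num_iterations 3 -db nr -out_ascii_pssm <id>.pssm`. The files
then load with `read_fasta()`, `read_annotations()` and `load_pssm_dir()`.

## Known limitations

* The all-centres network is O(n²) in training sites; it is meant for
  curated datasets (hundreds of residues), not proteome scans.
* Binary SAAP indicators perturb the Gaussian kernel by at most one unit of
  squared distance, so their influence is inherently gentle at σ = 5; many
  correlated pairs, or a smaller bandwidth, amplify them.
* A window of ±6 cannot see cross-domain coordination partners.
* Selection maximises raw accuracy, which under-weights the minority class;
  on heavily imbalanced data selecting on MCC would be preferable.
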