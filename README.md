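# metalbindr

Prediction of metal-binding cysteine and histidine residues in electron
transport proteins.

## The problem

Electron transport chains move electrons through oxidation–reduction
reactions in which protein-bound metal ions (Fe in complexes I–III, Cu in
complex IV) act as donors and acceptors. The metals are coordinated almost
exclusively by cysteine and histidine side chains, so the practical
question for a curator or structural biologist is: *given a new electron
transport protein, which of its C and H residues bind a metal ion?*

`metalbindr` answers this as residue-level binary classification. It is
aimed at bioinformaticians who have sequences, per-residue binding
annotations (for training), and PSI-BLAST profiles, and who want a small,
fully reproducible pipeline rather than a web service.

## The method

Every candidate residue (each C, or each H — the two residue types are
modelled separately, and the negative class for a model is the non-binding
residues of the *same* type) is represented by its 13-residue window
(6 flanking positions each side, `X`-padded at termini). A window encodes
to a 13 × 20 = 260-dimensional feature vector under one of four schemes:
residue identity (one-hot), BLOSUM62 or PAM250 rows (min–max rescaled to
[0, 1]), or the PSI-BLAST PSSM rows of the corresponding positions squashed
by the logistic 1/(1 + e^(−x)).

On top of the window encoding, *significant amino acid pairs* (SAAPs) are
mined: for every pair of residues (a₁ at offset i, a₂ at offset j),
i < j ≠ 0, occurring in n of the N training windows and x of the M positive
windows, the enrichment p-value is the hypergeometric upper tail

    p = Σ_{k ≥ x} C(M, k) · C(N − M, n − k) / C(N, n).

Pairs with p < α (default 0.05) are ranked by p-value, and a greedy forward
selection over 10-fold cross-validation picks the prefix length k* that
maximises accuracy; the chosen pairs join the feature vector as binary
indicators.

The classifier is a Gaussian radial basis function network of the
all-centres, fixed-bandwidth kind: every training vector is a kernel centre
with bandwidth σ = 5,

    g_j(q) = Σ_i w_ij · exp(−‖q − μ_i‖² / (2σ²)),   j ∈ {binding, non-binding},

with output weights solved as a (optionally ridge-stabilised) linear
least-squares fit against one-hot class targets. Prediction is the argmax
output node; exact ties resolve to non-binding. Performance is reported as
sensitivity, specificity, precision, accuracy and Matthews correlation
coefficient from the pooled cross-validated confusion matrix, or from an
accession-disjoint independent test set.

A seeded synthetic-data generator emulates the statistical structure of an
annotated dataset (background composition, planted enriched residue pairs,
conservation-shaped PSSM profiles with sampling noise, conserved non-binding
decoys), so the entire pipeline is testable offline; see the methods
vignette in `vignettes/`.

## Worked example

```r
library(metalbindr)

syn     <- generate_synthetic(synth_config(seed = 42))   # 44 proteins, 80 binding C
sites   <- syn$sites
catalog <- mine_saaps(syn$records, sites, alpha = 0.05)
head(as.data.frame(catalog), 3)
#>   offset1 aa1 offset2 aa2  n  x      p_value
#> 1      -4   C       1   P 82 68 2.338121e-46
#> 2      -6   V       1   P 10 10 1.853824e-07
#> 3      -4   C       6   L  9  9 9.164677e-07

plan <- make_cv_plan(sites, k = 10, seed = 42)
sel  <- forward_select_saaps(syn$records, sites, catalog, plan,
                             encoding = "PSSM", profiles = syn$profiles, max_k = 25)
run_cv(syn$records, sites, plan, encoding = "PSSM", profiles = syn$profiles)$metrics
#> TP=64 FP=16 TN=264 FN=16
#> Sensitivity 80.0%  Precision 80.0%  Specificity 94.3%  Accuracy 91.1%  MCC 0.74
run_cv(syn$records, sites, plan, encoding = "PSSM", profiles = syn$profiles,
       n_saaps = sel$k_star, saap_scope = "fold")$metrics
#> TP=68 FP=10 TN=270 FN=12
#> Sensitivity 85.0%  Precision 87.2%  Specificity 96.4%  Accuracy 93.9%  MCC 0.82
```

The mined catalog is headed by the planted pair (−4C, +1P): a cysteine four
positions before the candidate plus a proline directly after it, present in
68 of the 80 binding windows. Adding the selected SAAP indicators to the
PSSM encoding raises pooled 10-fold CV accuracy from 91.1% to 93.9% and MCC
from 0.74 to 0.82 on this dataset — pair features recover the conserved
non-binding decoys that profile features alone cannot separate.

A fitted model is an ordinary S3 object:

```r
fit <- metalbind(syn$records, residue = "C", encoding = "PSSM",
                profiles = syn$profiles, saaps = head(catalog, sel$k_star))
fit
#> Metal-binding cysteine classifier (PSSM + 1 SAAPs): 746 centres, sigma = 5
predict(fit, syn$records, profiles = syn$profiles)   # per-site decision values
```

with `summary()`, `coef()`, `predict()` methods and a bit-exact JSON archive
(`write_rbfn()` / `read_rbfn()`). A command-line interface with subcommands
`simulate`, `mine-saaps`, `train`, `predict` and `evaluate` is installed
under `exec/metalbindr`.

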