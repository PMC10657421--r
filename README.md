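# guidefp

Interaction-fingerprint scoring and optimization of CRISPR-Cas9 guide RNAs.

## The problem

Cas9 tolerates several mismatches between its guide RNA and genomic DNA, so
a guide can cleave unintended loci (off-targets). Sequence-only encodings
discard most of what distinguishes a tolerated mismatch from a disruptive
one. `guidefp` works instead from a *per-base-pair-type interaction feature
table*: for each of the 16 RNA-DNA base-pair types (4 guide bases x 4
target bases, match and mismatch) it stores engineered physical descriptors
of the hybrid duplex — hydrogen bonding, binding free-energy terms, atom
positions, and base-pair/step geometry — of the kind measured from
molecular-dynamics simulations of short RNA-DNA hybrids. The package is
aimed at computational biologists designing or auditing SpCas9 guides.

## What it computes

- **Fingerprint encoding.** A 20-bp guide/off-target pair is encoded
  position by position with the feature table: with the canonical
  193-feature table, a fingerprint of 20 x 193 = 3860 values (position 1 =
  PAM-distal). One-hot (320-bit) and two-hot (160-bit) sequence baselines
  are included.
- **Candidate search.** Exhaustive two-strand genome scanning for 20-mers
  with an NGG-matching PAM and at most *k* mismatches (default 6), BED-style
  0-based coordinates.
- **Classification.** Cross-validated XGBoost ensembles over fingerprints,
  with leave-group-out (site-level) or leave-sgRNA-out (guide-level) splits,
  positive-class weighting for the extreme imbalance of candidate sets, and
  rank-statistic ROC-AUC / step-integrated PR-AUC evaluation.
- **Score map.** Tree-SHAP attributions are aggregated into a per-position,
  per-base-pair-type score map: at each position *i* the top *N* = 24
  features by mean-|SHAP| are selected and the map entry for type *RD* is
  the sum of their type-conditional mean attributions
  `S_{RD,i} = sum_j mean(SHAP_ij | type RD at i)`. A pair's raw score is
  the separable sum `S = sum_i S_{RD(i),i}`, reported as the affine
  calibration `score = aS + b` with `a, b` chosen exactly from the
  per-position extrema so the achievable range is exactly [0, 1].
- **Specificity.** Scored genome-wide candidates are counted in twenty
  0.05-wide score bins (`N_k`), weighted by per-bin active-off-target
  probabilities (`P_k`), and aggregated as
  `P_off = sum_k N_k P_k`, `spec = 10 / (10 + P_off)` in (0, 1].
- **Guide optimization.** All 60 single-nucleotide guide mutants are scored
  against the intended target; mutants above a score floor (default 0.85)
  are re-evaluated genome-wide and ranked by specificity.
- **Synthetic data.** Seeded generators for feature tables, genomes with
  planted sites, imbalanced labeled candidate sets with a known
  position-weighted mismatch model, and bin-probability tables make the
  whole pipeline testable without external downloads.

## Worked example

```r
library(guidefp)

tab  <- canonical_feature_table()          # 193 engineered features
fp   <- encode_pair("GAGTCCGAGCAGAAGAAGAA",
                    "GAGTCCGAGCAGAAGAAGAT", tab)
length(fp)
#> [1] 3860

## train on a synthetic imbalanced candidate set
d    <- simulate_offtarget_dataset(n_guides = 20, candidates_per_guide = 250,
                                   prevalence = 0.05, seed = 1)
plan <- split_dataset(d, "lgo", k = 5, seed = 1)
ens  <- train_ensemble(d, plan, encoder = "fp", table = tab,
                       nrounds = 100, seed = 1)
m    <- evaluate_scores(predict_heldout(ens, d, tab), d$label)
round(unlist(m), 3)
#> roc_auc  pr_auc
#>   0.929   0.428

## SHAP-derived score map, calibrated to [0, 1]
map  <- calibrate_score_map(build_score_map(shap_summary(ens, d, tab),
                                            top_n = 24))
ot_score("GAGTCCGAGCAGAAGAAGAA", "GAGTCCGAGCAGAAGAAGAT", map)
#> [1] 0.9394524

## specificity over a genome and single-nucleotide optimization
genome <- simulate_genome(100000, seed = 3)
prob   <- simulate_prob_table(seed = 1)
ot_spec("GAGTCCGAGCAGAAGAAGAA", map, prob, genome = genome)$spec
opt    <- optimize_guide("GAGTCCGAGCAGAAGAAGAA", map = map, prob = prob,
                         genome = genome, score_threshold = 0.85)
```

The held-out ROC-AUC of 0.929 and PR-AUC of 0.428 (9.6x the 4.5% realized
active fraction) are what the `seed = 1` run above prints; the score map
built from the same ensemble ranks unseen candidates with a strong
negative rank correlation against mismatch count (Spearman -0.837 on a
fresh simulated candidate set), recovering the PAM-proximal mismatch
weighting planted by the generator.

A command-line front end covering the same operations is installed at
`system.file("scripts", "guidefp", package = "guidefp")`:

```sh
guidefp simulate genome --seed 1 --length 100000 --out ref.fa
guidefp search --genome ref.fa --guide GAGTCCGAGCAGAAGAAGAA --max-mm 6 --out sites.tsv
guidefp spec --guide GAGTCCGAGCAGAAGAAGAA --genome ref.fa --map map.tsv --prob prob.tsv
```

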