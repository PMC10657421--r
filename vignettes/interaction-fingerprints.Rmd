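---
title: "Interaction fingerprints for CRISPR off-target scoring: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction fingerprints for CRISPR off-target scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidefp)
```

## The model

Cas9 cleavage depends on the stability and geometry of the RNA-DNA hybrid
formed between the 20-nt guide spacer and the protospacer. `guidefp`
represents a guide/off-target pair through the physics of that hybrid
rather than through sequence identity alone. The core object is a
*feature table*: one engineered value per interaction feature for each of
the 16 RNA-DNA base-pair types. The guide base is written in the DNA
alphabet (U mapped to T on ingest) and the off-target base is the
protospacer-strand base in guide orientation, so a Watson-Crick pair is a
letter match and a mismatch is any of the 12 non-identical combinations.

A pair is encoded position by position: the fingerprint slot
`(i - 1) * F + j` holds feature *j* of the base-pair type at position *i*
(position 1 PAM-distal, 20 PAM-proximal). With the canonical 193-feature
table this gives a 3860-dimensional, position-dependent fingerprint. The
PAM is deliberately not encoded; it acts as a hard constraint in the
candidate search instead.

### From raw hybrid measurements to the table

The engineering pipeline (`engineer_features()`) assumes raw measurements
over 256 3-bp hybrid contexts: every central base-pair type flanked by
each of the 4 x 4 Watson-Crick matches, embedded in fixed rG-dC padding
(`design_hybrids()` enumerates the panel). The steps, in order:

1. **Angles to (sin, cos).** Angle-valued features (degrees) are expanded
   to a sine/cosine pair *per context, before any averaging*. Averaging
   raw degrees across contexts is exactly the circular-statistics failure
   this transform exists to avoid (two contexts at 359 and 1 degree must
   not average to 180), so the transform precedes the mean even though
   either order is equivalent when angles are homogeneous.
2. **Mean over flank contexts.** Each central type's value is the
   arithmetic mean over its 16 flank contexts; the flanks are treated as
   nuisance variation.
3. **Rescaling.** Non-angle features are min-max rescaled to [-1, 1]
   across the 16 type means. The 16 means are the only values that ever
   enter a fingerprint, so they are the natural scaling population.
   Sin/cos components already live in [-1, 1] and are left untouched so
   they keep their geometric meaning.
4. **Variance filter.** Features with variance below 0.01 across the 16
   types carry no discriminative signal between base-pair types and are
   dropped. The filter runs *after* the transform and scaling, so the
   threshold has a single well-defined scale; applying it before scaling
   would make the cut depend on arbitrary raw units.

### The classifier

`train_ensemble()` fits one XGBoost classifier (gbtree, logistic
objective) per cross-validation fold and predicts with the fold-mean
probability. Two split modes ask different generalization questions:
leave-group-out (`lgo`) stratifies individual sites on the label, testing
generalization to unseen *sites* of known guides; leave-sgRNA-out (`lso`)
assigns whole guides to folds, the stricter test of transfer to unseen
guides. Candidate universes are extremely imbalanced (well under 1%
active in real genome-wide screens), so each fold weights positives by
its negatives/positives ratio by default. The default hyperparameters —
depth 6, eta 0.3, 100 rounds, hist method, single thread — are a small,
documented compromise between fit quality and determinism; all are
overridable through `params`. Single-threaded training plus a per-fold
seed makes retraining bit-reproducible.

ROC-AUC is computed from the Mann-Whitney rank statistic with average
ranks for ties; PR-AUC by step integration over unique score thresholds,
which yields exactly the prevalence for constant scores. Both are checked
in the test suite against brute-force oracles (exhaustive pairwise
comparison; hand-stepped precision-recall) and, for ROC, against pROC.

### From attributions to a score map

Tree SHAP decomposes each fold model's margin into per-slot attributions.
`shap_summary()` averages attributions across fold models and aggregates:

- `importance[j, i]`: mean |attribution| of feature *j* at position *i*
  (column sums give per-position importance);
- `per_type_mean[i, t, j]`: mean *signed* attribution among the samples
  that carry base-pair type *t* at position *i*.

`build_score_map()` selects, per position, the `top_n = 24` features by
importance (ties broken by catalogue order, so selection is deterministic)
and sums their type-conditional mean attributions into a 20 x 16 map. The
conditional mean — rather than a mean over all samples — is used because a
feature's attribution when type *t* is absent says nothing about *t*;
cells for types never observed at a position contribute 0. The
aggregation is a sum of means, which keeps the pair score separable
across positions.

### Calibration

Because the pair score is a sum of independent per-position lookups, its
extrema over all 20-position type assignments are exact:
`S_min = sum_i min_t S[i, t]`, `S_max = sum_i max_t S[i, t]`. Setting
`a = 1 / (S_max - S_min)` and `b = -S_min / (S_max - S_min)` maps the
achievable range onto exactly [0, 1], both endpoints attained. This is a
choice: any affine map to [0, 1] would do, and externally released maps
may ship different constants — `read_score_map()` loads `a`, `b` from the
JSON sidecar, so an external calibration can be dropped in unchanged.

### Specificity and optimization

Scored candidates are counted in twenty half-open bins of width 0.05 (the
final bin closed, so a score of exactly 1 is counted). Bin edges are
computed as exact divisions `k/20`, not accumulated sums — with
`seq(0, 1, 0.05)` the 0.95 edge exceeds the double representation of 0.95
and misbins boundary scores. `estimate_prob_table()` estimates per-bin
active probabilities as the unweighted mean of per-dataset active
fractions, skipping datasets with no sites in a bin; bins empty
everywhere default to probability 0 (no evidence of activity).

The aggregate `P_off = sum_k N_k P_k` is an expected count of active
off-targets; `spec = 10 / (10 + P_off)` compresses it into (0, 1]. Zero
candidates give spec 1; 40 candidates in a bin with probability 0.25 give
`P_off = 10` and spec 0.5; every additional candidate in a
positive-probability bin strictly lowers spec. The intended on-target
locus is excluded by genomic coordinates, not by mismatch count, so the
intended site of a *mutated* guide (which carries one mismatch) is still
excluded correctly.

`optimize_guide()` enumerates the 60 single-nucleotide mutants, keeps
those scoring at least `score_threshold` against the intended target
(default 0.85; 0.8 is the lowest floor still expected to cleave
reliably), re-evaluates each survivor genome-wide, and ranks by
specificity (ties: score, then label). By default each mutant's candidate
universe is re-searched, since a mutant can match sites the wild-type
search never reported; `reuse_candidates = TRUE` trades that correctness
for speed on large genomes.

## The synthetic-data layer

The generators exist so the full pipeline is exercisable and testable
without external sequencing data or simulation output. What they emulate,
and what they do not:

- `simulate_feature_table()` reproduces the *structure* of an engineered
  table — 193 features in the canonical category split (1 hydrogen-bond,
  42 binding-energy, 114 atom-position, 36 geometry), values in [-1, 1],
  matches systematically offset from mismatches — but its values are
  draws, not physics. Conclusions about which *real* interactions matter
  cannot come from it.
- `simulate_genome()` draws i.i.d. bases at a target GC fraction (default
  0.41, the human genome-wide value) and supports planting sites on
  either strand. It has no repeats, chromatin or composition structure,
  so real genomes will contain more near-duplicate candidates than it
  does.
- `simulate_offtarget_dataset()` draws, per guide, candidates with 0-6
  mismatches and labels them from a logistic latent model
  `plogis(intercept - sum(weights[pos]) + noise)`. The default position
  weights ramp linearly threefold (0.8 to 2.4 logits per mismatch) toward
  the PAM-proximal end, encoding the seed-region effect with a known
  direction so recovery tests can assert it. The weight *scale* was set
  once so the generator's own ground truth (the latent probability)
  achieves a held-out ROC-AUC near 0.95 at the default prevalence — a
  learnability ceiling comfortably above the 0.9 the recovery tests
  demand, while the Bernoulli labels and logit noise keep the task
  non-trivial. The intercept is root-solved per draw so realized
  prevalence matches the target (default 5%). Real activity depends on
  mismatch *identity* and position interactions, not position alone;
  models trained on this generator recover positions, which is what the
  tests assert, and nothing more.
- `simulate_prob_table()` produces a monotone bin-probability curve with
  the empirical shape of calibrated scores: essentially zero below 0.5,
  above 0.9 beyond a score of 0.8.

Every generator draws from a stream derived from `(seed, generator
name)`, so adding a generator never perturbs another's output, and all
are bit-reproducible per seed.

Passing the recovery tests therefore shows the pipeline is internally
consistent — encoder, learner, attribution, map and aggregation connect
correctly and recover planted structure. It does not certify performance
on real Change-seq/Site-seq-style data, which requires the externally
measured feature table and labeled screens.

## Problem sizes and determinism

The shipped tests run the recovery study at 5,000 candidates over 20
guides (5% prevalence, 5-fold splits, 100 boosting rounds) and the
search-oracle comparison on a 100-kb genome — sizes chosen so the whole
suite completes in a few minutes on one core while keeping the positive
class large enough (about 250 sites) for stable AUC estimates. All
randomized steps take explicit seeds; XGBoost runs single-threaded with a
per-fold seed.

Degenerate inputs are handled explicitly rather than silently: single-class
training folds, degenerate (constant) score maps, empty candidate sets,
unattainable target prevalences, and uncalibrated maps all raise
descriptive errors or warnings.

## Known limitations

- NGG PAMs only, and no DNA/RNA bulges: the candidate search counts
  letter mismatches over fixed-length windows. Alternative PAMs (NAG/NGA)
  and bulged alignments are out of scope.
- The fingerprint ignores the PAM and any epigenetic context (chromatin
  accessibility, methylation); two sites with identical protospacers are
  indistinguishable.
- The per-type table is position-independent at encoding time;
  position-dependence enters only through the learner and the score map.
- The packaged canonical table is simulated. Scientific use requires
  substituting a measured table via `read_feature_table()`.
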