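---
title: "Predicting combinative drug pairs by fusing heterogeneous drug features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting combinative drug pairs by fusing heterogeneous drug features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combifuse)
```

## The problem

A *combinative drug pair* is two individual drugs co-administered for a
synergistic therapeutic effect — the standard of care for many complex
diseases whose pathology involves multiple genes and pathways. Approved
combinations are scarce and expensive to establish, so the screening
question is a ranking problem: among all candidate pairs over a drug
universe, which look most like the approved ones? Crucially, realistic
screening includes *new* drugs — drugs with no approved combination at
all — so an evaluation that only ever tests pairs of already-combined
drugs overstates practical performance. This package implements a
drug-driven predictor, its scenario-aware evaluation, and the diagnostics
that motivate its feature channels.

## Data model

A `drug_universe` holds, per drug: a set of first-level WHO ATC codes
(letters from the 14-letter anatomical-main-group alphabet), a binary
drug–target interaction (DTI) profile, and a binary side-effect (SE)
profile. A `ddi_network` is a symmetric, zero-diagonal binary adjacency of
*pharmaceutical* drug–drug interactions — unwanted physical/chemical
incompatibilities. This network is an attribute of the drugs, not a label:
it is distinct from, and largely disjoint with, the combination pairs.
A `pair_labels` object carries the approved pairs (positives) and the
candidate scope; every scope pair outside the positives is treated as a
negative, the conventional (if noisy) closed-world assumption for this
problem. Drug order is lexicographic by identifier everywhere, so all
matrices are aligned by construction.

On disk the types map onto five small TSVs (ATC sets; long-format DTI and
SE profiles; a DDI edge list; a positive-pair list). Readers intersect the
sources — a drug must have all channels to enter the universe, mirroring
benchmark practice — and writers emit an `# items:` vocabulary header so
profiles with empty columns round-trip exactly.

## Feature channels

**DDI embedding.** The adjacency is decomposed by singular value
decomposition \(T = U \Sigma V^\top\); singular values below `sv_threshold`
(default \(10^{-6}\)) are discarded and drug \(i\) is embedded as row
\(i\) of \(U\sqrt{\Sigma}\), truncated to `n_keep` = 25 leading components.
For a symmetric \(T\) the singular values are the absolute eigenvalues, so
\(\Sigma \ge 0\) and \(\sqrt{\Sigma}\) is always defined; when \(T\) is
positive semidefinite the untruncated embedding reconstructs it exactly,
\((U\sqrt{\Sigma})(U\sqrt{\Sigma})^\top = T\), and in general the total
squared embedding mass equals the nuclear norm of \(T\). Isolated drugs
receive all-zero rows rather than being dropped.

**ATC similarity.** \(s_{ij} = |A_i \cap A_j|/|A_i \cup A_j|\) over
first-level code sets (e.g. \(\{A\}\) vs \(\{A,C,D,H,R,S\}\) gives
\(1/6\)). Full codes are accepted on input; only the leading letter is
retained. The similarity is used *directly* as a pairwise confidence
channel — any similarity in \([0,1]\) is the decision value of a trivial
nearest-neighbour classifier — so drugs with empty code sets get
similarity 0 (logged, not an error).

**DTI / SE profiles.** Used as-is (binary, lexicographic column order),
then reduced by mean-centered PCA to `pca_components` = 25 scores.
Centering is on; unit-variance scaling is off, deliberately: the columns
are same-scale Bernoulli indicators and rescaling rare features would
amplify noise. Going straight to 25 components (rather than first
truncating at an intermediate dimension) is the package's default; any
intermediate truncation is reachable through `pca_components`.

**Numerical conventions.** SVD and PCA components are only defined up to
sign, so every component is flipped to make its largest-magnitude loading
positive; outputs are therefore bit-reproducible. PCA requests beyond the
matrix rank are clipped with a warning. AUC uses the Mann–Whitney midrank
form (ties count one half); AUPR uses the non-interpolated step estimator
with tied scores entering a threshold together — stated explicitly because
interpolation conventions change AUPR values.

## Pair featurization and scoring

A pair is featurized as \(F_{ij} = f_i + f_j\): symmetric in the two
drugs, and additive so that a *joint* load (e.g. both members carrying
beneficial side effects) is visible to a linear scorer. Each of the three
real-valued channels trains a binomial logistic model
\(\log \frac{p}{1-p} = w^\top F + b\); the posterior probability is the
channel score. A weak L2 penalty (`lambda` = 1e-4, never on the
intercept) is the default: the PCA scores can be collinear and small
folds can be separable, where the unpenalized MLE diverges. `lambda = 0`
gives the plain MLE via `glm`; the coefficients are not otherwise
comparable across solvers, and the package makes no claim of reproducing
any particular published coefficient vector.

## Fusion

The four channel scores are combined by a normalized weighted mean
\(\sum_c w_c s_c / \sum_c w_c\). Three rules are provided:

- **mean** — uniform weights (the default, and hard to beat);
- **direct** — each channel weighted by its own training AUC;
- **greedy** — the best weight vector on the grid
  \(\{0, 0.1, \dots, 1\}^4\) (all-zero excluded; \(11^4 - 1 = 14{,}640\)
  candidates), scored by fused AUC on an internal half-split of the
  training fold. The exhaustive grid dominates any greedy coordinate
  path over the same steps, so it is implemented as a superset of a
  greedy search; ties break toward the lexicographically smallest
  weights, making the choice deterministic.

Normalizing by the weight sum is a design choice the underlying method
description leaves open; it keeps fused scores in \([0,1]\) and makes the
mean rule the exact uniform-weight special case. Weights are always chosen
on training data (for `greedy`, on a split *inside* the training fold), so
no test instance influences them.

## Cross-validation scenarios

- **S1 (known–known):** candidate pairs are partitioned into \(k\) folds
  (default \(k = 10\)).
- **S2 (known–new):** drugs are partitioned; test instances are pairs
  with exactly one member in the held-out drug fold, training instances
  are pairs among the remaining drugs only.
- **S3 (new–new):** as S2 with both members held out.

Per fold, the PCA reducers and logistic models are refitted on training
data only; for S2/S3 the PCA is fitted on training-drug profiles and used
to project the held-out drugs. The DDI embedding and the ATC similarity
are computed once on the full network/codes: both derive from
combination-label-free attributes that genuinely new drugs also possess
(a new drug still has a pharmacology), so using them is not label
leakage — "new" refers to having no approved combination, not to having
no attributes.

Metrics are averaged over folds; folds whose test set contains a single
class are skipped with a warning (common in S3, where a 12-drug fold has
only 66 candidate pairs and often no positive), and score pooling across
folds is available via `pooled = TRUE` as the alternative convention.

## Separability diagnostics

Four heuristic \([0,1]\) statistics summarize how much each channel
separates positives from negatives:

- **DDI distance:** fraction of positives at shortest graph distance
  exactly 2 versus the same fraction for negatives, combined as
  \(p/(p+q)\). "Exactly 2" is the chosen reading of "two steps apart"
  (combinative drugs rarely interact directly, i.e. distance 1, and are
  rarely far apart); `at_most = TRUE` gives the \(\le 2\) variant.
- **ATC sharing:** mean of the positive sharing fraction and the negative
  non-sharing fraction.
- **DTI/SE frequency:** a feature occurs in a pair if either member
  carries it; features are classified by *relative* occurrence frequency
  (occurrences divided by class size — absolute counts would trivially
  favour the much larger negative class), and the statistic is
  \(n_{\text{neg-enriched}}/(n_{\text{neg-enriched}} + n_{\text{pos-enriched}})\).
  Exact ties in nonzero relative frequency are counted in neither class
  and reported separately.

## The synthetic benchmark generator

Real approved-combination benchmarks are assembled from licensed external
databases, so the package generates synthetic universes that emulate their
*structure*: a sparse Erdős–Rényi DDI graph (density 0.04 over
\(m = 120\) drugs), 1–3 background ATC codes per drug, sparse Bernoulli
DTI/SE profiles (rates 0.02 over 300 targets, 0.05 over 800 side
effects), and \(n_{\text{pos}} = 100\) positive pairs among all 7140
candidates. Four signals are planted, one per channel and independently
so each can be ablated:

- each drug gets latent SE and DTI propensities that tilt its rates on
  planted beneficial/adverse side-effect sets (50/150 features) and
  positive/negative target-pattern sets (30/60 targets); positive pairs
  are drawn with weight
  \(\text{effect\_strength}^{z_{SE}} \cdot \text{effect\_strength}^{z_{DTI}}\),
  where \(z_c\) is the pair's standardized planted-set load (clipped at
  \(\pm 3\));
- with probability \(\gamma \, p_{\text{dist2}}\)
  (\(\gamma = 1 - 1/\text{effect\_strength}\)) a positive is drawn from
  the distance-2 pool of the DDI graph;
- with probability \(\gamma \, p_{\text{atc\_share}}\) a shared
  first-level code is injected into a positive pair's members.

At `effect_strength = 1` every mechanism switches off exactly and the
labels are exchangeable with the background — the null configuration used
to verify chance-level behaviour. The adverse/negative planted sets are
larger than the beneficial/positive ones, so the frequency diagnostics
point the same way as on real benchmarks. Default sizes keep a full
S1/S2/S3 evaluation under ten seconds on one CPU; the property-style
checks in the test suite use 5 seeds of the default configuration plus
smaller universes (\(m\) = 40–80) where many repetitions are needed.

What the generator does *not* emulate: correlated side-effect
vocabularies, scale-free interaction-network topology, entangled channel
signals (real channels share latent causes), and a curated negative
scope. Passing tests on synthetic data therefore demonstrate that the
pipeline recovers planted structure of the stated kind at the stated
strength — not any particular level of real-data performance.

## Known limitations

- The closed-world negative assumption mislabels yet-undiscovered
  combinations as negatives; AUPR values are accordingly pessimistic.
- Additive pair features cannot distinguish two positives within a clique
  of drugs with identical profiles; signal is drug-level by construction.
- Logistic scorers are the only classifier shipped; the scorer contract
  (`train_logistic`/`score_pairs`) is deliberately minimal so other
  probabilistic classifiers can be slotted in.
- S3 estimates are noisy at desk scale: with a 1.4% positive rate a
  held-out-drug fold often contains no positive pair and is skipped.
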