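---
title: "Masked diagnosis modeling of pediatric visit histories: models, generator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked diagnosis modeling of pediatric visit histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the synthetic data the tests run on, the numerical and
design choices made where the problem left them open, and what the test
suite does and does not establish.

## The prediction problem

A pediatric patient is an ordered sequence of inpatient/ER visits. Each
visit carries one to three diagnosis codes (the first-listed code is the
*principal* diagnosis — the condition judged the chief cause of the
encounter), the patient's age and county/zip at the time of the visit, and
a length of stay in whole days, with 0 for same-day discharges and
ER-only encounters. Patients are linked to a mother/birth record (gender,
races, education, prenatal care timing and intensity, the mother's
peripartum hospital utilization). Diagnoses are grouped at the ICD-9
two-digit sub-chapter level, giving a label space of ~115 classes; an
ICD-10 history can be mapped in through a user-supplied crosswalk table.

The two supervised tasks are defined on a history split at a random visit
index `v` (uniform on `2 ≤ v < T`): from visits `1..v`, predict the
principal diagnosis (115-way) and the LoS class (3-way) of visit `v + 1`.
Cohorts are restricted to patients with at least three encounters so that
a valid `v` always exists, and *all* splits — pre-train vs fine-tune
populations, and train/validation/test roles — are assigned at the patient
level, never the visit level, to rule out within-patient leakage.

**LoS classes.** The three classes are same-day (0 days), 1–3 days, and
more than 3 days. Published descriptions of such bins are sometimes
internally inconsistent ("LoS ≥ 1 day, 1 day > LoS ≥ 3 days, LoS > 3
days" cannot all hold simultaneously); we adopt the partition
`{0} / [1, 3] / (3, ∞)`, which matches the accompanying prose
("discharged on the same day", "> 3 days"), and expose both boundaries as
arguments of `los_class()` so the middle bin can start at 2 days instead
if a user prefers that reading.

## Tokenization

`build_history_tokens()` renders a history as
`[CLS] D₁ D₂ [SEP] D₁ [SEP] …`: the `[CLS]` token anchors the pooled
representation, and each visit's code block is closed by `[SEP]`.
Sequences are capped at `max_len` tokens (default 40); when a history is
longer, whole *earliest* visits are dropped until it fits, keeping the
most recent context — the side to truncate is a design choice; recency is
the clinically relevant context for next-visit prediction. A single visit
that cannot fit is an error rather than being split.

Each token carries three (optionally four) aligned id tracks:

- **visit ordinal** (1, 2, …, clipped at 20): the positional signal is the
  *visit index*, broadcast to every token of the visit, rather than the
  raw token position — consecutive codes of one visit are an unordered
  set, and the visit index is what encodes order in the history.
- **age bin**: integer years 0–25 (clipped), plus a reserved "none" bin.
  The discretization is ours; whole years are the natural resolution for
  pediatric follow-up spanning two decades.
- **county id**, and under the `base+zip` spec a **zip id**.

`[SEP]` inherits its visit's ordinal/age/county; `[CLS]` and padding carry
reserved "none" ids. Whether separator tokens should receive these
attributes at all is unstated in the literature we follow; broadcasting is
our convention and is exercised by the round-trip tests.

## Masked diagnosis modeling

Pre-training corrupts each tokenized history once (static masking; a
`remask_each_epoch` switch enables the dynamic variant):
`n_sel = max(1, round(0.15 · n_disease))` disease-token positions are
drawn uniformly; each becomes `[MASK]` with probability 0.8, a random
disease id with probability 0.1, and stays unchanged with probability 0.1
— the original BERT recipe, which the approach we implement defers to.
Special tokens and padding are never candidates. The model is trained by
cross-entropy at the selected positions only.

One property of the selection rule worth knowing: because `n_sel` is an
integer with a floor of 1, the *realized* fraction of selected tokens
exceeds 15% on corpora of short histories (e.g., with a median of ~7
disease tokens per patient the aggregate is ≈ 17%, purely from rounding).
On histories near the 40-token cap — the regime the recipe was designed
for — the aggregate is 15.0%. The masking-contract tests and the
acceptance script therefore measure the statistic on a long-history corpus
(8–12 visits, mostly multi-code); the rule itself is identical everywhere.

## The encoder and its heads

The input representation is the *sum* of the diagnosis-token embedding and
the visit-ordinal embedding (`base`), plus age and/or county embeddings
(`base+age`, `base+cnty`, `base+age+cnty`) or a zip embedding
(`base+zip`). The reference configuration is a 120 × 128 token-embedding
table, 6 identical layers, 12 attention heads, a 128-unit feed-forward
sublayer, dropout 0.1, and post-layer normalization: each layer computes
multi-head self-attention → dropout → add & norm → feed-forward (ReLU) →
dropout → add & norm. Padding positions are excluded from attention by an
additive key mask; in `causal` mode (the decoder comparator, `TDecoder`)
position *i* additionally attends only to positions `≤ i`, and the test
suite verifies this blindness is *exact* — outputs and gradients at
earlier positions are bit-identical under future perturbations, because
masked attention weights are exactly zero.

**Head-width arithmetic.** 128 is not divisible by 12. We use per-head
width `floor(d_model / n_heads)` (10), concatenate the 12 heads (120) and
project back to 128 with the output matrix — both printed numbers are kept
and the layer stays well-defined for any head count.

**Objectives.** Pre-training: AdamW (decoupled weight decay — "a decay of
0.01" is read as weight decay since no schedule is given) at learning rate
3e-5 for 15 epochs in the reference configuration. The causal comparator
is pre-trained with next-token prediction under the same hyperparameters.
Fine-tuning: a one-hidden-layer head (64 units, ReLU, dropout 0.3,
softmax) on the pooled final-layer representation, Adam 3e-4, up to 100
epochs with early stopping on validation loss (patience 5, `min_delta` 0 —
our defaults, as early stopping is stated without parameters), restoring
the best epoch. *All* encoder parameters are updated during fine-tuning,
not just the head.

**Pooling.** The pooled representation is the final-layer vector at
`[CLS]` (a `mean` switch averages over real tokens). The random-embedding
comparator (`NN_REmb`, `n_layers = 0`) must use mean pooling: without an
encoder stack the `[CLS]` slot is a constant embedding and CLS pooling
would make the comparator degenerate. Its reference head width is 564
units.

**Mother-attribute fusion.** Mother features (one-hot blocks per
categorical with an `"unknown"` level absorbing `NA`s and out-of-schema
values; min-max-scaled counts) are concatenated to the pooled
representation *before* the hidden layer, and appended to the multi-hot
inputs for the LR/RF comparators. Where exactly fusion happens is not
specified by the source approach ("integrating the mother's attributes
into all model configurations"); pre-head concatenation is the
conventional reading.

**Comparators.** The "logistic regression with dropout 0.1" is
well-defined only as a single softmax layer trained by gradient descent
with input dropout, which is how `train_logistic()` implements it. The
random forest (`train_random_forest()`, LoS task only — tree ensembles
are not fielded for the 115-class diagnosis task) is 10 trees of depth
≤ 5 with per-tree balanced bootstrap: each tree draws, with replacement,
the smallest class's count from every class; it is backed by the `ranger`
package with class-wise sampling fractions.

The engine itself (embeddings, attention, layer norm, backpropagation,
AdamW) is implemented in vectorized base R inside the package; gradients
are verified against central finite differences in the test suite (the
checks pass at ~1e-10 absolute error on the head path).

## Evaluation

`average_precision()` is the threshold-weighted precision sum
`Σ (Rₙ − Rₙ₋₁) Pₙ` over descending unique score thresholds;
`roc_auc()` is the Mann–Whitney statistic with half-credit for ties
(identical to trapezoidal integration of the ROC curve). Two averaging
schemes mirror how multi-class predictions are reported:

- **per-patient**: each patient's probability vector is a one-positive
  one-vs-rest instance; with mid-rank `r` of the true class among `C`
  scores, patient AUC is `(C − r)/(C − 1)` and patient AP is `1/r`; the
  report is the unweighted mean over patients. The closed form provably
  equals the generic AUC on the one-positive instance and is tested as
  such.
- **per-class**: pooled one-vs-rest per class, with support counts; a
  class with no positives is reported as `NA` and *excluded* from macro
  means (zero-filling or silent dropping would bias them); the number of
  undefined classes is reported alongside.

Mid-rank tie handling is used everywhere, stated explicitly because tie
conventions are usually left implicit. Pre-training validation APS/AUC is
computed by pooling all masked positions, scoring one-vs-rest per
vocabulary token, and macro-averaging over tokens with at least one
positive — the aggregation is our choice.

Embedding diagnostics: cosine similarity with percentile summaries over
off-diagonal pairs; an exact (non-Barnes–Hut) t-SNE to 2-D, implemented
in-package (adequate and fast for a 120-row table; seeded, with the
perplexity constraint reported in the error message when violated); and an
extrinsic gender-association test that cross-tabulates patients by gender
against whether any of their top-1 masked predictions is a target code,
with a two-sided Fisher's exact p-value computed by direct hypergeometric
enumeration (the customary 1e-7 relative tolerance decides ties; the
enumeration is cross-checked against `stats::fisher.test` and a
factorial-based oracle). The exact contents of such a 2×2 table are not
fully pinned down by the source description; the top-1 construction is one
faithful reading.

`fairness_report()` computes per-subgroup metrics over the audit bins —
patient age {0–2, 3–17, 17+}, visit count {3, 4–6, 7+}, raw levels for
gender, races, education, prenatal-care timing and counts, mother's birth
country — plus a pluggable county→region lookup (no default geography
ships). Subgroups under a minimum support are flagged rather than
silently dropped.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the models assume,
not any real population:

- **Co-occurrence clusters.** Codes are assigned round-robin to
  `n_clusters` latent clusters with 1/rank within-cluster emission
  weights; a visit draws its 1–3 codes from its cluster, and the cluster
  of successive visits follows a row-stochastic transition matrix
  (default: stay with probability 0.7). Latent clusters induce exactly
  the kind of within-visit and across-visit dependence masked modeling
  can learn, at trivial sampling cost — a deliberate simplification
  versus a full pairwise co-occurrence model.
- **Visit counts and ages.** Visit counts are drawn from a configurable
  distribution (default mass on 3–7 visits, tail to 12, matching a
  pediatric claims cohort filtered at ≥ 3 encounters); ages start at 0 and
  advance by a configurable gap distribution, so they are nondecreasing by
  construction.
- **Length of stay.** A two-part model per cluster: a point mass at 0 days
  (same-day/ER discharges) plus a shifted Poisson (`1 + Pois(λ)`),
  guaranteeing all three LoS classes are populated and making LoS
  cluster-dependent, hence learnable.
- **Gender skew.** A named ratio `r` per code multiplies the code's
  emission weight by `√r` for male patients and divides it by `√r` for
  female patients (then renormalizes). The symmetric form is the faithful
  reading of a male:female *prevalence ratio*; renormalization makes the
  realized ratio differ slightly from nominal `r`, so the generator test
  compares the empirical ratio against the exact expectation computed from
  the configured weights. Defaults skew the tuberculosis ("01") and
  congenital-anomaly ("74") sub-chapters 3:1 toward males.
- **Geography.** Zip strings are the county id plus three random digits —
  no real geography is modeled.

Mother attributes are drawn from fixed marginal distributions with
plausible level sets (races, education, prenatal care month 1–9 or
unknown, Poisson utilization counts). Only *marginals* are calibrated;
joint structure between mother attributes and the visit process (beyond
gender skew) is absent. Passing tests on this generator therefore
demonstrates that the pipeline recovers the structure it was told to
embed — co-occurrence, cluster geometry, LoS dependence, injected
subgroup effects — not that any particular real-data performance level
would be attained. Real claims data additionally exhibit code hierarchies,
secular trends, visit-type mixtures, and informative censoring that the
generator does not emulate.

## Desk-scale configurations

The reference architecture (6 × 12 × 128, 15 + 100 epochs) targets
millions of visits. The test suite runs the same code end-to-end at desk
scale, chosen so the full suite completes in minutes on one CPU while
leaving each property a clear margin: 2-layer, 2-head, 32-dimensional
encoders on 24-token histories; cohorts of 1,200–5,000 patients;
pre-training 3–10 epochs and fine-tuning 8–10 epochs at learning rate
1e-3 (small models tolerate and need a larger step than the reference
3e-5/3e-4). Property checks that compare stochastic training outcomes
(embedding geometry, pre-training benefit, fairness gaps) run over three
fixed seeds and require the expected ordering in at least two.

## Numerical notes

- Attention masking uses an additive −1e30 bias before the softmax, which
  underflows to exactly zero weight; causal blindness is therefore exact,
  not approximate.
- Layer norm uses ε = 1e-5; Adam uses (0.9, 0.999, 1e-8); parameters are
  initialized N(0, 0.02²), layer-norm gains at 1, biases at 0.
- Dropout is inverted (scaled at train time); evaluation passes are
  deterministic.
- All randomness (initialization, shuffling, masking, dropout, split
  assignment, the generator) flows through seeds carried in the config
  objects; identical configs reproduce results bit-for-bit, and the
  ambient RNG state is restored afterwards.
- Softmax rows are computed with max-subtraction; cross-entropy clips
  probabilities at 1e-12.

## Known limitations

- The generator's mother attributes are independent of the visit process
  except for gender skew, so mother-feature fusion can only be shown to be
  *plumbed correctly* (shapes, fusion point, determinism), not to improve
  skill as it does on real linked data.
- The ICD-10→ICD-9 crosswalk is an interface with first-match semantics;
  no mapping table ships with the package.
- The exact t-SNE is O(n²) per iteration and intended for token-embedding
  tables (~120 rows), not for large sample embeddings.
- Training is single-threaded CPU R; the engine is meant for method study
  and desk-scale experiments, not production-scale pre-training.
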