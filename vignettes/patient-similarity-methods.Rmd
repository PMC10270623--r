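---
title: "Measuring patient similarity from mixed-type data: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring patient similarity from mixed-type data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the statistical
machinery behind each module, the tunable parameters and their defaults,
what the synthetic cohort generator does and does not emulate, and the
places where the design was genuinely open and a choice had to be pinned.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The setting

A cohort is a complete-case table of m patients over a typed schema of 16
features: four numeric (age in years, BMI in kg/m², FEV1 % predicted,
eosinophil % of white blood cells), one ordinal (inhaled-therapy line,
`none < mono < dual < triple`, derived from ICS/LABA/LAMA prescription
combinations), and eleven binary features (sex, current-vs-ex smoking and
nine diagnosis flags). Missing values are rejected at load time — the
analysis is defined on complete cases only — and binary features are stored
as their level strings, never as 0/1 codes, so every downstream encoding is
explicit.

Patient similarity is the Euclidean distance between per-patient coordinate
vectors in a reduced space. Everything in this package is about how that
space is built and what the construction does to the relative influence of
the features.

## 2. The synthetic cohort generator

Real cohorts of this kind live under data-sharing licenses, so the
generator is a first-class module, not a test fixture. It draws:

* numeric features from truncated normals (inverse-CDF sampling, so a seed
  fully determines the draw). Default marginals: age 67.0 (10.8) truncated
  at the 35-year eligibility floor, BMI 27.5 (6.1) above 10, FEV1 %
  predicted 66.1 (20.9) in (5, 150), eosinophil % 3.0 (1.8) in (0, 20).
  The truncation bounds encode cohort eligibility and physiological
  plausibility; note that truncation shifts the realized mean (by ≈ +0.19
  for eosinophil %), and the marginal-fidelity tests therefore compare
  against the closed-form truncated mean, not the location parameter.
* binary features as Bernoulli draws of the first schema level (male
  54.5 %, current smoking 53.5 %, anxiety 10.1 %, depression 11.1 %,
  atopy 12.2 %, CRS 1.9 %, diabetes 16.2 %, hypertension 34.0 %, heart
  failure 15.1 %, IHD 23.0 %, GERD 8.9 %);
* the therapy line from a probability vector (37.6/13.2/33.0/16.2 %).

Optionally `k_planted` latent clusters are planted: cluster labels are
drawn uniformly, numeric means shift per cluster in SD units, binary
prevalences get additive offsets (clamped to [0, 1]), and ordinal
probabilities are exponentially tilted toward higher levels,
`p_l ∝ p_l · exp(t · (l−1)/(L−1))`. The hidden labels ride along as an
attribute that no pipeline ever reads — they exist solely so recovery tests
cannot leak.

**What the generator does not emulate.** Features are drawn independently
given the cluster label: the marginals are faithful, the correlation
structure of real data (e.g. FEV1–therapy dependence) is not, except what
planted clusters induce. There are no longitudinal records, no missingness,
no coding artefacts. A green test therefore establishes that the *methods*
behave as specified on data with known structure — not that any particular
clinical finding generalises.

The default train/test fraction is 0.7516, reproducing a 22899/7568
partition of a 30467-patient cohort; the split is seeded and is a partition
(checked property-style over random fractions and seeds).

## 3. Encodings

* **GOLD stage** from FEV1 % predicted: 1 at ≥ 80, 2 in [50, 80), 3 in
  [30, 50), 4 below 30 — a total, monotone map on the positive axis.
* **Therapy class** from prescription sets: no long-acting bronchodilator →
  `none` (ICS alone is still `none`); exactly one of LABA/LAMA without ICS
  → `mono`; any two of {LABA, LAMA, ICS} (with at least one bronchodilator)
  → `dual`; all three → `triple`.
* **Binning** is left-closed right-open with the last bin closed, matching
  the GOLD band definitions. The MCA pipeline bins FEV1 % predicted at the
  clinical edges 30/50/80 and the other numerics at training-set quartiles.
  The quartile choice is a default, not a reported fact: the source
  material names GOLD binning explicitly but never states the bins for age,
  BMI or eosinophil %. Quantile edges are fitted on the training split only
  and serialize to JSON with 17 significant digits, so a fitted transform
  re-applies to unseen data bit-identically.
* **One-hot encoding** produces one indicator column per schema level;
  every per-feature block sums to exactly 1 in every row (an invariant the
  MCA code checks rather than assumes).
* **Scaling** is fitted on the training split (min-max to [0, 1], or
  standardization); held-out data may legitimately fall outside the
  training range.

## 4. Linear embeddings

**PCA** standardizes columns by default: the numeric block mixes years,
kg/m² and two kinds of percentages, and unstandardized variances would
impose exactly the kind of silent weighting this package exists to expose.
Scores come from the SVD of the centered/scaled matrix; explained fractions
are eigenvalues over their total. Component signs are fixed by forcing the
largest-magnitude loading positive, for reproducibility across linear
algebra backends.

**MCA** is correspondence analysis of the indicator matrix (not the Burt
matrix): with P the correspondence matrix, r and c its margins, the SVD of
`S = D_r^{−1/2}(P − rcᵀ)D_c^{−1/2}` yields row principal coordinates and
principal inertias (squared singular values); total inertia is `J/Q − 1`
for Q features with J levels in total — an identity the tests check across
random schemas. Held-out rows are projected as supplementary profiles:
`f = ((z/Q − c)/√c) V`.

**Retention** keeps the smallest leading set of components whose cumulative
explained fraction reaches the threshold (default 0.75), never zero
components, monotone in the threshold.

**Inertia correction (open question, decided).** Raw indicator-matrix
inertias understate the share of the leading axes, and a 75 % threshold on
raw inertias retains many components (typically 15–20 on the 16-feature
cohort). Analyses of this design are sometimes reported with only a handful
of components at 75 %, which is plausible only under a Benzécri-style
adjustment that re-expresses the inertias above the 1/Q threshold. The
package defaults to uncorrected inertias (what the plain indicator-matrix
formulation defines) and exposes `fit_mca(correction = "benzecri")` for
users who want the concentrated variant.

## 5. The autoencoder

A symmetric feed-forward net: `hidden_layers` ReLU layers of `hidden_units`
on the encoder side, a *linear* bottleneck (default 6 units — fixed at
configuration time, matching the representation width of the
middle-complexity linear pipeline), the mirrored ReLU decoder, linear
output. The loss is plain MSE over all columns, indicators and scaled
numerics alike. Grid search trains every combination of depth {2,3,4,5} ×
width {10,12,16} × learning rate {0.1, 0.01, 0.001, 0.0001} and selects by
*test-set* reconstruction MSE (ties: fewer parameters, then lower learning
rate). A diverged fit (non-finite loss) is returned as a flagged failure so
the rest of the grid proceeds.

Training details are unstated in the source material and had to be pinned:

* **Optimizer: Adam with a fixed learning rate** (betas 0.9/0.999, no
  schedulers). Plain SGD — with or without momentum — at the selected
  learning rate of 0.001 leaves the network visibly under-trained within
  200 epochs (reconstruction MSE ~3× higher), and a learning-rate grid
  spanning 0.1 to 0.0001 with 0.001 winning is the signature of
  Adam-convention training. Determinism is preserved: the seed fixes
  initialization and batch shuffling, and two fits with the same seed are
  bit-identical.
* **Epochs 200, batch 64, He initialization.** Desk-scale defaults; the
  training-loss trace is checked to be non-increasing in 10-epoch moving
  average on generated cohorts.
* **Numeric scaling: standardize (deviation from the min-max default one
  might expect for bounded reconstruction targets).** Under min-max, the
  scaled numeric columns carry variance ≈ 0.02 against ≈ 0.25 per indicator
  column, so the MSE objective effectively ignores the numeric block and
  the bottleneck spends its capacity reconstructing Bernoulli noise. On
  cohorts with planted structure this demonstrably destroys cluster
  recovery from the AE representation (≈ 60 % congruity against truth
  versus ≈ 99 % under standardization — the acceptance suite computes
  this). Min-max remains available via `pipeline_config(scaling =
  "minmax")`.

## 6. Relative variability

For feature x and patients i, j, the pairwise difference is
`d_x^{ij} = |x_i − x_j|`. Cohort-level variability is the median of
`d_x^{ij}` over all pairs for numeric features, the mean absolute rank
difference (levels mapped to 0, 1, 2, …) for ordinal features, and the
disagreeing-pair proportion for categorical features. The neighborhood
statistic applies the same form to each patient's N = 20 (patient,
neighbour) pairs and averages over patients. RV is 100 × neighborhood /
cohort; features are ranked ascending (rank 1 = most similarity-driving).
MRV is the arithmetic mean per group and overall.

Pinned choices, in decreasing order of consequence:

* **Numeric neighborhood statistic: per-patient median** of the N absolute
  differences, mirroring the cohort-level median; the phrase "average
  absolute difference … as per the previous steps" admits a mean reading,
  available as `numeric_stat = "mean"`.
* **MRV grouping: ordinal features average with the categorical group.**
  A defensible alternative groups ordinal features with the numerics (their
  pairwise statistic is rank-based, like a numeric difference); the
  reference summary tables this implementation matches group the therapy
  line with the categorical features, so that is the default, with
  `group_ordinal = "numeric"` as the alternative flag.
* **Known bias of the null.** If neighbour sets are drawn at random
  (ignoring the representation), discrete features show mean RV within a
  fraction of a percent of 100, but numeric features converge to ≈ 108,
  not 100: the numerator averages *patient-anchored* medians while the
  denominator is the median over unanchored pairs, and
  `E_i[median_j |x_i − x_j|] > median_{ij} |x_i − x_j|` for unimodal
  marginals (tail patients contribute stochastically larger anchored
  differences). This is intrinsic to the metric's definition — it persists
  at N = m − 1 and is worse under the mean mode — so RV values of numeric
  and categorical features are not exactly commensurable near the null.
  The acceptance suite asserts the idealized ±5 band anyway and the
  numeric half is an expected, documented failure; comparisons *within* a
  feature type, and the rankings the metric exists to produce, are
  unaffected.
* **Scale invariance** (RV of a numeric feature is unchanged under positive
  rescaling) and **exactness** (pair enumeration is bit-identical to the
  production path up to 2 × 10⁶ pairs; above that, seeded uniform
  pair-subsampling of 10⁶ pairs approximates the numeric median, while
  discrete statistics stay exact via level counts) are checked
  property-style.
* **Zero-variability features** (constant in the cohort) are excluded from
  the RV table with a warning rather than reported as infinite.

## 7. Cluster-level evaluation

**Hopkins index.** Among several conventions, the package uses distances
raised to the power d (the coordinate dimension), with the uniform
reference drawn in the axis-aligned bounding box of the data and nearest
neighbours taken in the full data set: per repeat,
`H = Σu_i^d / (Σu_i^d + Σw_i^d)`, averaged over 20 repeats of m_h = 100.
This convention reproduces the 0 / 0.5 / 1 anchors (regular grid / uniform
/ two tight blobs) that the package's tests simulate. On predominantly
discrete representations H saturates near 1, because duplicated coordinate
rows make within-data nearest-neighbour distances collapse — worth knowing
before reading H as evidence of clinical subgroups.

**k-means.** Lloyd iteration to a 1e-6 centroid-shift tolerance, capped at
300 iterations; an emptied cluster is re-seeded with the worst-fitted
point. Initial centroids are k distinct patient indices drawn by the seeded
generator, so the same seed produces the same initial index sets whichever
representation is being clustered — the "identical random initialisations"
contract. One deliberate deviation: the implementation runs `restarts = 25`
such seeded initializations and keeps the lowest-inertia solution. A single
random index draw covers k well-separated clusters with probability only
k!/k^k (≈ 22 % at k = 3), which would turn cluster-recovery claims into
coin flips; 25 restarts make coverage near-certain while preserving
cross-pipeline identity of the initialization sets.

**Congruity.** Labelings from different pipelines carry no label
correspondence, and the matching procedure is unstated in the source
material; the package pins optimal assignment on the k × k contingency
table (exhaustive over permutations, k ≤ 8). This maximizes co-assignment
and therefore reports a conservative *upper* bound — any other matching
could only lower the agreement. Congruity is symmetric and label-invariant,
and never falls below 100/k.

**Bootstrap pair-stability** (the congruity-matrix diagonal): 20 repeats of
10 % subsampling and re-clustering; for patient pairs co-occurring in ≥ 2
repeats, the fraction of repeat-pairs agreeing on same-vs-different cluster
status, averaged and ×100. Pair status (rather than matched labels) is used
because subsamples differ in membership.

## 8. Expert rating and agreement

The web rating tool of the original workflow is replaced by a CSV round
trip: `export_vignettes()` samples reference patients (default 125),
attaches each pipeline's best *non-identical* match — exact duplicates on
all 16 raw features are skipped, however close in coordinate space — and
blinds pipelines behind a shuffled letter code whose mapping is stored
separately. Returned ratings (ranks 1 = best to 4 = worst, ties allowed,
but every case-rater must use both a 1 and a 4) are validated on ingestion.

Agreement statistics, for exactly two raters:

* **Raw agreement**: fraction of cases with identical ranks. The
  best/worst binarized modes use *positive-class-specific* agreement —
  among cases where either rater applied the label, the fraction where
  both did. (Plain binary agreement would make "is best" and "is not best"
  numerically identical, which contradicts how such tables are reported.)
* **Cohen's kappa**, unweighted, over the observed categories; weighted
  kappa is deliberately not implemented. Confidence intervals use the
  large-sample variance of the kappa *estimate* (the Fleiss–Cohen–Everitt
  estimation form) with a normal approximation; the simpler null-hypothesis
  variance is available via `variance = "null"` since the exact variant
  intended by "intervals as per Fleiss" is ambiguous. Degenerate tables
  (both raters constant and identical, p_e = 1) yield a flagged undefined
  kappa rather than an error.

## 9. Seeds, determinism and tolerances

A single master seed drives `evaluate_all()`: stage seeds (cohort
variability subsampling, Hopkins sampling, per-k k-means initializations,
bootstrap subsamples) derive from it by a fixed affine map mod 2³¹ − 1, so
the k-means initialization seed for a given k is identical across
pipelines. Two runs with the same inputs produce byte-identical serialized
reports; the acceptance suite checks this at m = 2000 over all four
pipelines. Numerical tolerances: orthogonality/projection identities at
1e-8; oracle agreement (dense eigendecomposition for PCA, explicit CA SVD
for MCA) at 1e-8 up to component sign; distance symmetry at 1e-12; RV pair
enumeration exact.

## 10. Known limitations

* The generator's independence structure makes MRV contrasts between
  pipelines milder than on real, correlated data; the package demonstrates
  the machinery, not the clinical conclusions.
* Hopkins saturates on discrete-dominated representations (see §7).
* The RV null bias for numeric features (§6) means "RV = 100" is not an
  exact no-information reference point for numerics.
* Congruity's optimal matching is an upper bound; with k > 8 clusters the
  exhaustive matcher refuses rather than approximates.
* The autoencoder is deliberately minimal (no denoising/variational
  variants, CPU-scale widths); its representation geometry is
  reconstruction-driven and nothing constrains it to preserve relative
  distances.
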