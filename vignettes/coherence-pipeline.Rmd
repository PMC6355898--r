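---
title: "From speech transcripts to coherence-predicted brain activation"
author: "cohera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From speech transcripts to coherence-predicted brain activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohera)
```

# The problem

When people speak at length, they vary in how well they keep to the point.
*Global coherence* is the degree to which an utterance relates semantically
to the topic under discussion; it declines in healthy ageing and in several
clinical conditions, and identifying its neural predictors requires a
quantitative, time-resolved measure of coherence that can be carried into a
functional-imaging analysis.  `cohera` implements that full computational
path: a latent-semantic-analysis (LSA) coherence scorer for transcribed
speech, block-level speech characteristics and their latent-factor
decomposition, construction of coherence- and time-modulated fMRI
regressors, and a voxelwise GLM with ROI, quintile, second-level,
ANCOVA and Monte-Carlo cluster-extent analyses — all exercisable end to end
on synthetic data with known ground truth.

# The coherence model

## Semantic space

Words are represented in an LSA vector space: the term-document count
matrix of a training corpus is weighted (log-entropy by default, the
standard LSA scheme: local weight $\log_2(1+tf_{ij})$, global weight
$1 + \sum_j p_{ij}\log_2 p_{ij}/\log_2 n$), and the rank-$k$ truncated SVD
taken.  Word vectors are the left singular vectors scaled by the singular
values.  A passage of speech is represented by the unweighted mean of its
in-vocabulary word vectors — a bag-of-words combination, invariant to word
order.  Similarity is the cosine.  Because the construction details of the
original full-scale space (corpus, dimensionality, weighting scheme) are
not part of this artifact's contract, all of them are configuration
options rather than fixed claims: `build_space(corp, k, min_doc_freq,
weighting)`.  `k = 300` is a sensible default for a real corpus; the test
suite uses `k` between 2 and 20 on small synthetic corpora, where the full
rank is tiny.

Two numerical conventions make spaces reproducible and scores
interpretable:

* **Sign convention.** Each SVD component's sign is fixed by forcing its
  largest-magnitude loading positive.  Cosines are unaffected; serialized
  spaces become bit-stable.
* **Clamping.** Cosines can be slightly negative after SVD even though the
  published measure lives on a 0–1 scale.  Reported scores are
  $100 \times \max(0, \cos)$, so the 0–100 reading ("0 = no semantic
  relationship with the topic, 100 = identical to it") holds; the raw
  cosine is exposed alongside for anyone who needs it.

## Scoring a response

For one response to one prompt:

1. Every *other* participant's response to the same prompt is converted to
   a passage vector; their unweighted mean is the **prototype** (composite)
   vector for the prompt — the typical semantic content of an answer.  The
   response under analysis is excluded (leave-one-out), so it never
   contributes to the standard it is scored against.  Averaging is over
   responses (one vector per response), not over pooled words.
2. A 20-word moving window — the current word and the 19 preceding it — is
   represented as a passage vector and compared with the prototype by
   cosine.  The value is assigned to the final word of the window.
3. The production period is divided into 5-s blocks and each block's
   coherence is the mean of the defined per-word values of the words
   produced in it (word-to-block assignment by onset time when available,
   otherwise a uniform speech rate; half-open intervals `[start, end)`).

Words before position 20 have no defined per-word value; the block-level
remedy is normative: **block 1 always receives block 2's value**, and any
other block with no defined word values receives the nearest *later*
defined block's value (falling back to the nearest earlier one at the tail
of a response), with a logged message.  *Local* coherence — how well
adjoining stretches of speech relate to one another — is computed the same
way but comparing the window ending at the current word with the
immediately preceding non-overlapping window; the exact construction of
the original local measure is not documented in this artifact's sources,
so `local_coherence_series()` is this package's reconstruction and is
labelled as such.

The per-word scorer uses rolling sums (each window's mean vector in O(1));
the test suite holds it to an independent brute-force recomputation of
every window at $10^{-10}$.

# Speech measures and factors

`block_measures()` computes, per 5-s block: word count, type:token ratio,
closed-class proportion, and the mean frequency, concreteness, age of
acquisition, semantic diversity and phoneme length of the nouns produced.
Nouns and closed-class words are identified by lookup lists supplied with
the norms table — a deliberate choice over a POS-tagger dependency, since
the synthetic generators control those lists exactly.  Correlations
between measures are Pearson, pairwise-complete (blocks without nouns
still contribute to the pairs they have), with constant columns flagged
`NA` rather than propagating `NaN`.

`extract_factors()` is a principal components analysis of the standardized
measure table retaining components with eigenvalues above one, followed by
oblique rotation: varimax, then promax with $\kappa = 4$ (the conventional
default; no other value is asserted anywhere in the pipeline).  Explained
variance is reported on the unrotated components.  Scores use the
regression method through the structure matrix, with the fitting sample's
means and SDs stored in the model so new blocks are scored on the same
scale.  Because factor order and sign are arbitrary, recovery tests match
recovered to planted factors by maximum absolute Tucker congruence over
column permutations (`match_factors()`).

# From blocks to regressors

Parametric modulators (block coherence, time-in-trial, factor scores) are
prepared per scanning run: values more than 2 SD from the run mean are
clipped to that bound (winsorized), then the series is mean-centred.  The
order — winsorize on the raw statistics, then centre — guarantees both
stated properties (exact zero mean, boundedness by the raw-mean ± 2 SD
limit) simultaneously.  One subtlety is worth recording: winsorizing and
re-centring is *not* a numerical fixed point when a value was actually
clipped, because clipping shrinks the SD, leaving the clipped point beyond
2 SD of the new series.  `prepare_modulator()` therefore treats
re-preparation of an already prepared series as a no-op (logged), which is
the behaviour a pipeline wants; the numeric recipe is a fixed point
exactly when nothing was clipped, and the tests check both statements.

The early/late timing variants (`shift_modulator()`) move each block's
value one block backward or forward strictly within its trial — the value
carried by block 4 appears at block 3 (early) or block 5 (late) — and the
block left vacant at a trial edge receives its nearest within-trial
neighbour's value, mirroring the first-block substitution spirit.
Shifting is pure reindexing; it deliberately does not re-centre, so the
early/late models re-prepare after shifting.

`build_design()` assembles, per run: HRF-convolved boxcars for the four
task events (8-s extended and automatic planning, 50-s extended
production as concatenated 5-s blocks, 15-s automatic production), one
column per modulator (block boxcars scaled by the prepared values before
convolution), the supplied per-volume nuisance columns (six motion
parameters and six externally computed noise components, accepted as a
table — their derivation is out of scope), a discrete-cosine drift basis
implementing the 180-s high-pass cutoff within the GLM
($K = \lfloor 2\,T_{\mathrm{run}}/180 \rfloor$ columns per run;
mathematically equivalent to filtering the data and easier to test), and
per-run intercepts.  The canonical HRF is the double-gamma (peak ~5–6 s,
undershoot ~16 s, 1:6 ratio, 32-s support), normalized to unit sum on a
microtime grid of 16 bins per TR (TR = 2.2 s), with regressors sampled at
bin 8 of each volume — the sampling most readers would assume.  Design
construction is free of randomness and bit-reproducible.

# GLM and group analyses

`fit_glm()` is ordinary least squares per voxel (pseudo-inverse with a
warning naming dependent columns if the design is rank-deficient);
`contrast()` gives $w^\top\hat\beta$ and its t with
$df = n - \mathrm{rank}(X)$.  `second_level()` fits participant contrast
estimates on an intercept plus mean-centred covariates (mean scan-to-scan
displacement — the mean over the six realignment parameters of the mean
absolute volume-to-volume change — and optionally each participant's mean
block coherence), so the intercept t is the one-sample group test.  Zero
residual variance is flagged as a signed infinite t, never `NaN`.

`quintile_effects()` ranks speech blocks by a parameter (stable
tie-breaking by block order), splits them into five near-equal sets, fits
one convolved regressor per set, and reports each set's effect relative to
the block-count-weighted overall mean — so the weighted relative effects
sum to zero by construction.  `anova_2x2()` implements the 2×2
repeated-measures ANCOVA (hemisphere × region with a between-participant
covariate) through within-participant difference scores regressed on an
intercept plus the centred covariate, giving each effect an F on
$(1, n-2)$ df.  With two-level factors no sphericity correction is needed.

## Cluster-extent correction

`cluster_threshold_montecarlo()` determines the minimum cluster size for
corrected $p < .05$: each simulation draws Gaussian white noise on the
mask grid, smooths it to the stated FWHM, standardizes it within the mask,
thresholds at the voxelwise $p = .005$, and records the largest
suprathreshold cluster.  Design choices that the sources leave open were
resolved as follows:

* **Tail.** One-tailed positive thresholding by default, since directional
  t contrasts are what the cluster correction is applied to;
  `tail = "two"` is available.
* **Connectivity.** 26-neighbour (face/edge/corner), matching common
  Monte-Carlo practice; 6-neighbour available.
* **Smoothness.** Taken as an input (the smoothing actually applied to the
  data, e.g. 12 mm); residual-based smoothness estimation is out of scope.
* **Stationarity.** Smoothing uses circular (FFT) convolution so the null
  field is stationary; zero-padding would depress edge variance and bias
  edge clusters small.
* **Threshold rule.** The minimum size is the 95th percentile (type-1
  quantile) of the max-cluster distribution plus one — the smallest extent
  whose simulated family-wise false-positive rate is ≤ 0.05.  The tests
  verify on fresh null fields that the realized family-wise error sits
  inside the binomial 95% interval around 0.05.

## Regions of interest

`roi_build()` thresholds a probabilistic atlas strictly (`> 0.30`: a voxel
at exactly 30% is excluded) and optionally removes voxels more medial than
$|x| = 30$ mm — the cut used to keep inferior-frontal masks out of medial
prefrontal territory.  `roi_effect()` is the unweighted mean of a
statistic map over the mask.

# The synthetic generators

Every input the pipeline needs can be generated with known ground truth,
and all generators are pure functions of (spec, seed):

* **Corpora** (`generate_corpus()`): documents drawn from per-topic
  unigram distributions with private vocabularies, an optional shared
  pool, and Zipf-like emission.  Disjoint vocabularies put topics in
  exactly orthogonal subspaces — which is what makes the scale endpoints
  (identical window → 100, orthogonal window → 0) analytically forced.
* **Responses** (`generate_responses()`): per block, words are on-topic
  with probability $p_0 - (b-1)\delta$ (defaults $p_0 = 0.95$,
  $\delta = 0.05$, 10 words per 5-s block, 10 blocks — the observed
  production rate over a 50-s period).  Off-topic words come in runs
  (excursions), each drawn from one randomly chosen other topic, so local
  and global coherence can dissociate.  The default topic spec uses six
  topics: with only two, every off-topic excursion necessarily aligns
  with the off-topic mass that drifts into the leave-one-out prototype
  itself, which destroys the monotone decline the generator is meant to
  emulate; with several topics the prototype's off-topic mass is spread
  across directions no single excursion matches.  Linear drift is the
  default (matching a monotone decline of coherence over the period).
* **Norms** (`generate_norms()`): seed-fixed lexical norms in realistic
  ranges with disjoint closed-class and noun lists.  Planted *factor*
  structure lives in `generate_measure_table()`, which maps latent scores
  through a planted loading matrix (default: four factors over nine
  measures — complexity, specificity, coherence, verbosity) plus noise.
* **BOLD** (`generate_bold()`): signal is the design times spatially
  varying planted betas (e.g. a spherical blob via `beta_blob()`), plus
  stationary AR(1) Gaussian noise.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: natural-language syntax and morphology, disfluencies
and repairs, speaker-specific vocabulary, realistic fMRI artefacts beyond
AR(1) noise (spikes, physiological cycles, motion-correlated signal), and
spatial noise correlation in the simulated BOLD outside the cluster
simulation.  Recovery results on this synthetic material demonstrate the
*computational correctness* of the pipeline, not the empirical effect
sizes a real study would yield.

# Problem sizes and runtime choices

The test suite runs at desk scale by design: corpora of 24–60 documents
with vocabularies of a few hundred words and spaces of rank 4–8; 4–12
responses of 100 words; BOLD grids of $4^3$–$20^3$ voxels over 50–230
volumes; 1000–2000 cluster simulations on $8^3$–$14^3$ grids.  These
sizes keep every property assertable in seconds while leaving the
algorithms identical to what a full-scale analysis would run.

# Known limitations

* The corpus behind the original full-scale LSA space is not reproduced;
  spaces trained here are synthetic or user-supplied.
* Local coherence is a reconstruction (consecutive non-overlapping
  windows); other definitions exist.
* Spatial preprocessing (realignment, normalization, smoothing) and the
  derivation of the six noise covariates are out of scope; nuisance
  tables are accepted as supplied.
* The ANCOVA covers the 2×2 two-level design only; higher-level factors
  would need sphericity handling it does not implement.
* `fit_glm()` is OLS; temporal autocorrelation is not prewhitened.  With
  AR(1) noise the betas stay unbiased (what the recovery tests check) but
  single-voxel t statistics are mildly optimistic.
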