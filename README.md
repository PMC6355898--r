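# cohera

Global coherence of connected speech, and where it shows up in the brain.

`cohera` is an R package for researchers studying extended speech
production — psycholinguists quantifying how well speakers stay on topic,
and neuroimagers relating that quantity to BOLD activity.  It implements a
complete, tested pipeline from raw transcripts to coherence-predicted
activation:

1. **LSA coherence scoring.**  A semantic space is trained by truncated
   SVD of a log-entropy-weighted term–document matrix.  A passage is the
   mean of its word vectors.  For each word of a response, the 20-word
   window ending at that word is compared by cosine with a *prototype*
   vector — the leave-one-out mean of all other participants' responses to
   the same prompt:

   score(word *i*) = 100 × max(0, cos(**w**<sub>i−19..i</sub>, **p**))

   100 means the speech is semantically identical to a typical response to
   the prompt; 0 means no semantic relationship with the topic.  Scores
   are averaged within 5-s blocks (block 1 takes block 2's value, since
   the window reaches back before speech began).  A local-coherence
   variant compares consecutive non-overlapping windows.
2. **Speech characteristics and factors.**  Per-block word count,
   type:token ratio, closed-class proportion and noun lexical norms;
   their correlation structure; and a PCA with eigenvalue-greater-than-one
   retention and promax rotation, with regression-method factor scores.
3. **Design construction.**  Block modulators winsorized at 2 SD and
   mean-centred per run, shifted early/late variants, canonical
   double-gamma HRF convolution at microtime resolution, discrete-cosine
   180-s high-pass drift basis, nuisance columns, per-run intercepts.
4. **GLM and group analyses.**  Voxelwise OLS, contrasts, one-sample
   second-level tests with centred covariates (including mean scan-to-scan
   displacement), probabilistic-atlas ROIs with a strict 30% threshold and
   ±30 mm medial cut, quintile effect profiles, 2×2 repeated-measures
   ANCOVA, and Monte-Carlo cluster-extent thresholds for smoothed null
   fields (voxel p = .005, corrected p < .05).
5. **Synthetic data.**  Seeded generators for topic corpora, responses
   with controlled coherence drift, lexical norms, planted factor
   structure, and AR(1) BOLD with known betas — so every stage is testable
   against ground truth.

## Worked example

Train a small space on a synthetic six-topic corpus, score drifting
responses, and build a coherence-modulated design:

```r
library(cohera)

spec      <- topic_model_spec()                       # 6 topics
corp      <- generate_corpus(spec, n_docs = 36, seed = 1)
space     <- build_space(corp, k = 8)
space
#> LSA semantic space: |V| = 237  k = 8  weighting = log-entropy

responses <- generate_responses(spec, prompt_topic = 1, drift_spec(),
                                n_participants = 5, seed = 2)
proto     <- prototype_vector(responses, exclude = "p01", space)
series    <- global_coherence_series(responses[[1]], proto, space)
series
#> global coherence series: 100 words, window 20, 81 defined values, mean 93.9

round(block_coherence(series, responses[[1]])$value, 1)
#>  [1] 98.1 98.1 98.3 98.3 98.7 98.9 97.2 96.0 90.2 72.9
```

The per-block values are on the published 0–100 scale; the generated
responses drift off topic, so coherence declines over the 50-s period
(block 1 repeats block 2 by the substitution rule).  Pooling all
responses:

```r
tab <- score_responses(responses, space, local = FALSE)
cor(tab$block, tab$global_coherence, method = "spearman")
#> [1] -0.39
```

The negative rank correlation is the drifting generator's planted
signature.  The block values then become a parametric modulator:

```r
mod <- prepare_modulator(tab$global_coherence[tab$participant_id == "p01"],
                         trial_ids = 1)
timings <- trial_timing(condition = c("extended_planning",
                                      "extended_production"),
                        onset = c(0, 8), duration = c(8, 50))
des <- build_design(timings, modulators = list(coherence = mod),
                    n_volumes = 50, tr = 2.2)
des
#> Design matrix: 50 volumes x 5 regressors (TR = 2.2 s)
#>   task: extended_planning, extended_production, coherence
```

From there, `generate_bold()` / `fit_glm()` / `contrast()` /
`second_level()` carry the analysis to group statistics, and
`cluster_threshold_montecarlo()` supplies the corrected cluster-extent
threshold.  `run_pipeline()` chains all stages on synthetic data and
writes coherence tables, the design, contrast maps and a provenance
summary.  The vignette (`vignettes/coherence-pipeline.Rmd`) documents the
model, the default parameters and the design decisions.

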