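# gazentropy

Analysis of visual exploration during spatial learning from eye-tracking
scanpaths, for researchers studying how scene context — in particular
human agents whose placement is congruent or incongruent with their
surroundings — reshapes gaze behaviour and supports spatial memory in
virtual environments.

The package implements a complete pipeline:

1. **Fixation classification** of raw 90 Hz gaze samples with an adaptive
   per-segment velocity threshold (`median + 3·1.4826·MAD` per 10 s) and a
   translational-movement correction for walking observers.
2. **Gaze transition entropy (GTE).** Forward transitions over eight
   visual categories are tabulated per origin category; each row's
   conditional entropy uses the Chao–Shen coverage correction

   H(X) = − Σₓ p̂(x)·log₂ p̂(x) / (1 − (1 − p̂(x))^N),  p̂(x) = C·p_ML(x),
   C = 1 − S₁/N,

   (S₁ singleton transitions, N row total); rows are aggregated with the
   stationary distribution π of the transition matrix and normalized by
   log₂ k, giving H_norm ∈ [0, 1].
3. **Agent-locked windows.** Non-overlapping 30-s pre/post windows around
   agent encounters (per-agent 30-s refractory rule) with per-window GTE.
4. **Five Bayesian hierarchical regressions** (fitted with JAGS): Gamma–log
   models for dwelling time and pointing error, Beta–logit models for
   windowed entropy (with a dimension-5 smoothing spline over encounter
   index), post-encounter entropy under sum-to-zero contrasts, and the
   mediator model — with the Smithson–Verkuilen transform for bounded
   responses and Normal(0,1) / Cauchy(0,2.5) / Student-t weak priors.
5. **Counterfactual mediation** by Bayesian parametric g-computation:
   plug-in mediator means per agent level and context, context-marginal
   potential outcomes Y₀₀, Y₁₀, Y₁₁, and NDE = Y₁₀−Y₀₀, NIE = Y₁₁−Y₁₀,
   TE = Y₁₁−Y₀₀ with their risk-ratio counterparts (TE = NDE + NIE and
   RR_TE = RR_NDE·RR_NIE hold exactly per posterior draw).
6. **A synthetic-data generator** reproducing the statistical structure
   the analysis assumes — condition-specific Markov transition matrices,
   Gamma dwell durations, post-encounter flattening, and linked
   mediator/outcome models — so the whole pipeline is testable end to end.

## Worked example

```r
library(gazentropy)

# Chao-Shen corrected entropy of a sparse transition-count row
chao_shen_entropy(c(2, 1, 1))
#> $H
#> [1] 2.543818     # bits; plug-in estimate would give 1.5
#> $C
#> [1] 0.5          # estimated sample coverage

# simulate one exploration session, classify, and score it
cfg <- sim_config(n_participants = 2, n_sessions = 1,
                  session_length = 600, seed = 7)
ss  <- simulate_gaze_session(cfg, participant = 1, session = 1,
                             condition = "incongruent")
fx  <- classify_fixations(ss$samples)   # 978 fixations from 54,000 samples
gte(fx$category[!is.na(fx$category)])
#> Gaze transition entropy
#>   categories observed : 7 of 8
#>   H_global            : 1.6090 bits
#>   H_norm              : 0.5363
#>   stationary weights  : eigen

# agent-locked 30-s windows: entropy rises after encounters
enc <- encounter_gte(fx, extract_encounters(fx, c(0, 600)))
colMeans(enc[, c("gte_pre", "gte_post")], na.rm = TRUE)
#>  gte_pre gte_post
#>    0.391    0.772
```

The entropy increase after agent fixations (here 0.39 → 0.77 on the
normalized scale) is the generative signature the hierarchical pre/post
model estimates on the logit scale, and the quantity the mediation
analysis routes from agent condition to pointing error.

Model fitting and mediation follow the same grammar:

```r
d <- simulate_model_data(cfg, "postgte", 500)
d$H_star <- sv_transform(d$H, nrow(d))
fit <- fit_model(model_spec("postgte"), d, mcmc_profile("test"), seed = 1)
summarize_posterior(fit, prob = 0.89)

md  <- simulate_mediation_dataset(cfg, 900)
# ... fit "mediator" and "perf", then:
# run_mediation(fit_mediator, fit_perf, w_res = 0.5, contrast = "both")
```

`run_pipeline(pipeline_config(...))` chains all stages —
simulate → classify → entropy → windows → describe → fit → mediate — with
deterministic seed fan-out and a manifest of per-stage seeds, row counts
and file digests; `pipeline_report()` assembles the result tables.

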