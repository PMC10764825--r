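# dietddm

Hierarchical Bayesian drift-diffusion modelling of dietary choice under
hunger suggestions, with the full analysis pipeline of a three-arm
suggestion-based placebo study: synthetic cohorts, Wiener first-passage
likelihoods, MCMC fitting with convergence diagnostics, DIC model
comparison, posterior-probability group contrasts, valuation regressions,
power analysis, and bootstrap ROI mediation.

## Who this is for

Researchers in decision neuroscience and biostatistics who study how
verbal suggestions (placebo manipulations) shift the latent components of
food choice — the weights of tastiness and healthiness on evidence
accumulation, the starting bias toward "yes", response caution and
non-decision time — and who need a tested, reproducible implementation
that runs end-to-end on synthetic data with a known ground truth.

## The model

Each trial's yes/no choice and signed response time (negative = "no")
follow a Wiener diffusion between absorbing boundaries 0 and α, starting
at fraction β of the separation, with drift

```
δ = ω_taste · TD + ω_health · HD,   TD, HD ∈ {−2, −1, 1, 2}
```

plus inter-trial drift variability δ_t ~ N(δ, ς²) and non-decision time
τ.  All five families (α, β, ω_taste, ω_health, τ) carry participant-level
random effects with uniform hyper-means and Gamma(1, 0.1) hyper-variances;
ς² has a Gamma(1, 0.1) prior truncated to [0.001, 2].  Posteriors are
sampled by adaptive Metropolis-within-Gibbs (3 independently seeded
chains), model variants are compared by `DIC = mean(D) + 0.5·var(D)`, and
group differences are summarized by `PP = mean((d_A − d_B) > 0)` with
`p_mcmc = 1 − PP` over concatenated chains.

## A worked example

```r
library(dietddm)

# a 12-participant, 150-trial cohort with the default ground truth
cfg <- ground_truth_config(n_per_group = 4, n_trials = 150, seed = 11)
study <- generate_study(cfg)

model <- build_ddm_model(study$trials, "two_weight")
fit <- sample_posterior(model, n_chains = 3, n_iter = 2400,
                        burn_in = 1200, thin = 3, seeds = c(101, 202, 303))

max(psrf_table(fit)$psrf)
#> [1] 1.009173
cor(study$subject_params$w_taste, subject_posterior_means(fit, "w_taste"))
#> [1] 0.9355732
mean(concat_chains(fit, "mu_w_taste"))
#> [1] 0.6342933
```

The maximum potential scale reduction factor of 1.009 says all three
chains agree for every subject- and population-level parameter (values at
or below 1.02 are taken as converged).  The correlation of 0.94 between
generating and recovered subject taste weights shows the per-participant
weights are identifiable at 150 trials, and the population taste-weight
mean 0.63 sits next to the cohort's generating mean 0.62.

Other entry points: `sample_size_ttest(0.5, power = 0.80, tails = 1)`
returns the 51-per-group/102-total a-priori sample size (59/118 at 85%
power); `bootstrap_mediation()` runs the group → ROI → hunger-change
mediation with percentile bootstrap inference and `bonferroni_gate()`
applies the 0.05/3 ROI correction; `run_pipeline(run_config(...))`
executes simulate → fit → DIC comparison → group contrasts → mediation →
valuation → report and writes a hash manifest (see
`inst/scripts/run_pipeline.R` for a shell wrapper).

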