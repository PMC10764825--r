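---
title: "Modelling suggestion-based placebo effects on dietary choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling suggestion-based placebo effects on dietary choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dietddm)
```

## The scientific problem

Verbal suggestions about a drink's effect on hunger can change how hungry
people feel and how they value food, even when the drink is plain water.
`dietddm` provides a complete, testable computational pipeline for studying
such suggestion-based placebo effects on dietary decision-making.  Its core
is a hierarchical Bayesian drift-diffusion model (DDM) of yes/no food
choices and their response times, in which the tastiness and healthiness
ratings of each food jointly drive the evidence accumulation.  Around the
core sit the surrounding analyses such a study needs: model comparison,
posterior group contrasts, per-subject valuation regressions, calorie
median splits, composite hunger scoring, a-priori power analysis, and a
bootstrap mediation of group effects through region-of-interest (ROI)
activations.  Because raw data from such studies are typically shareable
only on request, the package includes a first-class synthetic-cohort
generator so every downstream stage can be exercised and validated without
external data.

## The decision model

On each trial an evidence signal accumulates between two absorbing
boundaries: 0 ("no") and $\alpha$ ("yes").  The accumulation starts at a
fraction $\beta \in (0,1)$ of the boundary separation, drifts at mean rate

$$\delta = \omega_{taste}\,TD + \omega_{health}\,HD,$$

where $TD, HD \in \{-2,-1,1,2\}$ are the trial's 4-point taste and health
rating codes (0 is never a legal code), and is perturbed by standard
Brownian noise with unit standard deviation — the scaling convention in
which all other parameters are expressed.  The response time is the
first-passage time plus a non-decision time $\tau$; the boundary reached
determines the choice, and "no" choices are coded with negative signed
response times.  The per-trial drift is additionally drawn from
$N(\delta, \varsigma^2)$ with $\varsigma^2$ the inter-trial drift
variance, which captures trial-to-trial variability in evidence quality.

The trial likelihood is the defective Wiener first-passage density,
implemented in C++ with both the small-time and the large-time series
expansion and an automatic switch at the point where each representation
needs the fewer terms (truncation error $\le 10^{-10}$ on the normalized
density, far below the $10^{-7}$ target).  The inter-trial drift mixture
is integrated by Gauss-Hermite quadrature (9 nodes by default); an exact
zero density — e.g. a response time inside the non-decision time — is
floored at $\log f = -10^{10}$ rather than $-\infty$ so that MCMC
proposals fail gracefully.

## Hierarchy and priors

Each of the five free parameter families (boundary $\alpha$, start
fraction $\beta$, $\omega_{taste}$, $\omega_{health}$, $\tau$) has
participant-level random effects drawn from a truncated normal with a
population mean and variance:

* attribute-weight means: Uniform(-5, 5);
* boundary mean: Uniform(0.001, 2), with the subject-level boundary capped
  at 2 (the cap is read as the fixed trial-level maximum; a
  `fix_boundary = 2` flag reproduces the fully fixed reading);
* start-fraction mean: Uniform(0, 1) on the fraction scale, 0.5 neutral;
* non-decision-time mean: Uniform(0, 10) seconds;
* every population variance: Gamma(shape 1, rate 0.1), placed on the
  variance as stated (a switchable convention, since Gibbs-sampler
  folklore often parameterizes precision);
* inter-trial drift variance: Gamma(1, 0.1) truncated to [0.001, 2], per
  participant.

The single-attribute variants (`taste_only`, `health_only`) fix the
excluded weight to zero; everything else is unchanged.

## Posterior sampling

The target density (priors × Wiener likelihood) is sampled by adaptive
Metropolis-within-Gibbs: scalar random-walk updates of every subject-level
parameter and every hyper-parameter, with each proposal scale adapted
toward 44% acceptance during burn-in by a Robbins-Monro rule and frozen
afterwards, so the post-burn-in kernel is a valid time-homogeneous MH
chain.  Initial values are drawn from the priors, except each
participant's non-decision time, which starts below their minimum absolute
response time so no trial begins in the floored likelihood region;
degenerate starts are redrawn (bounded retries).  Chains are fully
deterministic given their seeds, and each chain requires its own distinct
seed.

Groups are fitted separately, as in the study design the package
emulates.  The default reduced-scale settings (3 chains, 2,400 post-burn-in
iterations after 1,200 burn-in, thinning 10 -> 3 at this scale, i.e. 800
retained draws per chain) were chosen so a 12-participant × 150-trial fit
completes in about two minutes on one CPU while still passing the
convergence bar below; the study-scale settings (3 × 10,000 iterations
after 5,000 burn-in, thinning 10) are plain arguments.  Note one
arithmetic choice: 3 chains × 10,000 thinned by 10 gives 1,000 retained
draws per chain and 3,000 concatenated — the "3,000-values-per-parameter"
reading — and all posterior-probability contrasts operate on the
concatenated draws, paired by draw index.

With `use_likelihood = FALSE` the target collapses to the prior and the
sampler switches to ancestral prior draws — an independence MH kernel
whose proposals are always accepted when the target is the prior — giving
i.i.d. draws for exact prior-recovery checks (Kolmogorov-Smirnov tests of
every population-level marginal against its stated prior).

Convergence is monitored by the classic Gelman-Rubin potential scale
reduction factor (between/within-chain variance ratio), computed for every
subject- and population-level parameter; the default synthetic fit keeps
the maximum at or below 1.02, with the deviance chain's psrf ~ 1 reported
separately.  Lag-100 autocorrelations of the retained chains are ~0.

## Model comparison and group contrasts

Model fit is compared by the deviance information criterion in its
half-variance form,

$$\mathrm{DIC} = \overline{D} + \tfrac{1}{2}\mathrm{var}(D),$$

with $D = -2\sum \log f$ the per-draw deviance and the sample $(n-1)$
variance (the convention difference is negligible at thousands of draws).
DIC is reported unscaled.  Group differences in population-level
parameters are summarized by the posterior probability

$$PP = \mathrm{mean}\big((d_A - d_B) > 0\big), \qquad p_{mcmc} = 1 - PP,$$

over the concatenated difference draws, with strict inequality so
exact-zero draws count against the stated direction.  Default directions
follow the design's prior predictions — taste weight and start bias:
increased > decreased and control > decreased; health weight reversed —
and are configurable per contrast.

## The synthetic cohort

The generator emulates the statistical structure of a three-arm
suggestion study (decreased-hunger, control, increased-hunger): balanced
seeded group assignment; 4-point taste/health ratings (uniform by default
— empirical rating frequencies are not published — with an optional
Gaussian-copula correlation, default 0); log-normal calorie densities with
median 1.48 kcal per 100 g/ml; 7-point composite hunger and 10-point
expectancy ratings from truncated normals; and choices/RTs simulated by
Euler-Maruyama at the task's 8 ms step with a 10 s censoring horizon
(matching the non-decision-time prior's upper bound; censored trials are
excluded and counted).

Only group *differences* in the decision parameters are published, so the
absolute generating levels are package defaults chosen to reproduce all
printed pairwise differences exactly: taste weight 0.50 / 0.66 / 0.70,
health weight 0.10 / 0.14 / 0.04, start bias 0.52 / 0.57 / 0.56 for
decreased / control / increased (differences: taste +0.20 and +0.16,
health 0.06 and 0.10, bias +0.04 and +0.05).  Boundary (1.4), non-decision
time (0.35 s), drift variance (0.30) and the between-subject SDs (0.15,
0.08, 0.04, 0.15, 0.08, 0.08) are unpublished and set to values typical of
food-choice DDM fits; all are configurable.  Hunger-change means (+0.21 /
+0.60 / +0.96 for decreased / control / increased) follow the published
pilot means, and expectancy means (5.6 / 4.3 / 5.3) reproduce the reported
pattern of both suggestion groups expecting more change than controls.
The mediation table is generated directly from the structural chain
$M = a X + \epsilon_M$, $Y = b M + c' X + \epsilon_Y$ with defaults
$a = 0.5$, $b = 0.4$, $c' = 0.21$, unit noise; ROI betas are scalars by
construction (no image synthesis), and the true indirect effect $ab$ is
recorded in the output metadata.

What passing tests on such data do *not* show: real rating distributions
are not uniform or independent of calorie density, real RT distributions
carry contaminants (lapses, fast guesses) the Wiener likelihood does not
model, real ROI betas are noisy spatial summaries rather than clean linear
functions of group, and real hunger scales are discrete.  Recovery and
convergence results here demonstrate correctness of the machinery, not
robustness to those violations.

## Numerical and design choices

* **Simulator discretization.**  Plain Euler-Maruyama at 8 ms has the
  standard first-passage overshoot bias (the effective boundary widens by
  about $0.58\sqrt{dt}$), visible as a choice-probability shift of ~0.01
  at typical parameters.  The step size is an argument; agreement tests
  against the analytic density run at 0.2 ms, where the bias is inside
  Monte-Carlo noise.  Because generation (discrete) and fitting
  (continuous-time likelihood) differ slightly, fitted boundaries run a
  few percent above generating values; weights, bias and non-decision
  time are recovered essentially unbiased.
* **Rating-code validation** rejects 0 everywhere: the 4-point scale has
  no neutral point, and a zero code silently destroys the drift mapping.
* **Median-split ties** go to the low-calorie half (the convention is
  otherwise unstated).
* **Power analysis sidedness.**  The published behavioural sample-size
  bracket (51-59 per group at 80-85% power, d = 0.5, alpha = 0.05) is
  reproduced by a one-tailed two-sample noncentral-t computation;
  two-tailed gives 64-73.  One-tailed is therefore the default, consistent
  with the explicitly one-sided imaging power calculation.
* **Bootstrap mediation.**  Raw observations are resampled (10,000 draws
  by default) with multinomial weights after canonically ordering the
  records, so p-values are invariant to row order; degenerate resamples
  (single group level, collinear X/M) are redrawn and counted.  "Weighted
  two-tailed p-values from bootstrap confidence intervals" is not a
  defined estimator, so the standard percentile convention
  $p = 2\min(\Pr(\theta^* \le 0), \Pr(\theta^* \ge 0))$ is the default
  with a normal-approximation option.  Both conventions are strongly
  conservative for the product $ab$ when *both* paths are null (the
  product's bootstrap distribution excludes zero only when each path
  individually clears ~2.3 SD), a known property of product-coefficient
  tests; calibration simulations should therefore use single-path nulls
  if nominal type-I behaviour is the question.
* **Reduced problem sizes.**  The convergence/recovery cohort is 12
  participants × 150 trials; model-recovery replicates use 9 × 100 and
  directional-sensitivity replicates 20 participants per suggestion group
  × 150 trials (the smallest scale at which the 0.04 bias difference is
  reliably decodable; the emulated study ran ~85 per group) — large
  enough for the published effect pattern, small enough to run in
  minutes.
* **Quadrature accuracy.**  With 9 Gauss-Hermite nodes the log-density
  error against a 41-node reference is below 1e-3 for inter-trial drift
  variances up to ~0.6 (the generating regime); very large variances near
  the 2.0 truncation bound would need more nodes (`gh_nodes` argument).
* **Hierarchical shrinkage.**  Subjects whose generating taste weight
  lies far from the group mean are pulled toward it, as expected from
  partial pooling with ~12 subjects; subject-level recovery correlations
  stay above 0.8 at 150 trials while extreme individual weights are
  attenuated.

## A worked run

```{r example}
cfg <- ground_truth_config(n_per_group = 4, n_trials = 150, seed = 11)
study <- generate_study(cfg)
model <- build_ddm_model(study$trials, "two_weight")
fit <- sample_posterior(model, n_chains = 3, n_iter = 2400,
                        burn_in = 1200, thin = 3, seeds = c(101, 202, 303))
max(psrf_table(fit)$psrf)                 # convergence check
cor(study$subject_params$w_taste,
    subject_posterior_means(fit, "w_taste"))  # recovery check
```

## Known limitations

The sampler is a general-purpose scalar Metropolis scheme: adequate at
desk scale, slower to mix than a tuned Gibbs or Hamiltonian kernel at
study scale.  There are no collapsing bounds, no attribute-onset
asymmetry between taste and health, no trial-order dynamics, no
contaminant mixture for lapses, and no WAIC/LOO (DIC only, by design).
Linear mixed-effects analyses of hunger/expectancy outcomes are ordinary
off-the-shelf fits and are not re-implemented here; their group codings
(-1/0/1) are reused by the generator and contrasts.
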