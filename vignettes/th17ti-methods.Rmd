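---
title: "Methods: Bayesian calibration and discrimination of Th17 core-network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian calibration and discrimination of Th17 core-network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The modeling problem

Naive CD4+ T cells differentiate into Th17 cells when stimulated with
IL6 and TGFb. The core transcriptional program involves STAT3
(phosphorylated downstream of IL6), the Th17 master regulator RORgt
(activated jointly by intracellular TGFb and phospho-STAT3), and FOXP3,
the master regulator of the competing iTreg lineage. `th17ti` encodes
this core network as a family of mass-action ODE models, couples them to
time-course RNA-seq read counts through a negative-binomial (NB)
observation model, and asks a model-discrimination question: which
combination of four *hypothetical* regulatory mechanisms -- basal FOXP3
induction, TGFb-driven FOXP3 induction, FOXP3 inhibition of RORgt, and
STAT3 inhibition of FOXP3 -- does the data support? Each admissible
combination (FOXP3 must be produced somehow, so at least one induction
mechanism is active) gives one of twelve variants M1--M12
(`build_variant()`).

# The dynamic model

Extracellular cytokines convert to intracellular pools at unknown
first-order rates, giving closed forms
`[IL6_int](t) = (added/reference) (1 - exp(-theta1 t))` and likewise for
TGFb with rate `theta9`; doses are expressed relative to the Th17
polarizing condition (IL6 20 ng/ml, TGFb 1 ng/ml). The six remaining
states follow mass-action kinetics: STAT3 mRNA (basal transcription
`theta2`, autoregulation by phospho-STAT3 `theta3`, degradation
`theta4`), STAT3 protein (translation `theta5`, IL6-driven
phosphorylation `theta6`, degradation `theta7`), phospho-STAT3
(degradation `theta8`), RORgt mRNA (activation
`theta10 [TGFb_int][STAT3*]`, optional inhibition `theta11 [FOXP3*]`,
degradation `theta12`; no basal term -- RORgt is essentially absent in
naive cells), FOXP3 mRNA (optional basal `theta13`, optional TGFb-driven
`theta14`, optional inhibition `theta15 [STAT3*]`, degradation
`theta16`), and FOXP3 protein (`theta17`, `theta18`). Proteins are
dimensionless and start at 1 (phospho-STAT3 at 0); mRNA initial levels
are taken from the data (replicate-mean abundance at 0 h). RORgt mRNA
can alternatively start at 0 (`rorgt_from_data = FALSE`); from-data is
the default because all measured mRNA initials come from the data.

Rates attached to inactive mechanisms are *removed* from the parameter
vector rather than pinned at zero, so each variant's prior lives only on
its own mechanisms and the evidence's complexity penalty acts on the
true model dimension (14 backbone rates + 1--4 mechanism rates).

**Numerics.** The system is integrated with a BDF stiff solver
(deSolve/`lsode`, `mf = 22`, rtol 1e-8 / atol 1e-10) with the
right-hand side compiled in C; wide log-normal prior draws routinely
produce stiff regimes. Cytokine levels enter the right-hand side through
their closed forms, reducing the integrated dimension to six; the full
10-state path (`cytokines = "ode"`) is kept for validation (closed-form
agreement below 1e-6, cytokine mass balance). Failed integrations
(divergence, step-count exhaustion) return a flagged trajectory -- never
silent NaN -- and the likelihood maps them to `-Inf`, so the sampler
simply rejects such proposals. We deliberately do not clip small
negative solver undershoots before evaluating production terms;
tolerances are tight enough that undershoot stays below 1e-8 and
clipping would bias the likelihood.

# The observation model

Read counts are modeled as `D_ijk ~ NB(mu_ij, phi_ij)` with
`mu_ij = count_scale * L_jk * x_i(t_j, theta)`, where `L_jk` is the
library size of sample (j, k), `phi_ij` the gene- and time-specific
dispersion (estimated upstream, e.g. by edgeR, and consumed as input),
and variance `mu + phi mu^2`. The pmf is evaluated through
log-gamma/log-beta identities, which keeps it finite up to counts of
1e7 and accurate in the Poisson limit.

`count_scale` is the model's scaling constant: model states are O(1)
dimensionless abundances (proteins start at 1; rates have standard
log-normal priors centred at 1/h), while a single transcript's share of
a bulk library is ~1e-4 and below. The constant (default 1e-4 in the
synthetic generator, stored with the data) carries that unit conversion.
The likelihood is invariant to moving mass between `count_scale`,
`L_jk`, and the state scale, so its exact value is a units convention,
not a fitted quantity -- but *some* such constant is essential: without
it O(1) states against 1e7-read libraries imply per-gene means of 1e7
reads and log-likelihood ranges of ~1e6 nats across the prior, which
destroys the conditioning of evidence estimation.

All rates are strictly positive with independent standard normal priors
on their natural logarithms (`log_prior()`); sampling happens in log
space. Natural rather than base-10 logs are assumed.

For continuous-time prediction the likelihood is interpolated
(`interpolated_loglik()`): the mean library size replaces `L_jk`,
dispersions are interpolated linearly in time (exact at observed time
points -- the simplest scheme with that property), and the NB kernel is
evaluated as a continuous function of its first argument.

FOXP3 protein dose-response data (% FOXP3+ cells at 72 h under TGFb
dilutions 1/16...1 ng/ml at fixed IL6) extend the likelihood
multiplicatively with normal terms: observed mean ~
`N(s * [FOXP3*](72 h; dose), sd^2)` with the replicate SD. The scale
`s` linking the dimensionless latent level to a percentage is treated
as one additional free parameter with the same log-normal prior,
because the dose-response *shape*, not its absolute level, carries the
evidence; a fixed-scale mode is available through
`protein_loglik(..., s = )`. Since nothing feeds back into the FOXP3
equations except phospho-STAT3 (dose-independent when only TGFb
varies), the latent level is affine in the dose and all five doses
follow from two integrations; this superposition is the default and is
property-tested against per-dose integration.

# Inference

Marginal likelihoods (evidence) are estimated by thermodynamic
integration over power posteriors
`p_beta ∝ p(D|theta)^beta p(theta)` on the ladder
`beta_j = ((j-1)/(N_beta-1))^5`, `N_beta = 30` by default; the
expected log-likelihood per rung (estimated by the sample mean over
retained draws) is integrated with the trapezoidal rule. Samples come
from a population MCMC sampler (`power_mcmc()`): one chain per
temperature on the product target, each iteration performing one
symmetric multivariate-normal Metropolis update per chain followed by
exchange attempts between adjacent temperature pairs chosen uniformly
at random. Five independent samplers are run per model
(`sampler_settings()`); the evidence is their mean with the
between-sampler SE. Convergence is monitored by per-parameter
Gelman-Rubin PSRF across samplers plus acceptance-rate summaries.

Design choices where the standard construction leaves freedom:

* **Exchange frequency.** We attempt `N_beta - 1` uniformly chosen
  adjacent-pair swaps per iteration. Exchange moves cost no likelihood
  evaluations, and a single attempt per iteration demonstrably
  throttles information flow along a 10--30 rung ladder at desk scale;
  each attempt individually satisfies detailed balance, so the product
  target is preserved.
* **Initialization.** All chains start at the best-log-likelihood point
  among 64 prior draws (`init_strategy = "best_of_prior"`). Independent
  cold prior starts leave mid/high-temperature chains in transients of
  ~1e5 nats that a desk-scale burn-in cannot absorb;
  `init_strategy = "prior"` retains the independent-prior-draw
  behaviour.
* **Adaptation.** Burn-in (default 50%) uses isotropic proposals whose
  scalar step size is tuned toward ~30% acceptance in batches; at the
  burn-in boundary, per-temperature proposal covariances are set once to
  `2.38^2/d` times the empirical covariance of the late burn-in history
  (plus diagonal jitter) and then frozen for the collection phase.
* **Thinning.** The full-scale protocol retains every 1000th iteration
  and targets final sample sizes of 10,000 (count-only) or 5,000 (with
  protein data) per model; package defaults thin every 10th so that
  exploratory runs are cheap. Reduced-scale tests use 2,500--12,000
  iterations with 8--12 temperatures, sizes chosen so the whole suite
  runs on one CPU in minutes.
* **Seeding.** A master seed deterministically derives per-sampler
  seeds, making every fit and the full generate-fit-predict pipeline
  bit-reproducible.

Ranking (`rank_models()`) orders variants by log evidence with no prior
model preference; exact ties break deterministically by variant id.

# Posterior prediction

`posterior_predictive()` draws, for each retained posterior sample, one
observation per grid point from the interpolated NB density and reports
pooled empirical percentiles (type-7; 5/50/95 by default) per gene on
the common relative-abundance scale (counts divided by
`count_scale * library size`). One predictive draw per posterior draw
keeps cost linear and is the standard posterior-predictive Monte Carlo.
`predict_dose_response()` reports the posterior mean and percentiles of
the *latent* scaled FOXP3 level at 72 h per dose (the protein noise
model has no count-type counterpart, so the latent mean is the natural
"average level"); failed simulations are dropped and counted, never
imputed. Structurally, basal-only variants (e.g. M4) are exactly
dose-invariant, while variants with the TGFb mechanism predict levels
nondecreasing in dose for every draw -- the qualitative signature that
protein data contribute to discrimination.

# The synthetic-data generator

`synth_config()`/`generate_dataset()` emulate the statistical structure
of the motivating experiment: 3 genes (STAT3, RORGT, FOXP3) x 8 time
points (0, 1, 3, 6, 12, 24, 48, 72 h -- dense early, where
differentiation kinetics are fast) x 3 replicates; library sizes
log-uniform in [5e6, 2e7] (typical bulk depth); dispersions log-uniform
in [0.01, 0.5] per gene and time (spanning typical RNA-seq
over-dispersion); NB counts drawn from the trajectory of a chosen
variant; optionally a 5-dose protein table (doses 1/16...1 ng/ml,
normal noise with SD 2 percentage points, true scale 25 -- a unit
latent level maps to 25% FOXP3+ cells, placing the dilution series in
the single-digit-to-~30% range typical of such assays).

The generating truth defaults to a fixed, documented reference rate
vector (`reference_theta()`, all rates 0.2--0.6/h): one underlying
biology with STAT3 basally stable, RORgt induction following the
cytokine ramp, and FOXP3 shaped by the active mechanisms, with every
log-rate inside the bulk of the prior. A prior-drawn truth
(`theta = "prior"`) is supported but not the default, because a random
prior draw need not be integrable or biologically sensible, and
validation conditions should not depend on which truth a seed happens
to produce. The generator refuses non-integrable truths.

What passing tests on these fixtures shows -- and what it does not: the
generator inverts the exact observation model the likelihood assumes
(NB with known dispersions and library sizes, no batch effects, no
mapping or normalization artifacts, a correctly specified ODE family).
Recovery and discrimination results on synthetic data therefore
validate the *inference machinery*, not the biological adequacy of the
model for any particular real data set.

# Validation protocol and problem sizes

The test suite checks, at desk scale on one CPU: closed-form cytokine
agreement (<1e-6 over 100 prior draws); NB pmf normalization, Poisson
limit, and moment identities (1e6 draws); TI accuracy on a conjugate
normal-normal toy with analytic evidence (within 0.1 nats at the
30-rung exponent-5 ladder, with bias shrinking as the ladder
densifies); prior-chain correctness (KS) and exact product-target
occupancy on an enumerable two-temperature toy (chi-squared);
90% credible-interval coverage of the generating log-rates of M8
(>= 80% of 17 parameters; 10 temperatures, 10,000 iterations, 3
samplers); evidence-based recovery of M8 against M4 and M12 from
count + protein data in >= 4 of 5 seeded replications (10 temperatures,
2,500 iterations, 2 samplers per fit); exact dose-invariance of M4 and
per-draw dose-monotonicity of M8 predictions; and PSRF < 1.1 across
independent toy samplers. In pilot runs of the discrimination check the
evidence gaps were ~3--10 nats for M8 over M12 (the Occam penalty for
the superfluous basal mechanism) and ~50--90 nats over M4 (which cannot
reproduce the protein dose dependence), against between-sampler SEs
well below the gaps.

# Known limitations

* The evidence estimates at reduced scale carry ladder-discretization
  bias (shared across variants of similar dimension); absolute log
  evidences should be compared only within a run at a fixed ladder.
* The NB likelihood consumes dispersions and library sizes as known
  inputs; uncertainty in their upstream estimation is not propagated.
* The protein noise model is a normal approximation on percentages and
  can place mass below 0 at low doses.
* Exchange pair selection and sampler scheduling follow one standard
  reconstruction of population MCMC; other schedules (deterministic
  sweeps, all-pairs) are equally valid and would differ only in
  efficiency.
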