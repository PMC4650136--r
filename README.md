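# th17ti

Bayesian calibration and evidence-based discrimination of mechanistic
ODE models of the Th17 core transcription-factor network against
time-course RNA-seq read counts.

## The problem

Th17 differentiation of naive CD4+ T cells is driven by IL6 and TGFb
through STAT3, the master regulator RORgt, and FOXP3 (the master
regulator of the competing iTreg lineage). The backbone of the network
is well established; four regulatory mechanisms are hypotheses:

1. basal FOXP3 induction,
2. FOXP3 induction by TGFb,
3. RORgt inhibition by FOXP3,
4. FOXP3 inhibition by STAT3.

Every admissible on/off combination defines one of twelve ODE model
variants M1–M12. `th17ti` fits each variant to time-course read counts
(optionally extended by FOXP3 protein dose–response measurements) and
ranks the variants by marginal likelihood, so that the data decide which
mechanisms are supported.

## The statistics

Counts are modeled directly, without ad hoc normalization:

    D_ijk ~ NB(c · L_jk · x_i(t_j, θ), φ_ij),   Var = μ + φ μ²

with library sizes `L_jk`, gene/time dispersions `φ_ij` (consumed as
input, e.g. from edgeR), model trajectory `x(t, θ)`, and a fixed model
scaling constant `c` converting dimensionless model states into
per-library read shares. Rates carry independent standard normal priors
on `log θ`. Evidence `p(D|M) = ∫ p(D|θ,M) p(θ|M) dθ` is estimated by
thermodynamic integration over power posteriors
`p_β ∝ p(D|θ)^β p(θ)` on the ladder `β_j = ((j−1)/(N_β−1))^5`
(N_β = 30 by default), sampled with a population MCMC sampler (one
chain per temperature, covariance-adapted local moves plus exchange
moves, five independent samplers, Gelman–Rubin PSRF monitoring).
Posterior predictive bands in continuous time use an interpolated NB
likelihood; FOXP3 dose–response predictions use the latent protein
level at 72 h.

See `vignettes/th17ti-methods.Rmd` for the full model, priors,
sampler design, and numerical choices.

## Worked example

Generate a synthetic data set from variant M8 (TGFb-driven FOXP3 with
both inhibitory mechanisms), fit M4/M8/M12, and rank them:

```r
library(th17ti)

ds <- generate_dataset(synth_config(variant = 8, seed = 42))
ds$counts
#> Th17 count data: 3 genes x 8 time points x 3 replicates

st <- sampler_settings(n_beta = 10, n_iter = 2500, thin = 5,
                       n_samplers = 2)   # reduced desk scale
fits <- lapply(c(8, 4, 12), function(v)
  fit_th17(ds$counts, v, protein = ds$protein, settings = st, seed = 1))

rank_models(fits)
#>   variant log_evidence         se rank
#> 1       8    -461.5272 0.08744227    1
#> 2      12    -465.9106 0.07440098    2
#> 3       4    -535.4322 0.18642875    3
```

The generating model M8 wins. M12 (which adds a superfluous basal
FOXP3 term) trails by ~4 nats — the Occam penalty of an extra
mechanism — and M4 (basal-only FOXP3, no TGFb dependence) loses ~74
nats because it cannot reproduce the protein dose–response:

```r
predict_dose_response(fits[[1]], max_draws = 100)
#>   dose_ng_ml  mean   q05   q50   q95
#> 1       0.06  1.91  1.73  1.88  2.12
#> 2       0.12  3.81  3.47  3.77  4.23
#> 3       0.25  7.62  6.93  7.53  8.46
#> 4       0.50 15.24 13.86 15.07 16.92
#> 5       1.00 30.48 27.72 30.13 33.85
```

i.e. the predicted % of FOXP3+ cells at 72 h rises with the TGFb dose;
under M4 the same table is exactly flat. `posterior_predictive()` gives
the per-gene 5/50/95% predictive bands over continuous time on the
relative-abundance scale.

A YAML-driven pipeline (generate → fit → predict, with TSV outputs
carrying the seed and a config hash) is exposed through
`cmd_generate()` / `cmd_fit()` / `cmd_predict()` and the thin CLI in
`inst/exec/th17ti`.

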