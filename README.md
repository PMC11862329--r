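# bufferscape

Structured demographic buffering in stochastic environments.

`bufferscape` is for population ecologists and stochastic demographers who
want to know *how buffered* a size-structured population is against
environmental stochasticity, and *why*: which environmental components
(temporal autocorrelation φ vs. variance σ²) drive shifts in buffering, and
through which demographic mechanisms (population structure vs. the
progression and fertility rates themselves). It works with environmentally
explicit, parameter-stochastic integral projection models (IPMs): vital-rate
regressions over size and named environmental drivers, discretized to kernel
matrices K = P + F and driven through time by AR(1) environmental series
rescaled to exact target moments.

## The core estimator

The buffering measure is the summed numerical stochastic elasticity of
variance. A timeseries of kernels A_t yields a stochastic growth rate
λs = exp E[ln(N_{t+1}/N_t)] (burn-in discarded). For each kernel element
a_ij with temporal variance var(a_ij,t) > 0, the element's series is
variance-perturbed — deviations from its temporal mean scaled by √(1+δ),
δ = 10⁻⁵, so the sample variance grows by exactly (1+δ) — the population is
re-projected through the otherwise identical sequence (common random
numbers), and

    E_ij = [var(a_ij,t)/λs] · (λs* − λs) / (δ · var(a_ij,t))

∑E_ij ≤ 0 in practice: it is the proportional cost of demographic-rate
variance to λs, and values closer to 0 mean a more buffered population.
Perturbing only the progression subkernel P (survival-dependent size
transitions) or only the fertility subkernel F gives subkernel sums whose
difference, the P–F contribution, says which rates' variance costs more.
Structure diagnostics (average size distribution, ASD-weighted expected
buffering and its scaled deviance from ∑E, and the mean buffered size — the
elasticity-weighted centroid of the size domain) link buffering to
population structure. A fully factorial φ × σ²prop landscape is swept by
`run_landscape()`, and each landscape response is attributed to
environmental components by polynomial regression (degrees 1–3 per
predictor, optional interaction, AIC-selected) with sequential
sums-of-squares shares.

## Worked example

```r
library(bufferscape)

ipm <- make_reference_species()          # documented synthetic perennial
env <- generate_driver_matrix(ipm, phi = 0.3, sigma2_prop = 1,
                              T = 1000, seed = 42)
seq <- build_kernel_sequence(ipm, env)
n0  <- rep(1/60, 60)

el  <- stochastic_elasticity_matrix(seq, n0)   # whole-kernel sweep
sk  <- subkernel_elasticities(seq, n0)         # P and F sweeps
asd <- average_size_distribution(seq, n_inits = 200, seed = 1)
profile <- stage_buffering_profile(el$E)
```

This prints (via the obvious `cat()` calls):

```
lambda_s        0.9568
lambda_1        0.9640
sum_E           -0.00908
P-F contribution -0.00908
expected buffering | ASD -0.000134
mean buffered size 0.573
```

Read: under a moderately autocorrelated environment (φ = 0.3) at baseline
variance, stochasticity costs this declining population about 0.7% of log
growth per step (λs < λ1); the summed elasticity −0.0091 quantifies that
cost per unit proportional variance. The P–F contribution equals ∑E here
because the reference species' fertility is environment-independent (all
variance cost sits in progression). Buffering is centred slightly above
mid-domain sizes (mean buffered size 0.57), and the ASD-weighted expected
buffering is far less negative than ∑E because most individuals sit in
stages whose transitions carry little variance cost.

A thin CLI wraps the same functions
(`inst/cli/bufferscape.R`: `synthesize-species`, `lambda-s`, `elasticity`,
`simulate-landscape`, `partition`); model files are plain JSON (see
`?read_model`), and manifests for three published species' driver
structures ship in `inst/extdata/` for users who transcribe the
corresponding vital-rate coefficients.

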