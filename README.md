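# debipm

Size-structured demographic projection for the bulb mite (*Rhizoglyphus
robini*) in fluctuating food environments, built on an integral
projection model (IPM) whose vital rates come from dynamic energy budget
(DEB) theory. The package is aimed at population ecologists who want to
ask how noise colour, the frequency of good periods, and size-selective
harvesting shape the long-run stochastic growth rate of a fast,
plastic life history — and which life-history traits that growth rate is
most sensitive to.

## The model

The state of a female is her body length `L` (mm). Over one day she
survives, grows, and (if mature) produces eggs, so the female length
distribution `N(L, t)` evolves as

    N(L', t+1) = ∫_Ω [ D(L', L) R(L) + G(L', L) S(L) ] N(L, t) dL

with four vital-rate functions driven by the feeding level `E(Y)` ∈
(0, 1] (a gut-fullness proxy for food availability):

- **Survival** `S(L) = exp(-μ)` while maintenance can be met
  (`L ≤ Lm·E(Y)/κ`), 0 beyond that starvation bound.
- **Growth** `G(L', L)`: Gaussian around the von Bertalanffy mean
  `L·exp(-ṙB) + (1 - exp(-ṙB))·L∞`, with `L∞ = Lm·E(Y)` and
  `ṙB = 1/(151.0 - 137.8·L∞)`; s.d. `(1 - exp(-ṙB))·Lm·σ(Y)`.
  Individuals above `L∞` shrink.
- **Reproduction** `R(L) = E(Y)·Rm·L²/Lm²` for mature females
  (`L ≥ Lp = 0.539·L∞` — maturation is plastic), 0 otherwise.
- **Inheritance** `D(L', L)`: all offspring enter at the birth length
  `Lb` (point offspring-size distribution).

The kernel is discretized over 200 length bins (destination bins
integrated exactly by normal CDF differences) and projected daily
through food time series that reproduce a laboratory harvesting
experiment: 37 four-day blocks of 2 or 8 yeast rods whose temporal
arrangement is recoloured blue/white/red by spectral mimicry, or a
two-state Markov chain with daily switching probabilities `p`
(good→bad) and `q` (bad→good), autocorrelation `ρ = 1 - p - q` and
good-state frequency `f = q/(p + q)`. Size-selective constant-effort
harvesting removes 50% of adults above 1.0235× the mean adult length
every 8th day. The headline output is the log stochastic growth rate
`log λs = (1/τ) Σ log(N_{t+1}/N_t)` and its elasticities to the
life-history parameters.

## Worked example

```r
library(debipm)
params <- deb_params()      # published bulb mite life-history values
grid   <- size_grid(params) # 200 bins on [0.9*Lb, Lm]

# the experiment's food series, recoloured blue by permutation
white <- make_white_series(seed = 1)
blue  <- optimise_autocorrelation(white, "minimize", seed = 1)
sim <- run_experiment_simulation(blue, EY_low = 0.25, EY_high = 0.45,
                                 grid = grid, rule = harvest_rule())
sim
#> DEB-IPM experiment simulation (blue noise, harvest on)
#>   EY low/high/mid: 0.25 / 0.45 / 0.35
#>   tau = 148 days, 37 censuses
#>   log lambda_s = 0.01021
#>   mean log counts: eggs 6.588, juveniles 5.190, adults 4.533
```

The blue-recoloured series keeps the white series' value multiset
(mean 5.24 rods, sample variance 9.19) while its lag-1 autocorrelation
drops to -0.873. Under it, the harvested population still grows
(`log λs = 0.0102` per day) and the average census holds about
`exp(4.53) ≈ 93` adult females.

```r
# a red, good-environment-dominated Markov regime
env <- markov_environment(p = 0.1, q = 0.3)   # rho = 0.6, f = 0.75
stochastic_lambda(env, params, grid, seed = 1)
#> [1] 0.04205  (attr "tau": 2500)

elasticity(env, params, grid, seed = 1)
#>   parameter  elasticity
#> 1       L_b  0.12757
#> 2  lp_coeff -0.11017
#> 3       L_m -0.01253
#> 4       R_m  0.02540
#> 5  rb_scale  0.04622
#> 6     kappa  0.00000
#> 7        mu -0.02923
```

Here the population grows at `log λs = 0.042` per day and is most
sensitive to the birth length (a 1% larger egg raises `λs` by about
0.13%), with the maturation-length coefficient a close negative second.
`crosslevel_sweep()` repeats the experiment simulation over grids of
low/high feeding levels, `stochastic_grid()` and `elasticity_grid()`
map `log λs` and its most influential parameter over `(p, q)`, and
`generate_study()` / `bootstrap_bca()` / `compare_to_observed()` run
the prediction-versus-census comparison end to end on synthetic tables
(a pre-generated one ships in `inst/extdata/`).

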