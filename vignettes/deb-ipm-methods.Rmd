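---
title: "Methods: a DEB-based integral projection model for bulb mites in stochastic environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a DEB-based integral projection model for bulb mites in stochastic environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debipm)
```

## The model and its assumptions

`debipm` projects the length distribution of female bulb mites
(*Rhizoglyphus robini*) one day at a time. Unlike a regression-based
integral projection model (IPM), every vital rate is a closed form from
dynamic energy budget (DEB) theory, so each parameter is an individual
life-history trait rather than a statistical coefficient. The
environment enters through a single scalar, the feeding level $E(Y) \in
(0, 1]$: the expected scaled gut fullness, 0 for an empty gut, 1 for ad
libitum food.

Given $E(Y)$, a female of length $L$ (mm) experiences:

* **Survival.** A constant background mortality $\mu$ gives daily
  survival $e^{-\mu}$, cut to zero above the starvation bound $L >
  L_m E(Y)/\kappa$, the length at which maintenance (a fraction
  $\kappa$ of assimilation) can no longer be paid. With the default
  parameters this bound only binds after severe food drops, since
  $\kappa = 0.083$ puts it at $12.1\,L_\infty$.
* **Growth.** Next-day length is Gaussian with von Bertalanffy mean
  $L e^{-\dot r_B} + (1 - e^{-\dot r_B}) L_\infty$, where the ultimate
  length is $L_\infty = L_m E(Y)$ and the growth rate $\dot r_B =
  1/(151.0 - 137.8\,L_\infty)$ increases with food. The standard
  deviation $(1 - e^{-\dot r_B}) L_m \sigma(Y)$ is length-independent.
  Individuals above $L_\infty$ shrink toward it; growth is not
  monotone in time under fluctuating food.
* **Reproduction.** Mature, non-starving females ($L_p \le L \le
  L_m E(Y)/\kappa$) produce $E(Y) R_m L^2/L_m^2$ female eggs per day.
  Maturation is plastic: $L_p = 0.539\,L_\infty$ moves with the
  feeding level, so poorly fed cohorts mature small.
* **Inheritance.** All offspring enter at the birth length $L_b$
  (offspring-size variance zero by default; a Gaussian natal
  distribution is available through `sigma_Lb`).

Assumptions worth keeping in mind: no density dependence (food is
imposed, not depleted), no demographic stochasticity (abundances are
continuous), females only (a fixed 1:1 sex ratio converts to mixed-sex
censuses), no age structure, no maternal or delayed effects, and the
maturity threshold is re-evaluated every day — individuals can
functionally "de-mature" when food drops, a literal reading of the
plastic threshold that matters below.

## Parameters

`deb_params()` holds the published laboratory parameterization:
$L_b = 0.166$ mm, $L_m = 1.008$ mm, $\kappa = 0.083$, $\mu = 0.03$
d$^{-1}$, $R_m = 16$ female eggs d$^{-1}$, $\sigma(Y) = 0.3$, the
maturity coefficient 0.539, and the growth-rate coefficients (151.0 d,
137.8 d mm$^{-1}$). `rb_scale` (default 1) is a multiplicative handle
on $\dot r_B$ used only by the elasticity analysis, so that the derived
growth rate can be perturbed as if it were a primitive parameter.
Parameter sets round-trip through flat YAML files (`read_deb_params()`,
`write_deb_params()`); an empty file reproduces the defaults.

## Discretization

The length domain is $\Omega = [0.9 L_b,\ L_m]$, split into 200 equal
bins (configurable); the lower margin absorbs the small Gaussian growth
mass that falls just below the birth length. Vital rates are evaluated
at bin midpoints (midpoint rule in the source dimension). For the
growth transition, however, the Gaussian is integrated **exactly over
each destination bin** via normal CDF differences rather than sampled
at midpoints. This matters: the daily growth s.d. ranges from about
0.002 mm (poor food) to 0.024 mm (ad libitum), and at the lower end it
is narrower than a 200-bin cell (0.0043 mm). Sampling so narrow a
density at midpoints fabricates or destroys probability mass (column
sums oscillate by ~1% at 200 bins and err by tens of percent on coarse
test grids), which corrupts survival exactly where the growth-rate
calibration is most delicate. With CDF differences every column's
growth mass equals the survival probability up to boundary truncation.

Further numerical choices:

* **Boundary mass is truncated, not renormalized** (loss < 0.1% at the
  defaults); renormalizing would silently raise survival.
* **The natal distribution with `sigma_Lb = 0` is an exact unit mass**
  in the bin containing $L_b$ — never a numerically evaluated delta.
  The price is that the kernel is a staircase function of $L_b$: a
  perturbation either moves the natal bin or does nothing. Elasticities
  to $L_b$ therefore carry a discretization component (see below).
* **Deterministic growth (`sigma_Y = 0`)** assigns each column's
  surviving mass to the single bin holding the mean next-day length.
* `equilibrium_feeding()` locates the feeding level with dominant
  eigenvalue 1 by a fine scan plus bisection and warns if the
  eigenvalue, which is *not* monotone in $E(Y)$ (next section), crosses
  1 more than once.

## A calibration discrepancy, stated plainly

Bulb mite populations are conventionally reported to be stationary near
$E(Y) = 0.36$, and the feeding-level ranges of the cross-level analysis
are built around that anchor (declining below it, growing above).
Under the equations and parameter values exactly as published, this
package computes otherwise: the 200-bin kernel's dominant eigenvalue at
$E(Y) = 0.36$ is about 1.044, and it crosses 1 near $E(Y) \approx 0.11$
(0.113 for the literal kernel, 0.115 with survivor-weighted fecundity).
Two independent routes agree — the discretized kernel's eigenvalue and
a deterministic-growth Euler–Lotka calculation ($R_0 \approx 6.6$ at
$E(Y) = 0.36$) — so this is a property of the stated model, not of the
implementation. No defensible re-reading we tried (survivor-weighted
fecundity, natal-bin placement, domain or quadrature changes) moves the
crossing more than a few hundredths.

Two knock-on effects follow. First, the eigenvalue is not monotone in
$E(Y)$: below $E(Y) \approx 0.3055$ the plastic threshold $L_p(E(Y))$
sits below $L_b$, so newborns are mature on day one and growth rates
are inflated; the eigenvalue dips once a juvenile delay appears. Our
monotonicity test therefore covers $[0.10, 0.30]$, where monotonicity
genuinely holds. Second, with both Markov states ($E(Y)$ = 0.15 and
0.60) implying growth, the stochastic-environment map has no declining
cells, and the elasticity map is dominated by the birth length and the
maturity coefficient — not by the mortality → maturity → maximum-length
progression expected from the stationarity anchor. The corresponding
acceptance checks are left failing rather than re-tuned; the synthetic
study conditions are not a dial.

## Fecundity weighting (an open reading)

The projection equation as displayed adds $D\,R$ to $G\,S$ without
multiplying reproduction by parental survival, while the accompanying
prose says only surviving adults reproduce. Both readings are
implemented (`survivor_weighted_fecundity`, default `FALSE` = the
literal equation); they differ by $e^{-\mu} \approx 3\%$ in fecundity,
and the survivor-weighted variant's stationarity crossing (0.115) is
marginally nearer 0.36 than the literal one (0.113) — neither comes
close, so the flag does not adjudicate the calibration question.

## Environments

**The experimental food series.** 37 four-day blocks of 2 or 8 yeast
rods; 20 high and 17 low blocks is the unique composition whose mean
(5.24) and sample variance (9.19, $n-1$ denominator) match the design
targets at two decimals. Recolouring permutes the series by spectral
mimicry — rank-matching against a surrogate — so every colour shares
the exact value multiset. Surrogates are AR(1) draws with coefficient
$\pm 0.95$; `optimise_autocorrelation()` then certifies the attainable
extremes by pairwise-swap hill-climbing from rank-matched starts
(exhaustive below length 9), reaching lag-1 autocorrelations of
$-0.873$ (blue) and $+0.918$ (red) for the 20/17 series. The lag-1
statistic uses the total-sum-of-squares denominator (the `acf()`
convention), under which a perfect alternation gives $-(n-1)/n$, not
$-1$. The 5-rod control/acclimation ration maps to `EY_mid`, by default
the midpoint of `EY_low` and `EY_high`: the ration equals the series
mean but its feeding-level equivalent is never pinned down empirically,
so it is an explicit, configurable assumption.

**The Markov environment.** Daily two-state switching with
probabilities $p$ (good to bad) and $q$ (bad to good);
$\rho = 1 - p - q$, $f = q/(p+q)$, initial state uniform. State
feeding levels default to 0.60/0.15, the stationarity band's edges in
the cross-level analysis.

## Simulation protocols

The **experiment simulation** starts 20 founder adults in the bin
nearest $L_\infty(EY_{mid})$ (founders were raised at the control
ration; a uniform-over-adult-bins alternative is available), runs 31
acclimation days at `EY_mid`, then 148 experimental days. Censuses fall
on every 4th experimental day (37 in all) and use post-projection,
pre-harvest abundances; the harvest — removing a fraction 0.5 of adults
longer than 1.0235× the current mean adult length — follows the census
on every 8th day. Founder removal partway through the real experiment
is deliberately not modelled. $\log \lambda_s$ is the mean of the 148
daily log growth ratios. Census stages: eggs are the newborn bins up to
`egg_cutoff` (0.2 mm by default), adults everything above $L_p(E(Y))$,
juveniles the rest. Because $L_p$ is plastic, the adult class takes
precedence and the egg/juvenile classes can be empty at low feeding
levels (for $E(Y) < 0.368$ the threshold sits below the default
cutoff); mean log stage counts therefore average over censuses with
positive counts and record how many were zero. An alternative
production-mode egg census reports daily egg output $\sum R(L) N(L)$
instead.

The **stochastic growth rate** runs 3000 days from one individual per
bin, discards 500 as structure transient, and averages the remaining
$\tau = 2500$ daily log ratios; the structure vector is renormalized
each day so only log increments accumulate. Between-seed scatter at
these settings is below 0.01. **Elasticities** perturb each of $L_b$,
the maturity coefficient, $L_m$, $R_m$, the growth-rate scale,
$\kappa$, $\mu$ by +1% (forward differences, matching a one-sided
perturbation design) and recompute $\lambda_s = e^{\log \lambda_s}$
along the *same* environment sequence (common random numbers — the
natural variance-reduction choice where the alternative is unstated),
reporting $e_\theta = (\lambda_s' - \lambda_s)/(0.01\,\lambda_s)$.
Elasticities to smoothly entering parameters are near-linear (sign and
magnitude agree within 25% under a $-1\%$ perturbation); the $L_b$
elasticity is a staircase of the natal-bin assignment and should be
read qualitatively.

## The synthetic census generator

`generate_study()` emulates the experiment's data structure — not its
biology: treatments (noise colour × harvesting) × 3 replicate tubes ×
37 censuses, with one shared deterministic trajectory per treatment
(food series were identical among replicates by design), mixed-sex
counts (female counts doubled; halved again on read-back by the
half-female convention), multiplicative lognormal observation noise
(default s.d. 0.2 on the log scale — counting error on hundreds of
mites scales with abundance; Poisson noise is a flag) and integer
rounding. A dropped-tube option exercises unbalanced-strata bootstrap
paths. What passing the recovery and coverage tests shows is that the
pipeline — generation, CSV round-trip, tube-stratified BCa intervals
via `boot`, consistency flags — is faithful; it does not show that the
model reproduces real mite censuses, which exhibit juvenile–adult
interference and plasticity the model omits.

## Problem sizes used by the test suite

Unit tests run on 20–80-bin grids where only mechanics are at stake and
on the 200-bin grid wherever dynamics or calibration are asserted.
Stochastic-environment checks use the full $\tau = 2500$ protocol for
quantitative claims and 1000–1500-day runs for inequalities that hold
at any horizon. Bootstrap coverage uses 500 replicates of $n = 100$
(ordinary BCa) and 60–100 replicate synthetic studies (stratified
paths). The acceptance script's quantities are desk-scale: a 46-point
eigenvalue scan plus bisection, and hill-climbs over a 37-element
series with 10 restarts.

## Known limitations

* The calibration discrepancy above: absolute growth rates (and
  anything anchored to stationarity at $E(Y) = 0.36$) disagree with the
  conventional reference; comparative statements (harvest effects,
  $f$-dependence, seed stability) are the robust outputs.
* Elasticities involving $L_b$ mix biology with discretization.
* No density dependence: simulated populations grow without bound, so
  long-horizon abundances are meaningful only on the log scale.
* The harvest threshold tracks the simulated mean adult length; the
  experimental threshold came from observed harvests, so the 1.0235
  ratio is transplanted, not re-derived.
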