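---
title: "Dual-phosphorylation ERK kinetics: models, identifiability and topological posterior comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-phosphorylation ERK kinetics: models, identifiability and topological posterior comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualphos)
```

## The system and the three models

MEK phosphorylates ERK on two sites.  With mass-action kinetics the
mechanism

S0 + E <-> C1 -> C2 or S1 + E,  S1 + E <-> C2 -> S2 + E

gives six coupled ODEs in the species
(S0, C1, C2, S1, S2, E) with rate constants
(kf1, kr1, kc1, kf2, kr2, kc2): binding in 1/(uM min), unbinding and
catalysis in 1/min.  Two linear conservation laws hold exactly,

* S_tot = S0 + S1 + S2 + C1 + C2,
* E_tot = E + C1 + C2,

and the experimental design fixes S_tot = 5 uM, E_tot = 0.65 uM, with
measurements of the three phosphorylation states at seven time points
(wild type and activating mutants: 0.5, 2, 3.25, 3.75, 5, 10, 20 min;
the SSDD phosphomimetic: 1, 2, 3.25, 5, 10, 20, 40 min) across 11, 5 or
6 replicates.  Both Michaelis-Menten constants
kM_i = (kc_i + kr_i)/kf_i are about 25 uM, far above E_tot, which makes
the complex concentrations negligible relative to the substrate states
and justifies treating the measured channels (S0+C1, S1+C2, S2) as
(S0, S1, S2).

Two reductions to the three substrate states are implemented:

* the **Rational model**, with shared saturation denominator
  `gamma1*S0 + gamma2*S1 + 1`, and
* the **Linear model**, `dS0 = -kappa1 S0`,
  `dS1 = -kappa2 S1 + (1-pi) kappa1 S0`,
  `dS2 = pi kappa1 S0 + kappa2 S1`,

with the reduced parameterisation kappa_i = E_tot kf_i kc_i/(kc_i+kr_i)
(kinetic efficiencies), pi = kc2/(kc2+kr2) (processivity: the chance the
second phosphorylation happens in the same enzyme encounter) and
gamma_i = kf_i (kc1+kc2)/((kc1+kr1)(kc2+kr2)).  The Linear model has the
closed-form solution implemented in `linear_solution()`, evaluated
through a series-stable difference quotient so the kappa1 = kappa2
branch is continuous; the branch switches at
|kappa1-kappa2| < 1e-8 relative because the naive two-branch formula
cancels catastrophically near the diagonal.

## Algebraic quasi-steady-state reduction

`erk_split_system()` splits the network into retained substrate states
and eliminated complexes after substituting free enzyme through either
conservation law (`conservation_E`: E = E_tot - C1 - C2, the Rational
path; `conservation_S`: E = E_tot - S_tot + S0 + S1 + S2, the Linear
path).  `qss_reduced_rhs()` evaluates the generic reduction
(f1, -D2f2^-1 D1f2 f1); the zero set of the eliminated-block dynamics
(the quasi-steady-state variety) is an invariant set of this flow, which
`variety_residual()` certifies numerically.  Jacobians are analytic for
the two ERK subsystems and central finite differences (step
1e-6 x max(1, |x|)) for user-supplied systems; invertibility is decided
by the scale-free test |det| > 1e-12 x product of row infinity-norms.

One finding is worth recording.  Solving the eliminated-block equations
exactly for (C1, C2) under the E = E_tot - C1 - C2 substitution yields a
rational vector field of exactly the published form but with saturation
coefficients

* gamma1* = kf1 (kc1 + kc2 + kr2) / ((kc1+kr1)(kc2+kr2)),
* gamma2* = kf2 / (kc2 + kr2),

whereas the published map uses kf_i (kc1+kc2)/((kc1+kr1)(kc2+kr2)) in
both slots.  The two coincide only when kr2 = 0 and kr1 = kc2; at
generic rates they differ by a common factor of order gamma*S (a few
percent at the experimental magnitudes, where both are approximately
1/kM).  The package implements the published map in
`reduced_from_full()` (it is the parameterisation the inference uses)
and tests the exact-elimination coefficients separately; the
corresponding end-to-end check of the published coefficients against the
exact elimination is expected to fail at tight tolerance, and the test
records exactly that.

Accuracy of the reductions is assessed empirically with
`reduction_error()`: at kM = 25 uM both reduced models track the full
model to within ten percent of S_tot over 20 minutes, with neither more
than an order of magnitude worse than the other.  The linear reduction
error decreases monotonically as E_tot -> 0, the regime in which the
reduction is exact.

## Practical identifiability

The model prediction map phi sends parameters to the noise-free
observable trajectory replicated r times (species fastest, then time,
then replicate).  Under i.i.d. Gaussian noise with a single variance,
the likelihood-based confidence region at threshold delta equals the
preimage under phi of an open data-space ball of radius
rho = sqrt(rss + 2 sigma^2 (-log k*)); `confidence_spec()` assembles
both forms and the tests verify their algebraic identity.  Practical
identifiability at level alpha is boundedness of this region.

The critical value -log k* is calibrated two ways: `wilks_neg_log_kstar()`
returns the chi-square asymptote (3.907 for three parameters at the 5%
level), and `algorithm1_neg_log_kstar()` simulates it: datasets drawn
from the fitted model, a multi-start bounded least-squares inner
maximisation (Latin-hypercube starts plus the fitted point itself, so
the ratio statistic is never negative), and the empirical (1-alpha)
quantile with linear interpolation between order statistics.  Because
the fixed-sigma Gaussian ratio statistic is asymptotically pivotal in
the number of observations -- already 231 at r = 11 -- the simulated
calibration sits near the Wilks value at both r = 11 and r = 200 in our
hands.  A much smaller small-replicate value has been reported for this
assay (0.477 for the wild type); we could not reproduce a gap of that
kind from the printed construction, and the corresponding acceptance
check documents the discrepancy rather than hiding it.  A plausible
mechanism is an inner maximisation that fails to improve on the
simulation truth, which biases the ratio toward zero.

`algorithm2_marginal_region()` approximates the confidence region
marginalised to a named parameter pair.  Its default (`method =
"profile"`) samples the pair uniformly in its box and minimises the
residual over the remaining parameters, targeting the projection of the
region onto the pair -- the set the marginalised confidence-area figures
display, and the reading consistent with passing bounds only for the
pair.  A full-dimensional rejection sampler is available as
`method = "joint"`, but at realistic noise the region occupies a
vanishing fraction of any honest full box, so the joint sampler returns
empty sets at feasible sample counts.  Profiling warm-starts from the
previous accepted point and from a ridge-scaled guess (remaining
rate-like parameters co-scaled with the proposed pair), which is where
the Rational model's non-identifiability lives: large
(kappa1, gamma1) with kappa1/gamma1 held near kappa1_hat x S remain
inside the region, so accepted points run along that ridge out of the
(0, 1000)^2 box and `boundedness_assessment()` reports boundary
contact.  The verdict ignores contact with proposal bounds that
coincide with hard parameter-space limits (rates are non-negative, the
processivity lives in [0, 1]): a region resting against kappa2 = 0 or
gamma1 = 0 is bounded there by the parameter space itself, and only
contact with an interior box edge counts as evidence of
unboundedness.  Linear-model pair boxes are centred on the fit with
half-width 12 Gauss-Newton standard errors (`mle_standard_errors()`),
so the box scales with the data's actual information content.  Trajectories on the ridge are stiff (rates of order 1e3-1e4
per minute), so the compiled integrator switches from an explicit
Cash-Karp pair to an L-stable Rosenbrock scheme when its step budget
trips.

**Noise level for the dichotomy study.**  The separation "Linear
bounded, Rational unbounded" is a property of data at the experimental
noise scale.  The saturated-denominator family deviates from
Linear-truth trajectories by a fixed squared misfit (about 3.5 uM^2
summed over the wild-type design), so the ridge lies inside the region
only when the threshold margin 2 sigma^2 (-log k*) exceeds it; at
sigma = 0.1 uM the Rational region is provably bounded, and the
dichotomy emerges at immunoblot-scale noise.  The dichotomy scenario
therefore uses sigma = 0.75 uM (15% of S_tot), chosen once from that
margin argument; the clean recovery studies elsewhere use the
sigma = 0.1 uM default.

Structural identifiability of the Linear model is witnessed
constructively: `recover_linear_params()` inverts noise-free
observations at any three distinct positive times (kappa1 from S0,
(kappa2, pi) from two S1 equations with the third as a consistency
check, root-bracketed on a log grid and Newton-polished).  Round trips
reach 1e-8 provided both exponentials are resolvable in double
precision, which the tests ensure by scaling the time triple with the
faster rate; outside that regime the inversion is well defined but
ill-conditioned in finite precision, a floating-point limit rather than
a model property.

## Bayesian inference

For the Linear model the parameter is (kappa1, kappa2, pi, sigma) with
independent uniform priors: kappa_i on (0, 10) 1/min, sigma on (0, 10)
uM, pi on (0, 1).  `sample_posterior()` runs four adaptive random-walk
Metropolis chains (componentwise scaling early, then a jointly adapted
empirical-covariance proposal, frozen after warm-up), pools 2000
post-warm-up draws, and gates on split-Rhat < 1.05 and ESS > 100 per
coordinate, retrying with doubled warm-up before failing.  Any
asymptotically correct sampler satisfies the downstream contract; the
topological stage only consumes the pooled cloud marginalised to
(kappa1, kappa2, pi).  Rational/full-model priors extend the same
pattern, but those posteriors pile up against the prior box edges --
the Bayesian face of practical non-identifiability -- and are exposed
for inspection, not routine use.

On the recovery criterion: posterior means land within about one
posterior standard deviation of the simulation truth for typical seeds
(data noise moves the whole posterior), so the check is stated as
"within 3 posterior standard deviations"; a Monte-Carlo-standard-error
reading (sd/sqrt(ESS)) would fail for essentially every seed by
construction, since the MCSE is an order of magnitude below the
posterior sd.

## Topological comparison of posterior clouds

The pipeline in `ph_of_cloud()` follows the density-filtration
construction: select a bandwidth b, estimate the density with the
Epanechnikov kernel K(u) = c_m (1 - |u|^2) on the unit ball (c_m =
(m+2)/(2 V_m)), build the Vietoris-Rips complex at scale b, extend the
density to simplices by the minimum over vertices, filter by minus the
density (a super-level-set filtration), and compute persistent homology
over F2 by standard boundary-matrix column reduction in a deterministic
order (value, then dimension, then lexicographic vertex tuple).
Bandwidths start from a normal-reference rule b0 = 2.2 s n^(-1/(m+4))
and are refined by 5-fold cross-validated held-out log-density over a
multiplicative grid; the CV constant and protocol are the package's own
choices since standard references leave them open.  This signature is
translation-invariant -- it measures the shape of the uncertainty, not
its location.

Bottleneck distances are exact: candidate values are bisected with a
bipartite-matching feasibility test; bars may retire to the diagonal at
half their persistence; essential bars (death = infinity) may only match
essential bars, and unequal essential counts make the distance
infinite.  This follows the "infinity minus infinity = 0" convention
strictly; it also means the distance degenerates to infinity whenever
two complexes disagree about essential classes, which shapes two design
choices below.  `bobrowski_bound()` evaluates the density-filtration
convergence guarantee (with the scale parameter in the exponent read as
the bandwidth, resolving a notational mismatch in the source theorem);
the sample sizes it demands for direct significance statements are far
beyond desk scale, which is why significance is assessed by resampling
instead.

**Null-resample bandwidth policy.**  The resampling null distribution
compares a reference subsample's barcode against barcodes of fresh
subsamples from the same source.  Because the density scale varies as
b^-m, re-selecting the bandwidth per resample injects selection noise
directly into the null at the scale of the signature itself; and a
resample containing a small far-tail satellite can split the
fixed-scale complex, changing the essential-class count and driving the
strict-convention bottleneck distance to infinity.  The null
computations therefore reuse the reference's selected bandwidth,
floored at each resample's single-linkage connectivity radius (the
longest minimum-spanning-tree edge), which guarantees a connected
complex while perturbing the bandwidth only marginally.  Sources with
genuinely separated posterior modes would be bridged by that floor;
the synthetic suite is unimodal by construction, and the limitation is
noted below.

**Empirical p-value direction.**  The published rank formula
((beta+1-j)/(beta+1) with j the rank among the null distances from
largest) assigns *large* p to *large* distances, which contradicts the
published table where the most distant variant pairs carry p = 0.01.
The package implements the standard exceedance form
p = (#{null >= observed} + 1)/(beta + 1), which reproduces the table's
rank structure; with beta = 99 a distance exceeding every null draw
yields exactly 0.01.

**Choice of homology dimension for the synthetic suite.**  The
five-cloud stand-in (`make_variant_suite()`) consists of four unimodal
Gaussian clouds of similar dispersion and one (SSDD) several-fold more
concentrated, all truncated at Mahalanobis radius 2.5 so that tail
points sit in appreciable local density (compact support keeps the
fixed-scale complex stable across resamples).  For such unimodal
clouds the discriminating signal is the density scale, which lives in
H0 (mode density as minus the birth value, prominence as persistence).
H1 of a 200-point subsampled complex is either empty (dense regime) or
carries sampling-noise holes whose essential-class counts differ
between resamples, driving strict-convention bottleneck distances to
infinity; the published comparison used H1 on real posterior clouds
where that degeneracy evidently did not arise.  `compare_variants()`
keeps k = 1 as its default to match that usage, and the synthetic
comparison is run with k = 0.  With beta = 99 resamples per variant the
SSDD row dominates the distance matrix by two orders of magnitude and
every SSDD pair attains p = 0.01.

## What the synthetic generator does and does not emulate

`generate_timecourse()` reproduces the assay's statistical skeleton:
the per-variant designs, shared S_tot/E_tot, i.i.d. additive Gaussian
noise with one variance, and (optionally) the compound measurement
channels of the full model.  It does not emulate heteroscedastic or
correlated measurement error, plate/batch effects, negative-value
censoring (negative draws are kept, as the Gaussian model implies), or
any real fitted parameter values -- none are published, so the
demonstration truth (kappa1, kappa2, pi) = (0.5, 1.5, 0.3) with sigma =
0.1 uM is illustrative.  Passing tests therefore certify the methods
under the stated noise model, not the reproduction of any particular
laboratory dataset.

## Problem sizes and numerical defaults

Simulations use the experimental design sizes throughout: 3 x 7 x r
data arrays, r in {5, 6, 11} (plus r = 200 for the asymptotic
calibration check), 2000 posterior draws, 200-point topological
subsamples with 99 null resamples, 2000 region proposals per model, 500
simulated datasets per likelihood-ratio calibration, 1000 inversion
round trips.  ODE tolerances default to rel 1e-8 / abs 1e-10
(explicit adaptive Runge-Kutta; the systems are non-stiff at
experimental magnitudes), relaxed to rel 1e-6 inside region sampling
where the membership comparison tolerates it.  All stochastic entry
points take explicit seeds and restore the caller's RNG state.

## Known limitations

* The published Rational-model saturation coefficients differ from the
  exact elimination (see above); both are small at kM = 25 uM, so the
  practical conclusions are unaffected, but the discrepancy is real.
* The small-replicate likelihood-ratio calibration gap (0.477 vs 3.907)
  does not reproduce under a faithful reading of the construction.
* The strict infinite-bar convention makes H1 bottleneck comparisons of
  sparse subsampled complexes degenerate; use k = 0 or denser clouds.
* The null-resample connectivity floor would bridge genuinely separated
  posterior modes; the resampling test as configured targets unimodal
  (or mildly multimodal) posterior clouds.
* Full-model fitting exposes the same practical non-identifiability as
  the Rational model; its six-parameter regions are provided for
  inspection and should not be summarised by point estimates.
```
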