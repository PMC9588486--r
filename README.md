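# dualphos

Dual-phosphorylation ERK kinetics: mass-action modelling,
quasi-steady-state model reduction, likelihood-based practical
identifiability, Bayesian inference of the reduced kinetic parameters,
and topological comparison of posterior samples.

MEK activates ERK by phosphorylating it on two sites.  The package is
aimed at systems biologists analysing time-course phosphorylation data
(three measured states at a handful of time points, a few replicates)
who want to go beyond a single fitted model: it asks which model of the
mechanism the data can actually support, and how the inferred kinetics
differ between enzyme variants.

Three nested models of the mechanism are implemented:

* the **Full model** — six mass-action ODEs in
  (S0, C1, C2, S1, S2, E) with rates
  θ = (k_f1, k_r1, k_c1, k_f2, k_r2, k_c2), carrying the conservation
  laws S_tot = S0+S1+S2+C1+C2 and E_tot = E+C1+C2;
* the **Rational model** — the algebraic quasi-steady-state reduction
  to (S0, S1, S2) with shared saturation denominator
  γ₁S0 + γ₂S1 + 1;
* the **Linear model** — dS0 = −κ₁S0,
  dS1 = −κ₂S1 + (1−π)κ₁S0, dS2 = πκ₁S0 + κ₂S1, with closed-form
  solution, where κᵢ = E_tot·k_fi·k_ci/(k_ci+k_ri) are kinetic
  efficiencies and π = k_c2/(k_c2+k_r2) is the processivity (the
  probability both phosphorylations occur in one enzyme encounter).

On top of the models sit:

* a generic quasi-steady-state reduction operator
  (f¹, −D₂f²⁻¹D₁f²f¹) with variety-invariance checks;
* practical identifiability via likelihood-ratio confidence regions
  U_δ = {θ : −log ψ(θ, z*) < δ} = φ⁻¹(B_ρ(z*)): simulated and Wilks
  calibrations of −log k*, marginalised region sampling, and a
  boundedness verdict (the Linear model comes out practically
  identifiable; the Rational and Full models do not);
* Bayesian posterior sampling of (κ₁, κ₂, π, σ) under uniform priors,
  with convergence diagnostics;
* persistent homology of kernel-density super-level sets over F₂
  (Vietoris–Rips complex at the bandwidth scale, filtration by minus
  the density), exact bottleneck distances, and resampling p-values
  for comparing posterior clouds between enzyme variants.

## Worked example

Simulate a wild-type-design time course from the Linear model, fit it,
and test practical identifiability:

```r
library(dualphos)

design <- default_designs()[["wild-type"]]     # 3 species x 7 times x 11
scen   <- variant_scenario(design, reduced_params(0.5, 1.5, 0.3),
                           sigma = 0.1)
z      <- generate_timecourse(scen, "linear", seed = 42)

fit <- mle_fit(z, "linear", seed = 1)
round(fit$theta_hat, 4)
#> kappa1 kappa2     pi
#> 0.4974 1.5866 0.2829
round(fit$sigma_hat, 4)
#> [1] 0.0969

nlk <- algorithm1_neg_log_kstar(fit$theta_hat, fit$sigma_hat, design,
                                "linear", alpha = 0.05, n_sim = 500,
                                seed = 2)
round(as.numeric(nlk), 3); round(wilks_neg_log_kstar(0.05, 3), 3)
#> [1] 3.74
#> [1] 3.907
```

The fitted rates sit within two standard errors of the simulation truth
(0.5, 1.5, 0.3), the noise estimate recovers σ = 0.1 μM, and the
simulated likelihood-ratio threshold lands near the Wilks asymptote
χ²₃(0.95)/2 = 3.907.  A marginalised confidence region then yields the
identifiability verdict:

```r
spec   <- confidence_spec(z, fit$theta_hat, fit$sigma_hat,
                          as.numeric(nlk), "linear")
se     <- mle_standard_errors(z, fit, "linear")
bounds <- list(lower = pmax(fit$theta_hat - 12 * se, 0),
               upper = pmin(fit$theta_hat + 12 * se, c(10, 10, 1)))
region <- algorithm2_marginal_region(z, spec, bounds,
                                     c("kappa1", "kappa2"),
                                     n_samples = 2000, seed = 3)
boundedness_assessment(region)
#> [1] "bounded"
```

Comparing posterior-like clouds for the five MEK variants
topologically (H₀ density signatures, 99 null resamples):

```r
suite <- make_variant_suite(seed = 7)
cmp   <- compare_variants(suite, beta = 99, n = 200, k = 0, seed = 11)
round(cmp$distance, 1)
#>           wild-type  Y130C   F53S  E203K   SSDD
#> wild-type       0.0   70.7   90.3   22.2 5903.5
#> Y130C          70.7    0.0  161.0   48.5 5974.2
#> F53S           90.3  161.0    0.0  112.6 5813.2
#> E203K          22.2   48.5  112.6    0.0 5925.7
#> SSDD         5903.5 5974.2 5813.2 5925.7    0.0
cmp$p_value["SSDD", 1:4]
#> wild-type     Y130C      F53S     E203K
#>      0.01      0.01      0.01      0.01
```

The SSDD variant — whose cloud has a deliberately distinct density
profile — is separated from every other variant by two orders of
magnitude in bottleneck distance, at the smallest attainable
resampling p-value 1/(β+1) = 0.01.

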