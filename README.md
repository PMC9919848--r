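# dfret

Diffusion-enhanced Förster resonance energy transfer (DFRET) analysis of
flexible peptides and polymers, for spectroscopists who want to extract
*both* structure (the end-to-end distance distribution `p(r)`) and
dynamics (the intrachain diffusion coefficient `D`) from FRET
measurements on donor/acceptor-labelled chains.

When the donor–acceptor distance diffuses during the donor lifetime,
transfer is enhanced and the excited-chain population `N(r, t)` obeys a
reaction–diffusion equation with an `r^-6` sink (the Haas–Steinberg
equation):

    dN/dt = -N/tauD - (R0/r)^6 N/tauD + d/dr( D N0 d(N/N0)/dr ),
    N(r, 0) = N0(r) = p(r)

The measurable interface is the effective distance
`Reff = R0 ((1-E)/E)^(1/6)` derived from the transfer efficiency `E`. It
runs from the static limit `L` (no diffusion, a closed-form average of
Förster efficiencies over `p`) down to the dynamic limit
`R = <r^-6>^(-1/6)` (infinite diffusion). Normalized between the two,
the diffusion influence `DI = (Reff - L)/(R - L)` is a near-perfect
sigmoid in `X = sqrt(D tauD)/R0`:

    DI(X) = (X/X0)^M / (1 + (X/X0)^M)

with midpoint `X0` and steepness `M` functions only of the ratio
`R0/rL` (contact distance `rL`). The package

* solves the population equation by a deterministic time-integrated
  boundary-value method (production path) and a stiff time-domain
  marcher (validation oracle), plus an independent Brownian-dynamics
  Monte Carlo estimator;
* calibrates `(X0, M)` over the 56-combination grid `R0` = 9–15 Å ×
  `rL` = 1.5–5 Å and fits the second-degree polynomials `X0(rho)`,
  `M(rho)` (built-in reference coefficients included);
* evaluates the resulting closed analytical surrogate for `Reff`
  without any PDE solve (the Haas–Steinberg–Jacob equation);
* globally fits `(D_ref, b, rL)` to multi-condition effective-distance
  data and generates synthetic experiments with known ground truth.

## Worked example

Calibration fixture `R0 = 12` Å, `rL = 4` Å, shifted ideal chain with
`b = 2 R0 = 24` Å, donor lifetime 100 ns:

```r
library(dfret)
dist  <- distance_distribution("ideal_chain_shifted", b = 24, rL = 4)
photo <- photophysics(tau_D = 100, R0 = 12)

static_limit_L(dist, 12)   # 18.09131  (A; no diffusion)
dynamic_limit_R(dist)      # 13.90716  (A; infinite diffusion)

solve_time_integrated(hse_problem(dist, photo, D = 1))
#> <dfret_hse_solution> time_integrated: E = 0.144834, R_eff = 16.1329 A
#>                      (D = 1 A^2/ns, J = 0.694444)

fit <- profile_and_fit(dist, photo)   # 32 PDE solves + sigmoid fit
fit
#> <dfret_sigmoid_fit> X0 = 0.8898, M = 1.7842 (rms 2.36e-03, ...)
```

`X0 = 0.8898` and `M = 1.7842` are the sigmoid midpoint and steepness of
this ratio-3 profile (reference values 0.8929 and 1.7876, reproduced
within 0.4%). The closed form then predicts effective distances in
microseconds instead of PDE solves:

```r
hsje_reff(dist, photo, D = 1, details = TRUE)[c("X", "DI", "R_eff")]
#> $X 0.8333  $DI 0.4668  $R_eff 16.1380 (A; the PDE gives 16.1329)
```

Recovering structure and dynamics from a synthetic 12-condition
viscosity series (truth `D_ref = 1` Å²/ns, `b = 24` Å, `rL = 4` Å,
0.2 Å noise):

```r
obs <- generate_dataset(synthetic_truth(noise_sd = 0.2, seed = 1))
fit_global(obs, model0 = list(D_ref = 4, b = 17, rL = 3,
                              free = c("D_ref", "b", "rL")))
#> <dfret_fit_result>
#>   D_ref = 0.91325 A^2/ns (free, se 0.173)
#>   b     = 23.512 A (free, se 0.587)
#>   rL    = 4.1488 A (free, se 0.127)
#>   SSR = 6.28152 over 12 observations; Jacobian condition 853
```

A command-line front end with subcommands `hsje`, `calibrate`,
`simulate`, `fit` and `mc-check` is installed under
`inst/cli/dfret.R`.

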