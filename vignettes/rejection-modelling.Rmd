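---
title: "Modelling protein rejection in open ultrafiltration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling protein rejection in open ultrafiltration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ufreject)
```

## The problem

Classic ultrafiltration (UF) assumes complete protein retention. Protein
*fractionation*, by contrast, needs membranes open enough to pass proteins
partially, and there the observed rejection becomes a strong function of
operating conditions: transmembrane pressure (through the flux), pH and
ionic strength (through electrostatic exclusion), and crossflow
hydrodynamics (through concentration polarization). `ufreject` implements a
solution–friction description of this regime with a deliberately small
number of lumped parameters, so that a protein/membrane pair can be
characterized from a limited set of flux–rejection measurements without
knowing pore sizes or charges.

## The transport model

Solute transport is treated as two layers in series. In the concentration
polarization layer the solute moves by advection toward the membrane and
diffuses back along its concentration gradient; integrating the
advection–diffusion balance across the layer gives a polarization Peclet
number $Pe_d = v_w/k_{dbl}$, where $v_w$ is the volumetric flux and
$k_{dbl}$ the layer's mass-transfer coefficient. Inside the membrane the
same balance holds with hindrance factors $K_c$ (advection) and $K_d$
(diffusion) and a partition jump $\Phi$ at each pore mouth; its integral
defines the membrane Peclet number $Pe_m = v_w/k_m$ with
$k_m = K_d D_m / (K_c \delta_{mem})$. The sieving coefficient
$\sigma = 1 - K_c \Phi$ lumps partitioning and advective hindrance.
Combining the layers yields the generalized observed-rejection equation

$$R_{obs} = 1 - \frac{1-\sigma}{(1-\sigma) +
  e^{-Pe_d}\left(1 - e^{-Pe_m}\right)\sigma},$$

and, in the advection-dominated limit $Pe_m \to \infty$ appropriate for
open membranes at high flux,

$$R_{obs} = 1 - \frac{1-\sigma}{(1-\sigma) + e^{-Pe_d}\,\sigma}.$$

Two limits anchor the interpretation: at vanishing flux $R_{obs} = \sigma$
(the thermodynamic maximum), and at large $Pe_d$ polarization drives
$R_{obs} \to 0$ for any $\sigma < 1$. Partitioning itself can be estimated
sterically with the Ferry expression $\Phi = (1 - r_s/r_p)^2$ or extended
with a Boltzmann factor $e^{-E_T/k_BT}$ for a net solute–membrane
interaction energy, which is how electrostatic exclusion at low ionic
strength enters qualitatively.

```{r ferry}
phi <- ferry_partition(r_s = 3.48e-9, r_p = 5.69e-9)
c(partition = phi, sigma = sieving_coefficient(1, phi))
```

## The numerical oracle

The closed forms above are integrals of linear boundary-value problems, so
the package carries an independent check: `solve_profile_numeric()`
integrates both layer ODEs with fixed-step fourth-order Runge–Kutta
(`deSolve`), applies the partition jumps explicitly, and shoots on the
permeate concentration. Because the system is linear the exit residual is
affine in $c_p$; two trial integrations determine the solution and secant
refinement continues until the relative exit-condition violation is below
1e-10 (at most 200 iterations; non-convergence is an error carrying the
achieved imbalance). With 2000 steps per layer the discretization error is
far below the 1e-6 relative agreement the test suite demands between the
oracle and `rejection_general()`, for Peclet numbers up to about 10. The
oracle never calls the closed-form rejection equations.

Numerical corner cases are resolved analytically rather than left to
floating point: $e^{-Pe}$ is taken as exactly 0 beyond $Pe = 709$ (the
double-precision underflow edge), $\sigma = 1$ maps to $R_{obs} = 1$ and
$Pe_m = 0$ to $R_{obs} = 0$ before the generic ratio is formed, an
oversized solute gets $\Phi = 0$ (the squared Ferry form would otherwise
rise again past $r_s = 2r_p$), and the layer-flux expressions return their
L'Hôpital limits (flagged with a warning) at zero Peclet number, where the
printed forms are singular.

## Mass-transfer correlations

`k_dbl` can alternatively be estimated from hydrodynamics via Sherwood
correlations $Sh = A\,Re^m Sc^n = k_{dbl} d_h / D$. Five published
power laws are provided (Schock–Miquel, Graetz–Leveque,
Harriott–Hamilton, Bandini–Morelli, Shi), with exponents kept exactly as
their sources print them — 0.33 and 1/3 are deliberately distinguished,
with a `third = TRUE` switch to unify them. Applicability ranges
(laminar/turbulent) produce advisory warnings, not errors, because in
practice all five are compared at a single operating point. The default
geometry/fluid profiles (spacer porosity 0.85, specific surface 1e4 1/m,
channel length 0.3 m, water-like density and viscosity at 25 °C, BSA
diffusivity 6.0e-11 m²/s) are representative textbook values for a small
1812 spiral-wound module and a dilute protein feed — stand-ins a user
should replace with measured spacer and fluid data. Literature correlations
of this kind systematically underestimate `k_dbl` for open membranes,
where permeation stabilizes the near-wall flow (the suction effect); the
package therefore treats them as one option for freezing `k_dbl`, not as
ground truth.

## Inference

Fits minimize the sum of squared rejection residuals with
Levenberg–Marquardt (`minpack.lm`), with rate coefficients parameterized
on the log scale — positivity without hard bounds, and better conditioning
at the 1e-6 m/s magnitude. `sigma` is unbounded by default because real
fits can land marginally above 1; a strict mode is available for physical
simulation. Starting values are scale-free and deterministic: `sigma` at
the largest observed rejection (its vanishing-flux limit), rate
coefficients at the median flux (placing Peclet numbers near 1).
Convergence tolerances are 1e-10 on gradient, step and objective, with up
to 500 iterations.

Three strategies mirror how such data are analysed in practice:
`fit_condition()` fits each solution condition separately (2 or 3
parameters), `fit_shared_kdbl()` shares one `k_dbl` across all conditions
(per-condition `sigma` plus one rate), and `fit_fixed_kdbl()` freezes
`k_dbl` — at an average fitted value or a Sherwood estimate — leaving
`sigma` alone. Duplicate measurements enter as individual observations
rather than being averaged; this preserves residual degrees of freedom for
the F test. Confidence intervals are linearized (Jacobian-based) with t
quantiles at the residual degrees of freedom, matching standard nonlinear
regression tools; their finite-sample coverage for `sigma` is verified by
simulation (95.6% over 500 replicates at 1% rejection noise, n = 10).

Nested fits are compared with
$F = \frac{(SS_1 - SS_2)/(df_1 - df_2)}{SS_2/df_2}$ and an upper-tail
F probability. A larger model that fails to improve the fit can produce
$F \le 0$; it is reported as computed with $p = 1$. One calibration caveat
is worth stating plainly: when the smaller model is the $k_m \to 0$
boundary of the larger one (advection-dominated vs general equation), the
null distribution of $F$ is a 50:50 mixture of a point mass at zero and an
F distribution, so the test rejects at roughly half the nominal rate
(about 0.025 at $\alpha = 0.05$ in our simulations) — conservative, never
anticonservative. When the reduced model fixes a parameter at an interior
value (e.g. `k_dbl` frozen at its true value), the classical calibration
holds (0.055 measured over 1000 replicates).

## The synthetic study generator

`default_design()` reproduces the layout of a pilot-scale crossflow study
on BSA: six solution conditions (pH 7 at 0, 0.08, 0.15, 0.2 M NaCl; pH 4.9
at 0 and 0.2 M NaCl), pressures of 0.2, 0.5, 0.8, 1.5 and 3 bar, duplicate
concentration measurements, a 0.5% (w/v) feed and 0.167 m/s crossflow.
`default_ground_truth()` supplies per-condition sieving coefficients
(0.9993, 0.9935, 0.9686, 0.9646, 0.9977, 0.9916) and a shared
`k_dbl = 7.34e-6` m/s representative of that system. Flux is tied to
pressure by a linear law (default permeability 5e-6 m/s/bar), which places
$Pe_d$ between about 0.14 and 2 — the informative range where rejection
visibly bends with flux — and deliberately excludes limiting-flux/cake
behaviour. Noise enters where measurement noise actually arises: each
concentration reading (retentate and permeate) is perturbed by independent
multiplicative Gaussian noise (default relative sd 1%), and the recorded
rejection is recomputed from the noisy pair. Everything is deterministic
given a seed, and the caller's RNG state is left untouched.

What the generator does **not** emulate: flux-dependent mass transfer
(suction effect), adsorption and fouling, oligomerization-driven changes
in effective solute size, retentate concentration drift across pressure
steps, and any coupling between conditions. Passing round-trip and
coverage tests on these simulations therefore demonstrates the estimator's
correctness and calibration under the stated noise model — not that the
model captures every feature of real pilot-scale data.

## Problem sizes and reproducibility

The test suite regenerates every dataset it uses in code: 100 random
parameter sets for oracle–closed-form agreement, the full 60-observation
factorial for round-trip recovery, 1000 Monte-Carlo replicates for F-test
calibration and 500 for confidence-interval coverage, all under fixed
seeds. These sizes keep each Monte-Carlo standard error a few times
smaller than the band being checked. `scripts/acceptance.R` recomputes the
headline steric-partitioning figure from scratch at run time.

## Known limitations

- Electrostatics enter only through the lumped interaction energy of the
  partition formula; Donnan or Poisson–Boltzmann treatments would need
  membrane charge and pore-size information the model deliberately avoids.
- `k_dbl` is taken as flux-independent; at high permeation rates the
  suction effect makes this an underestimate of mass transfer.
- The linear flux–pressure law of the generator is a convenience, not a
  membrane-transport claim; fits consume measured fluxes directly.
- Least squares is unweighted and homoscedastic, as the measured rejection
  noise at a fixed condition is approximately constant across the flux
  range of interest; replicate-level weighting is out of scope.
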