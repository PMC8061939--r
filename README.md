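# hepasim

Dynamic modelling of ischaemic (hypoxic) hepatitis: hepatocyte necrosis and
the serum biomarkers AST, ALT and LDH.

Ischaemic hepatitis is an acute liver injury in which an underlying
condition — cardiac failure, respiratory failure, shock — starves the liver
of oxygen. Hepatocytes that cannot sustain ATP production die by necrosis;
lysing cells release AST and ALT into serum, and the surviving hypoxic
cells up-regulate LDH. `hepasim` is for modellers and quantitative
clinicians who want to relate the measurable enzyme trajectories to the
unmeasurable quantities that matter: the fraction of the liver still
healthy, and the time remaining before damage becomes irreversible (below
~30% healthy hepatocytes a transplant is indicated).

## The model

A six-state ODE system couples hepatic ATP `A`, healthy/damaged hepatocytes
`H`, `Z`, and serum enzymes `S` (AST), `L` (ALT), `D` (LDH):

```
dA/dt = rho·H·O(t) − k·H·A/A_norm
dH/dt = r·H·(1 − (H+Z)/H_max) − eta·H·(1 − A/A_norm)      [− c·|dO/dt|·H]
dZ/dt = eta·H·(1 − A/A_norm) − delta_Z·Z                  [+ c·|dO/dt|·H]
dS/dt = delta_Z·beta_S/(theta·H_max)·Z − delta_S·(S − S_min)
dL/dt = delta_Z·beta_L/(theta·H_max)·Z − delta_L·(L − L_min)
dD/dt = beta_D/(theta·H_max)·H·(1 − O(t))·(1 − D/D_max) − delta_D·(D − D_min)
```

Oxygen sits at the injury level `O0` until the underlying condition is
treated at time `tau`, then returns logistically to 1 at rate `epsilon`
(midpoint 3 h after `tau`). The bracketed terms are the optional
reperfusion-injury extension. The package provides closed-form equilibria
with feasibility and stability classification, normalized sensitivity
indices, scenario sweeps over treatment time and initial oxygen,
time-to-critical-damage curves with exponential fits, bisection for the
critical oxygen level, calibration of `epsilon` against peak targets, and a
seeded generator of literature-like peak-value cohorts for validation. See
`vignette("ischaemic-hepatitis-model")` for the full account.

## Worked example

A patient drops to 50% oxygen delivery; the cause is corrected after 8
hours:

```r
library(hepasim)

params <- model_parameters()          # literature defaults, rates per day
s8 <- run_scenario(params, O0 = 0.5, tau_hours = 8)
s8[, c("peak_S", "peak_L", "peak_D", "min_healthy_fraction",
       "time_to_critical_h")]
#>     peak_S   peak_L   peak_D min_healthy_fraction time_to_critical_h
#> 1 2078.212 1162.667 4030.943             0.265258            10.2536
```

AST peaks at ~2078 IU/L and ALT at ~1163 IU/L (released by lysis of
damaged cells), LDH at ~4031 IU/L (produced by the surviving hypoxic
cells); the healthy pool bottoms out at ~27% of normal, crossing the 30%
critical threshold about 10.3 h after injury — this patient reaches the
transplant-risk zone despite treatment. Validation against the compiled
literature cohort:

```r
validate_peaks(s8)[, c("biomarker", "model_peak", "range_low", "range_high", "verdict")]
#>   biomarker model_peak range_low range_high      verdict
#> 1       AST   2078.212      1927       4587 within_range
#> 2       ALT   1162.667      1803       1959  below_range
#> 3       LDH   4030.943      3067       4494 within_range
```

AST and LDH fall inside the reported study ranges; ALT falls short of its
range, the expected pattern for this model at 50%/8 h. The stability of the
healthy liver, and how long an untreated patient has:

```r
classify_stability(params)$eigenvalues
#> [1] -143.000   -5.000   -1.000   -0.920   -0.459   -0.350

sweep_scenarios(params, O0 = c(0.3, 0.8), tau_hours = Inf,
                horizon = 6)$time_to_critical_h
#> [1]  6.865698 30.817484
```

All eigenvalues of the healthy equilibrium are negative (locally stable);
untreated, critical damage arrives after ~6.9 h at 30% oxygen but ~30.8 h
at 80%. A complete run — equilibrium report, sweeps, critical-time curve,
reperfusion sweep, cohort and validation, with a checksummed manifest:

```r
run_full_pipeline("results/full_run", seed = 1)
```

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "ihsim.R", package = "hepasim")`.

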