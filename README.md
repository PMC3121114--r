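# xlnrdyn

Kinetic modeling and stability analysis of the D-xylose–induced **XlnR
regulon** of *Aspergillus niger*.

The xylanolytic activator XlnR is the master regulator of a set of enzyme
genes (the regulon) that *A. niger* switches on when D-xylose appears in
the medium. `xlnrdyn` is for systems biologists who want to explore the
*dynamics* of this induction before committing to time-course
experiments: how fast genes and proteins respond to a sugar pulse, what
delayed feedback from target proteins onto the *xlnR* gene does to the
response, and for which feedback strengths the network is stable or
oscillatory.

## The model

Each gene $i$ contributes an mRNA/protein pair $(x_i, z_i)$:

$$\dot x_1 = \rho_1 + b_1 u(t) + \text{feedback} - k_{1d} x_1,\qquad
  \dot x_i = \rho_i + k_{is}\frac{k_{i1} z_1}{1 + k_{i1} z_1} - k_{id} x_i,\qquad
  \dot z_i = r_i x_i - \eta_i z_i,$$

with the D-xylose pulse $u(t) = u_0/(\beta + e^{Kt})$ and, optionally, a
delayed feedback drive
$H k_{ls}\bigl[\sum_{j\in S_1} (1 + k_{RL} z_j(t-\tau))^{-1} +
\sum_{l\in S_2} k_{AL} z_l(t-\tau)/(1 + k_{AL} z_l(t-\tau))\bigr]$
on the master gene, gated by the carbon-catabolite repressor CreA
($H = 0$ when CreA is present). Stability is read off the analytic
$2n \times 2n$ Jacobian: without feedback the spectrum is exactly the
negated degradation rates; with a feedback gain $\omega_1$ from the XlnR
protein onto its own gene the perturbed eigenvalue pair is closed-form,
giving the stability condition $\omega_1 < \eta_1 k_{1d}/r_1$ and the
oscillation condition $\omega_1 < -(\eta_1 - k_{1d})^2/(4 r_1)$. Gains at
other cells are scanned numerically with bisection-refined thresholds.

## Worked example

```r
library(xlnrdyn)

sc <- xlnr_scenario(with_feedback = TRUE)   # canonical 3-gene scenario
tr <- simulate_regulon(sc$model, sc$input)  # open-loop pulse response
summary(tr)
#>   species     initial      peak t_peak       final
#> 1      x1 0.004000000 46.472523    2.6 0.004076472
#> 2      x2 0.008749500  7.322104    7.1 0.009015852
#> 3      x3 0.007332533 10.935823    7.8 0.008617382
#> 4      z1 0.002000000 21.318283    3.8 0.002054622
#> 5      z2 0.004374750  3.591724    8.2 0.004564211
#> 6      z3 0.003666267  5.378114    8.9 0.004550588
```

The 50 mM pulse lifts the master mRNA `x1` from its basal level 0.004 to
a peak of 46.5 within 2.6 h — the master relaxation time is
`relaxation_time(sc$model, 1)` = 2 h, the fastest in the network — and
everything decays back toward basal as the sugar is consumed. Adding the
delayed feedback loop (CreA absent) elevates peaks and terminal levels:
`simulate_regulon(sc$model, sc$input, sc$feedback)` ends with
`x1 = 1.78` instead of `0.004`.

Stability of feedback configurations:

```r
m <- sc$model
omega1_conditions(m)
#> $oscillation
#> [1] -0.125
#>
#> $stability
#> [1] 1

s <- scan_feedback_gain(m, position = 1)   # gain at Jacobian cell (1,4)
s$thresholds
#>          type omega_lo omega_hi  omega
#> 1   stability        1        2  1.000
#> 2 oscillation       -1        0 -0.125
```

Positive autoregulation of XlnR destabilizes the regulon beyond
$\omega_1 = 1$; negative autoregulation is always stable and oscillates
(damped) below $\omega_1 = -0.125$. Scans of the target-protein cells
(`position = 2, 3`) flip to unstable only at large negative gains, whose
location depends on the Jacobian evaluation point (see the vignette).

File-based pipelines mirror these analyses: `run_simulate()`,
`run_scan()`, `run_promoter()` and `run_report()` write CSV/JSON outputs
with a provenance record, and `inst/cli/xlnrdyn.R` wraps them for shell
use.

## Documentation

The methods vignette (`vignettes/xlnr-regulon-dynamics.Rmd`) documents
the equations, parameter meanings and defaults, numerical choices, the
evaluation-point sensitivity of scan thresholds, and the limits of what
the synthetic scenarios can show.
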