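---
title: "An organism-scale model of metastasis under systemic inhibition of angiogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An organism-scale model of metastasis under systemic inhibition of angiogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiomet)
```

## The model

Autopsy series consistently find occult, non-progressing tumors in most
adults, and animal experiments show that a tumor secretes both stimulators
and inhibitors of its own vasculature. Because circulating angiogenesis
inhibitors (angiostatin, endostatin, thrombospondin-1) are cleared far more
slowly than stimulators such as VEGF, a growing population of lesions can
accumulate enough systemic inhibitor to suppress the vascular development
of *every* lesion, its own included. `angiomet` implements a deterministic
organism-scale model of this mechanism and asks when it produces *global
dormancy*: a homeostatic steady state of the whole tumor/metastasis system
in which total burden stabilizes while composed of occult micro-lesions.

Every lesion is described by two traits, a volume $V$ (mm³) and a carrying
capacity $K$ (mm³) representing its current vascular support:

$$\dot V = a V \log(K/V), \qquad
  \dot K = bV - \bigl(d\,V^{2/3} + e\,I\bigr) K .$$

Volume growth is Gompertzian toward the dynamic capacity. The capacity is
driven up by angiogenic stimulation $bV$ (stimulators clear fast, so their
effect is proportional to current tumor mass) and down by two inhibitory
terms: a *local* one, $d V^{2/3} K$, and a *systemic* one, $e I K$, where
$I$ (mg) is the total circulating inhibitor produced by **all** lesions:

$$\dot I = p\Bigl(V_p + \int\!\!\int V \rho \, dV\, dK\Bigr) - kI,
  \qquad I(0) = 0 .$$

Here $V_p$ is the primary tumor volume and $\rho(t, V, K)$ the structured
density of metastases. Each lesion above the angiogenic-switch volume
$V_m$ seeds new metastases at rate $\beta(V) = m V^{\alpha}$
($\alpha \in [0,1]$ is one third of the fractal dimension of the tumor
vasculature; $\alpha = 2/3$ corresponds to superficial vascularization).
Newborn metastases enter at one cell, $V_0 = 10^{-6}$ mm³, with capacity
$K_0 = 1$ mm³, so the renewal boundary condition feeds the density at a
single point of state space. Metastases whose capacity is driven below one
cell shrink back, and leave the population (death by nutrient deprivation)
when their volume itself returns to $V_0$ — the outflow boundary of the
domain $(V_0,\infty)\times(0,\infty)$, where the characteristic flux
points outward exactly when $K < V_0$.

The primary follows the same structural model with its own kinetic
parameters $(a_p, b_p, d_p)$; production $p$ and efficacy $e$ are common
to all lesions, which also forces $d_p = d$ (below).

### The local inhibition coefficient is not free

The local term is derived, not fitted. Treating a lesion as a sphere of
radius $R$ with uniform volumetric inhibitor production $p$, negligible
intra-tumor clearance and surface concentration equal to the systemic
level, the quasi-steady diffusion problem
$D^2 \frac{1}{r^2}\bigl(r^2 n'\bigr)' = -p$, $n(R) = i$, gives
$n(r) = i + p(R^2 - r^2)/(6 D^2)$, a volume-mean excess of
$p R^2/(15 D^2)$. Substituting $R^2 = (3V/4\pi)^{2/3}$ and weighting by
the systemic efficacy $e V_d$ yields

$$d = \frac{e\, V_d\, p}{15\, D^2} \left(\frac{3}{4\pi}\right)^{2/3},$$

implemented in `derive_local_inhibition()`. With the angiostatin values
below it evaluates to $0.0717$ mm⁻² day⁻¹, and it is linear in $p$: a
regime with stronger inhibitor production proportionally strengthens
local inhibition too, which is how the dormancy scenario rescales $d$.

### Parameters

`default_parameters()` ships the canonical set for the 4T1 mouse mammary
carcinoma system (units mm³ / mg / day):

| symbol | value | meaning |
|---|---|---|
| $a_p$, $a$ | 0.154 d⁻¹ | proliferation rate, primary / metastases |
| $b_p$, $b$ | 16.7, 12.5 d⁻¹ | angiogenic stimulation |
| $d_p = d$ | 0.0717 mm⁻² d⁻¹ | local inhibition (derived) |
| $m$ | 0.0229 mm⁻³ᵅ d⁻¹ | colonization coefficient |
| $\alpha$ | 2/3 | vascular fractal exponent |
| $p$ | 8.3·10⁻⁶ mg mm⁻³ d⁻¹ | inhibitor production (12.5 µg/day ÷ 1500 mm³) |
| $k$ | 0.38 d⁻¹ | inhibitor elimination (half-life 1.8 d) |
| $e$ | 7.5 mg⁻¹ d⁻¹ | inhibitor efficacy |
| $V_0$ | 10⁻⁶ mm³ | newborn volume (one cell) |
| $K_0$ | 1 mm³ | newborn capacity (avascular plateau) |
| $V_m$ | 1 mm³ | emission threshold (angiogenic switch) |
| $D^2$ | 0.156 mm² d⁻¹ | inhibitor diffusion coefficient |
| $V_d$ | 7000 mm³ | distribution volume (20 g mouse) |

The growth and dissemination values come from the two-stage fit described
below; the inhibitor values from angiostatin pharmacology. The emission
threshold applies to the primary exactly as to metastases — nothing in the
model exempts it — and with the canonical $m$ a 200 mm³ lesion emits
`r round(emission_rate(200, 0.0229, 2/3), 3)` metastases per day, i.e.
roughly 0.8 per day. (Reported prose for this quantity is ambiguous
between a rate of ~0.77/day and an interval of 0.77 days; the computed
rate supports the former reading, the package simply reports
$\beta(200)$.)

## Numerics

### The cohort (Lagrangian) scheme

Because births are point-valued, the metastatic density is supported on
the one-parameter family of characteristics indexed by birth time, and
no 2-D grid in $(V, K)$ is ever needed: `simulate_system()` *straightens
the characteristics*, creating one cohort per time step at $(V_0, K_0)$.
A cohort born at time $t_j$ carries weight $w_j = E(t_j)$, the emission
rate of the whole system at its birth:

$$E(t) = \beta(V_p(t)) + \int_0^t \beta\bigl(V(t;\tau)\bigr)E(\tau)\,d\tau ,$$

with the birth-time integral evaluated by the trapezoid rule. The count
carried by a cohort over a step is $w_j\,\Delta t$; total count, burden
and the size histogram are weighted sums over live cohorts, and an exact
per-step balance (emitted minus removed equals the change in count) holds
to machine precision by construction and is asserted in the tests.

All cohorts, the primary and the inhibitor are advanced together by an
explicit second-order Heun step (`method = "heun"`). This choice is
deliberate: a metastasis grows through roughly twenty e-folds of volume,
and a first-order step accumulates a systematic under-integration of
Gompertz growth that still amounts to double-digit percentage errors on
the 32-day burden at $\Delta t = 0.05$ d. With the Heun step the default
$\Delta t = 0.05$ d reproduces an adaptive reference integration of a
single lesion to ~0.1%, and halving the step changes every reported
observable by well under 1% in all bundled scenarios (asserted in the
tests). The classic first-order scheme remains available as
`method = "euler"` for convergence studies; with it, quantities dominated
by the largest metastases converge so slowly that results at practical
steps are materially biased. This matters for interpretation: previously
reported endpoint figures for these scenarios (e.g. a 32-day metastatic
burden near 63 mm³ with ~43 visible metastases of mean size ~1.48 mm³)
are mutually consistent with a first-order run at a coarse step, while
the converged model prediction under the identical inputs is a burden of
~93 mm³ with ~45.6 visible metastases (the counts move little, the
burden a lot, because the burden is carried by the few earliest, largest
metastases). The package reports converged values and leaves the
corresponding comparisons red rather than degrading its numerics to match.

Two further consequences of accurate integration are worth recording.
First, systemic inhibition at the canonical production rate is *not*
negligible in the 32-day replicate: switching the inhibitor on moves the
burden by ~34% (counts by ~2%), though the experiment is conventionally
simulated with $I = 0$; the package follows that convention in its
`"huang"` scenario and tests the (failing) negligibility claim honestly.
Second, in the full cancer-history run the inhibitor feedback delays the
time at which the metastatic burden reaches the 5000 mm³ stopping
threshold by ~5 days relative to an $I = 0$ run.

Coupling details: stage rates are evaluated with the current inhibitor
amount and total volume, the predictor re-evaluates both, and emission
and removal are applied once per step after the state update. The
stopping time for a burden threshold is interpolated linearly within the
crossing step. Degenerate inputs (non-positive `dt`, `T`, initial
states; unsorted histogram breaks; non-finite states during integration)
raise immediately with descriptive errors.

### The independent oracle

`solve_renewal()` solves the same system by completely different
numerics: Picard iteration on the renewal integral equation, with every
cohort trajectory integrated by `deSolve::lsoda` at tolerances 1e-8/1e-12,
the Volterra equation solved by trapezoid marching (explicit because
$\beta(V_0) = 0$), and the inhibitor propagated by an exact exponential
integrator with trapezoidal source. The two solvers share only the rate
laws, so sub-1% agreement — asserted on three scenarios (the 32-day
replicate; the cancer history truncated to 40 days; the dormancy regime
truncated to 120 days, with renewal grids of 320, 200 and 300 intervals
respectively) — is evidence of correctness rather than of shared bugs.
The iteration starts from the no-feedback guess $E^{(0)} = 0$ and
converges in 2–8 iterations for all parameter sets exercised; the
residual history is returned, and non-convergence raises with it.

## Calibration

The two-stage least-squares procedure mirrors how the canonical values
were obtained, and is exposed so that synthetic datasets can be fitted
end to end:

1. `fit_primary()` estimates $(a_p, b_p)$ from a primary growth curve by
   minimizing the sum of squared errors of the solved growth model with
   $I = 0$ (systemic inhibition is negligible over such short
   implantation experiments *for the fit*, and holding $d_p$ at its
   derived value removes an indeterminacy). The optimizer is the
   Levenberg–Marquardt trust-region implementation of `minpack.lm`,
   protected by five deterministic log-spaced starts and box constraints
   ($a_p \in [10^{-3}, 10]$, $b_p \in [0.1, 100]$); $R^2$ is reported. A
   curve with constant volumes makes $a_p$ unidentifiable (the Gompertz
   factor vanishes) and is returned flagged instead of fitted.
2. `fit_metastatic()` fixes everything else (metastatic proliferation is
   tied to the fitted primary value, growth differences being attributed
   to the microenvironment through $b$) and estimates $(b, m)$ from two
   endpoint observables — visible metastasis count and mean visible size
   — by least squares on the 2-vector of relative residuals: two
   parameters for two data points. Bounds $b \in [0.1, 100]$,
   $m \in [10^{-4}, 10]$, same multi-start policy.

The *mean size* convention throughout is total burden divided by the
count of metastases above the 10-cell (10⁻⁵ mm³) visibility threshold,
matching how dissecting-microscope counts are reported.

## Synthetic data

No public accession exists for the underlying 4T1 experiment, so
`synthetic_spec()` + `generate_growth_curve()` / `generate_endpoints()`
emulate its design from known model parameters: seven volume
measurements every 4 days from day 8 to day 32 on a primary implanted at
0.1 mm³ (10⁵ cells, initial capacity 200 mm³ — a fixed scenario input),
and endpoint count/mean-size summaries at day 32 with a 10-cell
visibility threshold. Measurement noise is multiplicative log-normal
(volumes are positive and scatter grows with the mean — an assumption of
this package, not a reported property), with a 5% log-sd default; the
seed fixes a dataset bit-for-bit without disturbing the caller's RNG
stream. The generator does not emulate detection-probability details of
dissecting microscopy, inter-animal variability beyond measurement
noise, or censoring; recovery results on synthetic data therefore
demonstrate identifiability and optimizer correctness, not robustness to
every feature of real data. Under the default design, 100 replicates at
5% noise recover $a_p$ and $b_p$ with median relative errors under 5%
and bias under 1% (asserted in the tests at looser thresholds).

## Bundled scenarios and problem sizes

* `"huang"` — 32-day in-silico replicate of the implantation experiment,
  $I = 0$, 640 steps.
* `"history"` — the whole cancer history from one cell
  ($V_p(0) = 10^{-6}$ mm³, $K_p(0) = 1$ mm³), inhibitor active, stopping
  when the metastatic burden (primary excluded) reaches 5000 mm³,
  ~1300 steps.
* `"dormancy"` — inhibitor production raised to
  $p = 2.5\cdot10^{-4}$ mg mm⁻³ d⁻¹ (≈30× canonical) with $d = d_p$
  rescaled proportionally through the diffusion formula to
  2.16 mm⁻² d⁻¹, 350 days (7000 steps).

In the dormancy regime the primary peaks near 21 mm³ around day 78 and
then shrinks under inhibition from its own metastases, while the burden
saturates: its relative change over the last 30 days of the run is ~5%,
still above the 1%/30 d plateau criterion at day 350, with the
asymptote near $k\,(b - d V_m^{2/3})/(e\,p) \approx 2100$ mm³ approached
slowly from below. The entire final population sits below 10 mm³ —
dormancy of the system, not of any individual lesion's proliferation.

## Known limitations

* Spatial structure beyond the radially symmetric quasi-steady diffusion
  analysis is not modeled; neither are pharmacokinetics of exogenous
  drugs, immune-mediated concomitant resistance, or treatment schedules.
* The model is deterministic; inter-animal variability enters only
  through the synthetic data generator.
* Cohort weights are densities (metastases per day), so counts are real
  numbers; integer-valued realizations would require a branching-process
  layer that is out of scope.
* The dormancy plateau is approached slowly; runs substantially longer
  than a mouse lifespan would be needed to see the strict asymptote.
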