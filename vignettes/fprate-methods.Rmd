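---
title: "From spiking networks to low-dimensional rate models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spiking networks to low-dimensional rate models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A large population of adaptive exponential integrate-and-fire (aEIF) neurons,
sparsely coupled by delayed current pulses and driven by fluctuating external
input, produces a population spike rate `r_N(t)`. `fprate` implements a chain
of reductions of that system:

1. the **ground truth**: Euler–Maruyama simulation of the `2N`-dimensional
   stochastic network (`simulate_network`);
2. the **intermediate mean-field model**: a 1+1-dimensional Fokker–Planck
   (FP) equation for the membrane-voltage density `p(V, t)`, coupled to an
   ODE for the population-averaged adaptation current `<w>` and one for the
   delayed rate `r_d` (`run_fp`);
3. four **low-dimensional rate models** derived from the FP description —
   two spectral models (`spec1`, `spec2`) obtained from a truncated
   eigendecomposition of the FP operator, and two linear–nonlinear cascade
   models (`lnexp`, `lndos`) built from the FP linear rate response
   (`run_rate_model`);
4. a **benchmark harness** that feeds one identical input realization to
   every description and scores each reduction against the network rate by
   Pearson correlation and RMS distance (`compare_models`).

Units are fixed package-wide: time in ms, voltage in mV, rates in kHz,
input mean μ in mV/ms and input variance σ² in mV²/ms, so σ carries
mV·ms^−1/2. Figure-style captions elsewhere often print σ in "mV/ms"; we
standardize dimensionally and keep the numerical values identical.

## Model assumptions

* **Diffusion approximation**: each neuron's summed synaptic input is
  replaced by white noise with moments
  μ_syn = μ_ext + J·K·r_d and σ²_syn = σ²_ext + J²·K·r_d. Valid for many
  weak inputs (K ≫ 1, |J| small against V_T − V_r).
* **Mean-field limit**: input fluctuations are uncorrelated across neurons
  (sparse random connectivity).
* **Adiabatic adaptation**: the individual adaptation current w_i is
  replaced by its population average, justified when τ_w (200 ms by
  default) is much larger than the membrane time constant C/g_L = 20 ms.
* **Exponential delay distribution**: the delayed rate obeys
  dr_d/dt = (r − r_d)/τ_d. Identical delays (a ring buffer) and no delays
  are also supported everywhere except in the `spec2` coefficients, which
  are derived for the exponential case only.

## The quantity table

All four reduced models evaluate quantities of the *detached* EIF population
(no adaptation, no coupling) as functions of generic input moments (μ, σ):
the steady-state rate r∞ and mean voltage ⟨V⟩∞ with their μ- and
σ²-derivatives, the two dominant eigenvalues λ₁, λ₂ of the FP operator with
the lumped scalars M, S, F_μ, F_σ², and the cascade filter parameters τ_μ,
(τ, ω), τ_σ. `precompute_quantities` fills these on a rectangular (μ, σ)
grid; the table is keyed by the EIF parameters only, so changing input,
coupling or adaptation parameters never forces a recompute. Default
production spacings are Δμ = 0.025 mV/ms and Δσ = 0.1 mV·ms^−1/2; lookups
bilinearly interpolate, and out-of-range queries clamp to the boundary so
that brief excursions of μ_tot during stiff transients do not abort a run.

The supported noise floor is σ ≥ 0.5 mV·ms^−1/2 — below it the FP
parametrization and the numerics degrade. OU-generated variance processes
reject parametrizations that dip below the floor more than rarely and clamp
isolated excursions with a warning.

## Numerical methods

**Finite-volume FP solver.** The voltage domain [V_lb, V_s] is split into
equidistant cells; fluxes use the exponentially fitted Scharfetter–Gummel
form (centered differences recovered for vanishing drift, upwinding for
strong drift), with a reflecting lower boundary, an absorbing ghost-cell
closure at the spike voltage, and reinjection of the outflow at the reset
cell one refractory period later (at least one time step). Time stepping is
implicit Euler with coefficients frozen at the step start; each step is one
tridiagonal (Thomas) solve. Probability bookkeeping (density mass plus the
refractory pipeline) is conserved to ~1e−13 per step; the scheme is first
order in ΔV and Δt. Flux weights use `expm1`-based evaluation with a series
branch below |v ΔV/D| < 1e−10 to avoid 0/0 at vanishing drift.

**Stationary solve.** The steady state is obtained directly rather than by
time marching: the one-dimensional nullspace of the discrete operator (with
reinjection) is pinned by fixing the last cell's density, solving the
remaining tridiagonal system, and renormalizing so that density mass plus
refractory mass r∞·T_ref equals one. Time marching is retained in the test
suite as an oracle (agreement within 0.5%).

**Spectral solver.** Eigenvalues of the FP operator are the roots of the
lower-bound eigenflux: the first-order system for (eigenflux, eigenfunction)
is integrated backward from the spike voltage by a one-term Magnus scheme
with analytic 2×2 matrix exponentials evaluated at cell midpoints (series
fallback when the local exponents nearly coincide). The state is rescaled at
fixed checkpoints (every 128 steps) and the accumulated positive log-scale
returned, which keeps the root structure intact while preventing under- and
overflow across the strongly hyperpolarized part of the domain. At a
sufficiently negative mean input the whole spectrum is real (in that regime
the EIF density dynamics reduces to an Ornstein–Uhlenbeck problem whose
eigenvalues are −n·g_L/C, a useful analytic anchor used in the tests);
branches are then continued toward larger μ with damped complex Newton
iterations. When two real branches collide they are replaced by one complex
conjugate-pair representative; lost roots trigger internal μ-step refinement
(up to 2⁵-fold). λ₁ is the nonzero eigenvalue of smallest |Re|; λ₂ is the
next one subject to λ₁ + λ₂ being real (the conjugate partner, or the next
real eigenvalue when λ₁ is real). The λ₁/λ₂ selection jumps across the
diffusive-to-regular transition curve; affected nodes are interpolated over
when filling the table, a known source of (small) spec2 error near that
curve.

Adjoint eigenfunctions are integrated forward from the lower bound with
ψ(V_lb) = 1, ψ'(V_lb) = 0, which both fixes their normalization smoothly
across (μ, σ) and makes the reset-derivative condition automatic; the
remaining boundary condition at V_s is monitored as a residual. Inner
products use non-conjugated trapezoidal quadrature. The couplings
c_n^x = ⟨∂_x ψ_n, φ₀⟩ use a local finite-difference stencil
(h_μ = 0.005 mV/ms, h_σ² = 1% of σ²) with the eigenvalue re-polished at
each stencil point — more accurate than differencing across table nodes and
free of cross-column storage.

**Linear rate response.** The response spectra R̂_μ(f), R̂_σ(f) are computed
by linearizing the *discrete* finite-volume system around the stationary
solution and solving one complex tridiagonal-plus-rank-one system per
frequency (Sherman–Morrison with two Thomas solves). Working at the discrete
level makes the f → 0 limit agree with finite differences of the discrete
stationary solve to ~1e−8, so the cascade filters are exactly DC-normalized.
The frequency grid is 64 log-spaced points in [1e−3, 1] kHz; f = 0 is
handled by the stationary derivative.

**Filter fits.** τ_μ comes from a complex least-squares Lorentzian fit over
the grid (the variant used by `lnexp`); the tail-matched closed form
τ_μ = Δ_T ∂_μ r∞ / r∞ is also stored. The damped-oscillator parameters
(τ, ω) match the normalized response at the frequencies where its real and
imaginary parts peak (quadratically refined in log f), minimizing the
equally weighted two-point complex mismatch; a degenerate peak at the grid
edge falls back to ω = 0. τ_σ is a Lorentzian fit when ∂_σ r∞ > 0 and the
delta-filter limit τ_σ = 0 otherwise (large mean, small variance). At
quiescent nodes (numerically zero rate) the DC normalization is undefined;
those nodes are filled from the nearest responsive node along μ. Note that
the least-squares and tail-matched τ_μ agree closely only in the mean-driven
regime; in the fluctuation-dominated regime the full fit follows the slow
dominant decay (≈ 1/|Re λ₁|) and is roughly twice the tail-matched value —
the reason `lnexp` uses the least-squares variant.

**Reduced-model integration.** All four models share the adaptation and
delayed-rate dynamics and integrate with Heun's method by default
(dt = 0.01 ms; explicit Euler available, needing smaller steps for `spec2`
and `lndos` to avoid oscillatory artifacts). `spec2` and `lndos` require
twice- (once-) differentiable inputs: OU inputs are Gaussian-smoothed with
σ_t ≥ 1 ms and their time derivatives computed by central differences at
the signal resolution. `spec2` clamps negative rate excursions (rate and
slope reset to zero); `spec1` clips only its real-part output, leaving the
complex state untouched to preserve the linear dynamics. Initial conditions
default to the stationary values at the initial total moments (`spec1`,
`spec2`) and to the initial synaptic moments (`lnexp`, `lndos`).

**Network simulator.** Euler–Maruyama at dt = 0.05 ms with per-neuron
independent noise realizations; fixed in-degree K drawn uniformly without
self-connections; one delay sample per connection, rounded to the step and
delivered through a ring buffer (exponential delays are capped at 12 τ_d,
clamping ~6e−6 of the delay mass). Voltage and adaptation are clamped during
the refractory period; the population mean voltage averages non-refractory
neurons only, carrying the previous value if none are available. The
normal generator is a polar-method transform of `mt19937_64`, so runs are
bit-reproducible for a given seed. No reflecting barrier is imposed on the
particles — the finite lower bound is an FP-model construct.

## What the synthetic inputs emulate

The benchmark inputs are stationary OU processes for μ_ext(t) (and
optionally σ²_ext(t)), Gaussian-smoothed with σ_t = 1 ms, mimicking the
range of presynaptic population-rate fluctuations; the exact discretization
update is used so stationarity holds at any sampling step. They do not
emulate pulse-like or strongly non-Gaussian inputs, shared-noise
correlations, or conductance effects — good test performance therefore
speaks to input statistics within this family, not to arbitrary stimuli.

## Benchmark design and reported problem sizes

The comparison protocol feeds one smoothed OU realization to all models,
discards the first second (initial conditions are not matched), bins rates
at 1 ms, and reports ρ and d_RMS against the network rate plus the
input–output reference ρ(r_N, μ_ext). The package's reference benchmarks use
uncoupled populations of N = 10,000 neurons and 20 s of activity per
parametrization, with baseline means 1.5 and 4 mV/ms, noise intensities 1.5
and 2 mV·ms^−1/2, variation strength θ_μ = 0.54 mV/ms and correlation times
50 ms (moderate) and 5 ms (rapid); the test suite scales down to N = 5,000
and a coarser quantity grid. These sizes keep a full benchmark run in the
tens of minutes on one CPU while leaving the finite-size noise floor well
below the model-mismatch signal.

For the quasi-static consistency check (all five descriptions agreeing under
slow input) we use τ_ou = 500 ms with θ_μ = 0.3 mV/ms around a responsive
baseline (μ̄ = 2, σ_ext = 2): the adiabatic statement concerns a population
tracking its stationary map, so the trajectory must stay in the responsive
regime — excursions into quiescence make mean-rate-relative errors
ill-conditioned without bearing on the claim.

## Known limitations

* `spec2` supports neither a refractory period nor non-exponential delays
  (with coupling); both restrictions are inherited from its derivation.
* The λ-branch discontinuity curve in (μ, σ) leaves kinks in the spec2
  coefficient surfaces; no smoothing across the curve is attempted.
* Delayed-inhibition limit cycles require the actual (identical) delay
  distribution: replacing an identical delay d by an exponential kernel with
  τ_d = d smears the feedback phase enough to suppress the oscillation in
  the mean-field models, so the oscillation benchmarks use identical delays
  for that regime (and `spec2` is excluded there).
* First-order convergence of the FV scheme means accurate absolute rates
  need the production spacing (ΔV = 0.028 mV or finer); the coarse grids
  used in the test suite are for speed, with tolerances widened accordingly
  and documented inline.
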