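# fprate

Low-dimensional spike rate models derived from networks of adaptive
exponential integrate-and-fire (aEIF) neurons via the Fokker-Planck
mean-field equation.

## What problem this solves, and for whom

Simulating a population of tens of thousands of spiking neurons is slow, and
the resulting rate dynamics is hard to analyze. For computational
neuroscientists who need population-rate dynamics that *retain the
parameters of the underlying neurons* — for large multi-population
simulations, for bifurcation analyses of network states, or as a
quantitatively grounded rate model — this package reduces the network to a
handful of ODEs and quantifies how much accuracy each reduction gives up.

The chain of descriptions, all implemented here:

- **aEIF network** (ground truth): membrane voltage
  `C dV/dt = -g_L (V - E_L) + g_L Δ_T exp((V - V_T)/Δ_T) - w + I_syn(t)`
  with spike-and-reset at `V_s → V_r`, adaptation
  `τ_w dw/dt = a (V - E_w) - w`, `w → w + b` at spikes, sparse pulse
  coupling (in-degree `K`, strength `J`, delayed), and fluctuating external
  input with moments `μ_ext(t)`, `σ²_ext(t)`.
- **Fokker-Planck model**: in the mean-field limit the voltage density
  `p(V, t)` obeys a drift-diffusion PDE with total moments
  `μ_tot = μ_ext + J K r_d - ⟨w⟩/C`, `σ²_tot = σ²_ext + J² K r_d`, an
  absorbing boundary at `V_s`, reinjection at `V_r`, and the rate
  `r(t)` given by the flux through `V_s`. Solved with an implicit
  Scharfetter-Gummel finite-volume scheme.
- **spec₁**: `dr̃/dt = λ₁(r̃ - r∞)`, `r = Re r̃`, driven by the dominant
  eigenvalue `λ₁(μ_tot, σ_tot)` of the Fokker-Planck operator.
- **spec₂**: `β₂ r̈ + β₁ ṙ + β₀ r = r∞ - r - β_c`, with coefficients built
  from the two dominant eigenvalues and eigenfunction projections
  (`D = 1/(λ₁λ₂)`, `T = 1/λ₁ + 1/λ₂`, `M`, `S`, `F_μ`, `F_σ²`, …).
- **LN_exp / LN_dos**: linear-nonlinear cascades — the synaptic moments pass
  through an exponential (or damped-oscillator) filter fitted to the
  Fokker-Planck linear rate response, followed by the static nonlinearity
  `r = r∞(μ_eff, σ_eff)`.

Everything input-dependent enters through precomputed lookup tables over
generic input moments `(μ, σ)`; changing input, coupling or adaptation
parameters requires no recomputation.

## Worked example

Precompute a small quantity table, look up quantities, and benchmark all
four reduced models against a 2,000-neuron network driven by a smoothed
Ornstein-Uhlenbeck mean input:

```r
library(fprate)
np  <- neuron_params()              # regular-spiking cortical pyramidal cell
gs  <- grid_spec(mu_min = -1, mu_max = 4, d_mu = 0.1,
                 sigma_min = 1.0, sigma_max = 2.0, d_sigma = 0.5)
tab <- precompute_quantities(np, gs, dV = 0.02, dV_sweep = 0.02)

lookup(tab, 1.5, 1.5, c("r_inf", "mean_V_inf", "lam1_re", "lam1_im", "tau_mu"))
#> $r_inf        0.04556581      # steady-state rate, kHz (45.6 Hz)
#> $mean_V_inf   -56.68292       # steady-state mean voltage, mV
#> $lam1_re      -0.07148959     # dominant eigenvalue, 1/ms: 14 ms decay ...
#> $lam1_im      0.2909764       # ... with a 46 Hz damped oscillation
#> $tau_mu       1.278138        # LN_exp mean-filter time constant, ms

res <- compare_models(np, coupling_params(K = 0),
                      ou_params(mean = 1.5, theta = 0.54, tau_ou = 50, sigma_t = 1),
                      sigma_ext = 1.5, table = tab, N = 2000, T = 10000, seed = 1)
res$metrics[, c("model", "rho", "d_rms")]
#>   model   rho   d_rms
#> 1 spec1 0.945 0.00426
#> 2 spec2 0.956 0.00407
#> 3 lnexp 0.972 0.00312
#> 4 lndos 0.970 0.00314
res$rho_input
#> [1] 0.824
```

Reading the numbers: every reduced model tracks the network rate far better
than the input itself does (`ρ = 0.824`), the LN cascade models lead
(`ρ ≈ 0.97`), the one-eigenvalue spec₁ model trails (`ρ = 0.945`), and the
RMS distances are a few Hz (`d_rms` is in kHz) around a ~45 Hz mean rate.
With the production-scale settings (N = 10,000, 20 s, fine table) the same
ordering holds with `ρ` ≈ 0.98–0.99 for the top models.

The time-dependent Fokker-Planck solution (`run_fp`), the network raster
(`simulate_network(..., want_raster = TRUE)`), the eigenvalue machinery
(`track_spectrum`, `spectral_quantities`) and the response-function fits
(`linear_rate_response`, `fit_exp_filter`, `fit_dos_filter`,
`fit_sigma_filter`) are all exported individually; see the methods vignette
(`vignettes/fprate-methods.Rmd`) for the numerical choices.

A thin command-line front end with verbs `precompute`, `simulate-network`,
`run-fp`, `run-model` and `compare` lives at `inst/cli/fprate` and is driven
by a JSON run configuration.

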