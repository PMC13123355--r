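# confokit

Conformational-dynamics toolkit for receptor biophysics in solution.

G protein-coupled receptors activate by moving transmembrane helix 6 (TM6)
outward, and water-soluble receptor variants make that motion accessible to
solution biophysics: single-molecule FRET resolves the conformational
states and their populations, quasi-elastic neutron scattering (QENS)
quantifies global diffusion and internal dynamics, small-angle scattering
(SANS/SAXS) characterises the oligomeric ensemble, and thermal-shift assays
report ligand-induced stabilisation. confokit implements the full
quantitative chain for all four modalities, and pairs every analysis stage
with a synthetic-data generator so each estimator can be validated by
parameter recovery — no external data needed. It is written for
biophysicists analysing such experiments and for method developers who need
a reference implementation with ground-truth tests.

## What it computes

**smFRET.** Per-frame efficiency `E = I_A/(I_D + I_A)` up to the detected
photobleaching point (`compute_fret()`); conformational states by
step-transition / state-identification analysis — recursive change-point
detection with model size selected by minimum description length
(`stasi()`); state populations from Gaussian decomposition of the pooled
efficiency histogram (`fit_fret_histogram()`); and distances via the
Förster relation

&nbsp;&nbsp;&nbsp;&nbsp;R₀ = 0.211 · (κ² η⁻⁴ Q_D J)^(1/6),&nbsp;&nbsp;
J = ∫F_D(λ) ε_A(λ) λ⁴ dλ / ∫F_D(λ) dλ,&nbsp;&nbsp;
r = R₀ (1/E − 1)^(1/6)

(`forster_radius()`, `fret_to_distance()`, `fret_displacement()`).

**QENS.** Weighted fits of S(Q,E) with two Lorentzians convolved with the
instrument resolution plus a linear background (`fit_qens_spectrum()`);
global diffusivity from the Q² law Γ = DQ² (`fit_global_diffusion()`);
internal relaxation from the power law Γ = (1/τ₀)Q^α with τ = 658.2/Γ ps
(`fit_internal_dynamics()`); activation energies from Arrhenius fits of
ln X vs 1/T (`arrhenius_fit()`); or the whole chain via `qens_dynamics()`.

**Small-angle scattering.** Debye-formula curves from bead models
(`debye_curve()`, `sphere_bead_model()`, `oligomer_bead_models()`);
Guinier fits restricted to q·Rg ≤ 1.3 (`guinier_fit()`); pair-distance
distributions P(r) by regularized indirect Fourier transform
(`pr_transform()`); and minimal-ensemble decomposition of a measured curve
over candidate species — member identity searched by a genetic algorithm,
weights from exact non-negative least squares, fitness = reduced χ²
(`ga_select()`, `nnls_weights()`, `ensemble_exhaustive()`).

**Thermal shift.** Boltzmann sigmoid fits
F(T) = f_min + (f_max − f_min)/(1 + exp((Tm − T)/slope)) and condition
shifts ΔTm (`fit_boltzmann()`, `delta_tm()`).

**Generators and pipeline.** `simulate_fret_traces()`, `simulate_qens()`,
`simulate_sas_mixture()`, `simulate_melt_curve()` produce ground-truth
labelled inputs for every stage; `confokit_run()` orchestrates
simulate→analyze runs from one seeded configuration and
`acceptance_check()` compares a run report against target tables.

## Worked example

Simulate a four-state receptor at the canonical efficiencies
0.33/0.49/0.63/0.78 with slow exchange, recover the states and their
populations, and convert the active-like state to a TM6 displacement:

```r
library(confokit)

sim    <- simulate_fret_traces(fret_sim_config(n_traces = 200, seed = 7))
traces <- Filter(function(f) f$valid && f$n_valid >= 10,
                 lapply(sim$traces, compute_fret))

states <- stasi(traces)
states
#> STaSI fit: 4 states over 67399 frames (sigma = 0.0380)
#> State means: 0.331, 0.491, 0.630, 0.781

pops <- fit_fret_histogram(traces, coef(states), seed = 8)
pops
#> FRET histogram fit: 193 molecules, 67399 frames, 4 components
#>   mean     sd weight population_pct
#>  0.331 0.0386  0.231           23.1
#>  0.491 0.0365  0.270           27.1
#>  0.630 0.0369  0.234           23.4
#>  0.781 0.0415  0.263           26.4

fret_displacement(0.49, 0.78, R0 = 54.8)
#> [1] 10.79512
```

The four recovered means sit within 0.001–0.002 of the generating values,
the populations are consistent with the generator's uniform stationary law
(25% each, recovered within ~2 points at 193 usable molecules), and an
efficiency drop from 0.78 to 0.49 at R₀ = 54.8 Å corresponds to a ~10.8 Å
outward TM6 displacement. The QENS chain runs the same way:

```r
dyn <- qens_dynamics(simulate_qens(qens_sim_config(seed = 9))$spectra)
dyn
#> QENS dynamics analysis:
#>   global diffusion:  Ea = 21.4 +/- 0.9 kJ/mol
#>   internal dynamics: Ea = 8.6 +/- 1.0 kJ/mol
```

recovering the generating activation energies (21.1 and 8.2 kJ/mol) within
their fitted uncertainties from 3%-noise spectra.

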