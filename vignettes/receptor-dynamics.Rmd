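---
title: "Models and methods behind confokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind confokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

confokit implements the quantitative analysis chain used in solution-state
studies of receptor conformational dynamics — here the motivating system is
a water-soluble engineered mu-opioid receptor, where activation is read out
as an outward displacement of transmembrane helix 6 (TM6). Four
experimental modalities are covered, each as a matched
generator/estimator pair so that every stage can be validated by parameter
recovery on synthetic data with known ground truth. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic data do and do not establish about real measurements.

## Single-molecule FRET

**Measurement model.** A molecule hops between a small number of
conformational states, each with a characteristic FRET efficiency; with
donor and acceptor intensities $I_D$, $I_A$ the per-frame efficiency is
$E = I_A/(I_D + I_A)$. The generator (`simulate_fret_traces()`) evolves a
continuous-time Markov chain and integrates state occupancy within each
camera frame (default 100 ms), so frames containing a transition take
intermediate efficiencies, as in real data. Channel noise is additive
Gaussian (a shot-noise approximation appropriate at ~1000 photons/frame;
the downstream histogram model is Gaussian for the same reason).
Photobleaching is single-step: the acceptor dies first (donor recovers the
full intensity; E collapses), later the donor (both channels fall to
background).

**Defaults and why.** State means 0.33/0.49/0.63/0.78 (the four-state
ensemble of the motivating system); total intensity 1000 photons/frame
with 5% per-channel noise; per-frame bleach probability 0.002 (mean
photobleach time ~50 s). The default exchange rate is 0.2/s: transitions
must be slower than the 100-ms frame, and single molecules are expected to
sample only a subset of states during an observation window, which implies
dwell times of seconds. For *occupancy-matched* condition cohorts — runs
whose purpose is to impose prescribed per-frame state fractions on a
finite cohort (e.g. 154 or 94 molecules) — the generator additionally
stratifies initial states by largest-remainder quotas and the recommended
exchange rate is 0.5/s: at 0.2/s the dwell-time autocorrelation lets a
cohort's realised occupancy wander 2–4 percentage points from the
prescribed fractions, which is cohort sampling noise rather than analysis
error, while at much faster exchange mid-frame averaging starts to bias the
intermediate components. The choice is a property of the simulated
condition, not of the estimators.

**Trace processing.** `compute_fret()` subtracts per-channel backgrounds
and ends the efficiency trace at the photobleaching point. The terminal
(donor) bleach is detected when the summed intensity falls below half its
running median. The acceptor bleach leaves the sum unchanged, so it is
detected separately: acceptor below 0.15x the running median of the sum,
sustained for three frames (a run reaching the end of the trace is
accepted even if shorter), then extended backwards over adjacent
sub-threshold frames so noisy edge frames do not leak into the trace. The
0.15 floor sits far below the lowest state's acceptor level (0.33 of
total), so genuine low-FRET dwells do not trigger it. Backgrounds come
from post-bleach frames where available; the modal low-decile fallback is
accepted only when that mode is genuinely dark (<15% of the trace
median) — otherwise the trace never bleached, the low decile is signal,
and the baseline is taken as already corrected.

**State identification (STaSI).** `stasi()` estimates the noise scale
from the robust spread of first differences
($\sigma = \mathrm{MAD}(\Delta y)/(0.6745\sqrt{2})$), recursively splits
each trace at the frame maximising the two-sample t statistic (accepted
above the 99.9th percentile of the null t distribution), pools segment
means across traces, merges them agglomeratively, and selects the number
of states m by minimum description length. The description length used is
a complete two-part code:

$$\mathrm{MDL}(m) = \frac{\sum r^2}{2\sigma^2\ln 2}
  + \frac{m + n_{cp}}{2}\log_2 n + S \log_2 m,$$

with $n_{cp}$ change points and $S$ segments. The last term — the cost of
encoding which state each segment belongs to — matters: without it an
extra state costs only $\tfrac12\log_2 n$ bits while explaining the
sampling scatter of hundreds of pooled segment means, so the criterion
keeps splitting states indefinitely once many traces are pooled. With the
assignment term the selection behaves correctly from single traces up to
hundreds. Degenerate noiseless input ($\sigma = 0$) falls back to
unique-level counting.

**Populations.** `fit_fret_histogram()` pools valid frames (equal weight
per frame by default; per-molecule weighting is an option, since
published population histograms rarely state which convention they use)
into 50 bins over [0,1] and fits a sum of Gaussians by least squares.
Component means are fixed at the state values by default — the motivating
analysis uses condition-independent state values — widths are free above a
shot-noise floor (0.01), and populations are component areas normalised to
100%. Per-bin standard errors come from a bootstrap over molecules.

**Distances.** `forster_radius()` evaluates
$J = \int F_D\,\varepsilon_A\,\lambda^4 d\lambda / \int F_D\,d\lambda$ by
trapezoidal quadrature and $R_0 = 0.211\,(\kappa^2\eta^{-4}Q_D J)^{1/6}$
(Å, with $\lambda$ in nm and $\varepsilon_A$ in M$^{-1}$cm$^{-1}$);
defaults $\kappa^2 = 2/3$, $\eta = 1.4$. `fret_to_distance()` inverts the
Förster relation, $r = R_0(1/E-1)^{1/6}$, and `fret_displacement()`
reports $\Delta r$ against the highest-FRET state, which is assigned to
the inactive (most compact) conformation; distances are meaningful to
about 0.1 Å at these efficiencies.

## Quasi-elastic neutron scattering

**Model.** At each temperature and momentum transfer the quasi-elastic
signal is two unit-area Lorentzians plus a linear background, convolved
with the instrument resolution:
$S(Q,E) = R \otimes [A_1 L(\Gamma_1) + A_2 L(\Gamma_2)] + a + bE$. The
narrow component is global (translational) diffusion,
$\Gamma_1 = D Q^2$; the broad one is internal dynamics,
$\Gamma_2 = (1/\tau_0) Q^\alpha$ with the rate anchored at
$Q = 1\,$Å$^{-1}$ (the power law is dimensionally anchored only there).
Both follow Arrhenius laws $X(T) = X_0 e^{-E_a/RT}$. Rates convert to
times via $\tau[\mathrm{ps}] = 658.2/\Gamma[\mu eV]$
($\hbar = 658.2\,\mu$eV·ps).

**Defaults.** Temperatures 280–310 K, Q = 0.7–1.5 Å$^{-1}$, energy grid
±100 µeV at 0.4 µeV steps, Gaussian resolution of FWHM 3.4 µeV (only the
FWHM is specified by the backscattering instrument class, so a Gaussian is
assumed). The diffusivity prefactor is set so that
$D(300\,K) \approx 2$ Å$^2\mu$eV ($\approx 3\times10^{-7}$ cm$^2$/s, a
realistic protein translational diffusivity), with $E_a = 21.1$ kJ/mol;
the internal rate is anchored to $\tau(310\,K) \approx 55$ ps
($\Gamma \approx 12\,\mu$eV at $Q=1$) with $E_a = 8.2$ kJ/mol and
$\alpha = 1.4$, a sub-quadratic exponent typical of spatially confined
internal motion. Noise is 3% multiplicative.

**Numerics.** Convolution is performed numerically on the energy grid via
FFT, with the components evaluated on a grid padded by 25% per side so
edge effects stay out of the window; the grid must carry at least 5 points
per resolution FWHM (coarser grids are rejected). The fit is weighted
least squares (`minpack.lm::nls.lm`) with widths and areas
log-parameterised for positivity; components are reported ordered
($\Gamma_{narrow} < \Gamma_{broad}$), a width ratio below 1.5 raises a
collapse warning, and an optional resolution-shaped elastic line is off by
default (the standard model has none). The $Q^2$ fit runs through the
origin, as the law has no intercept (a free-intercept variant exists for
diagnostics); the power law is fitted log–log, with $\alpha$ fitted per
temperature. Buffer spectra, when supplied, are subtracted channel-wise
before fitting.

## Small-angle scattering

**Debye curves and bead models.** Theoretical curves come from the Debye
formula $I(q) = \sum_{ij} f_i f_j \sin(qr_{ij})/(qr_{ij})$, with the
analytic limit at $q \to 0$ and $I(0) = (\sum f)^2$. For models with more
than ~2·10⁵ bead pairs the pair distances are histogrammed (bin width
$0.02/q_{max}$, discretisation error <10⁻⁴). Oligomer fixtures mirror the
qualitative geometry of loosely associated, detergent-mediated oligomers:
monomer = filled sphere of radius 30 Å; dimer and square-planar tetramer
with 30 Å surface-to-surface gaps between subunits; compact trimer of
touching spheres. Decoy generators produce random ellipsoids and blob
composites for selection searches.

**Guinier.** Iterative fit of $\ln I = \ln I_0 - (R_g^2/3)q^2$ with the
window re-selected until $q_{max}R_g \le 1.3$ and $R_g$ stable within 1%;
systematic positive residuals at the lowest q raise an aggregation flag.

**P(r).** The pair-distance distribution is computed on an $n_r$-point
grid with $P(0) = P(D_{max}) = 0$ by smoothness-regularised weighted least
squares, $\min \|(I-KP)/\sigma\|^2 + \lambda\|P''\|^2$ with
$K_{jk} = 4\pi\Delta r\,\mathrm{sinc}(q_j r_k)$. Three numerical choices
matter. The system is solved by QR on the augmented matrix — normal
equations lose all precision at the weighting dynamic range of smooth
synthetic curves. Uncertainties are floored at 10⁻⁵ of the peak intensity,
because constant-relative-error curves assign absurdly tight errors to
deep form-factor minima, which would otherwise dominate the fit and bias
the recovered $R_g$ upward by several percent. The weight $\lambda$ is
dimensionless (scaled by the operator norms) and chosen automatically as
the smoothest solution whose misfit stays within 25% of the best
attainable over a wide grid — an L-curve-style trade-off with a selection
rule that is transparent and monotone, in place of curvature-corner
detection, which proved fragile on noiseless curves. $R_g$ and $I(0)$
derive from the moments of P(r).

**Ensemble decomposition.** `nnls_weights()` solves the non-negative
least-squares decomposition of a target curve over basis curves in the
error-weighted metric; reduced $\chi^2$ uses $n_q - n_{members}$ degrees
of freedom (a convention this package fixes, since "reduced chi-square" is
often quoted without its dof). `ga_select()` searches member *identity*
with a genetic algorithm while weights always come from exact NNLS per
candidate subset — the deterministic, reproducible division of labour.
GA settings: sizes 1..5, 100 generations, 5 randomised restarts per size,
population 64, tournament selection (size 2), uniform crossover on member
slots, per-slot mutation probability 0.1, duplicate-free chromosomes,
elitism. A restart ends early once the best fitness has stalled for 25
generations (elitism guarantees the incumbent is kept, and subset
fitnesses are memoised, so this only skips exhausted search). The reported
solution is the smallest ensemble size that ties the overall optimum, with
species-class fractions aggregated from member labels.
`ensemble_exhaustive()` provides the brute-force reference used to verify
the stochastic search on small pools.

## Thermal shift

Melt curves follow the Boltzmann sigmoid
$F(T) = f_{min} + (f_{max}-f_{min})/(1+e^{(T_m-T)/s})$ on a 20–90 °C ramp
(0.5 °C steps, 1% noise by default). `fit_boltzmann()` initialises the
plateaus from the first/last temperature deciles and $T_m$ from the
half-height crossing; descending curves (quenching dyes) are auto-detected
and fitted with plateaus swapped; a curve whose decile span is below three
times the residual scatter raises a no-transition error rather than
returning a meaningless midpoint. An optional upper-temperature cutoff
excludes post-plateau quench. `delta_tm()` reports condition shifts with
quadrature-propagated uncertainty; replicates are fitted individually and
averaged rather than averaged then fitted.

## Pipeline and reproducibility

`confokit_run()` executes simulate→analyze stages from one configuration
with a single seed that fans out to fixed per-stage substreams, so a rerun
of any stage in isolation reproduces its in-pipeline result and identical
config+seed give identical reports. `acceptance_check()` compares report
numbers against target tables with eq/le/ge/le_abs/mag_eq comparison
modes; missing values are marked unevaluable, not failed. Every generator
is bit-reproducible under a fixed seed.

## Problem sizes

The validation suite runs at the sizes the study design calls for: 200
traces × 500 frames for state identification; 154- and 94-molecule
cohorts for the condition histograms; 4 temperatures × 5 Q values of
501-point spectra for the QENS chain; a 24-member candidate pool (4 true
species + 20 decoys) for ensemble selection, with GA-vs-enumeration
agreement measured on a 12-member pool over 100 seeded runs; 100 melt
replicates per condition.

## What passing tests do and do not show

The generators reproduce the statistical structure the estimators assume:
Markovian state dynamics, Gaussian channel noise, single-step bleaching,
exact two-Lorentzian spectra, ideal Debye mixtures, exact sigmoids. Real
data violate all of these in ways the generators deliberately omit: dye
blinking and spectral crosstalk, donor-only molecules, gamma-correction,
non-Gaussian photon statistics at low counts, instrument-dependent
resolution shapes and detector effects, inter-particle structure factors
and contrast-layer scattering, and post-peak fluorescence quench.
Parameter recovery here therefore demonstrates the correctness and
calibration of the estimators under their stated models — not robustness
to every artefact of a real instrument. Rate constants (dwell-time
kinetics) are intentionally out of scope: the smFRET stage reports state
populations, not transition rates.
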