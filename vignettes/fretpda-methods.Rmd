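---
title: "Models and methods behind fretpda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretpda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fretpda)
```

# The scientific problem

A transmembrane helical hairpin — two membrane-spanning helices joined by a
short loop, the minimal unit of membrane-protein tertiary folding — can
exist in a compact (closed) conformation stabilized by helix–helix packing
and an open conformation in which the helices lose contact. With a donor
dye on one terminus and an acceptor on the other, the two conformations
produce distinct FRET efficiencies, and single-molecule measurements on
freely diffusing proteoliposomes resolve both subpopulations in one
histogram. fretpda implements the full quantitative chain for such
measurements: photon-level simulation, burst selection and filtering,
shot-noise-limited histogram analysis (PDA), two-state thermodynamics,
dose–response analysis of pharmacological rescue, and sequence-based
insertion energetics for the helices themselves.

# The photon-stream simulator

`simulate_photon_stream()` emulates the confocal experiment at the level
of detected photons, not optics. Its generative model:

* Molecule transits ("bursts") arrive as a Poisson process
  (`burst_rate`, default 20 s⁻¹ — the low occupancy of a <100 pM,
  single-molecule-per-vesicle regime); transit durations are exponential
  (`transit_time_mean`, default 1 ms); the photon count of a transit is
  Poisson(brightness × duration) with a default brightness of
  100 photons/ms. This is the simplest model producing the burst-size
  spread that PDA must marginalize over.
* Each dual-labeled burst draws a conformational state from the species'
  occupancies and an inter-dye distance `R ~ N(center, width)`; the
  transfer efficiency follows the Förster equation with `R0 = 5.5` nm by
  default. That default is the value consistent with a high-FRET
  population at `E ≈ 0.8` for a 4.4 nm closed state, which is the regime
  this package is calibrated around.
* Donor-excitation photons split binomially between acceptor and donor
  channels with probability
  `ε = (γE + α(1−E)) / (γE + (1+α)(1−E))`, the inversion of the standard
  ALEX correction, so that simulator and analysis share one detection
  model exactly. Direct acceptor excitation (δ) adds Dex→acceptor photons
  as Poisson(δ·N_AA), matching the `− δN_AA` correction in expectation.
  Defaults γ = 1, α = δ = 0: detection-calibration constants are
  instrument-specific and all corrections are configurable.
* Stationary Poisson background per photon class (defaults
  DD 1000 Hz, DA 600 Hz, AA 600 Hz — typical scattering/dark-count levels
  for a clean confocal setup).
* Donor-channel nanotimes are exponential with mean `τ_D(0)·(1−E)`
  (default `τ_D(0)` = 4 ns), carried for lifetime-vs-E diagnostics only;
  excitation-period labels are explicit per photon rather than inferred
  from nanotime gating, which keeps photon sorting independent of TCSPC
  detail.
* PIE alternation is reduced to a per-photon Dex/Aex label with
  `dex_fraction = 0.5`.

What the simulator deliberately does **not** emulate: the 3-D Gaussian
observation volume and diffusion re-entry, triplet blinking and other
photophysics, and intra-burst interconversion (dynamic FRET). An optional
`bleach_fraction` produces mid-burst acceptor bleaching solely to exercise
the asymmetry filter. Passing tests therefore demonstrate correctness of
the analysis chain under static two-state, shot-noise-limited conditions —
not robustness to photophysical artifacts in real data, which is exactly
the regime the burst filters are designed to restore by rejection.

Identical seed and settings give a bit-identical stream; the per-burst
ground truth (species, state, distance, efficiency) travels with the
stream for validation.

# Burst selection and filtering

`find_bursts()` uses the all-photon sliding-window criterion: a photon is
in a burst if it lies in a window of `m = 10` consecutive photons spanning
at most `T = 500` µs; maximal runs with at least 50 photons become bursts.
These field-standard defaults are configurable (`burst_search_params()`)
and recorded in output metadata.

`burst_metrics()` computes, per burst, raw and background-corrected counts
of the three ALEX classes, the proximity ratio `N_DA/(N_DA+N_DD)`, the
corrected efficiency and stoichiometry, and three heterogeneity scores:

* **ALEX-2CDE**: exponential-kernel density estimates (`τ = 100` µs) of
  the donor- and acceptor-excitation photon streams evaluated at each
  other's photon times, combined into brightness ratios such that a
  homogeneously interleaved burst scores near 0 and a burst whose Dex and
  Aex photons segregate in time (coincident molecules, bleaching) scores
  up to ~100. Retention threshold 10. With fewer than two photons in
  either excitation class the score is 0 by convention — such bursts are
  handled by the stoichiometry window instead, and no NaN propagates.
* **FRET-2CDE**: the analogous score over the two Dex channels, near its
  ideal value 10 for static bursts.
* **Asymmetry**: `(mean t(N_DA) − mean t(N_DD)) / duration` ∈ [−1, 1];
  mid-burst acceptor bleaching gives values below −0.25 and the burst is
  rejected; time reversal flips the sign exactly.

Background rates default to estimation from inter-burst photons of the
whole measurement (stationary-background assumption). `sort_species()`
retains bursts with S in [0.3, 0.7] and all filters clear — removing
donor-only (S ≈ 1) and acceptor-only (S ≈ 0) species — and is idempotent.
All thresholds live in the call signature and are echoed in the output
attributes.

# Probability distribution analysis

For a state with distance distribution `N(R_s, σ_s)` the expected
apparent-efficiency mass is computed by marginalizing twice:

1. **Distance**: Gauss–Hermite quadrature (32 nodes by default) maps the
   Gaussian onto apparent acceptor probabilities ε(R) through the Förster
   equation and the shared detection model. Quadrature was chosen over
   Monte-Carlo integration because it is deterministic and directly
   testable against a brute-force Monte-Carlo oracle — the suite's core
   correctness check, which agrees within multinomial error at 10⁶
   samples across a grid of distances, widths and burst sizes.
2. **Shot noise**: for every observed burst size N the acceptor count is
   exactly Binomial(N, ε); optional per-channel Poisson background counts
   are convolved in. Burst sizes above 250 are capped (equivalent to
   random photon subsampling), bounding the compute of very large bursts.

Masses are binned (40 bins on [0, 1] by default), mixed by state
fractions, and normalized so that the model histogram always sums to the
observed burst count.

`pda_fit()` minimizes the Pearson chi-square over free parameters: state
fractions on the simplex through a softmax parameterization, distance
centers (log-scale, bounded to 0.5–20 nm), and a single shared distance
width by default — per-state widths are not separately identifiable from
typical histograms, and sharing one width is the conservative choice.
Bins with expected counts below 3 are excluded from the statistic, and
degrees of freedom are reduced accordingly. For speed the objective
evaluates a precomputed binomial kernel on an ε-grid (step 0.0025) with
linear interpolation; the reported model "cityscape" is recomputed on the
exact path.

Uncertainties are the standard deviations of the estimates over ten
randomized restarts (Nelder–Mead with one simplex restart each, initial
values jittered around the supplied model). This restart interpretation is
recorded in the fit metadata. Restarts that converge into a clearly
different local minimum (chi-square above the best by more than
max(5%, 2)) are excluded from the error estimate, since they measure basin
hopping rather than the uncertainty of the reported optimum; fits where
more than half the restarts fail are flagged unreliable.

# Two-state thermodynamics

`delta_g()` converts a folded (closed-state) fraction into the standard
free energy of hairpin opening, `ΔG° = −RT ln(f_F/(1−f_F))`, with
`R = 8.314` J/(mol·K) and `T = 297.15` K (a 24 °C measurement temperature)
throughout. The sign convention makes a folded-majority population
favorable (negative); the function is exactly antisymmetric about
`f_F = 0.5` and returns signed-infinity sentinels with a warning at the
boundaries.

# Dose–response analysis

Corrector titrations follow the four-parameter logistic model

\[ f_F(c) = f_{F,max} + \frac{f_{F,min} - f_{F,max}}{1 + (c/\mathrm{EC_{50}})^n} \]

fitted by bounded Levenberg–Marquardt nonlinear least squares (unweighted
by default, optional 1/σ² weights), with heuristic starting values and
bounds `f ∈ [0,1]`, `EC50 ∈ (0, 10·max c]`, `n ∈ (0, 10]`. A coverage
warning fires when the fitted curve fails to reach 80% of its span inside
the measured range.

`delta_g_at_saturation()` reports the free energy of the rescued state
under **both** available conventions — the fitted curve at the highest
measured concentration, and the plateau parameter `f_F,max` — because the
two differ substantially whenever the titration stops short of the
plateau, and which one "saturation" means is a reporting choice that
should stay visible. The mode used is attached to the result.

`dose_recovery_experiment()` packages the parameter-recovery experiment:
simulate a titration from known parameters (8 log-spaced concentrations
from 1 to 2000 µM, 3 replicates, Gaussian noise σ = 0.03 — the design and
noise level of a realistic corrector titration), refit, and repeat over
100 derived seeds, reporting replicate medians. The median-of-replicates
design exists because this concentration range reaches only ~83% of the
response span, which leaves the single-experiment EC50 estimator strongly
right-skewed (fits that push `f_F,max` toward 1 drag EC50 up several-fold);
the replicate median is an unbiased, low-variance summary of what the
refit recovers, while single-round estimates are still returned for
inspection.

# Sequence energetics

Wimley–White whole-residue scales (kcal/mol; water→interface and
water→octanol, with explicit charged/neutral variants for Asp, Glu and
His) are bundled as data. `transfer_free_energy()` is the plain per-residue
sum converted with 4.184 kJ/kcal — no end-group corrections, which is the
convention under which the bundled scales reproduce published segment
totals. The interface-to-octanol difference predicts transmembrane
insertion propensity, and `hydrophobic_moment()` places the per-residue
interface-to-octanol values on an ideal helical wheel (100° per residue)
and reports the vector-sum magnitude. Titratable residues default to
charged Asp/Glu and neutral His (neutral pH); for the V232D TM4 segment
the charged-Asp setting is the physically and numerically consistent
choice. Results are conventionally reported to one decimal (kJ/mol) and
two decimals (moment).

The Liu–Deber segmental hydrophobicity scale is bundled in its commonly
distributed rendering (normalized to Gly = 0). Only the ordering of
residues — e.g. that an Asp substitution lowers a segment's mean
hydrophobicity — is relied upon anywhere in this package; the
transmembrane-propensity threshold (default 0.4) is configurable rather
than asserted.

# Numerical and design choices

* Timestamps are integer clock ticks (default 10⁸ ticks/s) stored as
  doubles; burst intervals are inclusive photon-index ranges; channel and
  excitation labels are categorical.
* Degenerate inputs never raise division errors: undefined efficiencies
  or stoichiometries flag the burst for exclusion, empty 2CDE classes use
  the conventional scores, missing asymmetry classes reject the burst.
* Histograms clamp efficiencies into the outer bins so counts are always
  conserved; efficiencies are left-closed binned with a right-closed last
  bin.
* Serialization is plain text: CSV tables with JSON sidecars carrying
  settings, filters, seeds and format versions; `run_pipeline()` writes an
  MD5-hashed manifest and reproduces bit-identically under a fixed master
  seed.

# Problem sizes

The shipped tests and the acceptance script run the analysis at moderate
scale chosen to make stochastic checks statistically decisive while
remaining quick: simulated measurements of 120–150 s at 20–25 transits/s
(2000–3800 bursts), 10⁶-sample Monte-Carlo oracles for the PDA
equivalence grid, and 100-round dose-recovery replication. All scale
parameters are ordinary function arguments.

# Known limitations

* Static PDA only: intra-burst interconversion (dynamic PDA) is out of
  scope, as are lifetime-based FRET distributions and Bayesian posterior
  sampling.
* The detection model treats leakage and direct excitation to first
  order; γ, α, δ defaults are stand-ins to be calibrated per instrument.
* Background handling assumes stationarity; drifting background would
  bias corrected efficiencies.
* The simulator's burst model (uniform photon times within a transit)
  ignores the intensity envelope of a diffusion path through the focus;
  burst-size distributions are Poisson-exponential rather than the
  heavier-tailed experimental ones. PDA is insensitive to this choice
  because it conditions on the observed burst sizes.
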