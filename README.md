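# fretpda

Quantifying the conformational equilibrium of transmembrane helical
hairpins from diffusion-based single-molecule FRET, with sequence-based
membrane-insertion energetics on the side. The package was built around the
folding problem of the CFTR TM3/4 hairpin — a two-helix unit whose compact
(closed) and open conformations report on helix–helix packing in a lipid
bilayer, whose equilibrium is shifted by the cystic-fibrosis point mutation
V232D, and whose misfolding is rescued by the corrector drug Lumacaftor —
but every stage is generic for two-state, dual-labeled molecules measured
under pulsed-interleaved excitation (PIE/ALEX).

## What it does

- **Synthetic photon streams** (`simulate_photon_stream`): a seeded
  emulator of freely diffusing, dual-labeled molecules in vesicles —
  Poisson burst arrivals, exponential transits, Gaussian inter-dye distance
  distributions per conformational state, binomial donor/acceptor photon
  partitioning from the Förster equation
  `E = 1/(1 + (R/R0)^6)`, Poisson background per photon class, donor-only /
  acceptor-only contaminants and exponential donor nanotimes. Every
  downstream stage can therefore be tested against ground truth.
- **Burst processing** (`find_bursts`, `burst_metrics`, `sort_species`,
  `build_fret_histogram`): all-photon sliding-window burst search,
  background-corrected FRET efficiency
  `E = (N_DA − αN_DD − δN_AA)/(γN_DD + N_DA − αN_DD − δN_AA)` and
  stoichiometry `S`, ALEX-2CDE / FRET-2CDE kernel-density scores,
  burst-asymmetry statistic for mid-burst acceptor bleaching, and
  stoichiometry-window species sorting.
- **Probability distribution analysis** (`pda_expected_histogram`,
  `pda_fit`, `fraction_folded`): shot-noise-limited fitting of FRET
  efficiency histograms. The expected histogram marginalizes each state's
  Gaussian distance distribution (Gauss–Hermite quadrature) and the exact
  binomial photon statistics at every observed burst size; Pearson
  chi-square minimization recovers state fractions and inter-dye distance
  centers, with errors from ten randomized restarts.
- **Thermodynamics and dose–response** (`delta_g`, `fit_dose_response`,
  `delta_g_at_saturation`): two-state free energy of opening
  `ΔG° = −RT ln(f_F/(1−f_F))` at 297.15 K, and the four-parameter logistic
  model `f(c) = f_max + (f_min − f_max)/(1 + (c/EC50)^n)` for corrector
  titrations, fitted by bounded Levenberg–Marquardt least squares.
- **Hydropathy** (`transfer_free_energy`, `interface_to_octanol`,
  `hydrophobic_moment`, `segmental_hydrophobicity`): Wimley–White
  whole-residue water→interface / water→octanol transfer free energies,
  the helical-wheel hydrophobic moment at 100°/residue, and Liu–Deber mean
  segmental hydrophobicity.
- **Pipeline** (`run_pipeline`): seeded multi-condition runs with CSV/JSON
  artifacts and an MD5-hashed manifest; identical configurations reproduce
  every stochastic stage bit-identically.

## Worked example

Membrane-insertion energetics of the wild-type and V232D TM4 segments
(charged aspartate):

```r
library(fretpda)
rbind(segment_energetics("SAFAGLGFLIVLALFQAGL"),   # wild-type TM4
      segment_energetics("SAFAGLGFLIDLALFQAGL"))   # V232D TM4
#>   dG_WI_kJ_per_mol dG_IO_kJ_per_mol hydrophobic_moment_kcal_per_mol
#> 1            -21.0            -5.31                            0.40
#> 2            -16.1             6.99                            3.34
```

The wild-type segment favors the transmembrane state
(ΔG_I→O = −5.3 kJ/mol); the charged aspartate of V232D inverts that
preference (+7.0 kJ/mol) while the membrane interface remains favorable
over water (ΔG_W→I = −16.1 kJ/mol), and the mutation turns a uniformly
hydrophobic helix into an amphiphilic one (μH 0.40 → 3.34).

A full simulate → burst-process → PDA round trip:

```r
sp  <- species_spec("hairpin", "dual",
                    state_fractions = c(0.7, 0.3),      # closed, open
                    distance_center = c(4.4, 6.3),      # nm
                    distance_width  = c(0.3, 0.3))
acq <- acquisition_settings(duration = 150, burst_rate = 25, seed = 11)
stream  <- simulate_photon_stream(sp, acq)
bursts  <- find_bursts(stream)
metrics <- burst_metrics(stream, bursts)
fret    <- sort_species(metrics)        # 2321 bursts; 2269 FRET-active
h   <- build_fret_histogram(fret)
fit <- pda_fit(h, pda_state_model(c(0.5, 0.5), c(4.0, 6.8), 0.4), seed = 11)
fit
#> PDA chi-square fit
#>   fraction se R_nm R_se
#> 1    0.699  0 4.45    0
#> 2    0.301  0 6.30    0
#> shared width: 0.30 nm (se 0.00)
#> reduced chi-square: 1.08 (30 dof, 9/10 restarts converged)
delta_g(fraction_folded(fit)["f_F"])
#> -2.08  # kJ/mol, favorable closed state
```

The fit recovers the programmed closed-state occupancy (0.70) and both
inter-dye distances (4.4 / 6.3 nm) from shot-noise-limited histograms, and
converts the folded fraction into the two-state free energy of opening.

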