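# ventbars

Simulation of β-adrenergic stimulation (BARS) in human ventricular
myocytes and 2-D tissue, for studying sympathetically modulated reentry.

Sympathetic activation phosphorylates a handful of sarcolemmal and
sarcoplasmic targets through the β-receptor → cAMP → PKA cascade,
shortening the action potential, enlarging the Ca²⁺ transient and
speeding conduction. `ventbars` models this endpoint as a dual-population
extension of the Ten Tusscher–Panfilov 2006 (TT2) epicardial myocyte
model: each of nine PKA targets (I<sub>Na</sub>, I<sub>CaL</sub>,
I<sub>Ks</sub>, I<sub>pK</sub>, I<sub>NaK</sub>, RyR release, SERCA
uptake, subspace-to-cytosol Ca²⁺ transfer, cytosolic Ca²⁺ buffering)
carries a non-phosphorylated (NP, baseline TT2) and a phosphorylated (P)
population, mixed linearly by a phosphorylation fraction α:

$$I_{net} = \alpha\,I_P + (1-\alpha)\,I_{NP}, \qquad
  \alpha(\mathrm{ISO}) = \alpha_{max}\frac{\mathrm{ISO}^{n}}{EC_{50}^{n}+\mathrm{ISO}^{n}}$$

with the isoproterenol concentration (ISO, µM) as the single stimulation
input. On top of the cell model the package provides:

* virtual experiments — steady-state pacing, voltage-clamp I-V curves,
  dynamic APD restitution (`pace_to_steady_state()`,
  `voltage_clamp_iv()`, `apd_restitution()`);
* an explicit monodomain reaction–diffusion solver for 1-D cables and
  2-D sheets with conductivity calibration and S1–S2 CV restitution
  (`monodomain_simulate()`, `calibrate_conductivities()`,
  `cv_restitution_cable()`);
* seeded substrate generators for random adrenergic-stimulation maps
  (5–50 % density) and three-region gradients (`assign_bars_density()`,
  `assign_bars_gradient()`);
* cross-field S1–S2 rotor induction with an automatic vulnerable-window
  search (`induce_rotor_s1s2()`);
* a Hilbert-phase rotor analysis pipeline: band-pass filtering,
  instantaneous phase, winding-number phase-singularity detection with
  local-regression confirmation, trajectory tracking, angular speed,
  localization area and wavelet counting (`phase_frames()`,
  `detect_phase_singularities()`, `track_singularities()`,
  `angular_speed()`, `localization_area()`, `count_wavelets()`).

The methods vignette (`vignettes/ventbars-methods.Rmd`) documents the
model equations, the calibration of the dose–response curves, the
numerical schemes and the known limitations.

## Worked example

Steady-state pacing at 1 Hz without and with saturating agonist:

```r
library(ventbars)

p0 <- pace_to_steady_state(iso = 0, pcl = 1000, n_beats = 1000)
p1 <- pace_to_steady_state(iso = 1, pcl = 1000, n_beats = 1000)
p0
#> <paced_cell> ISO = 0 uM, PCL = 1000 ms, 476 beats run (converged early)
#>   APD90 300.7 ms | peak Vm 42.8 mV | CaT amplitude 0.0007902 mM
p1
#> <paced_cell> ISO = 1 uM, PCL = 1000 ms, 728 beats run (converged early)
#>   APD90 257.0 ms | peak Vm 41.5 mV | CaT amplitude 0.003782 mM
```

The action potential shortens by about 15 % under saturating ISO while
the Ca²⁺ transient grows severalfold; the per-beat table in `p1$beats`
also tracks the peak I<sub>Na</sub>, I<sub>CaL</sub> and I<sub>Ks</sub>
densities of every beat, and `plot(p1$trace)` draws the final beat.

A small tissue experiment — induce and analyse a rotor on a 3×3 cm
sheet with uniform stimulation at 0.1 µM ISO:

```r
g   <- build_sheet(75, 75)                       # 3 x 3 cm at 400 um
rec <- induce_rotor_s1s2(g, iso = 0.1, duration_post_s2 = 2000)
pf  <- phase_frames(rec)                          # Hilbert phase maps
tr  <- track_singularities(pf)
angular_speed(tr[[1]], rec, window = 1500)        # ~4.7 Hz
localization_area(tr[[1]], window = 1500)         # ~11 mm^2
```

The plain (ISO = 0) counterpart of the same experiment rotates at about
4 Hz, so uniform adrenergic stimulation speeds the rotor, as expected
from its shorter APD and faster conduction. Full-scale 6×6 cm, 5 s
rotor studies — including the gradient substrates that splinter a rotor
into wavelets — are scripted in `scripts/full_scale_rotor.R`.

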