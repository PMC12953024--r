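---
title: "Modelling beta-adrenergic stimulation in human ventricular myocytes and tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling beta-adrenergic stimulation in human ventricular myocytes and tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ventbars` extends the Ten Tusscher–Panfilov 2006 (TT2) epicardial human
ventricular myocyte model with the steady-state electrophysiological
endpoint of the β-adrenergic receptor signalling (BARS) cascade
(catecholamine → G-protein → adenylyl cyclase → cAMP → PKA). Nine PKA
targets are represented: the fast Na⁺ current (I~Na~), the L-type Ca²⁺
current (I~CaL~), the slow delayed rectifier (I~Ks~), the plateau K⁺
current (I~pK~), the Na⁺/K⁺ pump (I~NaK~), RyR-mediated SR release
(I~rel~), SERCA uptake (I~up~), the diffusive subspace-to-cytosol Ca²⁺
transfer (I~xfer~), and cytosolic Ca²⁺ buffering (through its
half-saturation constant K~bufc~).

Each target exists as two channel populations: a non-phosphorylated (NP)
population with the baseline TT2 formulation, and a phosphorylated (P)
population with scaled conductances, shifted gating curves and scaled
time constants. The net contribution of a target is the linear mixture

$$I_{net} = \alpha I_P + (1-\alpha)\,I_{NP},$$

where the phosphorylation fraction $\alpha \in [0,1]$ is the model's only
link to the agonist: a Hill-type dose–response curve per target maps the
isoproterenol concentration (ISO, µM) to $\alpha$. The SR leak flux is
never modified, as its phosphorylation is not PKA-mediated.

Separate gating state is carried only where the P population's kinetics
differ: `h_P` (I~Na~ fast inactivation), `d_P, f_P, f2_P` (I~CaL~),
`xs_P` (I~Ks~ activation) and `Rbar_P` (RyR adaptation). The
Ca²⁺-dependent `fCaSS` gate is shared, since its kinetics are not voltage
shifted. Purely algebraic modifications (I~NaK~, I~pK~, I~up~, I~xfer~,
K~bufc~) are mixed without extra state; the buffering constant mixes as
$(1-\alpha)K_{bufc} + \alpha\,1.7\,K_{bufc}$.

### Phosphorylated-population parameters

| Target | Modification |
|---|---|
| I~Na~ | conductance ×1.7; fast inactivation gate *h* shifted −5 mV |
| I~CaL~ | conductance ×3; *d, f, f2* shifted −10 mV; activation 1.25× faster near threshold (V < 0); inactivation 1.6× slower at strongly positive V (> +20 mV) |
| I~Ks~ | conductance ×2.5; activation gate *xs* shifted −5 mV; activation rate ×2 (calibrated) |
| I~pK~ | current ×2; activation shifted +10 mV |
| I~NaK~ | intracellular Na⁺ half-saturation ×0.7 |
| I~rel~ | conductance ×1.6; opening rate k₁ ×1.4; closing rate k₂ ×1.8 |
| I~up~ | half-saturation ×0.85; maximal rate ×2 (calibrated, see below) |
| I~xfer~ | rate ×2.1 |
| K~bufc~ | ×1.7 (reduced buffer affinity) |

Three editorial conflicts in the source material were resolved as
follows, with the alternatives switchable through `bars_modifiers()`:

* the I~CaL~ gate shifts use −10 mV (the Methods text) rather than −5 mV
  (the summary table);
* the I~Ks~ −5 mV shift is applied to the activation gate `xs` — TT2's
  I~Ks~ has no inactivation gate, so the table's "inactivation" cannot be
  meant literally;
* "faster opening (140%) and closing (180%) rates" of the RyR are read as
  the channel opening rate k₁ (which enters the open probability) and the
  adaptation closing rate k₂ (which drives the `Rbar_P` state); this is
  the only reading in which both named rates exist in the TT2 RyR model.

Only the *h* gate of I~Na~ is shifted, not the slow inactivation gate *j*:
shifting both collapses channel availability at the diastolic potential
far below what the reported peak-current increase permits. The τ
adjustments of the I~CaL~ gates blend smoothly (5 mV sigmoids) between
the unmodified and modified regimes so the rate functions stay
continuous.

The SERCA modification carries a maximal-rate factor (`vmaxUp_scale`,
default 2) in addition to the half-saturation change. Baseline TT2 uptake
runs at ≈94 % of V~max~ at systolic Ca²⁺, so a half-saturation change
alone cannot raise the uptake flux appreciably; the reported ~1.9-fold
uptake increase under phosphorylated phospholamban requires a V~max~
component. The factor was calibrated once against that fold change.

### Dose–response calibration

The dose–response curves are
$\alpha(ISO) = \alpha_{max}\,ISO^{n}/(EC_{50}^{n}+ISO^{n})$ with $n = 2$,
$EC_{50} = 0.012$ µM (I~Ks~: 0.018 µM) and per-target plateaus

```
INa 1.00  ICaL 0.645  IKs 0.85  IpK 1.00  INaK 1.00
Irel 0.885  Iup 0.50  Ixfer 0.15  Kbufc 0.20
```

The curves are only constrained qualitatively by the source material, so
they were calibrated once — jointly with the I~Ks~ activation-rate factor
— against the model's published validation bundle (steady-state APD90 of
310 ms at ISO = 0 and 260 ms at 1 µM, peak paced I~Na~ of −358.2 pA/pF,
and the 3.6-fold I~CaL~ I-V increase at −10 mV), and then frozen. The
displaced I~Ks~ EC₅₀ is what makes APD(ISO) monotone: with a common
EC₅₀ the early I~Ks~ response undershoots the APD at 0.01 µM, while a
strongly delayed I~Ks~ curve lets the early Ca²⁺ response overshoot it.

### A structural trade-off near the Ca²⁺-overload cliff

Tripling G~CaL~ pushes TT2 towards a regenerative Ca²⁺-overload regime:
the cytosolic buffer (B~ufc~ = 0.2 mM) saturates, free Ca²⁺ amplitude
grows out of proportion to the underlying flux, Na⁺ accumulates through
the exchanger and the plateau prolongs. Within the dual-population
construction there is no parameterization that simultaneously reproduces
the published APD shortening (×0.83), CaT amplitude growth (×2.25), paced
I~CaL~ peak (−18.6 pA/pF) and paced I~Ks~ peak (2.2 pA/pF): operating
points with the correct APDs carry a CaT fold of ≈4.8, a paced I~CaL~ of
≈−13 pA/pF and a paced I~Ks~ of ≈4 pA/pF. The default calibration favours
the APDs, the I~Na~ peak and the clamp I-V ratio, which constrain the
construction most directly; the residual disagreements are measured, not
hidden, in the package's acceptance tests and are reported as-is by
`scripts/acceptance.R`. Per-beat sarcolemmal Ca²⁺ influx does roughly
double under saturating ISO (as expected from the I~CaL~ modification);
it is the *free* transient amplitude that overshoots, through buffer
saturation.

## Numerics

* **Cell integrator.** Rush–Larsen exponential updates for all
  Hodgkin–Huxley gates, exact exponential updates for the linear RyR
  adaptation variables, forward Euler for concentrations and V~m~;
  fixed step `dt = 0.02 ms`. Voltage-dependent quantities (gate targets,
  Rush–Larsen factors, driving-force and pump factors) are tabulated at
  0.02 mV resolution and linearly interpolated; halving the step or
  evaluating rates directly changes a steady-state APD90 by well under
  1 ms.
* **τ~f2~** follows the authors' released TT2 code (562·exp(−(V+27)²/240)
  + 31/(1+exp((25−V)/10)) + 80/(1+exp((V+30)/10))), which differs from
  the originally printed formula.
* **Steady-state pacing.** The reference protocol is 1000 beats with the
  criterion that APDs and CaT amplitudes of the last 100 beats vary by
  less than 1 %. A cheaper early exit (beat-to-beat change < 0.005 % for
  20 consecutive beats, which implies the reference criterion) is used by
  default. Slow Na⁺ drift continues beyond either criterion; the
  reference protocol is reproduced as printed rather than run to the
  (much later) true limit cycle.
* **Tissue.** Monodomain reaction–diffusion with operator (Lie)
  splitting: per-node ionic update followed by an explicit anisotropic
  5-point Laplacian with zero-flux boundaries, both at `dt = 0.02 ms`
  (the diffusion CFL number at 400 µm is ≈0.013, far inside stability).
  Fibres run along +x, so the tensor is diagonal. The printed
  conductivities are treated as the effective monodomain tensor
  (λ/(1+λ) folded in) with A~m~ = 1400 cm⁻¹ and C~m~ = 1 µF/cm²;
  `calibrate_conductivities()` absorbs residual discretization mismatch
  by bisecting a common multiplier of (σ~L~, σ~T~) until the cable CV is
  60 cm/s (the multiplier is reported).
* **Stimuli.** Single-cell stimuli are cell-equivalent current densities
  (60 µA/cm² ≡ 60 pA/pF at C~m~ = 1 µF/cm²). Volumetric tissue stimuli
  convert via I/(A~m~C~m~); note that the printed 250 µA/cm³ converts to
  ≈0.18 pA/pF, which is far subthreshold under this convention, so tissue
  protocols default to capture-checked amplitudes (cable S1 uses twice
  the bisected capture threshold, as in the cable protocol description).
* **S1–S2 rotor induction.** Plane-wave S1 from the left edge (600 ms
  BCL); S2 over the lower half-sheet timed by an automatic
  vulnerable-window search: candidate delays are swept in 10 ms steps
  around the repolarization time observed at a right-half probe, and the
  first delay that leaves the sheet active well after the S2 transient is
  kept. Per-node initial states come from the single-cell 600 ms BCL
  limit cycle at that node's ISO.

## Rotor analysis

Per-node V~m~ traces are band-passed (0.1–15 Hz; zero-phase Butterworth,
a second-order high-pass and fourth-order low-pass applied
forward–backward) and converted to instantaneous phase via the discrete
Hilbert transform; θ = −π/2 marks the wavefront by convention. Phase
singularities are candidate plaquettes whose closed-loop phase integral
is ±2π, confirmed by local plane regressions of sin θ and cos θ over a
10×10-node window (the fitted gradients must circulate with the winding
sign); detections within 5 nodes of the boundary are excluded and
positions are reported at plaquette-centre resolution, matching the
element-based localization-area definition. Tracking is greedy
nearest-neighbour linking with chirality matching (4 mm per frame, gaps
of up to 2 frames bridged). Angular speed counts full 2π revolutions of
the unwrapped Hilbert phase at a fixed probe 4 mm from the track's median
position; the localization area is the number of distinct elements
visited times the element area (0.16 mm² at 400 µm); the wavelet count is
the mean number of simultaneously alive tracks with lifetime ≥ 100 ms.
The brute-force plaquette winding number is the normative reference for
the detector and is exercised against it on randomized multi-spiral
fields in the test suite.

## What the synthetic experiments do and do not show

The substrate generator reproduces the study conditions: 6×6 cm (150×150
elements) and 9×6 cm (225×150) sheets at 400 µm, random uniform
adrenergic-stimulation maps from 5–50 % density, and three-region
gradients (20 % centre, ±Δ for Δ ∈ {5, 10, 15, 20} %), all seeded and
reproducible. These are phenomenological area-proportion maps on a
homogeneous, unidirectionally fibred monodomain sheet; they do not
represent real innervation geometry, fibre disarray, or dynamic
signalling (no cAMP/PKA kinetics, receptor isoforms or desensitization —
the ISO level is a steady-state input). Passing tissue tests therefore
demonstrate the electrophysiological consequences of *static, spatially
heterogeneous* phosphorylation, not the dynamics of sympathetic
activation.

The routinely exercised tissue checks run on a scaled-down substrate
(3×3 cm for 2 s of reentry) so the whole suite completes on a desk
machine; the full-scale 5 s study is reproduced by
`scripts/full_scale_rotor.R`. Scale matters for rotor *localization*: on
the small sheet both rotors are boundary-constrained and the faster,
shorter-wavelength rotor under uniform stimulation can drift more than
the plain one — the opposite of the anchoring contrast seen on the
full-size sheet — so the scaled property check on localization area is
reported with that caveat.

## Known limitations

* The Ca²⁺-side residuals described above: CaT amplitude fold, paced
  I~CaL~ and I~Ks~ peaks overshoot their reference values at the default
  calibration.
* CV restitution on the calibrated cable declines only below DI ≈ 100 ms
  (Na⁺-gate recovery in TT2); reference minimum-CV points quoted at DI
  250–375 ms sit at a capture boundary this construction does not
  reproduce, so the minimum captured CV over the 250–1000 ms S2 sweep is
  higher than the quoted value.
* Angular speed is probe-based and assumes a reasonably anchored rotor;
  for strongly meandering or short-lived singularities the probe window
  shrinks and the estimate inherits meander sensitivity.
* No bidomain formulation, 3-D anatomy, mechanics, or CaMKII pathway.
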