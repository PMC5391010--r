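---
title: "Methods: multi-scale excitation-contraction modelling with cardioec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale excitation-contraction modelling with cardioec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioec)
```

## What the package models

`cardioec` simulates the excitation-contraction chain of a human
ventricular myocyte and carries its output up to a reduced organ-level
surrogate:

1. **Membrane electrophysiology.** A modified Grandi-Pasqualini-Bers
   (GPB) ionic model: 38 free ordinary differential equations over four
   compartments (junctional cleft, subsarcolemmal space, bulk cytosol,
   sarcoplasmic reticulum), plus a clamped bulk K+ concentration and two
   added gates for a late sodium current,
   $$I_{\mathrm{NaL},x} = F_x\, g_{\mathrm{NaL}}\, m_L^3 h_L (V_m - E_{\mathrm{Na},x}),
     \qquad x \in \{\text{junc}, \text{sl}\},$$
   with Luo-Rudy-type activation kinetics and first-order inactivation
   with $\tau_{hL} = 233$ ms.  Two inter-compartment Ca diffusion
   constants are raised relative to the original formulation
   ($J_{\mathrm{Ca,juncsl}} = 1.2362\times10^{-12}$,
   $J_{\mathrm{Ca,slmyo}} = 7.4485\times10^{-12}$ L/ms) so that the
   healthy cytosolic Ca transient peaks near 1 µM, the operating range the
   myofilament model expects.
2. **Disease continuum.** Eleven dimensionless *impact factors* scale the
   quantities most relevant to failing-myocyte Ca handling
   ($\tau_{hL}$, $I_{\mathrm{NaL}}$, $I_{K1}$, $I_{\mathrm{NaK}}$,
   $I_{\mathrm{Nab}}$, $I_{\mathrm{Cab}}$, $I_{\mathrm{NCX}}$, $I_{to}$,
   $J_{\mathrm{SRleak}}$, $J_{\mathrm{SERCA}}$, $\mathrm{EC50_{SR}}$).
   The healthy state is the unit vector (case A); the end-stage failing
   state (case D) is a fixed published row; intermediate severities
   interpolate linearly, $f(s) = f_A + s\,(f_D - f_A)$, so cases B and C
   are $s = 1/3$ and $s = 2/3$.
3. **Myofilament tension.** The Niederer-Hunter-Smith (NHS) model in its
   native units (s, µM, kPa): troponin Ca binding with tension-dependent
   unbinding, tropomyosin site-availability kinetics $z(t)$,
   length-dependent activation, and three fading-memory crossbridge
   variables driven by the stretch rate.  Coupling is **one way**: the
   simulated cytosolic Ca transient drives the NHS troponin pool, and the
   membrane model keeps its own (separate) troponin buffer.  Under the
   default isometric protocol ($\lambda_f = 1$, $d\lambda_f/dt = 0$) the
   fading-memory variables remain exactly zero, which the test suite
   verifies.
4. **Tissue mechanics.** The Holzapfel-Ogden orthotropic strain energy
   $$W = \frac{a}{2b} e^{b(I_1 - 3)}
       + \sum_{i=f,s}\frac{a_i}{2b_i}\!\left(e^{b_i (I_{4i}' - 1)^2} - 1\right)
       + \frac{a_{fs}}{2b_{fs}}\!\left(e^{b_{fs} I_{8fs}^2} - 1\right),$$
   with $I_{4i}' = \max(I_{4i}, 1)$ so fibers and sheets bear load only in
   extension, the passive first Piola-Kirchhoff stress
   $P^p = \partial W/\partial F - a e^{b(I_1-3)} F^{-T}$ (exactly zero at
   $F = I$; the implementation normalises $W$ to zero there as well, an
   energy offset that leaves the stress unchanged), and the active Cauchy
   stress $\sigma^a = T_{\mathrm{scale}}\, T\, \bar{f}\otimes\bar{f}$.
5. **Pump-function surrogate.** A quasi-static, exactly incompressible
   thick-walled sphere replaces the full 3D fluid-structure model for
   *qualitative* trend studies: cavity pressure balances the radially
   integrated wall stress, with the active tension split equally between
   the two tangential directions, so the active contribution to the
   pressure balance is $T_a \ln(r_o/r_i)$.

## Default parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `g_NaL` | 0.0065 | mS/µF | late-Na maximal conductance |
| `tau_hL` | 233 | ms | late-Na inactivation time constant |
| pacing amplitude | −9.5 | µA/µF | inward square pulse |
| pulse duration | 5 | ms | |
| basic cycle length | 1000 | ms | 1 Hz pacing |
| pre-pacing beats | 100 | — | conditioning before the recorded beat |
| `rtol` / `atol` | 1e-7 / 1e-10 | — | lsoda tolerances |
| `T_ref` | 56.2 | kPa | NHS reference tension at resting length |
| `a, b, a_f, b_f, a_s, b_s, a_fs, b_fs` | 0.24, 5.08, 1.46, 4.15, 0.87, 1.6, 0.3, 1.3 | kPa / — | passive wall material |
| `T_scale` | 3.0 | — | myofilament-to-tissue tension scaling |
| sphere radii | 2.0 / 3.3 | cm | reference endo-/epicardial radii |
| ED / ES pressure | 8 / 150 | mmHg | surrogate loading |

`g_NaL` is not part of the printed parameter set of the modified model;
the value used here is the standard one in the Hund-Rudy-derived late-INa
lineage this formulation descends from, chosen once and not revisited.
The pacing protocol is likewise not printed; 100 pre-pacing beats at 1 Hz
with the conventional GPB stimulus is used as the package default
(`stimulus_protocol()`), and every protocol element is user-configurable.

## Numerical choices

* **Integration.** Stiff adaptive integration (`deSolve::lsoda`) of the
  46-state coupled system, with a compiled right-hand side.  A pure-R
  reference implementation of the same equations ships in the package and
  the test suite requires the two to agree to relative round-off at
  random valid states — this also pins the parameter-vector layout shared
  by the two implementations.  Each beat is integrated in two segments
  (pulse on / pulse off) so the solver never steps across the stimulus
  discontinuity.
* **Removable singularities.** All $x/(1-e^{-kx})$-type rates and GHK
  flux denominators use series/limit branches inside a small guard window
  ($|kx| < 10^{-4}$), so no reachable voltage produces NaN.
* **Dense output for derivatives.** Upstroke velocities are maximal
  centered differences on the recorded grid.  They converge only near
  0.02 ms sampling (365 V/s at 0.02 ms vs 285 V/s at 0.1 ms for the
  healthy AP), so table reproduction and the acceptance script record the
  beat at 0.02 ms; the package default for exploratory runs is 0.1 ms.
* **Crossings.** APD, ERP and RT50 crossings are linearly interpolated
  between samples.  The resting potential is the pre-stimulus sample;
  transient times-to-peak are measured from stimulus onset; RT50 is
  measured from the tension peak to the decay crossing of
  diastolic + half amplitude (the standard relaxation-time convention —
  diastolic tension is near zero here, so this nearly coincides with 50%
  of the absolute peak); the rate of tension development is the maximal
  $dT/dt$.  The refractory interval is read at a configurable
  repolarization fraction, default 0.85
  (`erp_repolarization_fraction()`): the level is not uniquely
  determined by the reference values, and 0.85 places the healthy
  interval a few percent below APD90, matching the published
  relationship.  At fraction 0.9 it coincides with APD90 by construction.
* **Ca conservation.** The cytosolic balance of the source model debits
  free Ca for occupancy changes of all seven cytosolic buffer states,
  including the two Mg-occupied ones; the conserved total in
  `total_calcium()` therefore includes those states.  With sarcolemmal Ca
  pathways closed, the suite verifies conservation along trajectories to
  integrator tolerance.
* **Sphere equilibria.** The pressure-radius curve of an activated sphere
  can fold; the solver scans the bracket $[0.3, 3] \times r_i$, refines
  every sign change, and deterministically selects the most contracted
  equilibrium.  This selection preserves the monotone trend directions
  (end-diastolic volume increasing in filling pressure, end-systolic
  volume increasing in afterload and decreasing in contractility).

## The disease cases and what reproduction shows

Pacing the four cases under the default protocol and extracting the
twelve biomarkers reproduces most healthy-case (A) values within a few
percent — APD90, resting potential, AP amplitude, maximal upstroke
velocity, Ca-transient peak, time to peak and amplitude — and captures
every qualitative ordering the reference table exhibits across the
healthy-to-failing continuum: APD and refractory interval lengthen,
Ca-transient and tension peaks, amplitudes and development rates fall,
times-to-peak and relaxation times lengthen.

Two systematic gaps remain and are reported honestly by the acceptance
test rather than absorbed into tolerances.  First, the failing-case APD
prolongation is under-predicted: every impact factor individually
prolongs the AP in this implementation, but over long pacing the failing
cell accumulates Na (for example ~9 to ~11 mM over several hundred
beats with halved Na/K-pump activity), which shifts NCX and the pump
current outward and erodes the prolongation.  Published failing-state
descriptions of this model family keep a long APD at comparable Na loads,
which points at formulation details of the remodelled currents beyond the
multiplicative scalings implemented here; no admissible late-Na
conductance reconciles both ends of the continuum (raising it prolongs
the healthy AP past its reference value before the failing AP reaches
its own).  Second, the tension-kinetics trio (rate of development, RT50,
and with it the peak) sits ~5-11% low for the healthy case, consistent
with the simulated Ca transient decaying slightly faster than the
reference one.

## What the synthetic generators emulate

`synth_triangle_ap()` and `synth_gaussian_transient()` produce idealised
waveforms whose biomarkers have closed forms; they validate the feature
extractors independently of any simulation.  They emulate the *shape
classes* the extractors must handle (sharp upstroke + slow repolarization;
smooth single-peak transient) and none of the physiology: passing those
tests shows the measurement code is correct, not that the model is.  The
simulated-trace tests and the acceptance script carry the physiological
burden.  `generate_fixtures()` also emits a short, coarsely sampled
healthy-model trace for regression pinning; bitwise reproducibility of
reruns is tested separately.

## Known limitations

* Equation provenance: the detailed appendix of the modified model was
  not available; the implementation layers the documented modifications
  on the published GPB formulation (see `MODEL_NOTES.md` for every
  divergence, including the suspected sign typo in the printed late-Na
  steady-state inactivation).
* The sphere surrogate makes no claim to organ-level magnitudes: it is a
  trend instrument.  Fed the resting-length isometric peak tension times
  `T_scale` = 3, it cannot hold 150 mmHg at reduced volume — ejection in
  the surrogate appears at higher contractility or lower afterload, which
  is exactly the compensation behaviour it is meant to illustrate.
  Length- and strain-rate-dependent tension amplification, 3D geometry,
  fiber architecture and fluid-structure interaction are out of scope.
* Bulk K+ is clamped, as in the source formulation: long-horizon K+
  redistribution (minutes to hours) is outside the model.
* One-way excitation-contraction coupling: no mechano-electric feedback.

## Problem sizes used by the shipped checks

The test suite and acceptance script simulate 101 beats per case (100
conditioning + 1 recorded at 0.02 ms output), four cases for the
biomarker table and two for the acceptance targets; property tests use
shorter protocols (1-10 beats) and the surrogate sweeps use 4-24 grid
points.  A full case runs in a few seconds on one CPU with the compiled
right-hand side.
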