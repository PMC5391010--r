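# cardioec

Multi-scale modelling of cardiac excitation-contraction coupling in
healthy and failing human ventricular myocytes, for computational
cardiologists and modellers who need a tested, scriptable implementation
of the full chain from membrane currents to active tension to organ-level
pump-function trends.

## What it computes

**Cell level.** A modified Grandi-Pasqualini-Bers ionic model (38 free
ODEs over junctional, subsarcolemmal, cytosolic and SR compartments,
clamped bulk K⁺) extended with a late sodium current

    I_NaL,x = F_x · g_NaL · mL³ · hL · (Vm − E_Na,x),   x ∈ {junc, sl}

(τ_hL = 233 ms) and with raised inter-compartment Ca diffusion constants
so the healthy Ca transient peaks near 1 µM. Heart-failure remodelling is
expressed through eleven multiplicative *impact factors* on the key Ca
handling quantities (τ_hL, I_NaL, I_K1, I_NaK, I_Nab, I_Cab, I_NCX, I_to,
J_SRleak, J_SERCA, EC50_SR): case A (healthy, all ones) to case D
(end-stage failing), with B and C the 1/3 and 2/3 points of the straight
line between them, or any continuous severity `s ∈ [0, 1]`.

**Myofilament.** The Niederer-Hunter-Smith active-tension model, one-way
coupled to the simulated Ca transient under an isometric protocol
(stretch λ_f = 1, dλ_f/dt = 0), producing tension T(t) in kPa.

**Tissue and organ.** The Holzapfel-Ogden orthotropic passive law

    W = a/(2b)·exp(b(I₁−3)) + Σᵢ aᵢ/(2bᵢ)·(exp(bᵢ(I₄ᵢ′−1)²)−1)
        + a_fs/(2b_fs)·(exp(b_fs·I₈fs²)−1),   I₄ᵢ′ = max(I₄ᵢ, 1)

with analytic first Piola-Kirchhoff stress, active Cauchy stress
`T_scale · T · f̄⊗f̄`, and an incompressible thick-walled-sphere left
ventricle surrogate for qualitative pressure-volume trends (preload,
afterload, contractility).

Twelve standard biomarkers are extracted from every simulated beat:
APD90, resting potential, AP amplitude, maximal upstroke velocity, a
refractory interval read at a configurable repolarization level, Ca
transient peak / time to peak / maximal rise rate / amplitude, and
tension peak / maximal rate of development / RT50.

## Worked example

Pace the healthy myocyte to beat 101 at 1 Hz and extract its biomarkers:

```r
library(cardioec)

tr  <- simulate_myocyte("A", stimulus_protocol(), record_dt = 0.02)
rep <- biomarker_report(tr)
t(as.data.frame(rep)[-1])
#> apd90_ms                       279.2175993
#> resting_potential_mV           -81.4181784
#> ap_amplitude_mV                124.3856070
#> ap_upstroke_velocity_V_per_s   364.8522209
#> erp_ms                         274.7295831
#> cat_peak_uM                      0.9353375
#> cat_time_to_peak_s               0.0400200
#> cat_upstroke_velocity_uM_per_s 125.9876673
#> cat_amplitude_uM                 0.8289619
#> tension_peak_kPa                 9.3372368
#> tension_rate_kPa_per_s         188.4958618
#> tension_rt50_s                   0.1622508
```

The healthy action potential lasts ~279 ms to 90% repolarization, the Ca
transient peaks at 0.94 µM 40 ms after the stimulus, and the isometric
myofilament tension peaks at 9.3 kPa. Swapping `"A"` for `"D"` (or a
severity fraction such as `0.5`) gives the failing phenotype: a smaller,
slower Ca transient and roughly a third of the healthy peak tension.
`autoplot(tr)` draws the beat; `plot_case_traces()` overlays cases;
`tidy()`/`glance()` return analysis-ready tibbles.

Feed the peak tension into the ventricle surrogate and sweep afterload
and contractility:

```r
sw <- lv_sweep(tension = rep$tension_peak_kPa,
               esp = c(100, 150), T_scale = c(3, 6))
as.data.frame(sw)
#>   edp esp T_scale edv_mL esv_mL  sv_mL ef_percent
#> 1   8 100       3  60.55  15.61  44.94      74.22
#> 2   8 100       6  60.55  14.18  46.38      76.59
#> 3   8 150       3  60.55  91.57 -31.02     -51.22
#> 4   8 150       6  60.55  14.43  46.13      76.17
```

At full afterload (150 mmHg) and baseline contractility the sphere cannot
eject (negative stroke volume); lowering afterload or raising `T_scale`
restores ejection — the surrogate reproduces trend *directions*
(Frank-Starling preload response, afterload and contractility effects on
end-systolic volume), not organ-level magnitudes.

A thin CLI wraps the same functions
(`inst/cli/cardioec myocyte|biomarkers|lv-surrogate|table1|table2|run`),
and YAML run configurations with full schema validation are supported via
`load_config()` / `run_config()`.

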