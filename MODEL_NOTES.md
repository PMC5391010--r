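# Model provenance notes

The electrophysiology core is the published Grandi-Pasqualini-Bers (2010)
human ventricular epicardial formulation, with the following modifications
layered on top (these define the "modified" model this package implements):

1. **Late sodium current** added in Hodgkin-Huxley form,
   `I_NaL = F_x * g_NaL * mL^3 * hL * (Vm - E_Na,x)` per membrane
   compartment, with Luo-Rudy-type activation kinetics
   (`alpha_mL = 0.32 (Vm + 47.13) / (1 - e^{-0.1 (Vm + 47.13)})`,
   `beta_mL = 0.08 e^{-Vm/11}`) and first-order inactivation with
   `tau_hL = 233 ms`.  `I_NaL` contributes to the junctional and
   subsarcolemmal Na+ mass balances.
2. **Steady-state inactivation sign.**  The form
   `hL_inf = 1 / (1 - e^{(Vm+91)/6.1})` that appears in some printed
   descriptions of this current is negative for `Vm > -91 mV` and cannot be
   a gate; the standard sigmoid `1 / (1 + e^{(Vm+91)/6.1})` is implemented
   (suspected sign typo in the printed form).
3. **g_NaL = 0.0065 mS/uF.**  The maximal late-Na conductance is not part
   of the printed parameter set; the value standard in the
   Hund-Rudy-derived late-INa lineage this formulation descends from is
   used.
4. **Ca diffusion constants** between compartments raised to
   `J_Ca_juncsl = 1.2362e-12 L/ms` and `J_Ca_slmyo = 7.4485e-12 L/ms`
   (1.5x and 2x the original values) so the healthy cytosolic Ca transient
   peaks near 1 uM, as the downstream myofilament model requires.
5. **Impact factors** (disease remodelling multipliers) applied
   multiplicatively to the quantity each is named after: tau_hL, g_NaL,
   I_K1 conductance, Na/K pump maximum, background Na and Ca conductances,
   NCX maximum, both transient-outward conductances, SR leak coefficient,
   SERCA maximum, and the SR-Ca half-activation EC50 of RyR release.

Housekeeping divergences from the published reference code:

- Bulk K+ is carried as a state but clamped (`dK_i/dt = 0`), as in the
  reference implementation; the registry therefore lists 38 free membrane
  ODEs + clamped K_i + 2 late-Na gates.
- The published initial value of the L-type `f` gate (1.000681) is clamped
  to 1 so the state satisfies the gate bounds exactly; the difference is
  erased by pre-pacing.
- All removable singularities in rate expressions (GHK fluxes at Vm = 0,
  the L-type activation time constant at Vm = -5 mV, the late-Na opening
  rate at Vm = -47.13 mV) use series/limit branches inside a small guard
  window.

The myofilament block is the Niederer-Hunter-Smith (2006) model in its
native units (s, uM, kPa), one-way coupled: the cytosolic Ca transient
drives troponin binding, with no feedback of myofilament Ca buffering onto
the electrophysiology Ca balance (the membrane model keeps its own troponin
buffer).  Tension feeds back on troponin unbinding within the NHS block
itself, as that model prescribes.
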