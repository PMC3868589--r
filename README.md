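# lvbulk

Inverse finite-element identification of the time-varying bulk modulus of
the human left-ventricular (LV) wall over a cardiac cycle.

Myocardium is conventionally idealized as incompressible, but intramural
blood displacement makes the *effective* compressibility of the working
wall change through the heartbeat. `lvbulk` treats the wall's bulk modulus
K (compressibility c = 1/K) as the single unknown material parameter of a
nonlinear finite-element model of the LV and identifies K(t) at every
sample of a pressure–volume cycle: at each time step it finds the K for
which the simulated cavity volume matches the target volume under the
measured cavity pressure,

    |V_FE(p(t), E_a(t), K) − V_target(t)| / V_target(t) ≤ 1% ,

with E_a(t) = 29.5·p(t) the pressure-proportional active myofiber modulus
(capped at 0.5 MPa). The package is aimed at cardiac-biomechanics
researchers who want a desk-scale, fully scriptable reimplementation of
this identification pipeline.

## What is inside

* **Model**: truncated-ellipsoid LV wall (cavity 50 ml, wall 73.6 ml,
  solved from the volumetric constraints), layered hexahedral mesh with an
  apex cap, rule-based myofiber/collagen architecture (regional helix
  angles, ±15° transverse rule, radial collagen), two-term Ogden matrix
  (μ₁ = 220 kPa, μ₂ = 110 kPa, α₁ = 11.77, α₂ = 14.34) with a tunable
  volumetric stiffness U = (K/2)(J−1)², follower cavity pressure, an
  epicardial elastic foundation (0.02 kPa/mm) and a fixed base plane.
* **Solver**: updated-Lagrangian Newton with mean-dilatation (Q1P0)
  hexahedra, consistent tangents (finite-difference verified), an
  affine-invariant line search and automatic load substepping — robust from
  K = 0.01 kPa (grossly compressible) to K = 2×10⁸ kPa (incompressible
  limit).
* **Inverse loop**: per-step guarded secant/bisection in log K with warm
  starts, explicit bracket-saturation flags, and a cycle summary (peak K,
  peak compressibility, incompressible span, EDV/ESV/SV/ejection fraction).
* **Waveform generator**: synthesizes the healthy-heart reference cycle
  from printed anchors (EDV 130 ml, ESV 50 ml, SV 80 ml, peak pressure
  16.93 kPa, phase boundaries 0.1/0.21/0.3/0.43/0.5/0.65 s, 0.8 s cycle),
  or loads any user cycle from CSV.
* **Pipeline**: YAML-configured commands (`cmd_make_waveforms`,
  `cmd_build_model`, `cmd_forward`, `cmd_identify`, `cmd_compare`), CSV and
  JSON outputs, VTK mesh/fiber export, and a thin CLI
  (`inst/cli/lvbulk.R`).

## Worked example

```r
library(lvbulk)

cycle <- generate_cycle(reference_cycle_spec())   # synthesized P-V cycle
model <- cmd_build_model(default_config())        # 588-element reference LV
res   <- identify_cycle(model, cycle)             # ~4 min on one core
summary(res)
```

```
Inverse bulk-modulus identification
  peak K           : 748 kPa at t = 0.4 s
  peak compressibility: 25.1 1/kPa
  incompressible fraction of cycle: 50.0%
  max |rel. volume error|: 0.947% (0 bracket-limited, 5 low-sensitivity steps)
  EDV 130 ml, ESV 50 ml, SV 80 ml, Ef 61.5%
```

Reading the output: every one of the 41 time steps matched its target
volume within the 1% rule (no step hit the admissible K bracket). The wall
is most compressible during atrial systole and filling (c ≈ 25 kPa⁻¹,
K ≈ 0.04 kPa — the wall swells readily as it fills), stiffens steadily
through isovolumic contraction and ejection, and reaches its peak
*identified* bulk modulus at the end of ejection (t ≈ 0.4 s) before
softening again when rapid filling begins — the stiffen-by-contraction /
soften-by-relaxation pattern expected of working myocardium. During the
end-systolic plateau the cavity volume barely responds to K (the wall is
operationally incompressible); those five steps carry a low-sensitivity
mark and are excluded from the reported peak, since there the data only
bound the modulus from below. The per-step table (`as.data.frame(res)`)
carries t, p, target and fitted volume, relative error, K, compressibility,
the sensitivity estimate and the saturation flag for each step.

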