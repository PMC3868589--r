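---
title: "Inverse identification of the left-ventricular bulk modulus: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse identification of the left-ventricular bulk modulus: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Myocardial tissue is usually idealized as incompressible, yet intramural
blood is squeezed out of and drawn back into the wall over every heartbeat,
so the *effective* compressibility of the working ventricular wall varies in
time. `lvbulk` treats the bulk modulus $K(t)$ (compressibility $c = 1/K$) of
the left-ventricular (LV) wall as the one unknown material parameter of a
forward finite-element model, and identifies it at every instant of the
cardiac cycle by requiring the simulated cavity volume to match a measured
(or synthesized) pressure–volume cycle:

$$ \text{find } K(t_k): \quad
   \frac{\lvert V_\text{FE}(p(t_k), E_a(t_k), K) - V_\text{target}(t_k)\rvert}
        {V_\text{target}(t_k)} \le 1\% . $$

The 1% matching rule is the identification's convergence criterion, not a
statistical tolerance; per-step results that cannot reach it inside the
admissible bracket $[K_{\min}, K_{\max}]$ are returned at the nearest
endpoint and *flagged*, never silently accepted.

## Forward model

**Geometry.** The LV wall is a thick-walled prolate ellipsoid truncated at
two-thirds of the major axis (base plane at $a_\text{endo}/3$, apex at
$-a_\text{endo}$). Printed wall dimensions are not available, so the
geometry is solved from the two volumetric constraints that the study holds
fixed — cavity 50 ml and wall 73.6 ml — plus an endocardial aspect ratio
$a/b = 2$ (configurable) and uniform wall thickness. For the default
constraints this gives $b_\text{endo} \approx 20.0$ mm,
$a_\text{endo} \approx 40.1$ mm and a thickness of $\approx 9.2$ mm,
plausible values for a human LV.

**Mesh.** A structured shell of 8-node hexahedra: 7 equal transmural
layers, a configurable number of circumferential divisions and longitudinal
rows, and an apex cap of collapsed hexahedra. The default desk-scale
resolution is $12 \times 6 \times 7$ (588 elements); the reference
48-division discretization is available through the configuration. Because
a coarse chord-polygon mesh underestimates the enclosed volumes by several
percent, node placement is *calibrated* so that the discrete cavity volume
(divergence-theorem surface integral closed by a virtual lid at the base)
and the discrete wall volume (sum of quadrature volumes) equal the
prescribed 50 and 73.6 ml exactly — the study conditions fix these volumes,
so the discrete model must carry them, not their chord-underestimates.
`calibrate = FALSE` disables this for convergence studies.

**Fiber architecture.** Two embedded uniaxial fiber families are
superposed on the continuum by volume fraction (rebar): myofibers
(fraction 0.7) and radial collagen (fraction 0.015, Young's modulus
50 kPa). The myofiber direction follows the rule-based architecture: the
helix angle $\beta$ varies linearly across the wall between printed
regional endpoints (e.g. septum-basal $-60°$ at the epicardium to $+40°$ at
the endocardium) over eight regions — septum/anterior/lateral/posterior
crossed with basal/apical — and the transverse angle $\eta$ varies linearly
from $-15°$ at the apex through $0°$ at the equator to $+15°$ at the base.
Since the azimuthal extent of the regions is not printed, the four
circumferential sectors are 90° quadrants starting at the $-x$ axis
(septum), and the basal/apical split is the longitudinal midpoint; no
blending is applied across region boundaries. $\beta$ is evaluated at each
element's transmural layer midpoint ($s \in \{1/14, \dots, 13/14\}$ from
the epicardium), $\eta$ at the quadrature point's longitudinal coordinate.

**Passive matrix.** Two-term Ogden energy on isochoric stretches,
$W = \sum_p \frac{\mu_p}{\alpha_p}(\bar\lambda_1^{\alpha_p} +
\bar\lambda_2^{\alpha_p} + \bar\lambda_3^{\alpha_p} - 3)$ with
$\mu_1 = 220$ kPa, $\mu_2 = 110$ kPa, $\alpha_1 = 11.77$,
$\alpha_2 = 14.34$ (ground-state shear modulus
$(\mu_1\alpha_1 + \mu_2\alpha_2)/2 = 2083$ kPa). The volumetric energy is
$U = \tfrac{K}{2}(J-1)^2$ — the simplest convex law whose tangent bulk
modulus at $J = 1$ is exactly $K$, so the identified parameter *is* the
bulk modulus without unit juggling.

**Active elastance.** The myofiber Young's modulus is proportional to the
instantaneous cavity pressure, $E_a = c_\text{act}\, p$ with
$c_\text{act} = E_\text{max}/p_\text{peak} = 500/16.93 = 29.5$ (3 s.f.),
capping at the physiological ceiling of 0.5 MPa at peak pressure. The
constant 29.5 is therefore exact at the printed precision, and the
examples use the unrounded ratio.

A time-varying elastance is an *incremental* stiffness about the muscle's
operating point. Accordingly the active family's strain reference is the
configuration at the start of the current time step: within a step the
myofibers resist deformation away from that state with modulus $E_a(t)$,
and the reference advances with the solution. Anchoring the active strain
to the stress-free reference instead makes $E_a \propto p$ act as a
permanent passive spring whose stiffness grows with the very pressure that
drives filling; the reachable cavity volume then saturates near 62–68 ml
for *any* bulk modulus and the 110–130 ml diastolic targets become
unreachable — that variant cannot reproduce a physiological cycle at all.
Passive collagen, by contrast, keeps the stress-free reference and
accumulates the large filling strains. The price of the incremental active
law is mild time-step dependence of the transient response; the operating
state at the cycle start is defined as the settled fixed point of
solve-and-reset iterations (`solve_relaxed`), which coincides with the
cycle's periodic regime (the identified end-of-cycle volume returns to the
start-of-cycle value within the 1% matching tolerance).

**Loads and boundary conditions.** Cavity pressure is a follower load on
the endocardial faces (with its full nonsymmetric load stiffness); the
epicardium rests on a linear elastic foundation of 0.02 kPa per mm of
normal displacement, representing surrounding organs (the conventional FE
elastic-foundation unit for the printed "0.02 kPa"); base-plane nodes are
fixed longitudinally; the base-centre pressure node is the fixed apex of
the virtual lid that closes the cavity for the volume integral (it rides
with the mean base-ring motion so the enclosed volume is exactly invariant
under rigid translations). The long axis is $z$ here; the published
"UY = 0" base constraint translates to $u_z = 0$.

**Element technology.** Updated-Lagrangian assembly of 8-node hexahedra
with mean-dilatation (Q1P0) volumetric treatment: the volumetric energy is
evaluated on the element-average dilatation $\bar J = v_e/V_e$, which
removes volumetric locking in the near-incompressible regime. The Ogden
stress and spatial tangent are evaluated spectrally with the standard
coincident-eigenvalue limits; the consistent tangent (including the Q1P0
rank-one and dilatation-Hessian terms and the follower-load stiffness) is
verified against finite differences of the residual to better than
$10^{-5}$ in the tests.

**Nonlinear solver.** Newton–Raphson with an affine-invariant line search:
step acceptance is judged in the natural metric $\lVert J^{-1} R \rVert$,
which removes the extreme curvature the penalty-like volumetric term
induces in the plain residual norm near incompressibility (plain
backtracking crawls at bulk-to-shear ratios of $10^5$). The sparse
nonsymmetric tangent is LU-factorized (`Matrix`), with two rounds of
iterative refinement; convergence demands a residual below $10^{-6}$ of
the applied pressure-force norm, with a floor of
$100\,\varepsilon\, K \lVert \partial v/\partial u\rVert$ — the
floating-point noise level of the volumetric force, below which no residual
can be driven at extreme $K$. Failed increments trigger automatic
bisection of a load homotopy that interpolates $(p, E_a)$ linearly and $K$
in log space from the last converged state.

## The inverse loop

$V(K)$ at fixed $(p, E_a)$ is monotone *decreasing*: a softer volumetric
response lets the pressurized wall dilate (the mean stress in an inflated
shell is tensile), enlarging both the wall and the cavity. Each time step
therefore runs a guarded root search in $\log K$: a secant step from the
warm-start guess (the previous step's modulus), with fallback bisection
once a sign-changing bracket exists. The bracket is grown from the guess in
decade steps using warm-started continuation solves; the admissible range
$[10^{-2}, 10^5]$ kPa is never evaluated cold from the stress-free state —
solving at $K_{\min}$ under peak pressure from scratch is numerically
brutal and adds no information. Saturated steps (target outside the
achievable volume range) return the nearest endpoint with a `bracket_lo`
or `bracket_hi` flag. Each step also records an estimate of the volume
sensitivity $|\partial V/\partial \log K|$ from the search's own
evaluations (probing once when a step accepts on its first solve): near the
incompressible asymptote the acceptance band covers a half-line in $K$ and
the per-step value only *bounds* the modulus, so the summary's peak modulus
is taken over steps whose sensitivity exceeds the identifiability scale
$\text{tol}\cdot V_\text{target}$ (the band width per unit $\log K$),
excluding bracket-saturated and low-sensitivity steps alike. No smoothing
or regularization couples adjacent time steps: the identification is
strictly stepwise, and smoothing is left to post-processing.

## The synthetic cycle generator

The reference dataset is a healthy-heart cycle reconstructed from printed
anchor values: 0.8 s cycle; phase boundaries 0.1, 0.21, 0.3, 0.43, 0.5 and
0.65 s (end of atrial systole, isovolumic contraction, rapid ejection,
reduced ejection, isovolumic relaxation and rapid filling); volumes 110 ml
at the start, EDV 130 ml, ESV 50 ml (stroke volume 80 ml, ejection fraction
61.5%); peak pressure 16.93 kPa. Between anchors the pressure is a
Fritsch–Carlson monotone cubic through a configurable anchor table (fit per
monotone run, split at local extrema, so the anchored peak is attained
exactly and never overshot) and the volume a cubic smoothstep per phase (exactly constant on the isovolumic
plateaus). The interior anchors the source never tabulates were fixed once
at textbook healthy-human hemodynamics: 0.5 kPa at cycle start, 1.0 kPa at
end-diastole, 10.6 kPa at aortic opening, peak at $t = 0.26$ s (on the
default 0.02 s grid, mid rapid ejection), 15.5 kPa at the end of rapid
ejection, 13.0 kPa (≈100 mmHg) at aortic valve closure, 0.7 kPa at the end
of isovolumic relaxation, and 0.5–0.55 kPa through filling; volumes 60 ml
at the end of rapid ejection and 105 ml at the end of rapid filling. The
default grid is 41 samples (0.02 s).

What the generator emulates is the *shape class* of a healthy
pressure–volume cycle anchored at printed values; what it does not emulate
is the exact measured waveform, which exists only as a figure in the
source. Every quantity downstream of the waveform — most visibly the peak
bulk modulus and the duration of the nearly incompressible span — inherits
this uncertainty, and order-of-magnitude agreement is the honest
expectation there. Quantities pinned by the anchors themselves (stroke
volume, ejection fraction, modulus ceiling, the ≤1% matching rule) are
exact or tightly bounded. The three alternative physiological datasets
(lower ejection fractions, initial volumes 50/65/70 ml) can be expressed as
configurations with user-supplied anchor tables; no default anchor values
are claimed for them since their curves are not printed.

## Numerical choices and limitations

* Default problem sizes: the $12 \times 6 \times 7$ mesh and 41 time steps
  run the full identification in minutes on a single core; parameter
  recovery and the spherical-shell verification use the same scale.
* Fiber reinforcement acts in both tension and compression (a linear
  uniaxial law); a tension-only variant can make the tangent
  rank-deficient when $E_a$ is large and is deliberately not the default.
* The collagen Poisson ratio and density are recorded for completeness but
  unused — a uniaxial rebar has no transverse response and the quasi-static
  model no inertia.
* The identified $K$ is attributed to the matrix volumetric term; whether
  the published values refer to the matrix or the fiber–matrix composite is
  not decidable from the text.
* Where the cavity-volume sensitivity to $K$ is small (isovolumic plateaus
  at near-incompressibility), any sufficiently large $K$ satisfies the 1%
  rule and the reported modulus is correspondingly imprecise — these are
  exactly the steps the saturation flags, the `sens_ml` column and the
  summary's exclusion rule are for.
* No electrophysiology, no blood-flow coupling, no viscoelasticity, no
  contact: activation enters only through $E_a(t)$, and the model is
  quasi-static throughout.

## Verification surfaces

The package checks itself against independent oracles rather than against
its own output: closed-form and Monte-Carlo truncated-ellipsoid volumes;
finite differences of every stress against its energy and of the assembled
tangent against the residual; a semi-analytic incompressible thick-sphere
inflation (1-D integral of the Ogden stress difference) matched within 2%
at the default resolution; self-consistency recovery of prescribed
$K^\ast(t)$ schedules spanning 10–10⁴ kPa within 5% wherever the cavity
volume responds measurably to a 5% modulus perturbation; and the full
reference-cycle identification meeting the 1% matching rule at every step.
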