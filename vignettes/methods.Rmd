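---
title: "Methods: coupled field and bioheat simulation of unipolar RF brain ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled field and bioheat simulation of unipolar RF brain ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`rfablate` predicts the size of the thermal lesion made by a unipolar
radiofrequency electrode in brain tissue, composes multi-trajectory
pull-back lesion plans into a planned ablation volume, and closes the
loop by measuring the lesion on a synthetic post-ablation image. This
vignette documents the model, its discretization, the tunable
parameters and the design decisions, so that a reader can judge what
the package's numbers do and do not mean.

## Physical model and assumptions

**Electro-quasistatic field.** At the 100 kHz operating frequency of
clinical RF generators, the conduction current in brain tissue
(σ ≈ 0.3 S/m) exceeds the displacement current (ωε ≈ 0.02 S/m for
ε_r ≈ 3×10⁴) by an order of magnitude, so the complex-permittivity
potential equation is solved in its conduction-dominated reduction
∇·(σ∇φ) = 0 with real conductivities only. Grey matter is 0.28 S/m and
white matter 0.27 S/m at 100 kHz; the hippocampus is treated as grey
matter. The active tip (a 3 mm cylinder with a hemispherical cap,
1.6 mm diameter) is a Dirichlet equipotential; the insulated shaft
carries no normal current; the distant body ground of the unipolar
circuit is mapped onto the outer domain boundary (φ = 0). Conductivity
is taken temperature-independent, and electrode–tissue contact
impedance, charring and vaporization are outside the model.

**Bioheat.** Temperature follows the Pennes equation

ρc ∂T/∂t = ∇·(k∇T) + ρ_b c_b ω_b (T_b − T) + q_met + s(t) q,

with q = σ|∇φ|² the Joule source and s(t) the generator's dimensionless
power scaling. Because σ does not depend on temperature, the field is
solved once per voltage and only rescaled by the controller — never
re-solved during a run. The far boundary is held at the 37 °C body
baseline; perfusion sinks heat toward arterial blood
(ρ_b = 1050 kg/m³, c_b = 3617 J/(kg K)). Thermal-dose models
(Arrhenius, CEM43) are deliberately out of scope: the lesion margin is
defined purely by the 60 °C isotherm at the end of the ablation, the
convention used in surgical planning for this procedure.

## Tissue parameters

Electrical conductivities are the two values quoted above; they are the
model inputs with published provenance. The thermal and perfusion
parameters are standard brain-tissue literature values, collected in
one editable table (`brain_tissue_table()`) because they are the main
calibration surface of the model:

| label | σ (S/m) | k (W/m K) | ρ (kg/m³) | c (J/kg K) | ω_b (1/s) |
|---|---|---|---|---|---|
| grey matter | 0.28 | 0.55 | 1045 | 3700 | 0.0067 |
| white matter | 0.27 | 0.48 | 1045 | 3580 | 0.0021 |
| hippocampus | 0.28 | 0.55 | 1045 | 3700 | 0.0067 |

T_b = 37 °C and q_met = 0 throughout (metabolic heat is negligible
against Joule heating at watt level). Every value can be overridden per
label, e.g. `brain_tissue_table(grey_matter = list(omega_b = 0))`.

## Discretization

The simulation arena is an axisymmetric (r, z) tensor grid: the
electrode axis is r = 0 and cells are annular rings. Both solvers use
a finite-volume scheme with face conductances A/(d_P/c_P + d_N/c_N)
(harmonic-mean interface coefficients on a uniform grid), which
conserves flux exactly across material interfaces. Cells are classified
by their center (a cell belongs to the electrode if its center is
inside the electrode solid); Dirichlet cells carry no internal
resistance, which places the boundary value at the cell interface. The
r = 0 axis is a natural no-flux boundary (zero face area).

The reference grid grades from 0.25 mm cells in a window around the
tip to coarse cells at the 50 mm domain radius (~13 000 cells), and the
bioheat solver takes 900 implicit-Euler steps of 0.1 s, factorizing the
sparse SPD system once (Cholesky, via `Matrix`) and reusing the factor
every step; a full 90 s run takes a few seconds. Implicit Euler is
unconditionally stable — halving dt moves the 60 °C radius by well
under 0.1 mm (asserted in the tests) — and an explicit scheme with a
CFL guard is retained purely as a cross-check.

Verification is against closed forms: concentric spheres for the
potential, power and q(r) ∝ r⁻⁴ (within 2–3% on the graded grid); the
classic insulated-sphere steady solution ΔT_tip = σV²/(2k) (within
5%); and the uniform perfusion-relaxation ODE (within 10⁻³ °C). The
observed convergence of the potential under grid refinement is first
order, as expected for stairstepped Dirichlet boundaries, and is
non-monotone between consecutive halvings (the stairstep error
oscillates); the tests therefore assert a factor-2 error reduction per
quarter refinement.

## Electrode thermal models and the power controller

Two electrode thermal models are provided.

* **Insulated** (default for constant-voltage runs): no heat enters the
  electrode body. This is the configuration of the closed-form steady
  solutions and emulates field-focused simulation practice.
* **Conducting**: the electrode is a solid stainless-steel domain
  (k = 15 W/(m K), ρ = 7900 kg/m³, c = 500 J/(kg K)) that spreads heat
  along the tip and drains it up the shaft. This model exists because
  the clinical generator does not measure tissue temperature at all: it
  reads a thermocouple embedded in the metal tip. The sensed
  temperature is modelled as the mean temperature of the active-tip
  metal.

The temperature-controlled mode emulates the generator: a proportional
law s ← s·(1 + g·(T_set − T_sensed)/T_set) with gain g = 0.5 updated
every 0.5 s, delivered power clamped to the 2–6 W operating range, and
a setpoint T_set ramped linearly from 37 °C to 80 °C over 10 s —
clinical generators ramp their setpoint at a programmed rate rather
than applying it as a step, which is how a ~2 W device raises the
sensed temperature over 10–15 s rather than in the ~2 s that
unregulated minimum power would take. With these fixed settings the
sensed temperature first crosses 80 °C at ≈ 12.5 s with power between
2 and 2.8 W (computed by the acceptance script).

An alternative sensor, `"tissue_shell"`, regulates the maximum tissue
temperature within 0.5 mm of the tip surface instead; it is kept
because the tissue hotspot is the quantity that determines the lesion,
and the trace reports it (`tissue_max`) in every run.

## The two reference runs, and why

The package ships two reference configurations on the grey-matter
phantom, and they answer different questions.

**Constant 34 V for 90 s (insulated electrode)** is the
published-simulation emulation and the lesion-geometry reference. With
the uncalibrated literature thermal table above it yields a 60 °C
isotherm radius of ≈ 5.5 mm (diameter ≈ 11 mm) and an electrode power
of 4.4 W at 262 Ω — inside the 2–6 W range the generator reports
clinically. These are the numbers the tests check against the published
5.2–5.5 mm radius band.

**Temperature-controlled hold (conducting electrode)** is the generator
emulation and the protocol-timing reference (ramp time, power range).

The two are deliberately not merged, because an energy-balance argument
shows no single run can reproduce all published figures at once. Heat
leaving a quasi-spherical hot region of effective radius a ≈ 1.2–1.7 mm
at a true 80 °C surface hold is at most ΔT·8πka ≈ 1–1.5 W, and the
steady 60 °C radius under distributed Joule heating is bounded by
2·(43/23)·a ≈ 4 mm once perfusion is included — for any
literature-range thermal parameters. A regulated 80 °C hold therefore
cannot produce a 5.2–5.5 mm radius with this electrode; conversely,
holding the minimum 2 W of the generator's operating range keeps the
sensed tip near 95 °C, not 80 °C (the acceptance script reports the
computed plateau honestly). The constant-34 V run reproduces the
published lesion geometry without any parameter tuning, which is strong
evidence it is the configuration the published simulation actually ran;
the "~80 °C core" description matches the generator display during a
regulated clinical lesion, not the simulated hotspot.

## Lesion model and volumetrics conventions

The planning volume uses the hemisphere-plus-cylinder formula exactly
as used for planning, V = ½πr³ + πr²·3n with π = 3.14, where n is the
number of stacked coagulations at 3 mm pull-back steps and all lesions
on a trajectory share one radius (the cylinder idealization). The
geometric solid actually rasterized has volume ⅔πr³ + πr²·3n with
exact π; both are reported, and the ≈ 5–6% gap between them is visible
in the worked example. The isotherm radius is evaluated on the final
snapshot (t = 90 s), not the running maximum, and is the maximum
perpendicular distance from the electrode axis to the 60 °C contour
with sub-grid linear interpolation.

Percentage error is 100·|V_calc − V_meas|/V_calc — the calculated
volume is the fixed denominator — with percentages rounded to one
decimal and volumes to two, matching clinical reporting precision. The
published three-case series is reproducible under this convention for
its second case exactly (1.4%); recomputing all three cases
consistently gives a 2.3 ± 0.9% summary, slightly different from the
published 2.4 ± 0.7% whose per-case rounding conventions are internally
inconsistent. The tests freeze the consistent recomputation.

## Synthetic data: what it does and does not emulate

`build_layered_phantom()` paints geometric regions (slabs, spheres,
cylinders) with tissue labels to stand in for a segmented head model
(grey matter, white matter, hippocampus); generation is deterministic.
`make_postop_image()` emulates only the *decision-relevant* property of
post-operative T2 imaging — a bright lesion against darker
background — as background + contrast·mask + seeded Gaussian noise.
With zero noise, midpoint thresholding recovers the mask exactly; at a
5σ contrast-to-noise gap, misclassification is negligible; recovery
degrades monotonically with noise. No MR physics (relaxation, partial
volume, bias fields) is simulated, synthetic images share the planning
coordinate frame (no registration step), and real segmentation is out
of scope. Passing tests therefore demonstrate the pipeline's internal
consistency and its numerical accuracy against closed forms — not
accuracy on real patient imaging, where registration error, edema and
reader variability would add to the error budget.

## Numerical choices and degenerate inputs

* Field solves use a sparse Cholesky factorization; a relative residual
  above 10⁻⁸ or a discrete maximum-principle violation aborts with a
  solver error (the maximum principle is asserted on every solve).
* The Joule source is computed from face dissipation, so the energy
  identity ∫q dV = V·I holds to machine precision, and the per-step
  bioheat energy balance (source − perfusion − boundary = storage)
  closes to solver precision (asserted within 1%).
* Ties at material interfaces: cell-centered labels; a cell is
  electrode if its center lies inside the electrode solid.
* Degenerate inputs have defined behaviour: zero voltage gives a null
  field; a zero-duration protocol gives an empty lesion report; cold
  fields give radius 0 with `reached = FALSE`; empty masks give a
  0 mm³ measurement with a warning; an isotherm temperature at or below
  baseline is a parameter error (the whole domain would be "lesion").
* A single top-level seed drives every stochastic stage (image noise);
  deterministic stages are bit-identical across re-runs, which the
  tests check on the written artifacts.

## Known limitations

* Temperature-independent tissue properties: no conductivity rise
  before desiccation, no charring plateau; long or high-power
  ablations would need both.
* The 60 °C end-of-ablation isotherm is a planning convention, not a
  dose model.
* The axisymmetric arena assumes tissue homogeneity within each layer
  around the electrode axis; heterogeneity transverse to the axis
  (vessels, CSF) is not represented, and large vessels act as heat
  sinks that this model will overestimate lesion size near.
* The controller is a generic proportional law with a linear setpoint
  ramp; it reproduces the operating envelope of clinical generators
  but not any vendor's exact firmware behaviour.
* Multi-trajectory runs share a single radius per tissue context (one
  axisymmetric simulation), which ignores thermal interaction between
  trajectories ablated in sequence.
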