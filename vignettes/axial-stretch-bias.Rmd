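---
title: "Axial stretch and the bias of cross-sectional aortic distensibility estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axial stretch and the bias of cross-sectional aortic distensibility estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortalab)
```

## The problem

Aortic distensibility — the fractional change in lumen volume per unit of
distending pressure, here always `(V_max - V_min)/V_min/PP` on the
10^-3^ mmHg^-1^ scale — is rarely measured from volumes. Clinical practice
derives it from cine-MR cross sections: lumen areas are tracked over the
cardiac cycle and the area compliances `C_A = dA/dP` are integrated along
the centerline, holding the centerline length fixed at its diastolic value.
That last step silently assumes the proximal aorta does not lengthen during
systole. It does: ventricular contraction pulls the aortic root toward the
apex by roughly 3–19 mm, stretching the ascending aorta and arch
longitudinally. `aortalab` is a reduced-order, quasi-static model built to
quantify the resulting underestimation bias and the conditions (wall
stiffness, root motion) that amplify it.

## The model

The package replaces a patient-specific 3-D finite-element aorta with a
chain of thin-walled axisymmetric rings along a synthetic centerline.

**Wall material.** Each ring obeys the Holzapfel–Gasser–Ogden (HGO)
hyperelastic law: an incompressible neo-Hookean matrix
(`U_iso = C10 (I1bar - 3)`) reinforced by two symmetric families of
collagen fibers at ±`alpha` from the circumferential direction, dispersed
with coefficient `kappa`, contributing
`U_aniso = k1/(2 k2) * sum_a (exp(k2 Ea^2) - 1)` with
`Ea = kappa (I1bar - 3) + (1 - 3 kappa)(I4bar - 1)`. Incompressibility is
enforced analytically (`lambda_r = 1/(lambda_theta lambda_z)`), so the
volumetric energy term vanishes identically and the compressibility
coefficient `D` is carried but inert. The young-adult preset is
`C10 = 42` kPa, `k1 = 290` kPa, `k2 = 12.6`, `kappa = 0.315`,
`alpha = 55` degrees. A fiber family contributes only when its strain
measure is positive (`tension_only`, configurable off): the energy as
written is ambiguous for compressed fibers, and tension-only is the
standard solver convention. Note that at the preset's high dispersion the
`kappa (I1bar - 3)` term keeps `Ea` positive for essentially every
membrane state, so the switch is inert there; it matters only for
low-dispersion walls. The switch also places a curvature kink exactly at
the identity, which is why derivative checks avoid symmetric differences
across that point.

**Equilibrium.** Each ring satisfies the membrane (Laplace) balance
`sigma_theta * h / r = P - k (r - r_dia)`, with loaded radius
`r = lambda_theta R0`, loaded thickness `h = H0/(lambda_theta lambda_z)`,
and in-plane Cauchy stresses from the analytic plane-stress reduction
`sigma_i = lambda_i dU/dlambda_i`. The elastic term `k (r - r_dia)` is the
radial Robin-type support of the surrounding tissue, reacting against
displacement from the imaged diastolic radius; the dashpot part of the
support is stored but inert because only the diastolic and peak-systolic
endpoints of a quasi-static cycle are ever solved. The residual is
monotone in `lambda_theta` on the search bracket [0.5, 2.5], so the root
is unique; it is resolved by Brent's method to 10^-12^ on the stretch,
which leaves equilibrium residuals below 10^-9^ of the load scale.

Internally everything is expressed in kPa and mm — a self-consistent unit
system for membrane equilibrium (kPa·mm/mm = kPa) — with mmHg converted at
the I/O boundary using exactly 1 mmHg = 133.322 Pa.

**Zero-pressure state.** The imaged geometry is loaded at diastolic
pressure, so per-station unloaded radii are recovered by the fixed-point
scheme `R0 <- R0 - (r(R0; DBP) - r_target)`, with unloaded thickness from
incompressibility of the diastolic wall. The cycle cap of 6 mirrors the
original 3-D workflow, where buckling forced manual termination at a
residual of order 8% of the local diameter; the scalar reduction has no
buckling modes and converges far below that (about 0.05% of local
diameter after 6 cycles on the default geometry, first cycle about 8%).
The default tolerance is 0.5% of local diameter.

**Axial stretch.** In diastole `lambda_z = 1` everywhere. At peak systole
each inter-station segment carries a uniform passive strain `eps_p` plus
its share of the root displacement `y_b`, distributed by a linear decay in
arc length from the root station to the first spine-contact station and
zero beyond — the minimal interpolant consistent with a proximally imposed
displacement and a distally tethered descending aorta. Summed over
segments the elongation equals `eps_p * L + y_b` exactly, a conservation
property the tests enforce.

## The estimators

Tagged cross sections (7 by default, 8 in the two-phase in-vivo-style
mode; evenly spaced by diastolic arc length, since a synthetic geometry
has no anatomical landmarks) are integrated into volumes with the conical
frustum formula `pi L / 12 (D1^2 + D1 D2 + D2^2)`, diameters taken from
areas assuming circular sections. The *fixed-length* estimator uses
diastolic inter-tag lengths for both phases — the elongation-neglecting
clinical convention; the *variable-length* estimator uses each phase's own
lengths and differs from the volumetric reference only by the conical
integration error. Estimation errors are `(D_est - D_ref)/D_ref * 100`
and are always computed from unrounded internals: reproducing an error
from a table's rounded distensibility entries can differ by more than a
percentage point. Printed reports round to the conventional precision
(distensibility to 2 decimals on the 10^-3^ mmHg^-1^ scale, errors to 1).

## The synthetic aorta

`make_geometry()` emulates the proximal aorta from the root level down to
the celiac trunk: a straight ascending limb (60 mm), a planar
semicircular arch (radius 40 mm), and a straight descending limb, 350 mm
of centerline in total, with the lumen tapering linearly from 30 mm to
20 mm and wall thickness 10% of the local lumen diameter everywhere.
These dimensions are typical young-adult values, chosen once and exposed
in `aorta_config()`; the subject-specific geometry behind the original
study is not available. Stations are tagged `free`/`vicinity`/`contact`
(the distal half against the spine), which drives both the support
stiffness and the axial decay span. The default support stiffnesses
(contact 10, vicinity 1, free 0.1 kPa/mm) are reduced-model declarations,
not inherited values. Pressure defaults to a 110/70 mmHg single-peak
waveform; only its endpoints enter the quasi-static mechanics.

What the generator does *not* emulate: non-circular lumens, supra-aortic
branches, non-planar arch torsion, tissue heterogeneity, and — critically
for interpretation — any bending compliance of the arch. Passing tests on
this geometry therefore validate the estimator pipeline and the membrane
mechanics, not the full 3-D kinematics of a real aorta (see Limitations).

## Calibrations

Two scalar calibrations anchor the study conditions.

**Stiffness to pulse wave velocity.** Compliance levels are specified as
Bramwell–Hill pulse wave velocities (`PWV = 1/sqrt(rho D_A)`, blood
density 1060 kg/m^3^), and `calibrate_material_to_pwv()` scales
`{C10, k1}` by a common factor until the tangent area distensibility of a
straight tube (mean geometry dimensions, `lambda_z = 1`, no support) at
70 mmHg matches the target. Uniform scaling preserves the preset's
anisotropy structure and is the package's declared stiffening law for the
"intermediate" and "stiff" levels, for which only PWV targets exist. One
genuine property of the reduced model surfaced here: the DBP-tangent PWV
is *convex* in the scale factor — very soft walls distend so far at
70 mmHg that fiber strain-stiffening raises the tangent stiffness again —
with a floor of about 4.85 m/s at the fixed radius-to-thickness ratio of
5 (the floor is independent of absolute tube size, since the membrane
response depends on r/h only). A 4.8 m/s target therefore returns the
most compliant achievable wall, about 1% stiff of the target, with a
warning; this shortfall is a property of the thin-wall reduction with the
10% thickness rule, not a solver tolerance.

**Passive elongation.** Pressurization alone lengthens a curved
3-D aorta; the reduced model represents this with a single strain `eps_p`,
anchored once so that the *no-motion* scenario's fixed-length error equals
the reference value of -20.5%, then held fixed for every other scenario.
The anchor absorbs both passive arch elongation and any residual
integration bias; the error is monotone in `eps_p` on [0, 0.15], so a
bracketed scalar solve suffices.

## Numerical choices and degenerate inputs

* Root-finding: `uniroot` on analytic residuals; tolerance 10^-12^ on the
  stretch; dense-grid scans serve as independent oracles in tests.
* Exponential overflow: `k2 Ea^2` above a configurable cap (50) raises a
  material-instability error naming the offending station — the reduced
  analogue of a diverging 3-D solve.
* Rigid-limit inputs produce a reference distensibility indistinguishable
  from zero (below 10^-4^ on the 10^-3^ mmHg^-1^ scale); reports then
  return `NA` errors rather than ratios of numerical noise.
* Repeated displacement measurements are averaged and reported to one
  decimal with round-half-up, matching clinical reporting.
* Determinism: the pipeline has no hidden state; geometry jitter (off by
  default) is the only stochastic element and is fully seed-determined,
  so identical configs and seeds give byte-identical reports.
* Problem sizes: 40 centerline stations, 7 or 8 tags, 6 restoration
  cycles; the full six-scenario study solves in a few seconds on one CPU.

## What the sensitivity study shows — and a known limitation

The six-scenario study (`run_sensitivity_table()`) reproduces the
qualitative structure of the reference analysis exactly: the fixed-length
estimator always underestimates; the error deepens strictly with wall
stiffness (PWV 4.8 → 7 → 9 m/s) and strictly with root displacement
(0 → 5 → 9.5 → 15 mm); and integrating over the variable centerline
length recovers the reference within about 1–2%, an improvement of the
error magnitude by far more than half in every scenario. The volumetric
reference distensibilities themselves land close to the reference values
row for row.

The error *magnitudes*, however, run systematically deeper than the 3-D
benchmark (for example, about -42% rather than -30% for the generic
scenario under the default support). Two structural causes, both outside
the reduced model's scope, explain this. First, the membrane balance
transmits axial stretch to the hoop response at full strength — wall
thinning (`h` proportional to `1/lambda_z`) plus the `I1`/`I4` stiffening
— and the elongation is carried by the widest, proximal sections, so each
millimeter of root displacement suppresses more area gain than in a 3-D
wall. Second, and more fundamental, a 3-D aorta can absorb part of the
root displacement by swinging and bending the arch without stretching
wall material — increasingly so for stiff walls — whereas the reduced
kinematics converts the imposed displacement into centerline elongation
one-to-one by construction. Bending and shear of the wall are explicit
non-goals here, so this discrepancy is documented rather than patched:
users should read the reduced model's error magnitudes as an upper
envelope of the axial-stretch bias, and its trends and orderings as the
transferable result. Consistently, the eight-tag two-phase mode on the
generic synthetic aorta lands inside the error band reported for real
subjects.

## Other limitations

* Quasi-static: no wave propagation, no fluid–structure interaction, no
  viscoelastic transients (the support dashpots are carried but inert).
* Axisymmetric rings: no through-thickness stress gradients, no residual
  stresses, circular cross sections assumed when converting areas to
  diameters (the real-data CSV mode inherits this assumption).
* The temporal waveform and motion profiles are cosmetic; only the
  diastolic and peak-systolic endpoints matter.
* Pulse pressure in the two-phase mode is an explicit user input; it
  cancels in the estimation errors but scales the distensibilities.
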