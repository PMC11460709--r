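---
title: "Modeling device-related thrombus risk after left atrial appendage occlusion"
author: "laaoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling device-related thrombus risk after left atrial appendage occlusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laaoflow)
```

## The problem

After percutaneous left atrial appendage occlusion (LAAO), a clot can form
on the atrial face of the implanted occluder — device-related thrombus
(DRT). Two device-configuration factors are repeatedly implicated: a deep
implantation that leaves the pulmonary ridge (the fold between the left
superior pulmonary vein and the appendage) uncovered, exposing a pocket of
appendage wall to stagnant flow; and the device family (single-lobe "plug"
versus lobe-plus-disk "pacifier" designs).

`laaoflow` implements the in-silico side of this analysis as a reusable,
fully testable pipeline:

1. **Synthetic anatomy and flow** — an idealized atrium (ellipsoidal
   chamber, 4–6 pulmonary-vein tubes, tapering tubular appendage) and an
   analytic pulsatile velocity field, so every downstream stage runs
   without patient data or an external CFD solver.
2. **Device geometry** — parametric plug/pacifier models, centerline
   deployment, ostium and landing-zone measurement, ridge-coverage
   classification.
3. **Platelet transport** — a Lagrangian discrete-phase model (DPM) with
   the standard force balance and a worst-case wall-film adhesion rule.
4. **Wall-shear thrombogenicity indices** — TAWSS, OSI and ECAP with
   threshold classification.
5. **Cohort analytics** — descriptor tables, group summaries and
   descriptor–outcome concordance, executable against a bundled
   transcription of a published 20-patient cohort's printed tables.

## Carrier flow and particle force balance

Blood is an incompressible Newtonian fluid
(`rho` = 1060 kg/m^3, `mu` = 0.0035 kg/(m s), laminar). Platelet clusters
are point particles advanced by

$$m_p \frac{d\mathbf{u}_p}{dt} =
  m_p\frac{\mathbf{u}-\mathbf{u}_p}{\tau_r} + \mathbf{F}_{pg} +
  \mathbf{F}_{vm} + \mathbf{F}_{saff},$$

with drag relaxation time `tau_r = rho_p d_p^2 / (18 mu)` (the Stokes
form; the force balance assumes linear drag and leaves `tau_r`'s closure
to the implementation), pressure-gradient force
$\mathbf{F}_{pg} = m_p (\rho/\rho_p)(\mathbf{u}\cdot\nabla)\mathbf{u}$,
virtual-mass force
$\mathbf{F}_{vm} = C_{vm} m_p (\rho/\rho_p)
 \left((\mathbf{u}_p\cdot\nabla)\mathbf{u} - d\mathbf{u}_p/dt\right)$
with $C_{vm} = 0.5$, and Saffman shear lift

$$\mathbf{F}_{saff} = m_p\,
  \frac{2K\,\nu^{1/2}\rho\,d_{ij}}{\rho_p d_p (d_{lk}d_{kl})^{1/4}}
  (\mathbf{u}-\mathbf{u}_p), \qquad K = 2.954,$$

where $d_{ij}$ is the deformation tensor (symmetric part of the velocity
gradient). Gravity is off by default. The lift term is dropped below a
shear-magnitude floor of 1e-8 1/s to avoid a 0/0 at vanishing shear.

**Integrator.** The drag term is stiff for small clusters
(`tau_r` can be well below the 0.01 s step). Within each of the fixed
sub-steps (10 per step by default) the linear drag relaxation is
integrated *exactly* — an exponential integrator
$\mathbf{u}_p \leftarrow \mathbf{u}_{eq} +
(\mathbf{u}_p - \mathbf{u}_{eq})e^{-h/\tau'}$ with the non-drag
accelerations held constant — rather than by a drag-implicit Euler step.
Both are unconditionally stable; the exponential form is additionally
exact for the drag-only case at any `tau_r`, which the test suite checks
against the closed-form relaxation.

## Injection model

Platelet clusters enter through the pulmonary-vein inlet caps during the
first `n_ts` = 10 steps of each beat, one cluster per inlet facet per
step, repeated identically in the second beat. The plan is personalized
to the anatomy so the physiological platelet count is represented:

- platelets per cluster `n_ppc = c_p * Vol_LA / (n_inj * n_ts)` with
  `c_p` = 2e8 per mL,
- cluster volume `V_part = n_ppc * (4/3) pi (d_plat/2)^3` with
  `d_plat` = 3 um,
- cluster diameter `d_p = (6 V_part / pi)^(1/3) = n_ppc^(1/3) d_plat`,
- total mass `m_T = n_plat rho_p (4/3) pi (d_plat/2)^3`
  (`rho_p` = 1550 kg/m^3), flow rate `Q = m_T / t_inj`,
  `t_inj = n_ts * dt`.

Clusters start at the facet centroid with 0.01 m/s directed inward.

## Wall interaction

A worst-case wall-film rule: any trajectory segment crossing the
appendage wall or the device surface attaches the cluster at the impact
point regardless of speed (the impact speed is recorded). Attached
clusters are re-evaluated each step with a Weber-number criterion

$$We = \frac{\rho_p d_p v_t^2}{\sigma_p},$$

with surface tension `sigma_p` = 0.03 N/m and molecular viscosity
`mu_p` = 0.0025 kg/(m s) as the governing platelet properties:
`We > 1` with tangential fluid speed above 0.01 m/s rolls the cluster
along the surface tangent at the local tangential speed capped at
0.2 m/s; a rolling cluster above `16 We_crit` re-suspends; below the
floor it re-attaches. This replaces droplet-specific spray separation
models, which are under-specified for platelet clusters; the threshold
constants are configuration values in `particle_properties()` and are
echoed in all outputs. Clusters crossing the mitral outlet exit; clusters
leaving the domain anywhere else are reflected once at the chamber
surface and frozen on a second offence (counted and reported — the
behaviour in this corner case is a package convention, as no standard
treatment exists).

Count conservation (injected = suspended + attached + rolling + exited)
is asserted at every step of every episode.

## Hemodynamic indices

Over the analysis beat (the second of two, to avoid start-up transients):

- `TAWSS = (1/T) sum |tau(t_i)| dt`,
- `OSI = 0.5 (1 - |sum tau dt| / sum |tau| dt)` (vector accumulation;
  0 = unidirectional, 0.5 = fully reversing; defined 0 at zero shear),
- `ECAP = OSI / TAWSS`, flagged undefined where TAWSS < 1e-9 Pa and
  excluded from summaries with a reported count.

Risk thresholds follow the standard literature values: mean full-cycle
device-surface speed strictly below 0.2 m/s; maximum ECAP strictly above
0.5 1/Pa; platelet adhesion strictly above 10 % of injected clusters at
the end of the second beat; plus a recirculation flag. Region statistics
of wall-shear indices weight elements by area (they are element fields);
velocity statistics weight sample points equally (node-count weighting) —
an intentional asymmetry, since the velocity probes are point samples.

The recirculation score quantifies what is usually judged visually from
streamlines: `1 - |time-mean velocity| / time-mean speed` averaged over
region points (0 steady, 1 fully reversing). The flag requires both a
score at or above 0.5 *and* a mean speed below 0.2 m/s, so a slow but
steady jet is not mislabelled as an eddy. Both constants are
configuration values.

## The synthetic atrium and its flow

The generator's defaults are the study conditions: a 0.88 s beat sampled
at 88 steps (dt = 0.01 s), systole 0–0.30 s, diastole 0.31–0.88 s, two
beats with the second analysed; chamber semi-axes (42, 36, 26) mm giving
a ~164 mL chamber; a 25.6 mm circular ostium; a 30 mm tapering appendage;
4–6 PV tubes with the left superior vein immediately adjacent to the
appendage ostium (their shared fold is the pulmonary ridge); target mesh
edge length 0.68 mm. The transmitral waveform has an E-wave peak
(0.45 m/s at 0.50 s) dominating a reduced A-wave (0.18 m/s at 0.80 s),
the expected pattern in atrial fibrillation; clinical waveforms are not
tabulated anywhere, so the shapes are documented configuration, not a
fidelity claim.

The analytic velocity field superposes:

- a hemispherical sink at the mitral outlet plus an interior drift that
  vanishes at the chamber wall, blended into a uniform plug near the
  outlet cap so the imposed outlet waveform is recovered exactly there
  (verified to 1 %);
- a chamber vortex about the outlet axis (strength 0.5 of the transmitral
  speed at 30 mm radius), tapered off near the outlet;
- parabolic pulmonary-vein inlet jets scaled to balance the outlet flow;
- inside the appendage, ambient flow damped as `exp(-s / 5 mm)` with
  depth `s`, sealed behind the device face, plus a sign-reversing
  breathing cell whose amplitude scales with the exposed
  ostium-to-device gap and the forcing strength. The cell extends into a
  15 mm vestibule in front of the mouth so the exposed appendage
  actually exchanges particles with the chamber. A thin layer in front
  of the device proximal face removes the face-normal velocity
  component (a no-penetration surrogate — the analytic field has no
  solid-body boundary conditions);
- an optional divergence-free stochastic perturbation (four random
  transverse Fourier modes, wavelengths 15–40 mm) with amplitude 5 % of
  the peak transmitral speed, seeded and reported.

**The stasis parameter** (`stasis >= 1`, default 1) models impaired
appendage emptying: it attenuates the emptying half-phase of the
breathing cell by `1/stasis` and damps the ambient sweep in the mouth
vestibule by the same factor at the mouth. Raising it strictly lowers
the device-region mean speed; its effect on adhesion is tested as a
majority criterion over a seed ensemble (stasis 1 vs 4), because
adhesion counts are discrete and individual seeds can differ by a
particle or two.

By construction, a ridge-covering pose (device face at the ostium) sits
in fast ambient flow with the breathing cell suppressed, while a deep
pose (face 12 mm in) sits in damped flow behind an exposed, breathing
wall band — so the covered pose shows a higher device-surface mean
velocity and a lower attached-particle percentage. The end-to-end test
asserts this *ordering only*, never particular values.

**What the generator does not emulate:** patient-specific anatomy
(trabeculations, appendage lobes and bends, true PV antra), wall motion
(the geometry is rigid; mitral-annulus displacement models are out of
scope), Navier–Stokes dynamics (the field is analytic and only
approximately mass-consistent; the stochastic component alone is exactly
divergence-free), non-Newtonian rheology, and device strut/hub detail.
Passing tests therefore demonstrate the correctness and internal
consistency of the measurement and transport machinery, and the
qualitative covered-vs-uncovered contrast — not predictive accuracy on
real patients.

## Device models and measurement conventions

Devices are idealized: a plug is a capped cylinder (nominal diameter =
lobe diameter, default lobe length 0.75 × diameter); a pacifier adds a
distally offset sealing disk at least as wide as the lobe. Hubs, struts,
anchors and the catheter tip are omitted. Deployment is rigid along the
appendage centerline (cross-section centroids at 1 mm arc steps); wall
penetration is reported, not resolved — no contact mechanics.

The pulmonary ridge is *covered* when the distance from the LSPV
endpoint to the device surface is at most 10 mm (inclusive: uncovered
requires strictly more than 10 mm). The uncovered-region area is
operationalized as the appendage-wall band between the ostium plane and
the device proximal face; published analyses describe this region only
qualitatively, so the band is this package's measurable definition.
Landing-zone sizing uses the mean diagonal `d_mean = (d_max + d_min)/2`
(maximum point-pair distance and minimum caliper width of the contour);
the bundled sizing table is a documented package default in the spirit
of manufacturer charts, with boundary values resolving to the larger
size.

## Numerical choices and degenerate inputs

- Linear space-time interpolation, exact at stored nodes and steps;
  gradients are the analytic derivatives of the trilinear interpolant
  (exact for linear fields).
- Phase windows are closed on the sample grid, with the beat-period end
  mapping to the final stored step: systole and diastole partition the
  88-step beat exactly as 31 + 57 samples, and the full-cycle mean is
  exactly their length-weighted combination. (Half-open windows would
  silently drop the 0.30 s sample.)
- Region membership uses signed distances with a 1e-6 mm tolerance;
  degenerate bands (device at depth 0 with the fold on the ostium plane)
  collapse to the device surface alone.
- All-zero transmitral forcing is legal and produces an exactly null
  field; a net-inflow waveform is rejected.
- Zero-shear elements: OSI is defined 0, ECAP is flagged undefined and
  excluded from summaries with a count.
- Self-intersecting contours, non-planar contours (residual > 0.5 mm)
  and fewer than three points are geometry errors.
- Seeds control only the stochastic field perturbation and injection
  ordering; all physics is deterministic, and generators are pure
  functions of (spec, seed).

## Problem sizes used by the tests and the acceptance script

Unit tests run geometry at a 4 mm mesh edge and flows on small grids.
The transport experiments (the two-pose comparison and the stasis
ensemble) use a 3 mm mesh edge (~6000 faces), a 24^3 flow grid over two
beats, and ~1000 injected clusters — sizes chosen so a full episode
completes in tens of seconds on one CPU while keeping the orderings
stable across seeds, which was verified on a five-seed ensemble. The
printed-cohort arithmetic runs on the bundled 20-patient tables and is
instantaneous.

## Known limitations

- The analytic field is divergence-controlled, not divergence-free; mass
  balance between PV inflow and MV outflow is approximate.
- The breathing cell is axial: radial particle migration inside the
  appendage comes only from the damped ambient swirl and the stochastic
  modes, which makes absolute adhesion percentages construction-
  dependent; only orderings are meaningful.
- The Weber roll/detach criterion is a documented substitute for
  proprietary spray-separation models and is not calibrated to platelet
  biophysics.
- Group statistics on the bundled tables inherit the printed rounding;
  standard deviations are recomputed with the sample (n−1) estimator and
  printed sds are not treated as ground truth (the original estimator is
  unstated). Printed values are kept verbatim, including one obvious
  misprint in a standard deviation, which is never used in computation.
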