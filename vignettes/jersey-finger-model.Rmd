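---
title: "A reduced-order neuromuscular model of the jersey finger injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order neuromuscular model of the jersey finger injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jfisim)
```

## The injury and the modelling question

A jersey finger is the avulsion of the deep finger flexor (FDP) tendon from
its insertion on the distal phalanx. The canonical mechanism is a gripping
athlete whose closed fist is forced open by an opponent pulling away: the
finger flexors, contracting near-maximally, are loaded eccentrically while
the grip is pried open, and the tendon insertion — the weakest link of the
muscle-tendon chain — tears off the bone. `jfisim` implements a
reduced-order (planar, rigid-segment) neuromuscular pipeline for this
scenario: Hill-type muscle-tendon units (MTUs) with a piecewise serial
elastic tendon, via-point routing over revolute finger joints, two
calibration stages (routing against moment-arm curves; tendon material
against stress-strain curves), a two-stage grip-and-rod-retraction load
case, and threshold-based injury scoring.

The pipeline reproduces the *structure* of a full finite-element study at
desk scale: its purpose is to expose every modelling stage as tested,
reusable code, not to replicate commercial-solver results digit for digit.

## Muscle-tendon unit model

Each strand is a contractile element (CE) in series with an elastic tendon
(SEE), with a parallel elastic element (PEE) across the fiber and an
optional linear serial damping element (SDE) across the tendon.

**Tendon (SEE).** The force-elongation law is a convex "toe" followed by a
linear branch. With engineering strain $\varepsilon$ on the rest length
$l_{SEE,0}$, transition force $\Delta F_{SEE,0}$ (a fraction of the
strand's $F_{max}$), transition stretch $\Delta U_{SEE,nll}$ and linear
stretch increment $\Delta U_{SEE,l}$:

$$F_{SEE}(\varepsilon) = \begin{cases}
0 & \varepsilon \le 0\\
\Delta F_{SEE,0}\,(\varepsilon/\Delta U_{SEE,nll})^{\nu} &
0 < \varepsilon < \Delta U_{SEE,nll}\\
\Delta F_{SEE,0}\,\bigl(1 + (\varepsilon - \Delta U_{SEE,nll})/
\Delta U_{SEE,l}\bigr) & \text{otherwise,}
\end{cases}$$

with $\nu = \Delta U_{SEE,nll}/\Delta U_{SEE,l}$. The exponent is not a
free parameter: it is the unique choice that makes the force *and* the
stiffness continuous at the transition, which pins down the whole curve
from the three named parameters. The tendon Young's modulus is the
linear-branch slope over the cross-sectional area,
$E = (\Delta F_{SEE,0}/\Delta U_{SEE,l})/CSA$. Two parameter sets matter in
practice: the generic default $(0.4\,F_{max},\,0.0425,\,0.017)$, giving
$E \approx 0.7$ GPa, and the stiff positional-tendon set
$(0.8\,F_{max},\,0.02,\,0.01)$ recovered by `fit_see()`, giving 2.4 GPa.
Finger tendons are positional tendons; the compliant default would let the
forearm muscles contract without moving the fingertip, so the stiff set is
the package default for the hand fixture.

**CE and PEE.** The active force is
$a\,F_{max}\,F_{isom}(l_{CE})\,f_v(v_{CE})$ with a bell-shaped
force-length factor $\exp(-|(\lambda-1)/\Delta W|^{\nu})$
($\lambda = l_{CE}/l_{CE,opt}$) and the classic Hill hyperbola on the
concentric side ($a_{rel} = 0.25$, $b_{rel} = 2.25\,\mathrm{s^{-1}}$); the
eccentric branch is a second hyperbola with plateau $F_{ecc} = 1.5$ and a
slope at zero velocity $S_{ecc} = 2$ times the concentric one. The PEE
engages beyond the optimal fiber length and reaches $0.5\,F_{max}$ at the
end of the descending limb. These constants are documented defaults (the
source tables they would normally come from are not redistributable); all
are overridable per strand.

**Contraction dynamics.** The fiber velocity solves the series force
balance
$F_{SEE} + d_{SE}(v_{MTU} - v_{CE}) =
a F_{max} F_{isom} f_v(v_{CE}) + F_{PEE}$.
`contraction_rate()` solves it with a bracketed root find
($\pm 20\,l_{CE,opt}/\mathrm{s}$, tolerance $10^{-10}$); the simulator uses
the exact per-branch inversion (`fiber_velocity()`, a quadratic per branch
because the Hill law is hyperbolic), and the two are cross-checked to
$10^{-8}$ in the tests. The serial damping (default coefficient
$0.02\,F_{max}/(b_{rel}\,l_{CE,opt})$, about 15 N s/m for a 100 N strand)
matters mostly at very low activation, where the undamped force balance
becomes stiff; it also bounds the fiber velocity when the rod retraction
demands more force than the eccentric plateau provides.

**Initialization.** Every strand starts in a length equilibrium: the fiber
at its optimal length and the tendon rest length absorbing the rest of the
scaled path, $l_{SEE,0} = c_{e,f}\,l_{MTU,i} - l_{CE,opt}$ with
$c_{e,f} = 0.95$ for extensors and $1.05$ for flexors. In the straight
initial posture this leaves flexors slack and extensors briefly taut; the
flexor slack is taken up as the hand flexes into the grip, which is exactly
what lets the fibers operate near their optimum once the grip has formed.
Strands of a multi-tendon muscle split the whole-muscle maximum force
evenly ($F_{max,s} = F_{max,T}/n_s$; the FDP and FDS are four parallel
strands each).

## Hand model and routing calibration

Each digit (index to little finger) is a planar chain of three rigid
phalanges with revolute MCP, PIP and DIP joints — flexion positive, palmar
side at negative $y$, straight finger at zero. Muscles are routed as
polylines through via points fixed in the segment frames; the moment arm
about a joint is the tendon-excursion derivative
$r_j = -\partial L/\partial q_j$ (central difference with
$h = 10^{-6}$ rad in `moment_arm()`; exact analytic gradients inside the
simulator). Two independent oracles guard this identity in the tests: the
perpendicular-distance formula for a chord wrapping a joint, and a
virtual-work check that applies unit tension along the polyline and takes
moments of the nodal forces.

Routing calibration (`optimize_routing()`) adjusts one palmar wrap radius
per crossed joint and digit — the degree of freedom that actually sets the
moment arm — by bounded Levenberg-Marquardt least squares pooled over each
digit's curves, with seeded multi-start. Fit quality is scored with the
mean absolute error normalized to the mean of the measured series (NMAE,
in percent), which is invariant under a common rescaling of both series.
Digits decouple in the planar model, so they are fit separately; the full
flexor topology (FDP over three joints, FDS over two, four digits) yields
exactly 20 curves.

Joint properties: range of motion defaults MCP 0-90°, PIP 0-100°,
DIP 0-80°; passive stiffness 0.01 N m/rad and damping 0.001 N m s/rad
toward the straight rest posture; a 20 N m/rad penalty with 0.01 N m s/rad
extra damping beyond the limits. The ROM penalty damping is kept small on
purpose: the distal phalanx has an inertia of order $10^{-7}$ kg m², and a
larger damping coefficient would make the explicit integrator unstable at
the default step.

## Tendon calibration

`fit_see()` fits the three tendon parameters to a reference stress-strain
curve by bounded least squares on the 0-3% strain window, reporting the
0-5% window alongside. The windows are deliberate: the tendon model has
only a toe and an indefinite linear branch, so it cannot represent the
necking a real tendon shows beyond its linear region — the 0-3% fit is the
honest fit, and the widening gap between the two window scores
(NMAE$_5$ > NMAE$_3$) is reproduced on synthetic necking references. The
objective couples the toe exponent to both stretch parameters and has
several basins; the optimizer therefore multi-starts from a small grid of
candidate transition strains with the transition stress read off the
reference curve. The fit depends on $F_{max}$ and $CSA$ only through the
normalization stress $F_{max}/CSA$; the hand fixture uses 30 MPa, the
value back-derived from requiring the stiff parameter set to give a
2.4 GPa modulus. The synthetic reference generator
(`gen_tendon_reference()`) produces toe/linear/necking curves that lie
exactly in the tendon model family when necking is disabled, enabling
exact parameter-recovery tests.

## The grip-and-retraction load case

The load case (`run_load_case()`) has two stages. In stage 1 (0-100 ms)
the FDP and FDS strands receive a step neural input filtered by
first-order activation dynamics ($\tau_{act} = 10$ ms,
$\tau_{deact} = 40$ ms, floor $a_{min} = 0.005$; extensors stay at the
floor), and the digits close around a rigid rod (100 mm long, 20 mm
diameter) resting in the palm. At 80 ms a tied coupling engages for every
finger node then in contact, emulating the tied contact a full-scale model
uses to keep the reaction forces from prying the grip open. In stage 2
(100-200 ms, skipped for the model-check run) the rod is retracted at
11.615 m/s, reached through a 1 ms linear ramp standing in for the
unavailable retraction velocity profile; the ties stretch and release at a
5 mm breakaway elongation, after which only unilateral contact acts and the
rod eventually slips free.

Numerics, all chosen for an explicit fixed-step integrator at
$dt = 2\times10^{-5}$ s (4th-order Runge-Kutta, activation updated by its
exact exponential step between integration steps):

* Contact is a penalty normal force ($10^5$ N/m, 50 N s/m) between finger
  surface nodes (two per phalanx, 4 mm pad radius) and the rod circle.
* Friction ($\mu_s = 0.4$, $\mu_d = 0.3$) inside the integrator is
  *elastic-anchor* Coulomb friction: a tangential spring
  ($2\times10^4$ N/m) from a per-node stick anchor that slips between
  steps whenever the spring force exceeds the dynamic cone. A
  velocity-regularized law, the natural first choice, turns the stick
  phase into a viscous term whose gain exceeds the explicit stability
  limit at this step size and chatters; the displacement-regularized form
  holds static friction exactly and is stable. The stateless
  `contact_force()` helper retains the velocity-regularized law for
  single-point queries.
* Chain dynamics use the exact planar mass matrix per digit (segment
  linear density 0.4 kg/m); velocity-product terms are neglected — finger
  segments are light and joint, contact and tie damping dominate at the
  speeds of interest. Halving the step changes a 100 ms motion by less
  than $10^{-4}$ rad.
* Rod motion is prescribed (kinematic); gravity is off (the forearm is
  fully constrained).

With the stiff tie the grip is genuinely quasi-static at the end of
stage 1: net joint torque residuals fall below $10^{-3}$ N m in the
model-check run. During stage 1 the grip *creeps* — point contacts on a
smooth rigid rod cannot statically hold the fingertip torques, so the
distal joints slide slowly into a deeper wrap until the tie freezes the
configuration at 80 ms; this is a real property of the reduced geometry,
not a numerical artifact.

## Protocol, effectiveness and injury scoring

`run_protocol()` executes eight retraction runs on the activation grid
0, 20, 40, 60, 70, 80, 90, 100% plus the 100% no-retraction model check.
Per run, the activation effectiveness is
$\eta_a = \bar F_{MTU,f,a}/\bar F_{max,f}$: the mean over FDP/FDS strands
of each strand's peak force in the grip window, over the mean of their
maximum isometric forces.

Injury scoring (`assess_run()`): tendon avulsion when the strand force
reaches 105.91 N — the lowest experimentally reported avulsion load,
10.8 kg, converted with standard gravity 9.80665 m/s² (9.81 would give
105.95 and miss the printed value) — applied per strand because the
underlying experiments loaded single insertions; tendon strain grades at
4/8/10% strain (start of strain hardening, start of necking, failure) on
the tendon rest length; and a muscle strain criterion with the same
grading semantics on fiber strain, which ships *without* default
thresholds and is only evaluated when a triple is configured, to avoid
inventing numbers its source does not print here. All crossings are
inclusive ($\ge$), the conservative reading of a threshold being
"crossed".

Under the shipped study conditions the protocol reproduces the expected
structure, which the acceptance tests assert: $\eta_a$ strictly increasing
in activation; no injuries at low activation; first injuries appearing at
high activation and growing monotonically in count; every triggered injury
an avulsion (the stiff tendon transmits threshold-level forces at roughly
2-3% strain, far below the 4% minor grade), and the model check injury
free. The *identity* of the first injured strand and the exact
effectiveness percentages depend on the synthetic geometry and are not
asserted.

## What the synthetic data do and do not establish

The generators stand in for three literature inputs that cannot be
redistributed: moment-arm compilations (smooth, mildly angle-dependent
curves; the FDP-MCP mean anchored at 9.7 mm with an optional 2.0 mm
scatter), tendon stress-strain measurements (2.4 GPa linear modulus,
toe/linear/necking stages), and whole-muscle parameter tables (FDP 400 N,
FDS 380 N, one 160 N extensor group, split over four strands; optimal
fiber lengths 9 cm for the flexors with a widened ascending limb
($\Delta W_{asc} = 1$), reflecting the long excursion range the lumped
forearm flexors must cover in this fixture). All fixture values are
synthetic and flagged as such. Passing tests therefore demonstrate
internal consistency — parameter recovery on noise-free references,
correct threshold arithmetic, the qualitative activation-injury
relationship — not agreement with any particular cadaver dataset. Noise is
additive, independent per sample; real measurement error is smoother and
partly systematic, so recovery under the synthetic noise is a best case.

## Known limitations

Planar digits without abduction, pulleys, soft tissue or inter-digit
contact; a fixed metacarpal base throughout (the full-scale model fixes
the forearm only after gripping); lumped per-digit extensors; no fiber
architecture (pennation), no activation nonlinearity beyond first-order
dynamics, and no tendon creep, fatigue or plasticity — the strain
criterion grades peak strain only. The rod replaces the jersey fabric, so
loads release cleanly once the rod slips free; fabric that catches on the
fingers would load the tendons longer and harder.
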