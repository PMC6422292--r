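---
title: "Lumbar loads from sagittal spinopelvic alignment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lumbar loads from sagittal spinopelvic alignment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinoload)
```

## The question

Clinicians describe sagittal spinal alignment with a handful of radiographic
parameters: the sagittal vertical axis (SVA, the horizontal offset of the C7
plumb-line from the posterior-superior corner of the sacral endplate), the
Roussouly lumbar type (RT1–RT4, a taxonomy of healthy lordosis shapes), the
sacral slope (SS), and the pelvic incidence (PI, with the identity
PI = SS + PT linking it to pelvic tilt). `spinoload` asks a biomechanical
question about these parameters: *how do they shape the forces transmitted
through the lower lumbar spine and the trunk muscle forces needed to stand
still?*  The package builds a sagittal-plane rigid-body model of a standing
adult, imposes every combination of the four parameters over their healthy
ranges (2772 configurations in all), solves the static muscle-recruitment
problem in each posture, and reports the intersegmental force at L4L5 and
L5S1 decomposed into axial compression and anterior shear, together with
grouped muscle forces (multifidus, erector spinae, rectus abdominis).

## The mechanical model

### Posture construction

Everything lives in the sagittal plane: x anterior, y up, metres; angles in
degrees with flexion (anterior rotation of the superior end) positive, so an
extended vertebra has a negative inclination.  A posture is assembled in the
order SS, PI, RT, SVA:

1. **Sacral slope.** The sacrum-pelvis is one rigid segment whose built-in
   endplate inclination is 30°; the target slope is realised by rotating the
   whole segment about the L5S1 joint by `SS − 30` (so SS 40° is a 10°
   anterior rotation).  Every point fixed to the segment — the endplate
   corners, the pubic region, the sacral muscle attachments — rotates with
   it.  This rotation is the mechanism by which SS reaches the load
   predictions: it changes the extensor and flexor lines of action, not the
   lumbar chain itself.
2. **Pelvic incidence.** The hip joint centre sits a fixed 9 cm below the
   endplate midpoint and is shifted horizontally until the angle between the
   caudal endplate normal and the midpoint-to-hip line equals the target:
   `x = drop · tan(PI − SS)`.  Nothing above the hip moves, and no muscle
   attachment moves with it, so PI cannot influence any suprapelvic load —
   the model makes the study's null result exact by construction, and the
   sweep verifies it numerically rather than assuming it.
3. **Lumbar type.** Each lumbar vertebra carries a fixed world-frame
   inclination per type (e.g. RT1: L1..L5 = −17, −22, −27, −19, −8; RT4 has
   a strongly flexed L5 at +30).  Joints are chained caudally from L5S1
   with 3.5 cm joint-to-joint links.  Because the orientations are
   world-frame constants, the lumbar geometry of a type is identical at
   every SS, PI and SVA — a property the tests assert.
4. **Sagittal vertical axis.** The thorax (T12 to C7 plus ribcage, one
   segment, 42 cm) rotates about T12L1 until the C7 plumb-line offset to the
   posterior-superior sacral corner equals the target SVA.  The offset is
   strictly monotone in the rotation, and the solve is a bracketed 1-D root
   find (±45°, tolerance well below 10⁻⁶ cm).  The head counter-rotates to
   keep a horizontal gaze, and the arms hang plumb from the shoulders, so
   they enter as vertical loads at the shoulder's horizontal position.

Lumbar lordosis is not imposed; it is measured between T12 and S1 as
`LL = SS − T12 inclination`, where the T12 endplate inclination is the
thorax rotation plus a configurable offset (default −8°, standing for the
slope of the lowest thoracic vertebra inside the lumped segment).

### Mass distribution

The default body is 1.76 m and 75 kg.  Segment masses are fractions of the
total (head+neck 8.1 %, arms 10 %, thorax 21.6 %, five lumbar slices of
2.76 % each, pelvis and legs the remainder); the fractions must sum to one
to within 10⁻⁹ or the chain refuses to build.  Each lumbar "vertebra" is
really a trunk slice — bone plus viscera and abdominal wall — so its centre
of mass lies 3–4 cm anterior of the segment midpoint; the thorax COM sits
4 cm anterior of the spine line, the shoulders 5 cm.  These anterior offsets
matter: they set the sign of the gravity moment at each lumbar joint, and
through it the whole muscle-activation pattern.  All of them are editable
constants (`default_constants()`, or a YAML file via `read_constants()`),
and the robustness analysis jitters every one of them.

### Muscle set

The real lumbar musculature (the full model this package simplifies counts
188 fascicles) is lumped into 18 straight-line sagittal actuators, bilateral
pairs summed, in four groups:

* **multifidus** — five fascicles fanning out from the dorsal sacrum to each
  lumbar level (each spanning every joint between the sacrum and its
  vertebra) plus six deep single-joint fascicles (rotatores-like, with a
  stronger semispinalis-like element at T12L1).  Posterior offsets ≈ 3.5 cm.
* **erector spinae** (longissimus; the two names are used interchangeably) —
  one strong actuator from the sacrum to the posterior mid-thorax crossing
  every lumbar joint.  Its moment arms grow cranially (≈ 4 cm at L5S1 to
  ≈ 10 cm at T12L1) and, critically, grow with SS as its sacral origin
  rotates posteriorly.
* **rectus abdominis** — one flexor from the pubic region to the lower
  thorax with ≈ 8–10 cm anterior arms (the straight line stands for the
  abdominal-wall path).
* **psoas major** — five per-vertebra flexor fascicles running to the
  pelvis with small (≈ 1.5–3 cm) anterior arms.

Why this set and not something smaller?  A minimal set (per-joint extensors
plus one global flexor) turns out to be *uncontrollable* in the directions
this study exercises: the cubic recruitment criterion then produces large
antagonistic co-contraction whenever the demanded moment profile across the
six joints does not match any single muscle's arm profile, and the predicted
loads jump discontinuously along the SS axis.  The nested sacrum-anchored
families mirror how the anatomy solves the same problem — fascicles
reaching each level individually — and restore smooth, plausible recruitment.
They also carry the study's slope mechanism: with most extensor force
anchored on the sacrum, increasing SS lengthens every extensor moment arm,
lowering extensor force and with it the anterior shear projected at L4L5.
The set must leave every lumbar joint with at least one extensor and one
flexor crossing it; this solvability invariant is checked at construction
and under every anthropometric perturbation.

Abdominal pressure exists as a stub (an optional additive extension moment
per joint) and is **off** by default; every result in this package assumes
it off.

### Static recruitment

In each posture the gravity loads of all segments above a joint produce a
net flexion-positive moment there (six joints: T12L1 to L5S1).  Muscle
tensions must balance these moments exactly:

$$\min_{f \ge 0}\; \sum_i \left(\frac{f_i}{S_i}\right)^p
\quad\text{s.t.}\quad \sum_i r_{ji}\, f_i = M_j \;\; \forall j,$$

with extension-positive arms \(r_{ji}\) (signed perpendicular distances from
the joint to the line of action), strengths \(S_i\), and the polynomial
criterion power \(p = 3\) by default (exposed as a solver constant; any
\(p > 1\) gives a strictly convex problem with a unique minimiser).  Planar
hinge joints carry no moment, so moment balance is the only constraint;
force balance then *determines* the joint reaction.  The solver is a
primal-dual interior-point iteration followed by an active-set Newton
polish, which clamps vanishing fascicles to exactly zero and drives the
moment residual to machine precision (the contract is ≤ 10⁻⁶ N·m; achieved
residuals are ~10⁻¹⁵).  Activations above 1 are allowed with a warning
rather than capped — the default model never warns in any of the 2772
standing postures, but strongly jittered bodies occasionally do.  The test
suite checks the solver against closed-form cases (a single extensor must
carry \(M/r\); two equal synergists split evenly; two synergists of unequal
strength split as \((S_1/S_2)^{p/(p-1)}\)) and against a brute-force grid
search on randomly generated small programs.

### Outputs

The reaction transmitted to the element below a level is the superincumbent
gravity plus the pull of every crossing fascicle on the upper free body; in
standing it points caudally.  At L4L5 it is projected on the axis through
the two joints of L5 (axial, caudal) and its +90° orthogonal (anterior,
parallel to the upper endplate of L5); at L5S1 on the sacral-endplate
frame at the configuration's SS.  Compression and shear are reported
positive.  Because the L4L5 frame is fixed per type while the L5S1 frame
follows SS, the two frames diverge by |SS − L5 inclination| — up to 43° in
RT1 at SS 35°, 23–26° in the other types — which is why similar force
vectors can produce very different anterior shears at the two levels, and
why the L5S1 shear grows with SS (a near-vertical load projects onto an
endplate tilted further below the horizontal).

## What the sweep shows

Running `analysis/02_run_sweep.R` and `analysis/03_aggregate_tables.R`
reproduces, on this simplified model, the study's qualitative findings —
each of them is asserted by the acceptance test suite over the full grid:

* **PI changes nothing.** All outputs are bit-identical across the 21-point
  PI grid of every (RT, SS, SVA) stratum.
* **Balance dominates.** The frontward-imbalanced condition always
  compresses L4L5 more than the balanced one, and the erector spinae force
  orders front > med > back in every configuration.
* **The flexor side switches on only in backward imbalance.** The rectus
  abdominis is exactly zero in every frontward posture and in balanced
  posture for RT1–RT3, and strictly positive in every backward posture
  (its backward-posture force also grows RT1 → RT4, as the backward SVA
  targets grow).
* **Slope steers shear.** At each type's central PI, the anterior shear at
  L4L5 is lower, and at L5S1 higher, at the maximal slope than at the
  minimal one, in all four types and all three balance conditions.

Absolute Newton values depend on the lumped geometry and are model-specific;
the package reports them (medians over each SS × PI grid fall in the few
hundred newton range at both levels) but makes no claim that they match any
particular reference model, and no test asserts them.  The deep-extensor
group force in particular is larger than a fascicle-resolved model would
report, because the lumped multifidus group absorbs work that finer models
distribute over many short fascicles.

## The parameter sampler and what passing tests mean

`sample_params()` draws random design points (type by weight, SS and PI
uniform on the integer-degree grid inside the type's range, balance
condition uniform) and `perturb_anthropometry()` jitters every length,
offset, strength and mass fraction by an independent uniform factor within
±jitter (≤ 0.2), renormalising the mass fractions.  The robustness analysis
(`analysis/04_robustness.R`, mirrored by the last acceptance test) re-checks
every finding above under 20 such bodies at jitter 0.1, on a PI-reduced grid
(minimal, central, maximal PI per type — 396 configurations per body; the
full PI axis adds information only to the invariance check, which the
reduced grid already exercises).  During development the same check was run
under 40 seeds.  What this does *not* show: the generator samples the
printed parameter ranges independently, so it cannot tell how the findings
behave under the parameter interdependence of real subjects, nor under
bodies outside the ±10 % envelope, nor in non-standing poses.

## Numerical choices and degenerate inputs

* Strict range checking on SS and PI is on by default and can be disabled
  (`strict = FALSE`) for exploratory use outside the design ranges.
* The SVA root-find brackets at ±45° thoracic rotation and reports the
  achievable SVA interval when a target is out of reach; a PI with
  |PI − SS| ≥ 90° is unreachable by a horizontal hip shift and errors.
* Coincident fascicle attachments and coincident L5 joints are degenerate
  geometry errors; non-orthonormal projection axes are rejected.
* The recruitment solver errors (naming the joint) when a joint's demand
  has no muscle with an arm of the needed sign, and errors with
  diagnostics if the residual contract cannot be met; a zero-demand
  problem short-circuits to exactly zero forces.
* Medians of even-count cells use the midpoint of the two central order
  statistics (the full grid's cells are odd-sized, filtered runs need not
  be).

## Known limitations

Sagittal plane only; hinge joints without disc stiffness or facets; a rigid
thorax (which exaggerates wedge angles at the thoracolumbar junction);
straight-line muscle paths without wrapping; no force-length or passive
properties; abdominal pressure off; gravity 9.81 m/s² on a single default
anthropometry.  These match the scope of the study the package re-examines;
the constants file is the intended lever for anyone wanting to push beyond
it.
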