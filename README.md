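# spinoload

Static musculoskeletal simulation of how sagittal spinopelvic alignment
shapes lumbar spine loading in standing.

Clinicians summarise sagittal alignment with four radiographic parameters:
the **sagittal vertical axis** (SVA — horizontal offset of the C7 plumb-line
from the posterior-superior corner of the sacral endplate), the **Roussouly
lumbar type** (RT1–RT4, four healthy lordosis shapes), the **sacral slope**
(SS) and the **pelvic incidence** (PI, tied to pelvic tilt by PI = SS + PT).
Altered lumbar loads are implicated in disc herniation, vertebral fracture,
spondylolisthesis and low back pain, but internal forces cannot be measured
non-invasively — they have to be modelled.  `spinoload` builds a
sagittal-plane rigid-segment model of a standing 1.76 m / 75 kg adult
(sacrum-pelvis, five lumbar vertebrae, lumped thorax, head and arms; 18
lumped trunk-muscle actuators), imposes any combination of the four
parameters, and solves the inverse-statics muscle-recruitment problem

$$\min_{f \ge 0} \sum_i (f_i/S_i)^3 \quad \text{s.t.} \quad R f = M,$$

the cubic polynomial activation criterion under exact moment equilibrium at
every lumbar joint (T12L1…L5S1).  From the recruitment it extracts the
intersegmental force at L4L5 and L5S1, decomposed into **axial compression**
and **anterior shear** in endplate-aligned frames, plus grouped muscle
forces for the multifidus, erector spinae and rectus abdominis.  A batch
runner sweeps the full healthy design grid — SS and PI in 1° steps over each
type's range crossed with three balance conditions (SVAback / SVAmed /
SVAfront), 2772 configurations — and aggregates median-and-range tables.

## A worked example

```r
library(spinoload)

params  <- spinopelvic_params("RT1", ss = 25, pi = 40, sva_condition = "med")
result  <- simulate_configuration(params)
round(as.data.frame(result)[c("ll_deg", "fl4l5c", "fl4l5s",
                              "fl5s1c", "fl5s1s", "f_mf", "f_es", "f_ra")], 1)
#>   ll_deg fl4l5c fl4l5s fl5s1c fl5s1s   f_mf  f_es f_ra
#> 1   24.4  659.8    -15  585.6    358 1142.4 205.8    0
```

A balanced (SVAmed) flat-back posture: T12–S1 lordosis of 24.4°, about
660 N of axial compression at L4L5 and 586 N at L5S1.  The anterior shear
differs sharply between the neighbouring levels (−15 N vs 358 N) because the
L4L5 frame follows the nearly vertical L5 body while the L5S1 frame follows
the sacral endplate, 33° apart here (up to 43° at SS 35° in RT1).  The
extensors work (erector spinae 206 N plus the lumped deep-extensor group)
while the rectus abdominis is exactly silent — the flexor side only switches
on in backward-imbalanced postures.

The analysis scripts run the paper-scale studies and write their tables
under `results/`:

```sh
Rscript analysis/01_geometry_angles.R   # wedge & projection-axis geometry
Rscript analysis/02_run_sweep.R         # full 2772-configuration sweep
Rscript analysis/03_aggregate_tables.R  # median (range) load & muscle tables
Rscript analysis/04_robustness.R        # findings under 20 jittered bodies
```

Across the sweep: PI leaves every output unchanged (the hip shift moves no
suprapelvic mass or muscle point); frontward imbalance always compresses
L4L5 more than balance, with the erector spinae ordering front > med > back
everywhere; the rectus abdominis activates only in backward imbalance (and
mildly in balanced RT4); and a steeper sacral slope lowers the anterior
shear at L4L5 while raising it at L5S1 in every type and condition.
`vignettes/spinopelvic-loads.Rmd` documents the model, its assumptions and
the reasoning behind every constant.

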