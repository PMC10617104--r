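# uclga

Computer-aided measurement of **myometrial infiltration (MI) depth** for
early endometrial cancer staging on sagittal image slices.

Early endometrial cancer is staged FIGO IA or IB by how deeply the tumor has
invaded the muscular uterine wall (the myometrium): invasion of less than
half the wall thickness is IA, half or more is IB. On a sagittal slice this
is a geometric question — how far does the tumor reach from the uterine
cavity toward the outer uterine boundary, relative to the local wall
thickness? `uclga` answers it from a segmentation mask alone:

1. **Ellipse fit.** The uterine contour is fitted with the direct
   least-squares method: minimize the algebraic distance of the general conic

   *a x² + b x y + c y² + d x + e y + f = 0*

   subject to the ellipse-specific constraint *4ac − b² = 1*, solved by the
   numerically stabilized block decomposition (quadratic/linear coefficient
   split, reduced 3×3 eigenproblem) with mandatory point pre-normalization.
2. **Uterine cavity line (UCL).** The fitted ellipse's major-axis chord,
   clipped to the uterus mask, stands in for the collapsed uterine cavity —
   the presumed inner edge of the myometrium.
3. **Perpendicular rays.** From each of 200 sample points on the UCL, rays
   are cast along both unit normals in 0.25-px steps until they exit the
   uterus. Per ray, *n* is the distance to the exit (local wall thickness)
   and *m* the distance to the farthest tumor tissue before the exit.
4. **MI depth and stage.** *R* = max *m/n* over all rays; stage IA if
   *R* < 0.5, IB otherwise.

Around that core the package provides the full desk-scale pipeline: a
synthetic **phantom generator** (elliptical or banana-shaped uteri with a
known cavity line and a tumor infiltrating to a controlled fraction *f* of
the wall), detection-confidence **slice selection** with CAD1/2/3 accuracy
scoring, invertible **crop/letterbox transforms** (256×256 segmenter frame,
gray-128 padding; 512×512 detector frame), pluggable detector/segmenter
**backends** (ground-truth oracles and an intensity-threshold segmenter),
and the **evaluation statistics**: IoU / pixel accuracy / Dice, average
precision at a box-IoU threshold, confusion statistics with IA as the
positive class, ROC/AUC, and the DeLong paired-AUC test.

## Worked example

```r
library(uclga)

# a phantom whose tumor infiltrates exactly 30% of the wall
spec <- phantom_spec(uterus_center = c(256, 256), semi_axes = c(150, 80),
                     orientation = 0.3, infiltration_fraction = 0.30, seed = 7)
case <- make_phantom(spec)

ucl <- generate_ucl(case$mask)
print(ucl$geometry)
#> Ellipse: center (256.000, 256.000), semi-axes (149.538, 79.565), orientation 0.2999 rad

mi <- measure_mi(case$mask, case$mask, ucl)
print(mi)
#> MI depth R = 0.307 -> stage IA (argmax ray at (314.1, 274.0), side +1, m = 22.38, n = 72.88)
```

The fitted ellipse recovers the constructed geometry (axes 150/80, angle
0.3), and the measured depth 0.307 recovers the constructed infiltration
fraction 0.30: the deepest ray found 22.4 px of tumor in a 72.9-px wall.

Diagnostic statistics use stage IA as the positive class:

```r
cs <- confusion_stats(tp = 18, fn = 4, fp = 2, tn = 22)
sprintf("ACC %.1f%%  SEN %.1f%%  SPE %.1f%%", cs$acc*100, cs$sen*100, cs$spe*100)
#> "ACC 87.0%  SEN 81.8%  SPE 91.7%"
```

A whole simulate → run → evaluate round trip is available as R functions
(`cmd_simulate`, `cmd_run`, `cmd_evaluate` driven by a YAML `run_config`)
or from the shell:

```sh
Rscript inst/cli/uclga.R simulate --config cfg.yaml
Rscript inst/cli/uclga.R run      --config cfg.yaml --backend threshold
Rscript inst/cli/uclga.R evaluate --config cfg.yaml
```

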