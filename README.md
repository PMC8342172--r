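# symseg

Symmetry- and edge-constrained level-set segmentation of 2-D grayscale
images, built for bilaterally symmetric targets such as the tongue body in
computer-aided tongue diagnosis.  Tongue images are hard for classical
active contours: the tongue's colour is close to the surrounding lips and
skin (weak gradients), the surface carries speckle and coating, and a
median crack can split the gradient map.  `symseg` addresses this by
combining three ingredients:

1. **Edge-probability stop function.**  The contour's driving forces are
   gated by `g = 1 / (1 + (gain * E)^2)`, where `E` is a per-pixel edge
   probability in `[0, 1]` — either a precomputed map (e.g. the output of a
   learned boundary detector, loaded from file) or a classical fallback,
   the rescaled magnitude of the Gaussian-smoothed image gradient.

2. **Distance-regularized level-set evolution (DRLSE).**  The contour is
   the zero level of a field `phi` evolved by forward Euler on

   `d(phi)/dt = mu div(d_p(|grad phi|) grad phi)
              + lambda delta_eps(phi) div(g grad phi / |grad phi|)
              + alpha g delta_eps(phi)`

   with the double-well potential `p` keeping `|grad phi| = 1` near the
   interface (no reinitialization), a smoothed Dirac `delta_eps`
   restricting the forces to a band around the contour, and `alpha < 0`
   expanding an initial circle placed inside the target.

3. **Reflection-symmetry constraint.**  A symmetry axis is detected
   automatically (edge-mass centroid + Harris-corner tip search + a
   mirror-correlation refinement); the energy gains the term

   `S = eta * sum( H_eps(-phi) g - reflect(H_eps(-phi) g) )^2`

   penalizing contours whose edge-weighted inside-indicator differs from
   its mirror image across the axis.  Its descent direction
   `4 eta delta_eps(phi) g (H_eps(-phi) g - reflect(...))` holds back
   boundary leaks through one-sidedly weak edges by referencing the intact
   side.

The initial contour is a circle centred on the axis midpoint and inscribed
in the detected edge ring.  The package also ships the four standard
overlap metrics (precision, recall, F1, IoU with reference-normalized
confusion fractions), a seeded generator of tongue-like phantoms with
ground-truth masks, apexes, axes and edge maps (presets: `clean`,
`low-contrast`, `speckle`, `crack`, `weak-side`), and a small CLI.

## Worked example

```r
library(symseg)

ph  <- phantom_suite("weak-side", 1, seed = 7)[[1]]   # one side's edges at 20%
seg_d <- segment_image(image = ph$image, edges = ph$edges,
                       params = evolution_params(mode = "drlse"))
seg_s <- segment_image(image = ph$image, edges = ph$edges)  # default: sct mode
round(c(drlse = mask_iou(seg_d$mask, ph$mask),
        sct   = mask_iou(seg_s$mask, ph$mask)), 4)
#>  drlse    sct
#> 0.7442 0.8391
print(seg_s$axis)
#> symmetry axis: -44.48*x + 1.762*y + 2595 = 0
#>   centroid (60.74, 60.63), tip (62.50, 105.11), midpoint O (60.85, 63.50)
segmentation_metrics(seg_s$mask, ph$mask)
#> # A tibble: 1 x 8
#>      TP      FN    FP  prec  reca    F1   IoU degenerate
#>   <dbl>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1 0.999 0.00142 0.190 0.840 0.999 0.912 0.839 FALSE
```

Plain DRLSE leaks through the attenuated side (IoU 0.74); the symmetry
constraint references the strong side across the detected axis and
contains the leak (IoU 0.84).  On clean phantoms both modes agree and
reach IoU ≈ 0.98.

Command line (after install):

```sh
Rscript inst/cli/symseg.R synthesize --preset clean --n 5 --seed 1 --out phantoms/
Rscript inst/cli/symseg.R segment phantoms/clean_01_seed7920_image.png \
    --edge-map phantoms/clean_01_seed7920_edges.png --out results/
# masks are paired across the two directories by identical filename
Rscript inst/cli/symseg.R evaluate pred_masks/ ref_masks/ --out metrics.csv
```

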