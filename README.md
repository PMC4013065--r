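# phenorosette

Quantitative phenotyping of *Arabidopsis* rosettes from top-down
photographs, for researchers comparing natural accessions (ecotypes) or
mutants across a growth time course. Young rosettes grow flat, so a
single overhead image per plant per date captures most of the shape
information; the hard part is turning those images into defensible
statistics. This package implements the full chain:

1. **Segmentation** — nearest-neighbour RGB colour classification
   against user-picked foreground/background exemplars, morphological
   opening (disc erosion + dilation), and a pot-region filter; masks are
   calibrated in mm via a pixels-per-mm scale factor from an internal
   length reference.
2. **Shape descriptors** — twenty 2-D morphometric descriptors per mask:
   area, outer and hole-inclusive boundary lengths, convex-hull
   perimeter/area, compactness (area / hull area), roundness
   (circumference²/area, minimised at 4π by a disc), axis-aligned and
   minimal rotated bounding boxes, minimal enclosing circle, maximum
   diameter, centroid-to-boundary distance, principal-axis statistics
   and the normalised moment of inertia.
3. **Growth** — relative rosette area growth rate between consecutive
   imaging dates, `RRAGR = (ln A₂ − ln A₁)/(t₂ − t₁)` (day⁻¹), reported
   at the interval midpoint.
4. **Statistics** — natural-log transform policy for size-like
   descriptors, Bonferroni outlier screening on studentized residuals,
   and per descriptor the longitudinal mixed model

   `y ~ ecotype + das (+ das²) + ecotype:das + (1 | plant)`,
   AR(1) errors within plant (REML, `nlme`),

   with Wald-F effect tests, all-pairs ecotype/date contrasts with
   Bonferroni adjustment and `ns` / `<0.05` / `<0.01` tiers, scaled
   per-time-point PCA, and multi-class ReliefF feature ranking.
5. **Synthetic data** — a rosette renderer (elliptical leaves at
   phyllotaxis angles, exponential growth) and a descriptor-table
   generator that is the exact generative twin of the mixed model
   (default design: 19 ecotypes × 12 replicates × 5 dates), so the whole
   pipeline is testable without any original images.

See `vignettes/rosette-phenotyping.Rmd` for the model details, the
geometric conventions (pixel-union areas, corner-based hulls,
simplified-contour perimeters) and the reasoning behind every default.

## Worked example

```r
library(phenorosette)

## render a synthetic rosette and extract its descriptors
m <- render_rosette(rosette_params(), seed = 1)
m
#> <binary_mask> 256 x 256 px, 5874 foreground px, 4 px/mm
round(unlist(extract_descriptors(m)[c("area", "compactness",
        "circumference", "maxdiam", "roundness")]), 3)
#>          area   compactness circumference       maxdiam     roundness
#>       367.125         0.619       181.698        30.718        89.926
```

367 mm² of leaf area; compactness 0.62 (the rosette fills 62 % of its
convex hull — petioles and gaps account for the rest); roundness 89.9,
far above the disc minimum 4π ≈ 12.57, as expected for a lobed outline.

```r
## growth rate from an area series (mm^2) at 17/22/25/28/30 DAS
rragr(c(17, 22, 25, 28, 30), c(120, 210, 300, 420, 520))
#>   mid_das  rragr
#> 1    19.5 0.1119
#> 2    23.5 0.1189
#> 3    26.5 0.1122
#> 4    29.0 0.1068
```

The plant roughly quadruples its area over 13 days — a relative growth
rate near 0.11 day⁻¹ throughout.

```r
## simulate a 6-ecotype study with planted offsets, analyse log(area)
tab <- simulate_descriptor_table(table_effect_spec(n_ecotypes = 6,
         n_reps = 8, eco_offsets = seq(-1.5, 1.5, length.out = 6),
         seed = 1))
fit <- fit_lme(apply_transforms(tab), "area")
fit
#> <lme_result> area ~ ecotype * das + das^2 | AR(1) phi = 0.526
#>        effect numDF denDF         F            p
#> 1     ecotype     5    42  5.656505 4.486152e-04
#> 2        time     2   185 97.094305 1.476628e-29
#> 3 interaction     5   185  1.302671 2.646077e-01

pw <- tukey_pairwise(fit, "ecotype")
head(pw[order(pw$p_adjusted), c("contrast", "estimate", "p_adjusted",
                                "tier")], 3)
#>     contrast   estimate  p_adjusted  tier
#> 5  E01 - E06 -0.6015800 0.004099064 <0.01
#> 9  E02 - E06 -0.5131405 0.023047931 <0.05
#> 12 E03 - E06 -0.4986637 0.030232958 <0.05
```

The planted ecotype and time effects are recovered (P < 0.001), the
fitted within-plant autocorrelation (0.53) is close to the simulated
0.6, and the most separated ecotype pair (E01 vs E06, planted 3 SD
apart, here ≈ 0.60 log-units ≈ a 1.8-fold area difference) lands in the
`<0.01` tier after Bonferroni adjustment over all 15 contrasts.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "rosette", package = "phenorosette"))')
$CLI segment  --image plant.png --fg-samples fg.csv --bg-samples bg.csv \
              --erode 1 --dilate 1 --px-per-mm 7.31 --out mask.png
$CLI extract  --mask mask.png --px-per-mm 7.31 --plant-id p1 \
              --ecotype Col-0 --das 17 --out table.csv
$CLI growth   --table table.csv --out rragr.csv
$CLI stats    pca --table table.csv --das 17
$CLI simulate table --seed 1 --out synthetic.csv
```

Every invocation writes a JSON run manifest (command, parameters, seed,
input/output checksums) next to its output. A YAML/JSON `--config` file
can hold any flag; explicit flags win.

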