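# branchmorph

Quantitative morphometrics for 2D images of complex-shaped branching
organisms — the motivating case is pinnately branching thalloid
liverworts, but any flat, indeterminate branching form (root systems,
bryophytes, encrusting colonies) fits. Given a raster of a single
specimen on a contrasting background, the package binarizes it,
reduces it to a single-pixel skeleton by Zhang–Suen thinning, builds a
skeleton graph G = (V, E) of junctions and terminals traversed
depth-first from a root terminal, and quantifies six morphological
variables:

| symbol | variable           | definition |
|--------|--------------------|------------|
| da     | junction thickness | 2 × EDT at the branch-point disc centre |
| db     | branch thickness   | diameters of successive non-overlapping discs along each branch |
| dc     | terminal thickness | 2 × EDT at each skeleton tip |
| bl     | branch length      | skeleton arc between consecutive vertices (pixel count and chord also reported) |
| ba     | branch angle       | opening between the two daughter branches of a junction (degrees) |
| bs     | terminal spacing   | distance from each tip to its nearest other tip |

EDT is the exact Euclidean distance transform, so thicknesses are local
specimen widths. Loops caused by overlapping branches are detected
(cycle-space rank E − V + C), reported with coordinates, and can be
resolved with an explicit one-pixel-gap edit (`break_loop()`).

A statistics layer discriminates predefined groups from a per-specimen
measurement table: per-variable one-way ANOVA with Tukey pairwise
comparisons, Pearson correlation matrix, MANOVA with Wilks'
Λ = det(W)/det(W+B), and canonical discriminant analysis — the
eigenstructure of W⁻¹B with min(g−1, p) functions, canonical
correlations √(λᵢ/(1+λᵢ)), per-function Wilks tests (Rao's F), raw and
standardized coefficients, group means on the canonical variables, and a
nearest-group-mean classification matrix.

A synthetic thallus generator (`generate_thallus()`) renders tapered,
round-capped branching specimens with exact analytic ground truth
(including the crotch geometry and thinning-retraction terms an ideal
skeleton measurement would see) so the whole pipeline is validated by
parameter recovery rather than by eye.

## Worked example

```r
library(branchmorph)

# a synthetic pinnate thallus with known geometry, 0.02 mm per pixel
spec <- thallus_spec(depth = 2, branch_length = 60, branch_angle = 110,
                     width_junction = 15, width_branch = 11,
                     width_terminal = 7, seed = 1)
th <- generate_thallus(spec, pixel_scale = 0.02)
ms <- measure_thallus(th$image, id = "synthetic-thallus")
ms
#> <thallus_measurements> 'synthetic-thallus'
#>   local measurements: da=3, db=24, dc=5, bl=7, bs=5, ba=3
#>   means (px / deg):
#>     da     db     dc     bl     bs     ba
#>  14.02  10.34   8.81  47.16  76.68 119.72
#>   means (scaled, 0.02 units/px):
#>       da       db       dc       bl       bs       ba
#>   0.2804   0.2069   0.1762   0.9432   1.5340 119.7000
```

The three junction discs average 14 px (0.28 mm) — wider than the
nominal 11–13 px strokes because a branch point is locally thicker than
the branches it joins — the 24 branch discs average 10.3 px, the tips
8.8 px, and the mean daughter opening is 119.7° for a specimen built at
110° plus crotch geometry. The generator's `th$truth` tables carry the
analytic expectations for each of these if you want to check them.

Group discrimination on a simulated four-group measurement table at
magnitudes typical for *Riccardia*-like material (mm units):

```r
tab <- generate_group_tables(seed = 1)   # 138 specimens, 4 groups
fit <- cda(group ~ da + db + dc + bl + bs + ba, tab)
fit
#> Canonical discriminant analysis
#>    138 specimens, 6 variables, 4 groups: amazonica_AF, amazonica_SA, compacta, obtusa
#>    3 canonical function(s)
#>
#>   canonical_correlation eigenvalue wilks_lambda proportion      F num_df  p_value code
#> 1                 0.905      4.538        0.113     0.8901 23.532     18 2.26e-50  ***
#> 2                 0.575      0.494        0.628     0.0969  6.870     10 1.57e-09  ***
#> 3                 0.250      0.066        0.938     0.0130  2.210      4 7.13e-02    .

cda_classify(fit)$correct_rate
#> [1] 0.8550725
```

The first canonical function carries 89% of the discriminating variance
and the resubstitution classification recovers 85.5% of specimens.
(Simulated variables are drawn independently, which makes discrimination
easier than on real, strongly correlated measurements — see the methods
vignette.)

For batch work, `run_measure()` processes a directory of PNG/TIFF images
into per-image and summary CSVs with overlay PNGs and a parameter log,
and `run_stats()` turns a measurement table into the full set of
reports. `inst/cli/branchmorph.R` wraps both (plus the generator) as a
command-line tool with `measure`, `stats` and `synth` subcommands.

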