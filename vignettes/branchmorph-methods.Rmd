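---
title: "Skeleton-based morphometrics of branching thalli: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-based morphometrics of branching thalli: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchmorph)
```

## The measurement problem

Thalloid liverworts and many other modular organisms grow as flat,
indeterminate, pinnately branching bodies. Classical descriptors
(landmarks, outlines) fit organisms with fixed anatomy poorly here; what
carries taxonomic and ecological signal is the *architecture*: how thick
the axes are at branch points, along branches and at their tips, how long
branches are, at what angle they open, and how densely tips are packed.
branchmorph quantifies exactly these six variables from a 2D raster of a
single specimen on a contrasting background:

* **da** — junction thickness: the diameter of the largest disc centred
  at a branch point that fits inside the specimen;
* **db** — branch thickness: diameters of successive discs placed along
  each branch;
* **dc** — terminal thickness: the disc diameter at each branch tip;
* **bl** — branch length: the skeleton arc between consecutive vertices
  (pixel count and Euclidean chord are reported alongside);
* **ba** — branch angle: the opening between the two daughter branches
  of a junction, in degrees;
* **bs** — terminal spacing: the distance from each tip to its nearest
  other tip.

All thicknesses are *diameters* (local widths), twice the Euclidean
distance transform (EDT) value at the disc centre. Lengths are emitted in
pixels and, when a pixel scale is set, in physical units; angles are
never scaled.

## Pipeline

1. **Pre-processing** (`preprocess_image()`): grayscale conversion
   (ITU-R BT.601 weights 0.299/0.587/0.114), Otsu thresholding over all
   256 candidate 8-bit levels with a manual override and a polarity flag,
   then morphological opening and closing with disc-shaped structuring
   elements (default radius 1 px each). The threshold actually used is
   always recorded in the image's provenance, because a manually adjusted
   threshold is part of the measurement and must be reproducible. When
   the between-class variance is maximized by a plateau of levels (empty
   histogram gaps), the plateau midpoint is returned, so clean bimodal
   images threshold between their modes.
2. **Skeletonization** (`thin_zhang_suen()`): the classic two-subiteration
   thinning scheme, iterated to a fixpoint. It preserves 8-connected
   foreground components and 4-connected holes for objects at least
   about 3 px across; see *Known limitations* for the inherent
   diagonal-stroke artefacts.
3. **Feature classification** (`classify_features()`): terminals are
   skeleton pixels with exactly one neighbour, junction pixels those with
   three or more — under a *reduced* 8-adjacency in which a diagonal
   neighbour is ignored whenever one of the two shared orthogonal pixels
   is itself foreground. Plain 8-adjacency misreads every second pixel of
   a staircase-shaped diagonal run as a junction; the reduced adjacency
   restores degree 2 there and eliminates the spurious 3-cycles that
   would otherwise corrupt loop counting. Adjacent junction pixels are
   merged into one junction represented by the member nearest the
   cluster centroid.
4. **Spur pruning** (`prune_spurs()`): boundary irregularities create
   short terminal branches during thinning. Terminal paths shorter than
   `max(min_spur, EDT at the parent junction)` are removed iteratively;
   the adaptive term scales the threshold with the local half-width, so
   crotch artefacts disappear while genuine short laterals survive.
   Whole components that are simple paths are never pruned and the
   skeleton is never disconnected.
5. **Graph construction** (`build_graph()`, `traverse_dfs()`): vertex
   pixels are removed and the remaining chains become edges carrying
   their ordered pixel paths; every skeleton pixel belongs to exactly one
   vertex or one edge path. Each connected component is rooted at its
   lexicographically smallest terminal (or a user-chosen terminal) and
   traversed depth-first, children ordered by the initial direction angle
   of their edges — both rules exist purely to make outputs
   deterministic. The DFS assigns every edge a parent, which orients the
   branch-thickness walk and defines which edges are siblings at a
   junction. Cycles are flagged and reported, never silently traversed.
6. **Loops** (`detect_loops()`, `break_loop()`): overlapping branches in
   the photograph appear as cycles. Their number is the cycle-space rank
   E − V + C of the skeleton's pixel graph, and one fundamental cycle per
   independent loop is reported with coordinates. Automatic loop breaking
   is deliberately not attempted — deciding *which* branch crosses over
   is a biological judgement — instead `break_loop()` applies the
   user-chosen edit: a one-pixel-wide background gap carved across the
   branch perpendicular to its local direction (two pixel rows for
   diagonal cuts, where a single row would not break 8-connectivity).

## Measurement definitions and their numerical fine print

**Junction thickness.** Raster thinning does not place the junction pixel
exactly on the crest of the distance map: at a symmetric junction of
stroke width $w$ and opening $\theta$ the EDT maximum sits up the crotch
bisector, and the thinned junction lands near but not on it. `measure_thallus()`
therefore centres the da disc at the skeleton pixel with the largest EDT
value within one local radius of the junction pixel. Without this crest
search, da is biased low by 2–4 px at wide strokes.

**Branch thickness.** Walking each edge away from its parent, the next
disc is placed at the first path pixel whose background-limited disc no
longer overlaps the previous disc (starting from the parent's da or dc
disc), with diameter $2\min(\mathrm{EDT},\ d_{\text{prev boundary}})$.
For a constant-width branch this spaces centres about one diameter apart
and returns the branch width. A disc capped by the previous disc rather
than the specimen boundary is flagged `boundary_limited` and excluded
from the per-image summary mean — such discs measure packing geometry,
not width. The walk stops on entering the terminal-thickness zone of a
terminal child.

**Branch angle.** The naive estimator — vectors from the junction pixel
to the first db disc centre on each child — is biased upward at sharp
openings: the junction pixel retreats into the crotch by
$t^\* \approx \tfrac{w}{2}\,\frac{1-s}{s(1+s)}$ with $s=\sin(\theta/2)$,
which tilts vectors to nearby probe points outward by 10–16° at
$\theta = 60°$ regardless of width. The default estimator
(`probe = "direction"`) instead takes each child's direction as the first
principal component of the path pixels in a window just beyond the
junction disc, which has no origin bias and recovers 60/90/120° openings
within about 1° on rendered fixtures. The literal disc-centre rule
remains available as `probe = "first_db"`, and an intermediate rule
(`probe = "far_db"`, vector to a probe pixel at 3.5 junction diameters)
as well. Angles are reported in [0, 180]; junctions with a single child
emit a warning and no angle.

**Branch length.** Thinned skeletons staircase: a straight oblique branch
is traced as alternating axial steps rather than diagonals, which
inflates the raw pixel-to-pixel polyline length by up to ~25%. Edge arc
lengths are therefore summed over the path resampled every 5 px, which
removes the staircase while following genuine curvature with radius well
above 5 px. The raw pixel count and the endpoint chord are reported
alongside, since field descriptions use both conventions.

## The synthetic thallus generator

`generate_thallus()` renders a recursive, pinnately branching specimen as
a union of tapered, round-capped strokes (capsules): a main axis of
`branch_length` px whose two daughters open at the sibling angle, lengths
decaying by `length_decay` per generation, widths tapering linearly
across generations from `width_junction` through `width_branch` to
`width_terminal` (so the da > db > dc ordering of real pinnate material
holds by construction), optional endpoint jitter, and an optional
crossing bar between the first junction's subtrees to create loops for
cycle-handling fixtures.

Its ground truth is *analytic*, not read back from the raster, and it
models what an ideal skeleton-based measurement would return:

* the junction-thickness truth is the largest inscribed disc at the
  crotch of the exact continuous stroke union, computed from the three
  offset background wedges along the bisector (for narrow openings it
  approaches $2w/(1+\sin(\theta/2))$; at $\theta = 120°$ it equals
  $w/\sin(\theta/2)$ at the junction point itself);
* expected skeleton branch lengths include the crotch offset $t^\*$ by
  which thinning retracts each junction, projected onto the adjoining
  branches;
* expected skeleton tips sit `min(2.5, 0.5 + w/10)` px short of the cap
  centre — the cap retraction of discrete thinning, characterized on
  rendered bars across widths 5–25 px and orientations — and the
  tip-spacing truth uses these retracted positions.

The default main-axis orientation is 60° (30° off vertical). A specimen
lies on a slide at an arbitrary orientation, and exactly axis- or
diagonal-aligned strokes are degenerate rasters: the published
two-subiteration deletion conditions fully erode perfectly 45°-oriented
strokes at even intermediate widths (verified against an independent
implementation of the same conditions — it is a property of the scheme,
not of this implementation). At orientation ≡ 30 (mod 90) every branch
direction of the standard fixtures stays at least 15° away from the
diagonals.

The default validation battery crosses widths {7, 11, 15, 21} px with
lengths {40, 80} px at a 120° opening — the realistic regime for the
motivating organisms, whose mean openings are 112–128° — and varies the
opening {60°, 90°, 120°} at 7 px width. Sharp crotches on very wide
strokes are excluded by design: there the junction zone occupies a large
fraction of the branch and no local estimator can separate "branch" from
"junction", which is a property of the geometry rather than of any
implementation. On this battery the pipeline recovers thickness means
within ±1 px, angle means within ~1°, length means within ~2% and tip
spacings within ~1.6 px of truth.

What the generator deliberately does **not** emulate: curved branches,
width fluctuation and marginal wings along an axis, photographic texture,
uneven illumination, touching foreign objects, or herbarium damage.
Passing the recovery battery therefore demonstrates correctness of the
measurement chain on clean geometry, not robustness to every artefact of
real herbarium photographs — thresholds, cleanup radii and the spur rule
remain the user's responsibility on real material, and the provenance
log records what was used.

`generate_group_tables()` complements the image generator at the
statistics level: independent normal draws per variable and group at
given means/SDs (morphological means of this kind pass normality checks
on real material), with an optional common correlation matrix. The
bundled `example_group_params()` magnitudes (mm units) mirror the four
taxonomic groups of the motivating study. Because the draws are
independent across variables by default, multivariate discrimination is
*easier* than on real, strongly correlated measurements: the simulated
Wilks' Λ (~0.11) and resubstitution accuracy (~86%) are better than the
values reported on real material (0.232 and 70.3%), and this is expected,
not a defect.

## The statistics layer

`descriptives()`, `anova_pairwise()` (one-way ANOVA with Tukey HSD for
the all-pairs family — the standard companion when the source analysis
names only "multiple comparison"), `correlation_matrix()` (Pearson r with
t-transform p-values), and `manova_wilks()`
($\Lambda = \det W / \det(W+B)$ with Rao's F approximation) cover the
univariate and global multivariate questions.

`cda()` is the package's model object: for groups $g$ and variables $p$
it solves the symmetric-definite pencil $B u = \lambda W u$ via Cholesky
factorization of $W$ (numerically stable; a brute-force `eigen(solve(W) %*% B)`
agrees to 1e-8 and serves as an independent check in the tests). There
are $\min(g-1, p)$ canonical functions; canonical correlations are
$\sqrt{\lambda_i/(1+\lambda_i)}$; the Wilks' Λ for functions $i..f$ is
$\prod_{j \ge i} (1+\lambda_j)^{-1}$, each tested with Rao's F on the
reduced dimensions. Raw coefficients are scaled to unit pooled
within-group variance of the canonical variable (sign fixed by making
the largest-magnitude coefficient positive); standardized coefficients
multiply by the pooled within-group standard deviations. Classification
(`predict()`, `cda_classify()`) assigns each specimen to the nearest
group mean in canonical space with equal priors, and the resubstitution
matrix mirrors the in-sample "correctly classified" convention of the
source analyses.

Two statistical facts the tests make explicit rather than hide:

* *Resubstitution optimism*: on label-permuted data the resubstitution
  rate sits ~6–7 points above chance at n = 138, p = 6 — a property of
  resubstitution, not of the discriminant. Chance-level behaviour is
  therefore asserted out-of-sample (fit on permuted labels, classify a
  fresh draw), where the rate averages 25% as it must.
* *Power at the published magnitudes*: drawing groups at the published
  rounded means/SDs, the weakest junction-thickness pair
  (0.40 ± 0.09 vs 0.49 ± 0.14 at n = 37/26) has ~83% power at the 0.05
  level, so "all six pairs significant" occurs in roughly 80% of
  replicates, not near-always; the choice of multiple-comparison
  procedure barely moves this. The corresponding validation check
  documents this measured rate.

## Degenerate inputs and edge behaviour

* Constant-intensity images: `otsu_threshold()` errors (degenerate
  histogram).
* Empty foreground: thinning returns an empty skeleton; `build_graph()`
  errors.
* A single-pixel specimen: classified as a terminal; dc = 2 px.
* Pure rings (no terminal anywhere): `build_graph()` errors with a
  pointer to the loop report and `break_loop()`; `run_measure()` logs
  and skips such images instead of aborting the batch.
* Fewer than two terminals: `terminal_spacing()` warns and returns an
  empty table.
* Nonpositive pixel scale: error.

## Known limitations

* The two-subiteration thinning scheme erodes 2×2 blocks, 2-px diagonal
  strips and perfectly 45°-oriented strokes of even width; tips of
  near-diagonal branches retract by a few pixels. These are properties
  of the published deletion conditions. Real specimens photographed at
  reasonable resolution are far from these degeneracies, but hairline
  (≤ 2 px) structures in a binarized image will not survive faithfully.
* Greedy disc packing makes the db *count* integer-valued: on very small
  specimens one disc more or fewer (e.g. after rotation) can move the db
  mean by several percent. Summaries are meaningful when they pool tens
  of local measurements, as on real images.
* Branch angles at junctions whose daughters are shorter than about one
  junction diameter fall back to short-window estimates and lose
  accuracy.
* The statistics layer assumes complete cases and at least two specimens
  per group; classification uses equal priors and no cross-validation,
  matching the source convention — for honest error rates on new
  material, use `predict()` on held-out specimens.

## Reproducibility

Every stochastic element (generator jitter, simulated tables) is seeded;
batch runs with identical inputs, configuration and seed produce
byte-identical CSVs and reports, and the run log records the threshold,
pruning and scale settings actually used for every image. Validation
problem sizes (20 shapes for the thinning cross-check, 50 masks for the
distance transform, a 10-fixture recovery battery, 20 tables for the
discriminant algebra, 200 simulation replicates) were chosen so the
whole suite runs in well under a minute on a laptop while estimating
every rate to a few percent.
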