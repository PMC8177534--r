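---
title: "Quantifying tip-growth stability: methods and design notes"
author: "rhizotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tip-growth stability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizotrace)
```

Rhizoids of *Marchantia polymorpha* — and tip-growing cells generally — extend
by confining growth to a small apical dome. When the machinery stabilizing the
position of that dome fails (for instance when cortical microtubule bundles
are perturbed), the cell wanders as it grows and the mature cell is wavy
rather than straight. `rhizotrace` implements the quantitative toolkit for
studying this phenotype: a 3D **sinuosity** measurement from confocal stacks,
**microtubule bundling and parallelness** metrics, a two-channel
**longitudinal intensity-ratio profile**, a **candidate-variant filter
cascade** for UV-B mutagenesis screens, and **segregation-genetics**
arithmetic with the group statistics that accompany phenotype tables. A
synthetic-data module supplies inputs with exact ground truth, so every stage
is testable end to end without any microscope.

This vignette explains each method, the parameters that matter, the numerical
choices made where the design was genuinely open, and the limits of what the
synthetic validation shows.

## 1. Sinuosity of a tubular cell from an image stack

Sinuosity is the ratio of a curve's length to the distance between its
endpoints, reported as a percentage: a straight cell scores 100, and the
wavier the cell the higher the score. The pipeline reconstructs the cell's
centerline from a z-stack in five stages.

**Segmentation** (`collect_cogs()`). Each optical slice is thresholded
(Otsu's method per slice by default — the fluorescence histogram of a stained
tube on dark background is strongly bimodal — or a fixed value via
`threshold`), connected components become contours, and contours smaller
than 1% of the image area are discarded as noise (`filter_noise()`, strict
inequality). Each surviving contour contributes its centre of gravity (CoG):
the unweighted centroid of the component's pixels, converted to micrometres
as `(x·vx, y·vy, z·vz)` with 0-based slice indices. Slices containing several
surviving contours (two cells in frame, or one cell crossing a slice twice)
contribute one point per contour; membership is resolved by the ordering
stage, not here.

**Path ordering** (`order_path()`). The CoGs are ordered by solving an open
traveling-salesman problem with a fixed starting point (the cell base) by
simulated annealing: geometric cooling from an initial temperature equal to
the mean pairwise distance (rate 0.995 per iteration, 10^4 iterations),
2-opt segment reversals and single-point relocations as moves, three seeded
restarts (nearest-neighbour start, then random starts), and a deterministic
2-opt/or-opt descent polishing each restart's best tour. The returned
ordering never costs more than the input ordering, and on 8-point instances
it matches exhaustive enumeration essentially always (the test suite checks
50 seeded instances against the (n−1)! brute force). The base point defaults
to the CoG farthest from the cloud centroid — an endpoint of any elongated
cloud — and can be fixed explicitly with `base_index`.

**Fragmentation** (`split_by_direction()`). The local direction of each step
is its angle to the abscissa axis, measured in both coordinate planes that
contain the abscissa. A new fragment opens when a step's direction deviates
from the *reference direction of the current fragment* (its first step) by
more than `angle_threshold` (default 45°). Accumulated — rather than
step-to-step — change is what matters: a smooth bend turns by a few degrees
per step and never triggers a successive-step rule, yet it must be split so
that each piece is single-valued along its regression axis and so that
smoothing cannot flatten genuine curvature (see the numerical note below).
45° separates genuine turns from sampling jitter at sub-micrometre slice
spacing; fragments always keep at least two points.

**Smoothing** (`smooth_fragment()`). Within each fragment the two transverse
coordinates are regressed independently on the abscissa by LOWESS with span
`frac = 0.1` of the fragment's points (the locally weighted scatterplot
smoother of `stats::lowess`; we verified it agrees with the Python
statsmodels implementation to machine precision on our benchmark). Point
count and order are preserved, so the 3D dataset survives. By default each
fragment is regressed against its *own* dominant axis: fragmentation
guarantees a roughly constant direction within a fragment, so its axis of
largest extent is always a valid abscissa, including for fragments running
mainly along y or z where a fixed-x convention would degenerate. A fragment
with no abscissa spread at all falls back to the identity with a logged
warning.

**Measurement** (`assemble_and_measure()`). The smoothed fragments are
concatenated in path order; the regressed path length L is the sum of
segment lengths, the chord D the base-to-tip distance, and sinuosity
S = 100·L/D. The triangle inequality guarantees S ≥ 100, with equality only
for collinear paths, and S is invariant under rigid motions and uniform
scaling — both are asserted as property tests.

`measure_sinuosity()` chains the five stages; `cmd_sinuosity()` batches it
over files with per-file error capture.

### Numerical notes and validity regime

*Why accumulated-direction splitting matters.* LOWESS with a span of 10% of
the points is a low-pass filter with a window of 10% of the fragment's
physical extent. Applied to a whole 150 µm cell, that 15 µm window attenuates
a 50 µm wave visibly: on our benchmark sinusoid (amplitude 10 µm, wavelength
50 µm, true S = 132.07) single-fragment smoothing returns 128.2. With
accumulated-direction splitting the same path breaks into fragments of
roughly a quarter wave, the windows shrink accordingly, and the pipeline
returns 131.99 on analytic points and 130.2 end-to-end from voxels.

*Tube radius versus bend scale.* The per-slice CoG of an obliquely cut,
curved tube is not exactly on the centerline; the bias grows with the tube
radius relative to the local bend scale. At the rhizoid-realistic radius of
10 µm against a 50 µm wavelength the bias is substantial (measured S = 125.5
for the benchmark above), while at radius 4 µm it is within 1.5%. The
validation tubes therefore use radius 4 µm — the regime `r ≪ bend scale`
that real rhizoids (radius ≈ 10 µm, bends of order 100 µm and longer) occupy.
Conclusions from the synthetic suite transfer to real stacks only in that
regime; a cell whose bends approach its own diameter will be underestimated.

*Slicing geometry.* Per-slice centroids sample the centerline only where the
tube crosses the slicing planes transversally. The synthetic tubes are
rendered steep (axial coordinate mapped to the optical axis); the
semicircular benchmark is rendered with its chord perpendicular to the
optical axis, because a semicircle whose chord lies along the optical axis
necessarily runs parallel to the slice planes at its ends — no slicing
direction avoids tangency somewhere on a 180° arc, but placing the tangent
region in the arc's interior makes the error symmetric and small (158.2
measured against the closed form 157.08).

*Problem sizes.* The validation suite renders tubes of 96–130 slices at
0.4 × 0.4 × 0.8–1.2 µm voxels, and the noisy-recovery ensemble uses 20 tubes
spanning true sinuosity 100–140% (the range observed across wild-type and
mutant lines) at wavelength 100 µm with Gaussian noise at 5% of the wall
intensity; recovery is within 2 percentage points in 20 of 20 tubes.

### Diameter

`measure_diameters()` samples the cell every 5 µm of arc length along the
path and reports the *minimum caliper width* of the nearest contour — an
automated analogue of manually measuring the shortest diameter along the
shank. It is an extension of, not a reproduction of, manual measurement:
calipers on a segmented contour see boundary pixelation that a human with a
ruler tool does not.

## 2. Microtubule bundling and parallelness

Growing rhizoids arrange cortical microtubules in longitudinal, parallel
bundles along the non-growing shank. Two scalars quantify this organization
from a maximum-intensity projection of the cortical-most optical slices
(`project_cortical()`, default 4 slices ≈ 1.6 µm at 395 nm spacing).

**Bundling skewness** (`bundling_skewness()`). Bundles stack fluorophores:
pixels where b filaments coincide are about b-fold brighter than single
filaments, so bundling inflates the right tail of the intensity distribution
over microtubule pixels. The statistic is the sample skewness
g₁ = m₃/m₂^{3/2} of those intensities — invariant under gain and offset
changes (any positive affine transform), which makes it comparable across
imaging sessions. Microtubule pixels are extracted by rolling-median
background subtraction followed by Otsu thresholding (`mt_pixel_mask()`).
Higher skewness = more bundled; an unbundled mutant scores lower than wild
type. On synthetic textures with a controlled bundling factor
(`make_filament_texture()`), skewness at b = 4 exceeds b = 1 in 100 of 100
seeded replicates.

**Parallelness** (`skeleton_parallelness()`). The microtubule mask is
thinned to a one-pixel skeleton (Zhang–Suen two-subiteration thinning,
implemented in-package), cut at branch points detected by crossing number
(≥ 3 background-to-foreground transitions around a pixel — a raw
8-neighbour count misclassifies ordinary diagonal staircase pixels), and
decomposed into segments of at least 5 pixels. Each segment's axial
orientation in [0°, 180°) comes from the principal component of its pixel
coordinates. The scalar score is the circular order parameter on doubled
angles, |Σ w·e^{2iθ}|/Σw with segment-length weights: 1 for a perfectly
parallel array, 0 for balanced perpendicular mass. The raw angle list is
returned alongside for rank tests. The score is rotation-invariant within
discretization error (tolerance 0.05 in the tests).

**Intensity-ratio profile** (`profile_ratio()`). For two geometrically
aligned reporter channels, intensities are sampled by bilinear interpolation
along a 35 µm line from the apex into the cell, averaged over a 3-pixel
transverse window at each station, and reported as the per-station ratio of
channel means (undefined stations — zero denominator — become `NA`). This
reproduces the relative-abundance profile of a MAP reporter normalized by a
tubulin reporter, which rises from apex to shank when the MAP prefers
bundled shank microtubules.

What the texture generator does *not* emulate: the point-spread function,
photobleaching, out-of-focus haze, and curved filaments (bundles are straight
segments). The bundling-skewness ordering it validates rests on bundle
coincidence and crossings, the same mechanism as in real arrays, but absolute
skewness values are not comparable between synthetic and real images.

## 3. Candidate-variant discovery for UV-B mutants

Whole-genome sequencing of a mutant from a UV-B screen yields on the order
of 10^5 mismatches; the cascade (`run_cascade()`) reduces them to a handful
of candidates. Stages, in order, on records carrying the legacy
pileup-caller fields DP, DP4, FQ, AF1:

1. **Quality** — keep site quality strictly above 35.
2. **Coverage** — drop depth strictly above 100× (collapsed repeats).
3. **Support** — keep alternate support (DP4 alt-forward + alt-reverse)
   strictly above 7 reads.
4. **Homozygosity** — keep FQ < 0 *or* AF1 > 0.5001; a mutant isolated
   through vegetative propagation is homozygous at the causative site.
   Records missing both fields are dropped (conservative) with a warning.
5. **Privacy** — drop variants present in any non-allelic sequenced line or
   wild-type accession, matching on the full (chrom, pos, ref, alt) key:
   shared variants are background, not causative.
6. **UV signature** — keep G→A and C→T substitutions (one pyrimidine-dimer
   event read on either strand; the recorded pair is used literally, without
   strand complementation, since the two spellings cover both strands) and
   all indels.
7. **Consequence** (`annotate_consequence()`) — map survivors onto gene
   models, translate reference and alternate codons with the standard code
   (strand-aware: alleles complemented and positions mirrored within the
   reverse-complemented spliced CDS on minus-strand genes), and keep
   amino-acid-changing classes: nonsense, missense, frameshift and in-frame
   indels. Indels crossing an exon boundary are flagged `splice_region`;
   anything outside a CDS is `noncoding`.

All record-level predicates commute (asserted as a property test), so stage
order affects only the per-stage counts, never the survivor set. The
consequence caller is validated against an independent oracle that rebuilds
the entire mutant CDS and compares translated proteins, over 500 random
variants in simulated multi-exon, mixed-strand gene models — agreement is
exact. The synthetic variant generator plants records on both sides of every
threshold (quality 35/36, depth 100/101, support 7/8, AF1 exactly at its
cutoff) and computes each record's survival label at generation time with
independently coded predicates.

Open choices resolved here: "q quality" is read as site quality (the field a
pileup caller emits per record); "supported by more than seven reads" counts
alternate-supporting reads, not total depth (support of the *mismatch* is
what the phrase qualifies).

## 4. Segregation genetics and group statistics

`genetic_distance()` estimates map distance as the recombination fraction in
centimorgans (100·r/total). For the allelism crosses in scope every cross
yields zero recombinants, where every mapping function gives 0 cM, so the
plain fraction is the default and Kosambi's map function is an option.
`segregation_ratio()` formats marker co-segregation as the table convention
"1/x" (x = ratio rounded to one decimal), and `chi_square_1to1()` tests
counts against the 1:1 expectation of a single segregating insertion.

`compare_groups()` reproduces the phenotype-table statistics: a
Kruskal–Wallis omnibus, Dunn's rank-based post hoc tests of each group
against the control with Benjamini–Hochberg adjustment, and stars at
adjusted p < 0.05 / < 0.01; with exactly two groups it runs a two-sided
Mann–Whitney U test (exact where sample sizes permit). The Dunn test is
implemented in-package (z statistics on pooled ranks with the standard tie
correction, two-sided normal p-values — the variant without a one-sided
option, since the tables report two-sided stars); the omnibus, U test and
BH adjustment are the standard `stats` routines. Calibration is part of the
acceptance suite: the omnibus null rejection rate over 1000 simulations sits
inside [0.03, 0.07] at α = 0.05.

## 5. Synthetic data as ground truth

Generators are first-class, seeded, and bit-reproducible:

* `make_centerline()` — straight, sinusoid, helix or piecewise 3D curves
  with arc length by dense quadrature (exact polyline length for piecewise);
  ground-truth sinuosity = 100·arc/chord. `centerline_semicircle()` builds
  the closed-form 157.08% benchmark.
* `render_tube_stack()` — voxels within the tube radius of the densely
  sampled centerline get wall intensity, others background; additive
  Gaussian noise clipped at zero (Poisson shot noise optional); the slice
  axis is cut flush with the axial extent so end slices are clean
  cross-sections. Default stack geometry auto-sizes around the tube.
* `make_filament_texture()` — bundles of exactly b coincident unit-width
  filaments carrying summed intensity, orientation jitter around a mean,
  `"spread"` placement for guaranteed non-overlapping parallel arrays.
* `make_variant_table()` — per-predicate pass fractions, planted boundary
  cases, generation-time truth labels; `simulate_gene_models()` builds
  random genomes with multi-exon genes on both strands (CDS lengths
  divisible by three by construction).

Every generator's default *is* the condition used by the validation suite;
none of them is adjusted per test.

## 6. Known limitations

* The sinuosity pipeline assumes one dominant cell per stack after the 1%
  area filter; two cells are ordered into one path unless separated upstream.
  Branch detection is out of scope.
* Per-slice centroids undersample waves whose scale approaches the tube
  diameter (see the validity regime above); such cells are underestimated,
  never overestimated.
* The LOWESS span is a fraction of points, so its physical window scales
  with fragment length; extremely long straight fragments smooth more
  aggressively in micrometres than short ones.
* The consequence caller handles substitutions and simple indels against
  ungapped gene models; it does not model splice-site creation, UTRs, or
  compound variants.
* The intensity-ratio profile assumes the two channels are already
  registered; no alignment is attempted.
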