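---
title: "Quantifying astrocyte morphogenesis: models, measurements and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying astrocyte morphogenesis: models, measurements and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromorph)
```

## The measurement problem

Cortical astrocytes mature from simple polygonal precursors into
profusely ramified cells during the first postnatal weeks, and
perturbations of astrocyte-neuron adhesion (for example silencing of
astrocytic delta-catenin/`Ctnnd2` or of N-cadherin) stunt that
morphogenesis. Studies of this process rest on a small set of
quantitative readouts, which this package implements as reusable,
oracle-tested operations:

* **Total branch length** *L* of a traced arbor (micrometres of cable),
* **Sholl intersection curves** *N(r)*: process crossings of concentric
  circles (2D cultures) or spheres (3D volumes) centred on the soma,
  every 5 micrometres by default, summarised by the peak count,
* **Territory volume** *V*: the volume of the convex hull of the traced
  arbor, a proxy for the tissue domain an astrocyte occupies,
* **Excitatory synapse density** within an astrocyte's territory:
  pixel-overlap colocalization of pre- and post-synaptic puncta
  (Bassoon/PSD95-style) normalized to astrocyte area,
* **RNA-FISH expression score** *E = V~mRNA~ / V~soma~*: suprathreshold
  probe volume normalized to soma volume, per cortical layer and
  developmental timepoint,
* the matching **hierarchical statistics** for nested designs (cells
  within animals or experiments).

Because the microscopy data behind such studies are rarely shared, the
package also ships a first-class synthetic-data generator with known
ground truth. The generator's presets *are* the study conditions: they
are calibrated once, by fixed documented constants, so that the
measurement pipeline reproduces the printed per-condition summary
statistics, and they are exercised end-to-end by the test suite.

## Filament trees and their statistics

A reconstruction is a rooted tree of 3D nodes (`FilamentTree`), the root
being the soma centre; edges are straight segments. `readSWC()` and
`writeSWC()` exchange the standard 7-column SWC format, with coordinates
in micrometres and a round trip that is exact at 6 significant digits.
Validity checks (single root, parents present, acyclicity, strictly
positive segment lengths) run on construction, so every downstream
operation can assume a well-formed tree.

`totalBranchLength()` is the sum of node-to-parent Euclidean distances.
`convexHullTerritory()` computes the exact volume of the convex hull of
the node coordinates with an incremental hull construction written for
this package (no qhull binding is assumed); the test suite verifies each
hull three ways: every input point satisfies every facet half-space, the
facet vertices are input points, and the facet-polytope volume agrees
with a Monte-Carlo hit test to 1%. Degenerate inputs (fewer than four
distinct points, collinear or coplanar clouds) raise errors instead of
returning zero, so tracing failures surface rather than silently
producing empty territories.

### The Sholl crossing rule

`shollIntersections()` counts, for each shell radius `r = k * step`, the
segments whose endpoint distances from the root straddle the shell: one
endpoint at distance `< r`, the other at `>= r` (the boundary belongs to
the outer side — a deterministic tie-break that is measure-zero for real
data). A segment spanning several shells contributes once to each. For a
segment whose distance to the root is monotone from parent to child this
equals the true circle/sphere crossing count of the polyline; a segment
that dipped towards the soma and back out within a single shell would
cross twice but be counted once. Outward-growing traces satisfy the
monotonicity condition essentially everywhere, and the dense-resampling
oracle in the test suite (which counts sign changes of `distance - r`
at 0.01 um sampling) is therefore run on random trees constrained to
endpoint-monotone segments. 2D Sholl analysis projects onto the x-y
plane first, matching epifluorescence images of cultured astrocytes.

`peakOfCurve()` reports the maximum count and the smallest radius
attaining it; the peak is both a complexity summary and the basis of the
experiment-level quality control below.

## Synapse quantification

`quantifySynapses()` reimplements the published procedure for confocal
stacks of sparse astrocytes with pre- and post-synaptic staining:

1. the stack (0.34 um z-step, ~3 um depth in the emulated acquisitions)
   is divided into consecutive 1.02 um substacks, each max-projected
   (`splitAndProject()`); a trailing incomplete group is dropped with a
   warning;
2. each projected channel is thresholded (`thresholdChannel()`); since a
   "manual" threshold is irreproducible, the default is a recorded 99th
   percentile per channel with a fixed-value override, plus Otsu;
3. suprathreshold connected components become puncta (`findPuncta()`),
   with components under 4 pixels removed (small-object filter);
   connectivity is fixed at 8 (2D) / 26 (3D) because component counts
   depend on it;
4. colocalization (`colocalizePuncta()`) counts **pre** puncta sharing
   at least one pixel with any post punctum — one synapse per pre
   punctum even when it touches several post puncta. An alternative
   `mode = "union"` counts connected components of the overlap region;
   both are deterministic and oracle-checked, and the choice matters
   because the published text fixes no arity rule;
5. only pre puncta whose centroid lies inside the astrocyte mask count
   ("within astrocyte" is likewise not pinned down in print; the
   centroid rule is the stated choice here), and the count is normalized
   to astrocyte area: `density = n_coloc / area` (`synapseDensity()`).

The synthetic stacks place Poisson-distributed Gaussian spots with a
programmable fraction `f` of pre puncta receiving a post partner within
half a punctum radius. At `f = 0` the measured colocalization equals
the analytic chance-overlap level `1 - exp(-lambda_post * pi * (2 r_eff)^2)`
(with `r_eff` the suprathreshold spot radius), which the tests check by
simulation; at `f = 0.5` the pipeline recovers the planted colocalized
density within 15% over 20 images. Default densities (0.12 puncta per
square micrometre per channel) keep that chance-overlap contamination
below ~8% of the planted signal — comparable to the regime of real
cortical synapse counts at these resolutions.

## RNA-FISH expression

`segmentSoma()` stands in for the interactive pixel-classifier step of
published FISH pipelines with a deterministic chain: Gaussian smoothing
(physical sigma, converted per-axis to voxels), Otsu or percentile
threshold, one-voxel morphological closing, largest connected component.
The closing acts **within z-slices**: with a 1 um z-step against 0.25 um
lateral pixels, a cubic structuring element is physically lopsided and
measurably inflates somata truncated by the stack faces (about +10%
volume on a 4 um sphere in a 6 um stack); the in-plane closing removes
that bias (verified against analytic sphere volumes in the tests).

`mrnaPunctaVolume()` counts suprathreshold probe voxels inside the soma
mask (a configurable dilation, default 0 um, accommodates the
alternative reading in which perisomatic puncta count), and
`fishExpression()` forms the unitless score `E`. No background
subtraction is applied — none is described for the emulated pipeline.
`assignCellType()` classifies puncta as astrocytic/neuronal when at
least half their voxels (configurable) overlap the respective marker.

The synthetic design mirrors the emulated study exactly: five cortical
layers by four timepoints (P1, P7, P14, P21), three animals per
timepoint, three sections per animal, one image per layer and section —
180 images. Each image carries one spherical soma (radius 4 um, crisp
boundary plus additive noise) with mRNA voxels totalling the programmed
stratum expression times the soma volume. Cell-level variability is a
mean-preserving lognormal factor (sd 0.1 on the log scale) with an
additional animal-level factor (sd 0.05). These dispersions are kept
deliberately modest — real FISH data are severalfold noisier — so that
the recovery tests isolate measurement bias from sampling noise; the
equal-expression null property (layer effects non-significant in at
least 90% of simulated datasets) is insensitive to that choice. The
default expression map is constant across layers (the layer-null
structure the emulated data showed) with a decline by P21. One
quantified astrocyte per image keeps the dataset compact; the per-animal
aggregation is unaffected.

Truth records (planted lengths, counts, expressions) are emitted next to
every generated artifact and are never read by any measurement function;
recovery tests compare measured values against them from the outside.

## The synthetic arbor generator and its calibration

Arbors grow by a Galton-Watson-style branching process: a drawn number
of primary processes leaves the soma in uniformly random directions;
after each traced segment (gamma-distributed length, direction = parent
direction plus Gaussian angular jitter) the branch bifurcates into two
daughters of the next order with probability `branchProb[order]`,
terminates with probability `stopProb[order]`, and otherwise continues.
Branches are capped at `maxSegments` segments (bounded branch length;
the cap also truncates the heavy geometric tail, keeping the
population-mean total length stable at n = 100 cells). This is a
generative stand-in, not a biophysical growth model.

Preset constants were fixed once against large-sample (n = 1500)
population means so that the measured mean total branch length per
condition matches the emulated study's printed values: about 14,523 um
for co-cultured controls, 4,551 um after silencing (a threefold
reduction, with fewer primary processes and no processes beyond third
order), 12,753 um for the rescue and 13,853 um for overexpression
(both rescaled controls, reproducing the "restored but slightly
contracted" phenotype as a pure length rescaling). Co-cultured control
arbors peak above 20 Sholl intersections (the co-culture health
criterion) and astrocyte-only monocultures peak at 8-9 (within the
observed 8-10 band and above the monoculture health threshold of 6).
In vivo presets reuse the same machinery at smaller physical scale.
All generators are pure functions of `(params, seed)`; populations are
generated from a single seeding so the whole batch is reproducible
bit-for-bit.

## Hierarchical inference

Cells nested in animals or experiments are pseudoreplicates; all group
comparisons therefore run at the proper level:

* `shollLmmCompare()` fits `count ~ condition * radius` with radius
  categorical and random intercepts for the nesting unit and for cell
  within unit, then contrasts condition marginal means averaged over the
  radius grid with Tukey family-wise adjustment (Satterthwaite degrees
  of freedom). Radius is categorical because the curve shape is not
  assumed; the published analyses fixed no formula, so this one is
  stated explicitly and its calibration is tested: type-I error within
  [0.02, 0.09] at nominal 0.05 over 200 identically-generated-group
  simulations, power above 95% for control-versus-silenced presets at
  30 cells per group.
* `nestedTTest()` / `nestedAnova()` fit `value ~ group + (1 | animal)`
  (the documented equivalent of spreadsheet "nested" tests), with a
  Welch test on animal means as the degenerate-variance fallback — which
  is also the exact analysis when each animal contributes one value.
  The suite verifies the nested test rejects less often than the naive
  cell-level t-test under a null with real between-animal variance.
* `twoWayAnovaDunnett()` runs on animal-level means (`value ~ layer *
  timepoint`) and tests every timepoint against the reference (default
  P1) within each layer. All contrasts of the analysis form **one**
  multiplicity family, adjusted jointly via the multivariate-t
  distribution (generalized Dunnett; the quasi-random integration is
  internally seeded for reproducibility). Per-layer families would
  multiply the panel-wise false-positive rate roughly fivefold and make
  the equal-expression null property unattainable.
* `normalityGate()` applies Shapiro-Wilk to both samples and routes to a
  two-sided Mann-Whitney U test if either rejects at 0.05, else a Welch
  t-test, reporting which branch ran.
* `qcExperiment()` excludes an entire experiment when its control cells'
  mean peak intersection count falls below 20 (astrocyte-neuron
  co-culture) or 6 (astrocyte monoculture); the boundary is strict
  (exactly 20 keeps), and no rule applies in vivo.
* `densitometryFold()` is the table-level surface/total fold-change
  ratio used for surface-expression blots.

## Numerical choices and degenerate inputs

* Shell boundary ownership: `r` belongs to the outer side (see above).
* Sholl curves always extend to the first shell beyond the farthest
  node, so curves padded onto a common grid end in structural zeros; the
  curve dataset builder optionally caps the common grid at a fixed
  analysis radius so a single sprawling cell does not pad every other
  cell's curve with dozens of empty shells (the power simulations use a
  300 um cap).
* Hull degeneracy raises; tolerance is `1e-9` of the point-cloud extent.
* Thresholds are recorded in results (`attr(mask, "threshold")`,
  run reports), so a "manual" choice is always reproducible.
* Connected components: 8/26-connectivity, labels compacted in
  column-major first-pixel order (deterministic).
* Mixed models are fitted with derivative checks off for speed; singular
  fits on boundary variance estimates are expected under null
  simulations and handled (the asymptotic fallback for degrees of
  freedom is detected and reported).
* All simulation entry points take explicit seeds; identical inputs give
  bit-identical outputs.

## Problem sizes in the shipped checks

The test suite regenerates everything programmatically: n = 100 arbors
per preset for the calibration checks, 200 null and 100 power
simulations for the curve model, 300 for the nested t-test, 20 synthetic
synapse images and the full 180-image FISH design for the recovery
checks, and 100 truth-level datasets for the layer-null property. These
sizes were chosen so the complete suite exercises every calibrated
property at useful precision while remaining runnable on a laptop.

## What passing tests do and do not show

The generator produces crisp, noise-controlled geometry: spot-like
synaptic puncta, spherical somata, traced arbors without tracing errors.
Passing recovery tests therefore demonstrate that the measurement
operations are unbiased and correctly composed on well-formed input, and
that the inference layer has its nominal operating characteristics under
the stated noise models. They do not certify performance on real
microscopy — anisotropic point-spread functions, uneven background,
tracing mistakes, segmentation of touching cells and departures from
lognormal variability are all outside the generator's scope, and
thresholds that are recorded here were chosen manually in the emulated
workflows. The honest claim is: given reconstructions and stacks of the
stated form, the numbers this package produces are the stated
quantities, to the stated tolerances, with calibrated error rates.
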