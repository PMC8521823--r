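---
title: "Depth profiling of spheroid fluorescence images: methods and design"
author: "SpheroidProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth profiling of spheroid fluorescence images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpheroidProfiler)
```

## The measurement model

A spheroid is a roughly spherical multicellular aggregate whose
microenvironment varies radially: oxygen and nutrients fall from the
surface toward the centre, producing, in order of depth, a proliferative
rim, a hypoxic and G1-arrested mid zone, and a necrotic core. An
equatorial section — a thin physical or optical slice through the
midplane — exposes this radial structure in 2D, and by symmetry the
distance of a cell to the spheroid *surface* (its depth) is the single
spatial coordinate along which all biology of interest varies.

SpheroidProfiler's unit of analysis is the cell. The pipeline is:

1. segment nuclei (primary objects) on a nuclear channel;
2. optionally grow whole-cell territories (secondary objects) from the
   nuclear seeds, for cytoplasmic stains such as pimonidazole;
3. segment the whole-spheroid footprint and take its perimeter as depth
   zero;
4. assign every object its signed centroid-to-perimeter distance;
5. aggregate per-object measurements into depth-binned profiles:
   mean intensity (hypoxia), positive fraction (cell death,
   cell-cycle reporters), counts or areal densities (PBMC
   infiltration), and the mKO2⁺/mAG⁺ count ratio (G1 arrest).

Assumptions: the section passes near the equator, the spheroid is
approximately round and radially symmetric (the ring-area normalisation
and the depth coordinate both rely on this), one section represents the
spheroid, and staining intensity is comparable across the section. For
visibly asymmetric spheroids or clustered co-cultures the depth
coordinate is not sufficient; `countNeighbors()` (pixel-set
boundary-to-boundary distances) supports neighbourhood-based analyses in
that regime, but 3D reconstruction is out of scope.

## Segmentation

**Thresholding.** `automatic` is two-class Otsu on the full image
histogram (256 levels over the observed range); `manual` applies a fixed
intensity. Otsu was chosen for determinism and ubiquity. For the
spheroid footprint a manual threshold is preferred: the object of
interest spans the whole intensity range, and a histogram split tuned to
single cells is the wrong scale. An image whose histogram is constant
yields an empty foreground rather than an error.

**Declumping.** Touching nuclei are split on shape: the Euclidean
distance transform of each foreground component is smoothed with a
Gaussian (a "filter of size *s*" means sigma = *s*/2.355, the FWHM
reading, fixed once for reproducibility), local maxima no closer than
`maximaMinDistancePx` become seeds (plateau-tolerant maximum filter,
then greedy suppression in descending height with row-major
tie-breaks), and a seeded watershed on the negated smoothed transform
assigns the split. Priority-flood ties resolve by insertion order, so
output is deterministic. Intensity-based declumping is not implemented:
shape declumping is the variant whose two controls (smoothing size,
maxima distance) the analysis exposes, and those two controls reproduce
the canonical under/over-segmentation trade-off — on a fused two-disk
phantom with centres 15 px apart the split count falls monotonically
from 2 to 1 as the maxima distance grows past the centre separation.

**Size and border gates.** Objects are classed `accepted`,
`discarded_size` (equivalent diameter outside the configured range) or
`discarded_border` (touching the outermost pixel rows/columns). The
border class overrides the size class, matching the three-colour
overlay convention (green / magenta / yellow) used in rendered
overlays. Accepted objects are relabelled 1..K in row-major scan order.

**Secondary objects.** Cells grow from accepted seeds by capped
nearest-seed propagation: every pixel within `maxExpansionPx`
(Euclidean, to the seed's pixel set) is assigned to its nearest seed,
ties to the lower label, so neighbouring cells meet exactly on the
equidistance locus and no cell pixel lies beyond the cap. The guide
image's threshold is computed and logged; under the candidate-territory
definition used here (above-threshold pixels united with the fixed
expansion zone) it does not further restrict the assigned region, which
keeps the fallback behaviour — low-signal regions still yield the fixed
expansion — uniform across the image. The assignment is computed
exactly (equal-distance offset groups scanned in order), not by an
approximate grid propagation, and is verified against a brute-force
per-pixel scan in the tests.

**Spheroid footprint.** The image is smoothed at scale
`diameterEstimate/20`, thresholded, morphologically closed (radius
`diameterEstimate/40`), hole-filled, and the largest 8-connected
component with equivalent diameter in [0.5, 2] x the estimate is
returned. The two scale factors suppress single-cell texture while
preserving the outline; hole filling makes a DAPI-dim necrotic core
part of the footprint, which is essential because depth is measured
from the outer surface only.

## Distances and binning

`distanceToSurface()` returns the exact minimum over perimeter pixels
of the Euclidean distance from the (fractional) centroid, in
micrometres, signed by the centroid's containing pixel (negative
outside). The exact scan — rather than sampling a distance transform at
the nearest pixel — keeps the measurement 1-Lipschitz in the centroid
and within sqrt(2)/2 px of any transform-based variant. Perimeter
pixels are mask pixels with a background 4-neighbour; objects are
8-connected; both conventions are fixed package-wide. An object
straddling the boundary is inside iff its centroid's containing pixel
is inside; surface-adherent objects (e.g. non-infiltrated PBMCs) are
retained with negative distance rather than dropped, so infiltration
analyses can report them as an outside count.

Profiles use half-open bins [k·w, (k+1)·w) from depth zero. The default
width is w = 25 um — a compromise between depth resolution and per-bin
counts at the package's default spheroid scale (radius 280 um, ~600
nuclei per section); for the FUCCI count ratio, whose per-bin variance
is driven by the smaller of the two class counts, a wider 50 um bin is
the recommended analysis choice (the biological zones being compared
are themselves ~70-105 um wide). Per-bin mean intensity is the
unweighted mean over objects, because the unit of analysis is the cell,
not the pixel. Empty bins (and zero-denominator ratio bins) are
reported as undefined, never zero-filled: a zero fabricates signal in
rings that simply contained no objects. Fractions are stored as
fractions and rendered as percentages. Ring-area normalisation uses the
idealised circular spheroid of equal area, consistent with the symmetry
assumption above. Conservation holds by construction: each profile's
bin counts sum to the inside-spheroid records supplied.

## The synthetic phantom

`generatePhantom()` draws a disk-shaped equatorial section with known
ground truth: nuclei are soft-edged disks (raised-cosine edge of ~1 px)
placed by dart throwing with minimum-separation rejection; the
pimonidazole amplitude follows a monotone depth ramp; DRAQ7 positivity
and the mAG fraction are Bernoulli draws from configurable depth
functions; necrotic-core nuclei (inside `necroticCoreRadiusUm`) carry
no cell-cycle reporter and keep 30 % DAPI amplitude — so a nuclear
channel alone under-segments the core, reproducing the real-data
motivation for merging nuclear-emitting channels; PBMCs are placed by
piecewise-constant ring densities. All channels receive a background
offset plus zero-clipped Gaussian noise. Identical seeds give
bit-identical output (a private Mersenne-Twister stream with a fixed
draw order; the caller's RNG state is restored).

Default conditions describe a medium melanoma-like spheroid: radius
280 um at 2 um/px (matching the deepest zone boundary of the depth
ranges the analyses are designed around), ~10 um nuclei, 600 nuclei and
150 PBMCs per section, necrotic core radius 100 um, hypoxia ramp
starting at 50 um depth, DRAQ7 probability rising around the core
boundary, mAG fraction falling logistically with depth, signal
amplitude 2000 DN over background 100 DN with noise sigma 20 DN. Where
the underlying biology gives only monotone descriptions, these shapes
were chosen once for testability, not biological fidelity.

`phantomProfileExpectation()` supplies the closed-form recovery targets:
nuclei are uniform over the disk, so a per-object quantity q(depth)
has bin expectation equal to the circumference-weighted average of q
over the bin's depth range (weight R − d), and PBMC counts follow the
ring-density mass. Tests compare measured profiles against these
expectations within 3 binomial/Poisson standard errors.

What the phantom does *not* emulate — and hence what passing tests do
not show about real data: point-spread blur and chromatic shifts
(soft-edged disks stand in for the PSF), Poisson shot noise and
detector gain, intensity attenuation with depth, irregular nucleus
shapes and true cytoplasm geometry, asymmetric spheroids, staining
heterogeneity, and sectioning artefacts. Parameter recovery on the
phantom validates the computational contracts, not microscope-specific
robustness.

## Numerical and I/O choices

* Disk representation is unsigned-integer digital numbers: a b-bit TIFF
  plane holds integers in [0, 2^b − 1] and round-trips bit-exactly
  (float planes are read as stored). The writer does not embed
  resolution tags, so the pixel size travels via config/override;
  resolution metadata of externally produced TIFFs is honoured on read,
  an explicit override always wins, and the absence of both is an
  error because all distances are reported in micrometres.
* Tables are comma-delimited UTF-8 with Unix newlines and doubles at 9
  significant digits, making write→read→write byte-idempotent.
* Otsu on per-object means requires at least two distinct values;
  otherwise a classed `degenerate_distribution_error` asks the caller
  for a manual threshold.
* The canvas margin around the phantom spheroid must be at least 10 %
  of its radius; dart throwing has a bounded retry budget and fails
  with a classed `packing_error` rather than looping forever.
* Pipeline runs stage into a hidden directory and promote on success,
  so a failing stage leaves no partial outputs; the error names the
  stage. The resolved-config snapshot (all defaults materialised)
  re-runs to byte-identical tables.

## Problem sizes used in the test and acceptance suites

Unit tests run on 120-nucleus phantoms of radius 120 um; recovery
checks use 300-600 nuclei at radius 280 um, 256 x 256 propagation
fields, and 50 random blob masks x 20 test points for the distance
oracle. These sizes give per-bin counts large enough for 3-SE
comparisons while keeping the full suite under a minute; they are the
package's chosen desk-scale study conditions, and the generator seeds
are fixed in the tests.

## Known limitations

* 2D only: depths are section depths; no 3D reconstruction.
* One spheroid per image: the largest size-plausible component wins.
* No intensity-based declumping and no machine-learned segmentation.
* The guide threshold does not constrain secondary growth beyond the
  expansion cap (see above); analyses needing threshold-limited
  cytoplasm boundaries should reduce the cap instead.
* Statistical comparison between profiles (replicates, treatments) is
  out of scope; profiles export as tidy CSV for downstream tools.
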