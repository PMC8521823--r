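# SpheroidProfiler

Quantitative and spatial depth profiling of tumour-spheroid fluorescence
images.

Tumour spheroids develop radial microenvironmental gradients: oxygen and
nutrients decrease from the surface toward the core, producing a hypoxic
mid zone, G1 cell-cycle arrest at depth, and a necrotic centre. Stains
imaged on an equatorial section make these gradients measurable —
pimonidazole immunofluorescence marks hypoxic cells, DRAQ7 marks
dead/dying cells, mAG/mKO2 (FUCCI) report cell-cycle phase, and
fluorescently labelled PBMCs report immune-cell infiltration.
SpheroidProfiler turns such multi-channel images into per-cell records
and depth-binned profiles of each readout. It is aimed at labs running
spheroid drug-response or immune-infiltration assays who want a
scripted, reproducible replacement for an interactive image-analysis
pipeline.

## What it computes

For a multi-channel TIFF of one spheroid section (nuclear stain plus
any subset of pimonidazole / DRAQ7 / mAG / mKO2 / PBMC channels):

1. **Nuclei** are segmented as primary objects: thresholding
   (Otsu or manual), hole filling, then shape-based declumping — local
   maxima of the Gaussian-smoothed Euclidean distance transform, no two
   closer than a configurable distance *d*, feed a seeded watershed.
   Objects are size-gated by equivalent diameter and optionally
   discarded at the image border.
2. **Cells** are grown from nuclear seeds by capped nearest-seed
   propagation: every pixel within *r*<sub>max</sub> of a seed joins its
   nearest seed, so neighbouring cells meet on the equidistance locus.
3. **The spheroid footprint** is segmented at coarse scale; its
   perimeter defines depth zero.
4. **Distance to surface**: each object's centroid-to-perimeter minimum
   distance *D* (in micrometres), signed negative outside the footprint.
5. **Depth profiles** over bins [*k·w*, (*k*+1)*w*): per-bin mean
   intensity, positive fraction (after manual or Otsu per-object
   classification), raw or ring-area-normalised counts, and the
   mKO2⁺/mAG⁺ ratio whose rise with depth indicates G1 arrest.

A synthetic phantom generator produces disk-shaped spheroid images with
known per-nucleus ground truth (positions, depths, class flags) so every
stage can be validated without microscopy data.

## Worked example

```r
library(SpheroidProfiler)

params  <- spheroidPhantomParams(seed = 7)   # 280 um spheroid, 600 nuclei
phantom <- generatePhantom(params)
phantom$image
#> MultiChannelImage: 6 channel(s) [DAPI, pimonidazole, DRAQ7, mAG, mKO2, PBMC], 323 x 323 px, 2 um/px

dapi   <- getChannel(phantom$image, "DAPI")
nuclei <- identifyPrimaryObjects(dapi, primaryParams(
  3, 16, thresholdStrategy = "manual", manualThreshold = 300,
  declumpSmoothingPx = 2, maximaMinDistancePx = 4))
nuclei
#> LabelMap: 596 object(s) (596 accepted, 0 size-discarded, 0 border-discarded), 323 x 323 px

spheroid <- identifySpheroid(dapi, 280, "manual", 200)
spheroid
#> SpheroidMask: area 61080 px, equivalent diameter 278.9 px (557.7 um), 824 perimeter px

records <- relateObjects(nuclei, spheroid)
draq7   <- measureObjectIntensity(nuclei, getChannel(phantom$image, "DRAQ7"))
records$DRAQ7_positive <- as.logical(classifyPositive(draq7$mean, "automatic"))

profile <- positiveFractionProfile(records, "DRAQ7", binWidthUm = 50)
head(as.data.frame(profile), 6)
#>   bin_start_um bin_end_um n_objects  value        value_kind defined
#> 1            0         50       202 0.0347 positive_fraction    TRUE
#> 2           50        100       151 0.0596 positive_fraction    TRUE
#> 3          100        150       122 0.0656 positive_fraction    TRUE
#> 4          150        200        77 0.4545 positive_fraction    TRUE
#> 5          200        250        41 0.8780 positive_fraction    TRUE
#> 6          250        300         3 1.0000 positive_fraction    TRUE
```

The dead-cell fraction is low near the surface and rises steeply around
the necrotic-core boundary (the phantom places the core at 180 um
depth) — exactly the spatial signal the DRAQ7 analysis is designed to
expose. `plotProfile(profile)` renders the curve with fractions shown
as percentages.

The segmentation recovered 596 of 600 ground-truth nuclei here; the
phantom deliberately dims necrotic-core nuclei to 30 % DAPI amplitude,
which is why a manual threshold of 300 (above background 100 + noise,
below the dimmed amplitude 600) is used — with an automatic Otsu
threshold the dim core nuclei are lost, mirroring the real-data
motivation for merging nuclear-emitting channels via
`mergeChannels()`.

## End-to-end runs

`runPipeline()` executes the whole analysis from a YAML config (see
`inst/extdata/example_config.yaml`) and writes object tables, profile
CSVs, category-coloured overlay PNGs (accepted = green, size-discarded
= magenta, border-discarded = yellow), a structured log, and a
resolved-config snapshot that reproduces the run byte-identically. A
thin CLI wraps the same functions:

```sh
Rscript inst/scripts/spheroidtool.R simulate --out sim --seed 3
Rscript inst/scripts/spheroidtool.R validate --config config.yaml
Rscript inst/scripts/spheroidtool.R analyze  --config config.yaml
Rscript inst/scripts/spheroidtool.R convert  --input sim/phantom_stack.tif \
    --out split --suffixes _dapi,_pimo,_draq7,_mag,_mko2,_pbmc --pixel-size 2
```

## Conventions

* Pixel coordinates are 0-based, row-major; a pixel's centroid
  contribution is its index (no half-pixel offset).
* 8-connectivity for objects; perimeter pixels are mask pixels with a
  background 4-neighbour.
* A "smoothing filter of size *s*" is a Gaussian with sigma = *s*/2.355
  (FWHM reading).
* Distances are micrometres; the pixel size comes from TIFF resolution
  metadata or an explicit override (an error if neither is present).
* Intensities are kept in native digital numbers; written TIFFs are
  8/16-bit unsigned and round-trip bit-exactly.

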