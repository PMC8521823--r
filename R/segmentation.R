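# Segmentation: primary objects (nuclei) with shape-based declumping,
# secondary objects (cells) by capped nearest-seed propagation, and the
# whole-spheroid footprint.
#
# Conventions, stated once and used everywhere: 8-connectivity for
# objects, 4-neighbour background test for perimeter pixels; a
# "smoothing filter of size s" is a Gaussian of sigma = s / 2.355 (the
# full-width-half-maximum reading of the filter size).

#' Primary-object detection parameters
#'
#' @param diameterMinPx,diameterMaxPx accepted equivalent-diameter range
#'   in pixels (objects outside it are kept but categorised
#'   \code{discarded_size}).
#' @param thresholdStrategy \code{"automatic"} (Otsu on the full image
#'   histogram) or \code{"manual"}.
#' @param manualThreshold intensity threshold, required iff manual.
#' @param declumpSmoothingPx size of the smoothing filter applied to the
#'   distance transform before seed detection (0 disables smoothing).
#' @param maximaMinDistancePx minimum allowed distance between declumping
#'   seeds (local maxima); larger values merge clumped objects.
#' @param preSmoothingPx optional image pre-smoothing filter size.
#' @param fillHoles fill holes in the thresholded foreground.
#' @param excludeBorder categorise objects touching the image border as
#'   \code{discarded_border} (this class overrides the size class).
#' @return a validated parameter list.
#' @export
primaryParams <- function(diameterMinPx, diameterMaxPx,
                          thresholdStrategy = c("automatic", "manual"),
                          manualThreshold = NULL,
                          declumpSmoothingPx = 4,
                          maximaMinDistancePx = 5,
                          preSmoothingPx = 0,
                          fillHoles = TRUE,
                          excludeBorder = TRUE) {
  thresholdStrategy <- match.arg(thresholdStrategy)
  if (!(diameterMinPx > 0 && diameterMinPx < diameterMaxPx))
    stopCondition("parameter_error",
                  "need 0 < diameterMinPx < diameterMaxPx")
  if (declumpSmoothingPx < 0 || maximaMinDistancePx < 1)
    stopCondition("parameter_error",
                  "declumpSmoothingPx >= 0 and maximaMinDistancePx >= 1 required")
  if (thresholdStrategy == "manual" && is.null(manualThreshold))
    stopCondition("parameter_error",
                  "manual threshold strategy requires manualThreshold")
  list(diameterMinPx = diameterMinPx, diameterMaxPx = diameterMaxPx,
       thresholdStrategy = thresholdStrategy,
       manualThreshold = manualThreshold,
       declumpSmoothingPx = declumpSmoothingPx,
       maximaMinDistancePx = maximaMinDistancePx,
       preSmoothingPx = preSmoothingPx,
       fillHoles = fillHoles, excludeBorder = excludeBorder)
}

#' Secondary-object (cell) propagation parameters
#'
#' @param maxExpansionPx distance cap: no secondary pixel may lie
#'   farther than this (Euclidean) from its seed's pixel set.
#' @param guideThresholdStrategy \code{"automatic"} or \code{"manual"}
#'   threshold on the guide image (computed and logged).
#' @param guideManualThreshold intensity, required iff manual.
#' @return a validated parameter list.
#' @export
secondaryParams <- function(maxExpansionPx,
                            guideThresholdStrategy = c("automatic", "manual"),
                            guideManualThreshold = NULL) {
  guideThresholdStrategy <- match.arg(guideThresholdStrategy)
  if (maxExpansionPx < 0)
    stopCondition("parameter_error", "maxExpansionPx must be >= 0")
  if (guideThresholdStrategy == "manual" && is.null(guideManualThreshold))
    stopCondition("parameter_error",
                  "manual guide threshold strategy requires guideManualThreshold")
  list(method = "distance_b", maxExpansionPx = maxExpansionPx,
       guideThresholdStrategy = guideThresholdStrategy,
       guideManualThreshold = guideManualThreshold)
}

# Local maxima of `surface` within `mask`, no two closer than minDist:
# plateau-tolerant max-filter candidates, then greedy suppression in
# descending value (ties broken by row-major position).
localMaximaSeeds <- function(surface, mask, minDist) {
  brushSize <- 2L * as.integer(ceiling(minDist)) + 1L
  mx <- maxFilterDisc(surface, brushSize)
  cand <- which(mask & surface > 0 & surface >= mx - 1e-12, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(cand)
  vals <- surface[cand]
  rowMajor <- (cand[, 1] - 1) * ncol(surface) + (cand[, 2] - 1)
  ord <- order(-vals, rowMajor)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  kr <- kc <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kr) == 0L ||
        min((kr - cand[i, 1])^2 + (kc - cand[i, 2])^2) >= minDist^2) {
      keep[i] <- TRUE
      kr <- c(kr, cand[i, 1]); kc <- c(kc, cand[i, 2])
    }
  }
  cand[keep, , drop = FALSE]
}

# Split one 8-connected foreground component by shape declumping:
# Gaussian-smoothed Euclidean distance transform, local-maxima seeds at
# minimum separation, seeded watershed on the negated smoothed EDT.
declumpComponent <- function(compMask, smoothingPx, minDist) {
  edt <- as.matrix(EBImage::distmap(compMask))
  sm <- gaussianSmooth(edt, sigmaFromFilterSize(smoothingPx))
  sm[!compMask] <- 0
  seeds <- localMaximaSeeds(sm, compMask, minDist)
  if (nrow(seeds) <= 1L)
    return(matrix(as.integer(compMask), nrow(compMask)))
  seedLab <- matrix(0L, nrow(compMask), ncol(compMask))
  seedLab[seeds] <- seq_len(nrow(seeds))
  cpp_seeded_watershed(-sm, seedLab, compMask)
}

#' Identify primary objects (nuclei)
#'
#' Pipeline: optional pre-smoothing; foreground by automatic (Otsu) or
#' manual threshold; optional hole filling; per-component declumping
#' (smoothed distance-transform maxima feeding a seeded watershed);
#' size gating by equivalent diameter; optional border exclusion. The
#' border class overrides the size class. Accepted objects are
#' relabelled 1..K in row-major scan order of their first pixel;
#' discarded objects follow with higher labels.
#'
#' @param image a \linkS4class{ChannelImage}.
#' @param params a \code{\link{primaryParams}} list.
#' @return a \linkS4class{LabelMap} with per-label categories and an
#'   attribute \code{threshold} recording the applied threshold.
#' @export
identifyPrimaryObjects <- function(image, params) {
  px <- image@pixels
  if (anyNA(px) || any(!is.finite(px)))
    stopCondition("input_error", "image contains non-finite values")
  if (params$thresholdStrategy == "manual" && is.null(params$manualThreshold))
    stopCondition("parameter_error",
                  "manual threshold strategy requires manualThreshold")
  work <- gaussianSmooth(px, sigmaFromFilterSize(params$preSmoothingPx))
  thr <- if (params$thresholdStrategy == "manual") params$manualThreshold
         else if (min(work) == max(work)) Inf
         else otsuThreshold(work)
  fg <- work > thr
  if (params$fillHoles && any(fg)) fg <- as.matrix(EBImage::fillHull(fg)) > 0
  out <- matrix(0L, nrow(px), ncol(px))
  nObj <- 0L
  comp <- cpp_label8(fg)
  nComp <- max(comp)
  if (nComp > 0L) {
    idx <- which(comp > 0L, arr.ind = TRUE)
    labs <- comp[comp > 0L]
    rmin <- tapply(idx[, 1], labs, min); rmax <- tapply(idx[, 1], labs, max)
    cmin <- tapply(idx[, 2], labs, min); cmax <- tapply(idx[, 2], labs, max)
    pad <- 2L
    for (ci in seq_len(nComp)) {
      rr <- max(1L, rmin[[ci]] - pad):min(nrow(px), rmax[[ci]] + pad)
      cc <- max(1L, cmin[[ci]] - pad):min(ncol(px), cmax[[ci]] + pad)
      sub <- comp[rr, cc, drop = FALSE] == ci
      split <- declumpComponent(sub, params$declumpSmoothingPx,
                                params$maximaMinDistancePx)
      k <- max(split)
      sel <- split > 0L
      block <- out[rr, cc, drop = FALSE]
      block[sel] <- split[sel] + nObj
      out[rr, cc] <- block
      nObj <- nObj + k
    }
  }
  relabelWithCategories(out, params, pixelSizeUm = image@pixelSizeUm,
                        threshold = thr)
}

# Size/border gating and deterministic relabelling: accepted first, then
# discarded, each group ordered by the row-major index of the object's
# first pixel.
relabelWithCategories <- function(lab, params, pixelSizeUm, threshold) {
  nr <- nrow(lab); nc <- ncol(lab)
  ids <- seq_len(max(lab))
  if (length(ids) == 0L)
    return(structure(LabelMap(lab, character(0), pixelSizeUm),
                     threshold = threshold))
  area <- tabulate(lab[lab > 0L], nbins = max(lab))
  eqd <- equivDiameter(area)
  cat4 <- ifelse(eqd < params$diameterMinPx | eqd > params$diameterMaxPx,
                 "discarded_size", "accepted")
  if (isTRUE(params$excludeBorder)) {
    borderLabs <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    borderLabs <- borderLabs[borderLabs > 0L]
    cat4[borderLabs] <- "discarded_border"
  }
  idx <- which(lab > 0L)
  rowMajor <- ((idx - 1L) %% nr) * nc + ((idx - 1L) %/% nr)
  firstPix <- rep(Inf, length(ids))
  o <- order(rowMajor)
  firstSeen <- !duplicated(lab[idx][o])
  firstPix[lab[idx][o][firstSeen]] <- rowMajor[o][firstSeen]
  grp <- ifelse(cat4 == "accepted", 0L, 1L)
  newOrder <- order(grp, firstPix)
  remap <- integer(length(ids))
  remap[newOrder] <- seq_along(ids)
  newLab <- lab
  newLab[idx] <- remap[lab[idx]]
  structure(LabelMap(newLab, cat4[newOrder], pixelSizeUm),
            threshold = threshold)
}

#' Identify secondary objects (cells) by capped seed propagation
#'
#' The "Distance-B"-style growth: accepted seeds grow outwards, each
#' candidate pixel within \code{maxExpansionPx} (Euclidean, to the
#' seed's pixel set) being assigned to its nearest seed, with ties going
#' to the lower seed label, so frontiers between neighbouring cells lie
#' on the equidistance locus. Candidate territory is the union of the
#' above-threshold guide pixels and the fixed expansion zone around the
#' seeds, so cells in low-signal regions still receive the fixed
#' expansion. Every secondary object is a superset of its seed and
#' carries the seed's label.
#'
#' @param seeds a \linkS4class{LabelMap} of primary objects (only
#'   accepted seeds propagate).
#' @param guide a \linkS4class{ChannelImage} of the same dimensions.
#' @param params a \code{\link{secondaryParams}} list.
#' @return a \linkS4class{LabelMap} (all categories accepted) with
#'   attribute \code{guideThreshold}.
#' @export
identifySecondaryObjects <- function(seeds, guide, params) {
  lb <- seeds@labels
  if (!identical(dim(lb), dim(guide@pixels)))
    stopCondition("shape_error", "seeds and guide dimensions differ")
  acc <- acceptedLabels(seeds)
  seedLab <- lb
  seedLab[!(lb %in% acc)] <- 0L
  # relabel accepted seeds 1..K preserving order (they already are 1..K
  # for maps produced by identifyPrimaryObjects)
  remap <- integer(max(lb, 1L))
  remap[acc] <- seq_along(acc)
  seedLab[seedLab > 0L] <- remap[seedLab[seedLab > 0L]]
  gThr <- tryCatch({
    if (params$guideThresholdStrategy == "manual")
      params$guideManualThreshold
    else otsuThreshold(guide@pixels)
  }, degenerate_distribution_error = function(e) Inf)
  out <- cpp_nearest_seed(seedLab, params$maxExpansionPx)
  structure(LabelMap(out, rep("accepted", max(out)), seeds@pixelSizeUm),
            guideThreshold = gThr)
}

#' Identify the whole-spheroid footprint
#'
#' Smooths the image at a scale proportional to the diameter estimate
#' (filter size estimate/20), thresholds (manual preferred; Otsu as the
#' automatic fallback), applies morphological closing (radius
#' estimate/40) and hole filling, and returns the largest 8-connected
#' component whose equivalent diameter lies within [0.5, 2] times the
#' estimate.
#'
#' @param image a \linkS4class{ChannelImage} (typically the nuclear
#'   channel, or a merged nuclear image).
#' @param diameterEstimatePx rough spheroid diameter in pixels.
#' @param thresholdStrategy \code{"manual"} (preferred) or
#'   \code{"automatic"}.
#' @param manualThreshold intensity, required iff manual.
#' @return a \linkS4class{SpheroidMask}.
#' @export
identifySpheroid <- function(image, diameterEstimatePx,
                             thresholdStrategy = c("automatic", "manual"),
                             manualThreshold = NULL) {
  thresholdStrategy <- match.arg(thresholdStrategy)
  if (diameterEstimatePx <= 0)
    stopCondition("parameter_error", "diameterEstimatePx must be positive")
  if (thresholdStrategy == "manual" && is.null(manualThreshold))
    stopCondition("parameter_error",
                  "manual threshold strategy requires manualThreshold")
  px <- image@pixels
  sm <- gaussianSmooth(px, sigmaFromFilterSize(diameterEstimatePx / 20))
  thr <- if (thresholdStrategy == "manual") manualThreshold
         else if (min(sm) == max(sm)) Inf
         else otsuThreshold(sm)
  fg <- sm > thr
  if (!any(fg)) stopCondition("no_spheroid_found", "empty foreground")
  closeRad <- max(1L, as.integer(round(diameterEstimatePx / 40)))
  brush <- EBImage::makeBrush(2L * closeRad + 1L, "disc")
  fg <- as.matrix(EBImage::closing(fg, brush)) > 0
  fg <- as.matrix(EBImage::fillHull(fg)) > 0
  comp <- cpp_label8(fg)
  if (max(comp) == 0L)
    stopCondition("no_spheroid_found", "no component after morphology")
  area <- tabulate(comp[comp > 0L], nbins = max(comp))
  eqd <- equivDiameter(area)
  ok <- which(eqd >= 0.5 * diameterEstimatePx & eqd <= 2 * diameterEstimatePx)
  if (length(ok) == 0L)
    stopCondition("no_spheroid_found",
                  "no component within [0.5, 2] x the diameter estimate")
  best <- ok[which.max(area[ok])]
  SpheroidMask(comp == best, image@pixelSizeUm)
}
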