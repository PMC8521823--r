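# Synthetic spheroid phantom: an equatorial-section disk with a
# radially increasing hypoxia signal, a DRAQ7-positive necrotic core,
# depth-dependent mAG/mKO2 zonation and a depth-dependent infiltrating
# PBMC point pattern, plus per-object ground truth.

#' Depth-dependent parameter functions
#'
#' Small parametric families used to describe how a phantom quantity
#' varies with distance from the spheroid surface (depth, micrometres):
#' a constant, a step (shallow value below \code{depthUm}, deep value at
#' or beyond it), a logistic transition of characteristic width
#' \code{scaleUm} centred at \code{midpointUm}, and a linear ramp from
#' \code{surface} at \code{onsetUm} to \code{core} at the spheroid
#' centre (used for the hypoxia gradient).
#'
#' @param value,shallow,deep,surface,core function levels.
#' @param depthUm step location in micrometres.
#' @param midpointUm,scaleUm logistic midpoint and width in micrometres.
#' @param onsetUm depth at which the ramp leaves the surface level.
#' @return an object of class \code{depth_function}.
#' @name depthFunctions
NULL

#' @rdname depthFunctions
#' @export
depthConstant <- function(value)
  structure(list(type = "constant", value = value), class = "depth_function")

#' @rdname depthFunctions
#' @export
depthStep <- function(depthUm, shallow, deep)
  structure(list(type = "step", depth_um = depthUm, shallow = shallow,
                 deep = deep), class = "depth_function")

#' @rdname depthFunctions
#' @export
depthLogistic <- function(midpointUm, scaleUm, shallow, deep)
  structure(list(type = "logistic", midpoint_um = midpointUm,
                 scale_um = scaleUm, shallow = shallow, deep = deep),
            class = "depth_function")

#' @rdname depthFunctions
#' @export
depthRamp <- function(onsetUm, surface, core)
  structure(list(type = "ramp", onset_um = onsetUm, surface = surface,
                 core = core), class = "depth_function")

# Evaluate a depth function at depths d (micrometres); `endUm` is the
# maximal depth (spheroid radius), needed by the ramp family.
evalDepthFunction <- function(f, d, endUm = NA_real_) {
  switch(f$type,
    constant = rep(f$value, length(d)),
    step = ifelse(d < f$depth_um, f$shallow, f$deep),
    logistic = f$deep + (f$shallow - f$deep) /
      (1 + exp((d - f$midpoint_um) / f$scale_um)),
    ramp = {
      span <- max(endUm - f$onset_um, .Machine$double.eps)
      frac <- pmin(pmax((d - f$onset_um) / span, 0), 1)
      f$surface + (f$core - f$surface) * frac
    },
    stopCondition("parameter_error",
                  sprintf("unknown depth function type '%s'", f$type)))
}

#' Parameters of the synthetic spheroid phantom
#'
#' Defaults describe a medium-sized melanoma-like spheroid section: a
#' 280 um radius disk imaged at 2 um/px, ~10 um diameter nuclei, a
#' hypoxia gradient rising from 50 um depth, a 100 um-radius necrotic
#' core whose nuclei keep 30\% DAPI amplitude (so the nuclear channel
#' alone under-segments the core, motivating channel merging), a DRAQ7
#' positivity probability rising steeply around the core boundary, a
#' depth-decreasing mAG (cycling) fraction among non-necrotic nuclei,
#' and an infiltrating PBMC density that is high at the periphery, drops
#' in the mid zone and recovers toward the core.
#'
#' @param spheroidRadiusUm spheroid radius in micrometres.
#' @param nNuclei number of nuclei to place.
#' @param nucleusRadiusUm mean nucleus radius in micrometres.
#' @param nucleusRadiusJitter fractional uniform jitter on the radius.
#' @param minSeparationUm minimum distance between nucleus centres.
#' @param pixelSizeUm pixel edge length in micrometres.
#' @param hypoxiaGradient \code{\link{depthFunctions}} object mapping
#'   depth to pimonidazole amplitude (monotone increasing with depth).
#' @param necroticCoreRadiusUm radius of the necrotic core (must be
#'   smaller than the spheroid radius).
#' @param draq7PositiveProb depth function giving the DRAQ7-positive
#'   probability.
#' @param magFraction depth function giving the mAG-positive fraction
#'   among non-necrotic nuclei (decreasing with depth); non-mAG
#'   non-necrotic nuclei are mKO2-positive.
#' @param pbmcCount number of infiltrating PBMCs.
#' @param pbmcDepthDensity list with \code{breaks_um} (ascending depth
#'   breaks from 0) and \code{density} (one relative areal density per
#'   ring).
#' @param pbmcRadiusUm PBMC dot radius in micrometres.
#' @param signalAmplitude peak amplitude (DN) of nuclear/PBMC signals.
#' @param noiseSd additive Gaussian noise standard deviation (DN).
#' @param backgroundLevel background offset (DN).
#' @param canvasMarginFrac canvas margin as a fraction of the spheroid
#'   radius (must be at least 0.1).
#' @param maxPlacementAttempts dart-throwing retry budget per nucleus.
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @return a validated \code{SpheroidPhantomParams} list.
#' @export
spheroidPhantomParams <- function(
    spheroidRadiusUm = 280,
    nNuclei = 600,
    nucleusRadiusUm = 5,
    nucleusRadiusJitter = 0.15,
    minSeparationUm = 11,
    pixelSizeUm = 2,
    hypoxiaGradient = depthRamp(50, surface = 300, core = 2500),
    necroticCoreRadiusUm = 100,
    draq7PositiveProb = depthLogistic(180, 15, shallow = 0.05, deep = 0.95),
    magFraction = depthLogistic(100, 30, shallow = 0.7, deep = 0.1),
    pbmcCount = 150,
    pbmcDepthDensity = list(breaks_um = c(0, 70, 175, 280),
                            density = c(1, 0.4, 0.8)),
    pbmcRadiusUm = 4,
    signalAmplitude = 2000,
    noiseSd = 20,
    backgroundLevel = 100,
    canvasMarginFrac = 0.15,
    maxPlacementAttempts = 200L,
    seed = 1L) {
  p <- as.list(environment())
  class(p) <- "SpheroidPhantomParams"
  validatePhantomParams(p)
  p
}

validatePhantomParams <- function(p) {
  if (p$spheroidRadiusUm <= 0 || p$nucleusRadiusUm <= 0 ||
      p$pixelSizeUm <= 0 || p$pbmcRadiusUm <= 0)
    stopCondition("parameter_error", "all lengths must be positive")
  if (p$necroticCoreRadiusUm >= p$spheroidRadiusUm)
    stopCondition("parameter_error",
                  "necroticCoreRadiusUm must be smaller than spheroidRadiusUm")
  if (p$nucleusRadiusJitter < 0 || p$nucleusRadiusJitter >= 1)
    stopCondition("parameter_error", "nucleusRadiusJitter must be in [0, 1)")
  if (any(p$pbmcDepthDensity$density < 0))
    stopCondition("parameter_error", "PBMC ring densities must be >= 0")
  if (length(p$pbmcDepthDensity$breaks_um) !=
      length(p$pbmcDepthDensity$density) + 1L)
    stopCondition("parameter_error",
                  "pbmcDepthDensity needs one density per ring")
  if (p$noiseSd < 0 || p$backgroundLevel < 0)
    stopCondition("parameter_error", "noise and background must be >= 0")
  invisible(TRUE)
}

# Additively draw a soft-edged disk (raised-cosine edge of ~1 px) into
# matrix `m` by per-pixel maximum. Centre is 0-based (row, col).
drawSoftDisk <- function(m, row0, col0, radiusPx, amplitude) {
  nr <- nrow(m); nc <- ncol(m)
  r1 <- max(1L, floor(row0 - radiusPx - 1) + 1L)
  r2 <- min(nr, ceiling(row0 + radiusPx + 1) + 1L)
  c1 <- max(1L, floor(col0 - radiusPx - 1) + 1L)
  c2 <- min(nc, ceiling(col0 + radiusPx + 1) + 1L)
  if (r1 > r2 || c1 > c2) return(m)
  rr <- (r1:r2) - 1
  cc <- (c1:c2) - 1
  d <- sqrt(outer((rr - row0)^2, (cc - col0)^2, "+"))
  f <- ifelse(d <= radiusPx - 1, 1,
              ifelse(d >= radiusPx, 0,
                     0.5 * (1 + cos(pi * (d - (radiusPx - 1))))))
  m[r1:r2, c1:c2] <- pmax(m[r1:r2, c1:c2], amplitude * f)
  m
}

#' Generate a synthetic spheroid image with ground truth
#'
#' Returns the six-channel phantom (\code{DAPI}, \code{pimonidazole},
#' \code{DRAQ7}, \code{mAG}, \code{mKO2}, \code{PBMC}) and a ground
#' truth listing every nucleus (centre, radius, depth, class flags) and
#' every PBMC. Nuclei are soft-edged disks placed by dart throwing with
#' minimum-separation rejection; DAPI marks all nuclei (necrotic ones at
#' 30\% amplitude); the pimonidazole amplitude follows the hypoxia
#' gradient at the nucleus depth over an enlarged (cytoplasmic)
#' footprint; DRAQ7/mAG/mKO2 positivity is drawn per nucleus from the
#' configured depth functions (necrotic nuclei are never mAG- or
#' mKO2-positive); all channels receive the background level plus
#' zero-clipped Gaussian noise. Identical seeds give bit-identical
#' output.
#'
#' @param params a \code{\link{spheroidPhantomParams}} object.
#' @return list with elements \code{image}
#'   (\linkS4class{MultiChannelImage}) and \code{truth} (list with
#'   \code{nuclei} and \code{pbmc} data.frames, \code{spheroid}
#'   geometry, and the realised \code{params}).
#' @export
generatePhantom <- function(params) {
  validatePhantomParams(params)
  if (params$canvasMarginFrac < 0.1)
    stopCondition("geometry_error",
                  "canvas margin must be at least 10% of the spheroid radius")
  ps <- params$pixelSizeUm
  Rpx <- params$spheroidRadiusUm / ps
  half <- ceiling(Rpx * (1 + params$canvasMarginFrac))
  n <- 2L * as.integer(half) + 1L
  ctr <- half  # 0-based centre index (row = col)
  Rum <- params$spheroidRadiusUm

  withPhantomSeed(params$seed, {
    # --- nucleus placement: dart throwing with rejection ---
    nN <- params$nNuclei
    rows <- cols <- radii <- numeric(nN)
    minSepPx <- params$minSeparationUm / ps
    for (i in seq_len(nN)) {
      rPx <- params$nucleusRadiusUm *
        (1 + params$nucleusRadiusJitter * stats::runif(1, -1, 1)) / ps
      placed <- FALSE
      for (att in seq_len(params$maxPlacementAttempts)) {
        rad <- sqrt(stats::runif(1)) * max(Rpx - rPx, 0)
        th <- stats::runif(1, 0, 2 * pi)
        r0 <- ctr + rad * sin(th)
        c0 <- ctr + rad * cos(th)
        if (i == 1L ||
            min((rows[seq_len(i - 1L)] - r0)^2 +
                (cols[seq_len(i - 1L)] - c0)^2) >= minSepPx^2) {
          rows[i] <- r0; cols[i] <- c0; radii[i] <- rPx
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopCondition("packing_error", sprintf(
          "could not place nucleus %d within %d attempts", i,
          params$maxPlacementAttempts))
    }
    distPx <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
    depthUm <- (Rpx - distPx) * ps
    necrotic <- distPx * ps < params$necroticCoreRadiusUm

    # --- class draws (fixed draw order keeps the stream aligned) ---
    uDraq <- stats::runif(nN)
    uMag <- stats::runif(nN)
    draq7Pos <- uDraq < evalDepthFunction(params$draq7PositiveProb,
                                          depthUm, Rum)
    magPos <- !necrotic &
      uMag < evalDepthFunction(params$magFraction, depthUm, Rum)
    mko2Pos <- !necrotic & !magPos

    # --- PBMC placement by ring densities ---
    nP <- params$pbmcCount
    grid <- seq(0, Rum, length.out = 4001L)
    dens <- stats::approx(x = params$pbmcDepthDensity$breaks_um,
                          y = c(params$pbmcDepthDensity$density,
                                params$pbmcDepthDensity$density[
                                  length(params$pbmcDepthDensity$density)]),
                          xout = pmin(grid,
                                      max(params$pbmcDepthDensity$breaks_um)),
                          method = "constant", rule = 2)$y
    w <- dens * (Rum - grid)
    cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
    pDepth <- pRow <- pCol <- numeric(nP)
    if (nP > 0) {
      u <- stats::runif(nP)
      pDepth <- grid[pmin(length(grid), pmax(1L, findInterval(u, cdf) + 1L))]
      thP <- stats::runif(nP, 0, 2 * pi)
      radP <- (Rum - pDepth) / ps
      pRow <- ctr + radP * sin(thP)
      pCol <- ctr + radP * cos(thP)
    }

    # --- draw channels ---
    amp <- params$signalAmplitude
    blank <- matrix(0, n, n)
    chDAPI <- chPimo <- chDraq <- chMag <- chMko <- chPbmc <- blank
    pimoAmp <- evalDepthFunction(params$hypoxiaGradient, depthUm, Rum)
    for (i in seq_len(nN)) {
      dapiAmp <- if (necrotic[i]) 0.3 * amp else amp
      chDAPI <- drawSoftDisk(chDAPI, rows[i], cols[i], radii[i], dapiAmp)
      chPimo <- drawSoftDisk(chPimo, rows[i], cols[i], 1.6 * radii[i],
                             pimoAmp[i])
      if (draq7Pos[i])
        chDraq <- drawSoftDisk(chDraq, rows[i], cols[i], radii[i], amp)
      if (magPos[i])
        chMag <- drawSoftDisk(chMag, rows[i], cols[i], radii[i], amp)
      if (mko2Pos[i])
        chMko <- drawSoftDisk(chMko, rows[i], cols[i], radii[i], amp)
    }
    pbmcRadPx <- params$pbmcRadiusUm / ps
    for (j in seq_len(nP))
      chPbmc <- drawSoftDisk(chPbmc, pRow[j], pCol[j], pbmcRadPx, amp)

    addNoise <- function(m)
      pmax(m + params$backgroundLevel +
             matrix(stats::rnorm(n * n, 0, params$noiseSd), n, n), 0)
    chans <- list(DAPI = chDAPI, pimonidazole = chPimo, DRAQ7 = chDraq,
                  mAG = chMag, mKO2 = chMko, PBMC = chPbmc)
    chans <- lapply(chans, addNoise)
    image <- MultiChannelImage(mapply(
      function(nm, m) ChannelImage(nm, m, ps), names(chans), chans,
      SIMPLIFY = FALSE, USE.NAMES = FALSE))

    truth <- list(
      nuclei = data.frame(
        id = seq_len(nN), row0 = rows, col0 = cols, radius_px = radii,
        depth_um = depthUm, necrotic = necrotic, draq7_pos = draq7Pos,
        mag_pos = magPos, mko2_pos = mko2Pos),
      pbmc = data.frame(id = seq_len(nP), row0 = pRow, col0 = pCol,
                        depth_um = pDepth)[seq_len(nP), , drop = FALSE],
      spheroid = list(center_row0 = ctr, center_col0 = ctr,
                      radius_px = Rpx, radius_um = Rum),
      params = params)
    list(image = image, truth = truth)
  })
}

#' Closed-form expected depth profiles under phantom parameters
#'
#' The analytic expectation of a depth profile under the phantom's
#' generating functions, computed by numeric integration over ring
#' geometry: nuclei are uniform over the disk, so within a depth bin
#' \code{[a, b)} the expectation of a per-object quantity q(depth) is
#' the average of q weighted by the ring circumference \code{(R - d)}.
#' Used as the recovery target for profile tests.
#'
#' @param params a \code{\link{spheroidPhantomParams}} object.
#' @param binEdgesUm ascending depth bin edges starting at 0.
#' @param quantity \code{"mean_intensity"} (pimonidazole amplitude),
#'   \code{"positive_fraction"} or \code{"count"} (PBMCs).
#' @param channel for \code{positive_fraction}: \code{"DRAQ7"},
#'   \code{"mAG"} or \code{"mKO2"}.
#' @param normalize for \code{count}: \code{"none"} (expected PBMCs per
#'   bin) or \code{"ring_area"} (per square micrometre).
#' @return data.frame with \code{bin_start_um}, \code{bin_end_um},
#'   \code{expected} (NA for bins entirely beyond the spheroid radius).
#' @export
phantomProfileExpectation <- function(params, binEdgesUm,
                                      quantity = c("mean_intensity",
                                                   "positive_fraction",
                                                   "count"),
                                      channel = "DRAQ7",
                                      normalize = c("none", "ring_area")) {
  if (!quantity[1] %in% c("mean_intensity", "positive_fraction", "count"))
    stopCondition("parameter_error",
                  sprintf("unknown quantity '%s'", quantity[1]))
  quantity <- match.arg(quantity)
  normalize <- match.arg(normalize)
  if (binEdgesUm[1] != 0 || any(diff(binEdgesUm) <= 0))
    stopCondition("parameter_error", "bin edges must ascend from 0")
  R <- params$spheroidRadiusUm
  coreDepth <- R - params$necroticCoreRadiusUm  # necrotic iff depth > this
  grid <- seq(0, R, length.out = 8001L)
  w <- R - grid
  q <- switch(quantity,
    mean_intensity = evalDepthFunction(params$hypoxiaGradient, grid, R),
    positive_fraction = switch(channel,
      DRAQ7 = evalDepthFunction(params$draq7PositiveProb, grid, R),
      mAG = evalDepthFunction(params$magFraction, grid, R) *
        (grid <= coreDepth),
      mKO2 = (1 - evalDepthFunction(params$magFraction, grid, R)) *
        (grid <= coreDepth),
      stopCondition("parameter_error",
                    sprintf("unknown channel '%s'", channel))),
    count = {
      dd <- params$pbmcDepthDensity
      stats::approx(x = dd$breaks_um,
                    y = c(dd$density, dd$density[length(dd$density)]),
                    xout = pmin(grid, max(dd$breaks_um)),
                    method = "constant", rule = 2)$y
    })
  nb <- length(binEdgesUm) - 1L
  expected <- rep(NA_real_, nb)
  if (quantity == "count") {
    massTot <- sum(q * w)
    for (k in seq_len(nb)) {
      sel <- grid >= binEdgesUm[k] & grid < binEdgesUm[k + 1]
      if (!any(sel)) next
      cnt <- params$pbmcCount * sum(q[sel] * w[sel]) / massTot
      if (normalize == "ring_area") {
        a <- binEdgesUm[k]; b <- min(binEdgesUm[k + 1], R)
        area <- pi * ((R - a)^2 - (R - b)^2)
        cnt <- cnt / area
      }
      expected[k] <- cnt
    }
  } else {
    for (k in seq_len(nb)) {
      sel <- grid >= binEdgesUm[k] & grid < binEdgesUm[k + 1]
      if (!any(sel) || sum(w[sel]) <= 0) next
      expected[k] <- sum(q[sel] * w[sel]) / sum(w[sel])
    }
  }
  data.frame(bin_start_um = binEdgesUm[-length(binEdgesUm)],
             bin_end_um = binEdgesUm[-1], expected = expected)
}
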