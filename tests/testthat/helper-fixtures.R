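# Fixture builders and independent oracles shared across tests.
# Oracles here are deliberately naive (double loops, exhaustive scans)
# and independent of the package's implementation paths.

# Hard-edged disk image (no soft edge, no noise).
diskImage <- function(n, centerRow0, centerCol0, radiusPx, amp = 1000,
                      bg = 0, pixelSizeUm = 1, name = "disk") {
  m <- matrix(bg, n, n)
  idx <- which(matrix(TRUE, n, n), arr.ind = TRUE)
  d <- sqrt((idx[, 1] - 1 - centerRow0)^2 + (idx[, 2] - 1 - centerCol0)^2)
  m[idx[d <= radiusPx, , drop = FALSE]] <- amp
  ChannelImage(name, m, pixelSizeUm)
}

# Add a hard disk onto an existing matrix.
addDisk <- function(m, centerRow0, centerCol0, radiusPx, amp = 1000) {
  idx <- which(matrix(TRUE, nrow(m), ncol(m)), arr.ind = TRUE)
  d <- sqrt((idx[, 1] - 1 - centerRow0)^2 + (idx[, 2] - 1 - centerCol0)^2)
  sel <- idx[d <= radiusPx, , drop = FALSE]
  m[sel] <- pmax(m[sel], amp)
  m
}

# Small, fast phantom for unit tests (overridable defaults).
tinyPhantomParams <- function(...) {
  base <- list(spheroidRadiusUm = 120, nNuclei = 120,
               necroticCoreRadiusUm = 40, pbmcCount = 40,
               pbmcDepthDensity = list(breaks_um = c(0, 120), density = 1),
               seed = 42L)
  do.call(spheroidPhantomParams, utils::modifyList(base, list(...)))
}

# Independent perimeter scan: mask pixels with a 4-neighbour background
# (out-of-image = background), via explicit loops.
oraclePerimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    bg <- (r == 1 || !mask[r - 1, c]) || (r == nr || !mask[r + 1, c]) ||
          (c == 1 || !mask[r, c - 1]) || (c == nc || !mask[r, c + 1])
    if (bg) out <- rbind(out, c(r - 1, c - 1))
  }
  out
}

# Brute-force signed distance to surface in micrometres.
oracleDistance <- function(centroid, mask, pixelSizeUm = 1) {
  per <- oraclePerimeter(mask)
  d <- sqrt(min((per[, 1] - centroid[1])^2 + (per[, 2] - centroid[2])^2))
  pr <- floor(centroid[1] + 0.5) + 1; pc <- floor(centroid[2] + 0.5) + 1
  inside <- pr >= 1 && pr <= nrow(mask) && pc >= 1 && pc <= ncol(mask) &&
    mask[pr, pc]
  (if (inside) d else -d) * pixelSizeUm
}

# Brute-force nearest-seed assignment within a cap (ties: lower label).
oracleNearestSeed <- function(seedLab, cap) {
  sp <- which(seedLab > 0L, arr.ind = TRUE)
  sl <- seedLab[seedLab > 0L]
  out <- matrix(0L, nrow(seedLab), ncol(seedLab))
  for (r in seq_len(nrow(seedLab))) for (c in seq_len(ncol(seedLab))) {
    d2 <- (sp[, 1] - r)^2 + (sp[, 2] - c)^2
    dmin <- min(d2)
    if (dmin <= cap^2) out[r, c] <- min(sl[d2 == dmin])
  }
  out
}

# Random single-component blob mask: a chain of overlapping disks (each
# new centre lies inside the previous disk, so the union is connected).
randomBlobMask <- function(n = 60, nDisks = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ctr <- c(n / 2, n / 2)
  r <- stats::runif(1, n / 10, n / 5)
  m <- addDisk(m, ctr[1], ctr[2], r, 1)
  for (i in seq_len(nDisks - 1)) {
    th <- stats::runif(1, 0, 2 * pi)
    step <- stats::runif(1, 0, 0.8 * r)
    ctr <- pmin(pmax(ctr + step * c(sin(th), cos(th)), n / 5), 4 * n / 5)
    r <- stats::runif(1, n / 10, n / 5)
    m <- addDisk(m, ctr[1], ctr[2], r, 1)
  }
  m > 0
}

# Greedy one-to-one matching of truth nuclei to detected centroids
# (match = centroid within one nucleus radius); returns F1 and mean
# matched centroid error in pixels.
matchDetections <- function(truth, records) {
  if (nrow(records) == 0L)
    return(list(f1 = 0, meanErr = NA_real_, recall = 0, precision = NA))
  d <- sqrt(outer(truth$row0, records$centroid_row, "-")^2 +
            outer(truth$col0, records$centroid_col, "-")^2)
  used <- logical(nrow(records))
  errs <- numeric(0)
  tp <- 0L
  for (i in order(apply(d, 1, min))) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (is.finite(d[i, j]) && !used[j] && d[i, j] <= truth$radius_px[i]) {
      used[j] <- TRUE; tp <- tp + 1L; errs <- c(errs, d[i, j])
    }
  }
  recall <- tp / nrow(truth)
  precision <- tp / nrow(records)
  list(f1 = 2 * precision * recall / (precision + recall),
       meanErr = mean(errs), recall = recall, precision = precision)
}

# Standard analysis parameters used on phantoms in tests: the manual
# thresholds sit above background (100 DN) plus noise and below the
# dimmed necrotic DAPI amplitude (600 DN).
phantomNucleiParams <- function()
  primaryParams(3, 16, thresholdStrategy = "manual", manualThreshold = 300,
                declumpSmoothingPx = 2, maximaMinDistancePx = 4)
phantomPbmcParams <- function()
  primaryParams(2, 12, thresholdStrategy = "manual", manualThreshold = 300,
                declumpSmoothingPx = 2, maximaMinDistancePx = 3)
phantomSpheroid <- function(image)
  identifySpheroid(image, 280, "manual", 200)
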