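# Internal helpers shared across modules.

# Signal a classed error so callers can condition on the failure kind
# (read_error, shape_error, parameter_error, ...).
stopCondition <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Perimeter pixels: mask pixels with >= 1 background 4-neighbour;
# out-of-image counts as background. Returns 0-based (row, col).
perimeterPixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  hasBg <- !pad[1:nr, 2:(nc + 1L)] | !pad[3:(nr + 2L), 2:(nc + 1L)] |
           !pad[2:(nr + 1L), 1:nc] | !pad[2:(nr + 1L), 3:(nc + 2L)]
  idx <- which(core & hasBg, arr.ind = TRUE)
  cbind(row = idx[, 1] - 1, col = idx[, 2] - 1)
}

# Label boundary pixels (8-neighbour test): object pixels adjacent to a
# different label or to background, or lying on the image border.
boundaryPixelMask <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  core <- labels
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    out <- out | (nb != core)
  }
  out & core > 0L
}

# Otsu threshold in native intensity units. EBImage::otsu works on the
# [0, 1] scale, so rescale, threshold, and map back.
otsuThreshold <- function(values, levels = 256L) {
  rng <- range(values)
  if (!is.finite(rng[1]) || rng[1] == rng[2])
    stopCondition("degenerate_distribution_error",
                  "cannot Otsu-threshold a constant intensity distribution")
  scaled <- (values - rng[1]) / (rng[2] - rng[1])
  thr01 <- EBImage::otsu(matrix(scaled, nrow = length(scaled)),
                         range = c(0, 1), levels = levels)
  rng[1] + thr01 * (rng[2] - rng[1])
}

# Run `expr` under a private Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards.
withPhantomSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  oldSeed <- if (hadSeed) get(".Random.seed", envir = globalenv())
  oldKind <- RNGkind()
  on.exit({
    RNGkind(oldKind[1], oldKind[2], oldKind[3])
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  set.seed(as.integer(seed))
  expr
}

# Equivalent diameter of a pixel count.
equivDiameter <- function(areaPx) 2 * sqrt(areaPx / pi)

# Gaussian sigma for a "smoothing filter of size s" (FWHM reading).
sigmaFromFilterSize <- function(s) s / 2.355

# Zero-pad a matrix by `pad` pixels on every side.
padMatrix <- function(m, pad, value = 0) {
  out <- matrix(value, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  out[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  out
}

# Gaussian blur with zero boundary; tolerates sigma = 0, plain matrices
# and images smaller than the kernel (via padding).
gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  kernSize <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  kern <- EBImage::makeBrush(kernSize, "Gaussian", sigma = sigma)
  pad <- kernSize
  sm <- as.matrix(EBImage::filter2(padMatrix(m, pad), kern, boundary = 0))
  sm[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
}

# Grayscale max filter (disc) with zero boundary, safe for small crops.
maxFilterDisc <- function(m, brushSize) {
  pad <- brushSize
  d <- as.matrix(EBImage::dilate(padMatrix(m, pad),
                                 EBImage::makeBrush(brushSize, "disc")))
  d[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
}
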