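test_that("an all-zero image yields an empty label map", {
  img <- ChannelImage("x", matrix(0, 32, 32), 1)
  lm <- identifyPrimaryObjects(img, primaryParams(3, 10))
  expect_length(categories(lm), 0L)
  expect_true(all(labelMatrix(lm) == 0L))
})

test_that("well-separated nuclei are recovered with sub-pixel centroids", {
  m <- matrix(0, 80, 80)
  m <- addDisk(m, 20, 20, 10, 1000)
  m <- addDisk(m, 55, 58, 10, 1000)
  img <- ChannelImage("x", m, 1)
  lm <- identifyPrimaryObjects(img, primaryParams(10, 30))
  expect_equal(sum(categories(lm) == "accepted"), 2L)
  rec <- relateObjects(lm, SpheroidMask(matrix(TRUE, 80, 80) == TRUE, 1))
  ord <- order(rec$centroid_row)
  expect_lt(max(abs(rec$centroid_row[ord] - c(20, 55))), 1)
  expect_lt(max(abs(rec$centroid_col[ord] - c(20, 58))), 1)
})

test_that("border and size gates categorise objects as in the outline legend", {
  m <- matrix(0, 60, 60)
  m <- addDisk(m, 30, 30, 8, 1000)    # accepted
  m <- addDisk(m, 2, 30, 8, 1000)     # clipped by the image edge
  m <- addDisk(m, 45, 10, 2, 1000)    # too small
  img <- ChannelImage("x", m, 1)
  lm <- identifyPrimaryObjects(img, primaryParams(
    10, 25, thresholdStrategy = "manual", manualThreshold = 500))
  expect_setequal(categories(lm),
                  c("accepted", "discarded_border", "discarded_size"))
  # the border class overrides the size class even for out-of-range objects
  mm <- matrix(0, 60, 60)
  mm <- addDisk(mm, 1, 30, 3, 1000)   # tiny AND border-touching
  lm2 <- identifyPrimaryObjects(ChannelImage("x", mm, 1), primaryParams(
    10, 25, thresholdStrategy = "manual", manualThreshold = 500))
  expect_equal(categories(lm2), "discarded_border")
  # with exclusion off the same object is size-discarded instead
  lm3 <- identifyPrimaryObjects(ChannelImage("x", mm, 1), primaryParams(
    10, 25, thresholdStrategy = "manual", manualThreshold = 500,
    excludeBorder = FALSE))
  expect_equal(categories(lm3), "discarded_size")
})

test_that("accepted labels are 1..K and diameters respect the configured range", {
  ph <- generatePhantom(tinyPhantomParams())
  params <- phantomNucleiParams()
  lm <- identifyPrimaryObjects(getChannel(ph$image, "DAPI"), params)
  lab <- labelMatrix(lm)
  cats <- categories(lm)
  acc <- acceptedLabels(lm)
  expect_identical(acc, seq_along(acc))
  area <- tabulate(lab[lab > 0L], nbins = length(cats))
  eqd <- 2 * sqrt(area / pi)
  expect_true(all(eqd[cats == "accepted"] >= params$diameterMinPx &
                  eqd[cats == "accepted"] <= params$diameterMaxPx))
  sizeDisc <- cats == "discarded_size"
  expect_true(all(eqd[sizeDisc] < params$diameterMinPx |
                  eqd[sizeDisc] > params$diameterMaxPx))
})

test_that("declump splitting follows the maxima distance and is monotone", {
  m <- matrix(0, 64, 64)
  m <- addDisk(m, 23, 31, 10, 1000)
  m <- addDisk(m, 38, 31, 10, 1000)   # centres 15 px apart, fused blob
  img <- ChannelImage("x", m, 1)
  counts <- vapply(c(3, 7, 11, 16, 22, 30), function(md) {
    lm <- identifyPrimaryObjects(img, primaryParams(
      5, 40, thresholdStrategy = "manual", manualThreshold = 500,
      declumpSmoothingPx = 2, maximaMinDistancePx = md,
      excludeBorder = FALSE))
    length(categories(lm))
  }, numeric(1))
  expect_equal(counts[2], 2)
  expect_equal(counts[6], 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("manual strategy without a threshold is rejected", {
  expect_error(primaryParams(3, 10, thresholdStrategy = "manual"),
               class = "parameter_error")
  img <- ChannelImage("x", matrix(c(0, 1), 4, 4), 1)
  expect_error(identifyPrimaryObjects(
    img, list(diameterMinPx = 1, diameterMaxPx = 10,
              thresholdStrategy = "manual", manualThreshold = NULL,
              declumpSmoothingPx = 0, maximaMinDistancePx = 1,
              preSmoothingPx = 0, fillHoles = TRUE, excludeBorder = TRUE)),
    class = "parameter_error")
})

test_that("secondary propagation matches brute-force nearest-seed assignment", {
  m <- matrix(0, 96, 96)
  m <- addDisk(m, 30, 30, 6, 1000)
  m <- addDisk(m, 30, 50, 6, 1000)
  m <- addDisk(m, 60, 40, 6, 1000)
  seeds <- identifyPrimaryObjects(ChannelImage("x", m, 1), primaryParams(
    6, 20, thresholdStrategy = "manual", manualThreshold = 500))
  # guide uniformly below threshold: pure fixed-expansion fallback
  guide <- ChannelImage("g", matrix(10, 96, 96), 1)
  sec <- identifySecondaryObjects(seeds, guide,
                                  secondaryParams(5, "manual", 100))
  expect_identical(labelMatrix(sec),
                   oracleNearestSeed(labelMatrix(seeds), 5))
  # superset of seed, same labels
  expect_true(all(labelMatrix(sec)[labelMatrix(seeds) > 0L] ==
                  labelMatrix(seeds)[labelMatrix(seeds) > 0L]))
})

test_that("zero expansion reproduces the seeds exactly", {
  m <- addDisk(matrix(0, 48, 48), 24, 24, 6, 1000)
  seeds <- identifyPrimaryObjects(ChannelImage("x", m, 1), primaryParams(
    6, 20, thresholdStrategy = "manual", manualThreshold = 500))
  sec <- identifySecondaryObjects(seeds, ChannelImage("g", m, 1),
                                  secondaryParams(0))
  expect_identical(labelMatrix(sec), labelMatrix(seeds))
})

test_that("adjacent cells meet on the equidistance locus in a bright guide", {
  m <- matrix(0, 64, 64)
  m <- addDisk(m, 32, 24, 5, 1000)
  m <- addDisk(m, 32, 44, 5, 1000)
  seeds <- identifyPrimaryObjects(ChannelImage("x", m, 1), primaryParams(
    5, 20, thresholdStrategy = "manual", manualThreshold = 500))
  guide <- ChannelImage("g", matrix(5000, 64, 64), 1)
  sec <- identifySecondaryObjects(seeds, guide,
                                  secondaryParams(8, "manual", 100))
  lab <- labelMatrix(sec)
  sl <- labelMatrix(seeds)
  s1 <- which(sl == 1L, arr.ind = TRUE)
  s2 <- which(sl == 2L, arr.ind = TRUE)
  for (L in 1:2) {
    px <- which(lab == L, arr.ind = TRUE)
    own <- if (L == 1L) s1 else s2
    other <- if (L == 1L) s2 else s1
    for (i in seq_len(nrow(px))) {
      dOwn <- min((own[, 1] - px[i, 1])^2 + (own[, 2] - px[i, 2])^2)
      dOther <- min((other[, 1] - px[i, 1])^2 + (other[, 2] - px[i, 2])^2)
      expect_lte(dOwn, dOther)   # never strictly closer to the other seed
      expect_lte(sqrt(dOwn), 8)  # distance cap
    }
  }
})

test_that("spheroid detection recovers disk geometry and fills dark cores", {
  img <- diskImage(260, 129.5, 129.5, 100, amp = 1000, bg = 20)
  sph <- identifySpheroid(img, 200, "manual", 500)
  expect_lt(abs(equivalentDiameterPx(sph) - 200) / 200, 0.02)

  expect_error(identifySpheroid(ChannelImage("x", matrix(0, 64, 64), 1),
                                50, "manual", 10),
               class = "no_spheroid_found")

  # dark necrotic-core-like interior is filled by hole filling
  m <- pixels(img)
  m <- ifelse(sqrt((row(m) - 1 - 129.5)^2 + (col(m) - 1 - 129.5)^2) < 40,
              20, m)
  sph2 <- identifySpheroid(ChannelImage("x", m, 1), 200, "manual", 500)
  expect_gte(sum(sph2@mask), 0.98 * pi * 100^2)
})
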