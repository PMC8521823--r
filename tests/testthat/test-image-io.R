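test_that("stack write/read round trip is bit-exact and plane-ordered", {
  set.seed(1)
  chs <- lapply(1:4, function(i)
    ChannelImage(paste0("ch", i),
                 matrix(sample(0:65535, 64 * 64, TRUE), 64, 64), 2))
  stack <- MultiChannelImage(chs)
  path <- tempfile(fileext = ".tif")
  writeStack(stack, path)
  back <- readStack(path, pixelSizeUm = 2)
  expect_equal(length(back), 4L)
  expect_equal(dim(pixels(getChannel(back, 1))), c(64L, 64L))
  expect_equal(pixelSizeUm(back), 2)
  for (i in 1:4)
    expect_identical(pixels(getChannel(back, i)), pixels(chs[[i]]))
})

test_that("single-plane pixel sum matches an independent decoder", {
  set.seed(2)
  m <- matrix(sample(0:65535, 32 * 32, TRUE), 32, 32)
  path <- tempfile(fileext = ".tif")
  writeStack(ChannelImage("x", m, 1), path)
  back <- readStack(path, pixelSizeUm = 1)
  # independent decode through EBImage's own TIFF binding ([0,1] scale)
  ref <- round(as.matrix(EBImage::readImage(path)) * 65535)
  expect_equal(sum(pixels(getChannel(back, 1))), sum(ref))
})

test_that("missing pixel size and unreadable files raise classed errors", {
  path <- tempfile(fileext = ".tif")
  writeStack(ChannelImage("x", matrix(0, 8, 8), 1), path)
  expect_error(readStack(path), class = "calibration_error")
  bad <- tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(readStack(bad, pixelSizeUm = 1), class = "read_error")
})

test_that("splitChannels writes one identical file per channel", {
  set.seed(3)
  chs <- lapply(1:4, function(i)
    ChannelImage(paste0("ch", i),
                 matrix(sample(0:255, 16 * 16, TRUE), 16, 16), 1))
  stack <- MultiChannelImage(chs)
  outDir <- tempfile()
  sfx <- c("_dapi", "_pimo", "_pbmc", "_draq7")
  paths <- splitChannels(stack, sfx, outDir, stem = "spheroid1")
  expect_equal(basename(paths), paste0("spheroid1", sfx, ".tif"))
  for (i in 1:4) {
    back <- readStack(paths[i], pixelSizeUm = 1)
    expect_identical(pixels(getChannel(back, 1)), pixels(chs[[i]]))
  }

  two <- MultiChannelImage(chs[1:2])
  p2 <- splitChannels(two, c("_a", "_b"), tempfile())
  expect_length(p2, 2L)
  expect_true(all(file.exists(p2)))

  three <- MultiChannelImage(chs[1:3])
  expect_error(splitChannels(three, c("_a", "_b"), tempfile()),
               class = "suffix_count_error")
})

test_that("mergeChannels is a per-pixel max: identity, bound, commutative, idempotent", {
  set.seed(4)
  A <- ChannelImage("A", matrix(runif(100, 0, 50), 10, 10), 1)
  B <- ChannelImage("B", matrix(runif(100, 0, 50), 10, 10), 1)
  expect_equal(pixels(mergeChannels(list(A))), pixels(A))
  M <- mergeChannels(list(A, B))
  expect_equal(channelName(M), "merged")
  expect_true(all(pixels(M) >= pixels(A)) && all(pixels(M) >= pixels(B)))
  expect_equal(pixels(M), pixels(mergeChannels(list(B, A))))
  expect_equal(pixels(mergeChannels(list(A, A))), pixels(A))
  C <- ChannelImage("C", matrix(0, 4, 4), 1)
  expect_error(mergeChannels(list(A, C)), class = "shape_error")
})

test_that("merged FUCCI+DRAQ7 channels cover every nucleus footprint", {
  # necrotic nuclei are all DRAQ7+ here, so each nucleus emits in >= 1
  # of the three merged channels
  p <- tinyPhantomParams(draq7PositiveProb = depthStep(80, 0, 1))
  ph <- generatePhantom(p)
  merged <- mergeChannels(list(getChannel(ph$image, "mAG"),
                               getChannel(ph$image, "mKO2"),
                               getChannel(ph$image, "DRAQ7")))
  floorLevel <- p$backgroundLevel + 6 * p$noiseSd
  m <- pixels(merged)
  peak <- vapply(seq_len(nrow(ph$truth$nuclei)), function(i) {
    r <- round(ph$truth$nuclei$row0[i]) + 1
    c <- round(ph$truth$nuclei$col0[i]) + 1
    max(m[max(1, r - 1):min(nrow(m), r + 1),
          max(1, c - 1):min(ncol(m), c + 1)])
  }, numeric(1))
  expect_true(all(peak > floorLevel))
})

test_that("object tables round-trip losslessly and idempotently", {
  df <- data.frame(object_id = 1:3,
                   centroid_row = c(1.123456789, 2.5, pi),
                   area_px = c(10L, 20L, 30L),
                   inside_spheroid = c(TRUE, FALSE, TRUE),
                   distance_to_surface_um = c(-1.5, 0, 123.456789))
  p1 <- tempfile(fileext = ".csv")
  writeObjectTable(df, p1)
  expect_length(readLines(p1), 4L)  # header + 3 rows

  empty <- df[0, ]
  pe <- tempfile(fileext = ".csv")
  writeObjectTable(empty, pe)
  expect_length(readLines(pe), 1L)

  back <- readObjectTable(p1)
  expect_equal(nrow(back), 3L)
  expect_equal(back$distance_to_surface_um, df$distance_to_surface_um,
               tolerance = 1e-8)
  p2 <- tempfile(fileext = ".csv")
  writeObjectTable(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("overlay colours outlines by category over the grayscale image", {
  img <- diskImage(40, 19.5, 19.5, 10, amp = 800, bg = 100)
  emptyMap <- LabelMap(matrix(0L, 40, 40), character(0), 1)
  rgbE <- renderOverlay(img, emptyMap)
  expect_equal(rgbE[, , 1], rgbE[, , 2])
  expect_equal(rgbE[, , 2], rgbE[, , 3])

  lab <- matrix(0L, 40, 40)
  lab[pixels(img) > 500] <- 1L
  lm <- LabelMap(lab, "accepted", 1)
  rgb1 <- renderOverlay(img, lm, "outlines")
  # independent 8-neighbour boundary scan
  bnd <- matrix(FALSE, 40, 40)
  for (r in 1:40) for (c in 1:40) {
    if (lab[r, c] == 0L) next
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > 40 || cc < 1 || cc > 40 ||
          lab[rr, cc] != lab[r, c]) bnd[r, c] <- TRUE
    }
  }
  drawn <- rgb1[, , 2] > rgb1[, , 1] & rgb1[, , 2] > rgb1[, , 3]
  expect_identical(drawn, bnd)  # green strictly dominant exactly on outline
  expect_error(renderOverlay(diskImage(8, 4, 4, 2), lm),
               class = "shape_error")
})
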