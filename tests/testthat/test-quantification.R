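test_that("intensity features are exact on constructed objects", {
  lab <- matrix(0L, 10, 10)
  lab[2:5, 2:5] <- 1L                 # area 16, constant value
  lab[8, 8] <- 2L                     # singleton
  lab[2:3, 8:9] <- 3L                 # half a, half b
  ch <- matrix(0, 10, 10)
  ch[2:5, 2:5] <- 4
  ch[8, 8] <- 7
  ch[2:3, 8] <- 2; ch[2:3, 9] <- 10
  lm <- LabelMap(lab, rep("accepted", 3), 1)
  f <- measureObjectIntensity(lm, ChannelImage("x", ch, 1))
  expect_equal(f$mean, c(4, 7, 6))
  expect_equal(f$median, c(4, 7, 6))
  expect_equal(f$integrated, c(64, 7, 24))
  expect_equal(f$integrated, f$mean * c(16, 1, 4))
  expect_error(measureObjectIntensity(lm, ChannelImage("x", ch[1:5, ], 1)),
               class = "shape_error")
})

test_that("positivity classification applies manual and Otsu thresholds", {
  f <- classifyPositive(c(5, 15), "manual", manualThreshold = 10)
  expect_equal(as.logical(f), c(FALSE, TRUE))
  expect_equal(attr(f, "threshold"), 10)

  allEq <- classifyPositive(rep(3, 5), "manual", manualThreshold = 10)
  expect_false(any(allEq))

  expect_error(classifyPositive(rep(3, 5), "automatic"),
               class = "degenerate_distribution_error")

  # bimodal means, positives ~5x negatives, as for a DRAQ7 stain
  set.seed(21)
  truthPos <- stats::runif(400) < 0.3
  means <- ifelse(truthPos, stats::rnorm(400, 500, 60),
                  stats::rnorm(400, 100, 20))
  flags <- classifyPositive(means, "automatic")
  expect_gte(mean(as.logical(flags) == truthPos), 0.95)
})

test_that("mean-intensity profile averages per bin and flags empty bins", {
  rec <- data.frame(distance_to_surface_um = c(10, 20, 60),
                    inside_spheroid = TRUE,
                    pimonidazole_mean = c(2, 4, 100))
  prof <- meanIntensityProfile(rec, "pimonidazole", 25, maxDepthUm = 100)
  df <- as.data.frame(prof)
  expect_equal(df$value[1], 3)
  expect_equal(df$value[3], 100)
  expect_false(df$defined[2])
  expect_false(df$defined[4])
  expect_equal(sum(df$n_objects), 3L)

  none <- rec[0, ]
  p0 <- meanIntensityProfile(none, "pimonidazole", 25)
  expect_true(all(!p0@defined))
  expect_true(all(p0@nObjects == 0L))
  expect_error(meanIntensityProfile(rec, "DRAQ7", 25),
               class = "parameter_error")
})

test_that("bin refinement re-aggregates exactly to the coarse profile", {
  set.seed(5)
  rec <- data.frame(distance_to_surface_um = stats::runif(200, 0, 150),
                    inside_spheroid = TRUE,
                    pimonidazole_mean = stats::rnorm(200, 500, 100))
  coarse <- as.data.frame(meanIntensityProfile(rec, "pimonidazole", 30,
                                               maxDepthUm = 150))
  fine <- as.data.frame(meanIntensityProfile(rec, "pimonidazole", 15,
                                             maxDepthUm = 150))
  for (k in seq_len(nrow(coarse))) {
    sub <- fine[fine$bin_start_um >= coarse$bin_start_um[k] &
                fine$bin_end_um <= coarse$bin_end_um[k], ]
    n <- sum(sub$n_objects)
    expect_equal(n, coarse$n_objects[k])
    if (n > 0)
      expect_equal(sum(sub$value * sub$n_objects, na.rm = TRUE) / n,
                   coarse$value[k])
  }
})

test_that("positive-fraction profile bounds, empties and label invariance", {
  rec <- data.frame(distance_to_surface_um = c(5, 10, 40, 90),
                    inside_spheroid = TRUE,
                    DRAQ7_positive = c(TRUE, TRUE, TRUE, TRUE))
  prof <- positiveFractionProfile(rec, "DRAQ7", 25, maxDepthUm = 100)
  df <- as.data.frame(prof)
  expect_true(all(df$value[df$defined] == 1))
  expect_false(df$defined[3])
  expect_equal(df$n_objects[3], 0L)

  set.seed(9)
  rec2 <- data.frame(object_id = 1:50,
                     distance_to_surface_um = stats::runif(50, 0, 100),
                     inside_spheroid = TRUE,
                     DRAQ7_positive = stats::runif(50) < 0.5)
  a <- as.data.frame(positiveFractionProfile(rec2, "DRAQ7", 20))
  shuffled <- rec2[sample(50), ]
  shuffled$object_id <- 1:50
  b <- as.data.frame(positiveFractionProfile(shuffled, "DRAQ7", 20))
  expect_equal(a$value, b$value)
})

test_that("infiltration profile conserves counts and reports outside objects", {
  rec <- data.frame(distance_to_surface_um = c(-5, -1, 3, 30, 80),
                    inside_spheroid = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  prof <- infiltrationCountProfile(rec, 25, normalize = "none",
                                   spheroidRadiusUm = 100)
  df <- as.data.frame(prof)
  expect_equal(sum(df$n_objects) + prof@extra$outside_count, nrow(rec))
  expect_equal(prof@extra$outside_count, 2L)
  expect_equal(df$n_objects[1], 1L)

  none <- rec[0, ]
  p0 <- infiltrationCountProfile(none, 25, spheroidRadiusUm = 100,
                                 normalize = "none")
  expect_true(all(p0@value == 0))

  dens <- infiltrationCountProfile(rec, 25, normalize = "ring_area",
                                   spheroidRadiusUm = 100)
  a <- binEdgesUm(dens)
  areas <- pi * ((100 - a[-length(a)])^2 - (pmax(100 - a[-1], 0))^2)
  expect_equal(profileValues(dens), df$n_objects / areas)
  expect_error(infiltrationCountProfile(rec, 25, normalize = "ring_area"),
               class = "parameter_error")
})

test_that("ratio profile divides positive counts and guards zero denominators", {
  rec <- data.frame(distance_to_surface_um = c(10, 12, 14, 40, 44),
                    inside_spheroid = TRUE,
                    mKO2_positive = c(TRUE, TRUE, FALSE, TRUE, FALSE),
                    mAG_positive = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  prof <- ratioProfile(rec, "mKO2", "mAG", 25, maxDepthUm = 50)
  df <- as.data.frame(prof)
  expect_equal(df$value[1], 1)              # 2 positives each
  expect_false(df$defined[2])               # zero mAG+ in [25, 50)
  expect_equal(df$n_numerator[2], 1L)
  expect_equal(sum(df$n_objects), 5L)       # conservation over all objects
  expect_error(ratioProfile(rec, "mKO2", "DRAQ7", 25),
               class = "parameter_error")
})

test_that("profile CSV export mirrors the data.frame rendering", {
  rec <- data.frame(distance_to_surface_um = c(10, 30),
                    inside_spheroid = TRUE,
                    DRAQ7_positive = c(TRUE, FALSE))
  prof <- positiveFractionProfile(rec, "DRAQ7", 25, maxDepthUm = 50)
  path <- tempfile(fileext = ".csv")
  writeProfileTable(prof, path)
  back <- readObjectTable(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$value, c(1, 0))
  expect_equal(back$n_positive, c(1L, 0L))
})
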