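test_that("low-pass binarisation handles flat, bimodal and blurred inputs", {
  # constant images give an all-background mask (not an error)
  expect_false(any(lowpass_binarise(matrix(0, 50, 50))))
  expect_false(any(lowpass_binarise(matrix(3, 50, 50))))

  # step image: Otsu recovers the bright half exactly (no smoothing)
  img <- cbind(matrix(0.1, 40, 20), matrix(0.9, 40, 20))
  mask <- lowpass_binarise(img, segmentation_params(lowpass_sigma = 0))
  expect_identical(mask, img > 0.5)
  # oracle: exhaustive threshold search for the maximal between-class variance
  vals <- sort(unique(as.vector(img)))
  bcv <- vapply(vals[-length(vals)], function(th) {
    w1 <- mean(img <= th); w2 <- 1 - w1
    w1 * w2 * (mean(img[img > th]) - mean(img[img <= th]))^2
  }, numeric(1))
  best <- vals[which.max(bcv)]
  expect_identical(mask, img > best)

  # bright disc, sigma = 2: mask area within 2% of the rendered disc
  disc <- one_ellipse_field(a = 25, b = 25)
  m <- lowpass_binarise(disc$img, segmentation_params(lowpass_sigma = 2))
  expect_equal(sum(m), sum(disc$mask), tolerance = 0.02)
})

test_that("area fraction is correct, intensity-scale invariant and accurate", {
  expect_equal(positive_area_fraction(matrix(FALSE, 100, 100)), 0)
  expect_equal(positive_area_fraction(matrix(TRUE, 10, 10)), 1)
  m <- matrix(FALSE, 100, 100); m[1:50, 1:50] <- TRUE
  expect_equal(positive_area_fraction(m), 0.25)
  expect_error(positive_area_fraction(matrix(logical(0), 0, 0)), "empty")

  # relative (Otsu) threshold makes the fraction invariant to rescaling
  f <- gen_if_image(ellipse_field_spec(n_objects = 6, noise_sd = 0.02,
                                       psf_sigma = 1), seed = 3)
  p <- segmentation_params()
  frac1 <- positive_area_fraction(lowpass_binarise(f$marker, p))
  frac2 <- positive_area_fraction(lowpass_binarise(f$marker * 7.3, p))
  expect_equal(frac1, frac2)

  # accuracy vs rendered ground truth at 10% noise
  sp <- ellipse_field_spec(n_objects = 8, intensity_fg = 0.8,
                           noise_sd = 0.08, psf_sigma = 1)
  for (seed in 1:3) {
    f <- gen_if_image(sp, seed = seed)
    mask <- size_filter(lowpass_binarise(f$marker, p), p$min_object_area)
    expect_lt(abs(positive_area_fraction(mask) - f$area_fraction), 0.01)
  }
})

test_that("size filter removes small components, is idempotent, 8-connected", {
  m <- matrix(FALSE, 40, 40)
  m[2:4, 2] <- TRUE                        # 3-px speck
  expect_false(any(size_filter(m, 10)))

  m2 <- matrix(FALSE, 40, 40)
  m2[2:4, 2:4] <- TRUE                     # 9 px
  m2[10:19, 10:19] <- TRUE                 # 100 px
  kept <- size_filter(m2, 10)
  expect_equal(sum(kept), 100)
  expect_true(all(kept[10:19, 10:19]))

  expect_identical(size_filter(m2, 1), m2)                   # identity
  expect_identical(size_filter(kept, 10), kept)              # idempotent

  # diagonal touch counts as one component (8-connectivity)
  d <- matrix(FALSE, 10, 10)
  d[1:3, 1:3] <- TRUE; d[4, 4] <- TRUE
  expect_equal(sum(size_filter(d, 10)), 10)
})

test_that("segmentation measures eccentricity and solidity correctly", {
  p0 <- segmentation_params(lowpass_sigma = 0, min_object_area = 20)

  # a large circle is (nearly) round
  circ <- one_ellipse_field(a = 25, b = 25)
  fc <- segment_cells(circ$img, p0)
  expect_equal(nrow(fc), 1)
  expect_lt(fc$eccentricity, 0.1)
  expect_gt(fc$solidity, 0.9)

  # 2:1 ellipse: eccentricity sqrt(3)/2, across orientations (b >= 10 px)
  for (th in c(0, pi / 6, pi / 4, 1.35)) {
    fe <- segment_cells(one_ellipse_field(a = 30, b = 15, theta = th)$img, p0)
    expect_equal(fe$eccentricity, sqrt(1 - (1 / 2)^2), tolerance = 0.02)
  }

  # ring: with hole filling the area and solidity are those of the disc
  ring <- one_ellipse_field(a = 20, b = 20)
  hole <- myodyn:::render_ellipse_mask(128, 128, c(64, 64), 10, 10)
  ring$img[hole] <- 0.05
  fr <- segment_cells(ring$img, p0)
  expect_equal(fr$area, sum(one_ellipse_field(a = 20, b = 20)$mask),
               tolerance = 0.02)
  expect_gt(fr$solidity, 0.9)
  # without filling, the ring is far less solid and smaller
  fr2 <- segment_cells(ring$img, segmentation_params(
    lowpass_sigma = 0, min_object_area = 20, fill_holes = FALSE,
    solidity_range = c(0, 1)))
  expect_lt(fr2$area, fr$area)
  expect_lt(fr2$solidity, fr$solidity)

  # empty result is valid
  expect_equal(nrow(segment_cells(matrix(0, 30, 30), p0)), 0)
})

test_that("frame mean eccentricity averages objects and flags empty frames", {
  f <- data.frame(eccentricity = c(0.2, 0.4, 0.9))
  expect_equal(frame_mean_eccentricity(f), 0.5)
  expect_equal(frame_mean_eccentricity(data.frame(eccentricity = 0.7)), 0.7)
  expect_true(is.na(frame_mean_eccentricity(
    data.frame(eccentricity = numeric()))))
})

test_that("well quantification aggregates fields and compares groups", {
  # fields average within wells
  man <- data.frame(well = "w1", condition = "a", value = c(0.1, 0.2, 0.3))
  q <- quantify_wells(man)
  expect_equal(q$wells$value, 0.2)

  # identical per-well values: t = 0, p = 1
  man2 <- data.frame(well = rep(c("w1", "w2", "w3", "w4"), each = 3),
                     condition = rep(c("a", "b"), each = 6),
                     value = 0.25)
  q2 <- quantify_wells(man2)
  expect_equal(q2$test$statistic, 0)
  expect_equal(q2$test$p.value, 1)

  # clearly separated groups with tiny jitter are significant
  set.seed(42)
  man3 <- data.frame(well = rep(sprintf("w%d", 1:6), each = 3),
                     condition = rep(c("a", "b"), each = 9),
                     value = rep(c(0.1, 0.2), each = 9) + rnorm(18, 0, 1e-6))
  q3 <- quantify_wells(man3)
  expect_lt(q3$test$p.value, 0.05)
  expect_equal(q3$groups$mean, c(0.1, 0.2), tolerance = 1e-4)

  # a single-well group cannot be tested but is reported
  man4 <- data.frame(well = c("w1", "w2", "w3"),
                     condition = c("a", "b", "b"), value = c(0.1, 0.2, 0.3))
  expect_true(is.na(quantify_wells(man4)$test$p.value))

  # image-backed path: rendered fields through the area pipeline
  sp <- ellipse_field_spec(n_objects = 4, noise_sd = 0.02)
  dirp <- tempfile(); dir.create(dirp)
  on.exit(unlink(dirp, recursive = TRUE))
  rows <- list(); i <- 0
  for (w in c("hi1", "hi2", "lo1", "lo2")) for (fld in 1:2) {
    i <- i + 1
    n <- if (grepl("hi", w)) 8 else 2
    f <- gen_if_image(ellipse_field_spec(n_objects = n, noise_sd = 0.02),
                      seed = i)
    path <- file.path(dirp, sprintf("%s_%d.tif", w, fld))
    write_field_tiff(f$marker, path)
    rows[[i]] <- data.frame(well = w, condition = substr(w, 1, 2),
                            path = path)
  }
  q5 <- quantify_wells(do.call(rbind, rows), mode = "area")
  g <- q5$groups
  expect_gt(g$mean[g$condition == "hi"], g$mean[g$condition == "lo"])
})
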