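# Channel-diameter measurement from synthetic images.

test_that("extract_profile returns perpendicular lines and validates input", {
  img <- gen_channel_image(100, 5, image_size = c(60, 80))
  p <- extract_profile(img, 40)
  expect_length(p, 60)
  expect_lt(min(p), 0.2)   # crosses the dark band
  expect_gt(max(p), 0.8)

  flat <- channel_image(matrix(0.5, 40, 40), 5)
  expect_equal(unique(extract_profile(flat, 10)), 0.5)
  expect_error(extract_profile(img, 0), class = "pulsephantom_invalid_input")
  expect_error(extract_profile(img, 1e4), class = "pulsephantom_invalid_input")

  # RGB converts by Rec. 601 luma
  rgb <- array(0, dim = c(20, 20, 3))
  rgb[, , 1] <- 1
  ci <- channel_image(rgb, 2)
  expect_equal(unique(as.numeric(ci$pixels)), 0.299)
})

test_that("diameter_from_profile measures boxes and blurred boxes sub-pixel", {
  img <- gen_channel_image(100, 5, image_size = c(120, 40))
  expect_equal(diameter_from_profile(extract_profile(img, 20), 5), 100,
               tolerance = 1e-9)

  imgb <- gen_channel_image(100, 5, image_size = c(120, 40), blur_sigma_px = 2)
  expect_equal(diameter_from_profile(extract_profile(imgb, 20), 5), 100,
               tolerance = 5 / 100) # within 5 um of 100 um

  expect_error(diameter_from_profile(rep(0.5, 100), 5),
               class = "pulsephantom_detection_failure")
  # two separated troughs are ambiguous
  p2 <- rep(0.9, 100)
  p2[20:30] <- 0.1
  p2[60:70] <- 0.1
  expect_error(diameter_from_profile(p2, 5),
               class = "pulsephantom_ambiguity_error")
})

test_that("measure_channel_diameter averages lines; single line has zero sd", {
  img <- gen_channel_image(100, 5)
  est <- measure_channel_diameter(img)
  expect_equal(est$diameter_um, 100, tolerance = 1e-9)
  expect_equal(est$sd_um, 0)
  expect_equal(est$diameter_um, mean(est$per_line_diameters_um))

  est1 <- measure_channel_diameter(img, n_lines = 1)
  expect_equal(est1$n_lines, 1L)
  expect_equal(est1$sd_um, 0)

  noisy <- gen_channel_image(100, 5, blur_sigma_px = 1, noise_sd = 0.05, seed = 5)
  estn <- measure_channel_diameter(noisy)
  expect_lt(abs(estn$diameter_um - 100), 5) # within 1 px at 5 um/px

  blank <- channel_image(matrix(0.8, 100, 100), 5)
  expect_error(measure_channel_diameter(blank),
               class = "pulsephantom_measurement_failure")
})

test_that("diameter estimate is invariant to linear intensity rescaling", {
  img <- gen_channel_image(150, 5, blur_sigma_px = 2, noise_sd = 0.02, seed = 8)
  p <- extract_profile(img, 100)
  d0 <- diameter_from_profile(p, 5)
  d1 <- diameter_from_profile(0.6 * p + 0.35, 5)
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("accuracy within 1 px across widths and blurs (seeded)", {
  for (w_px in c(10, 40, 200)) {
    for (blur in c(0, 1, 3)) {
      errs <- sapply(1:3, function(s) {
        img <- gen_channel_image(w_px * 5, 5, image_size = c(240, 100),
                                 blur_sigma_px = blur, noise_sd = 0.05,
                                 seed = s)
        measure_channel_diameter(img)$diameter_um - w_px * 5
      })
      expect_lt(abs(mean(errs)) / 5, 1) # mean error below 1 px
    }
  }
})

test_that("expansion_series recovers the generating pump slope", {
  slope <- 0.26
  voltages <- seq(0, 250, by = 10)
  scale <- 2
  images <- lapply(voltages, function(v)
    gen_channel_image(150 + 2 * slope * v, scale, image_size = c(220, 60)))
  cal <- expansion_series(voltages, images)
  expect_equal(cal$slope_um_per_v, slope, tolerance = 0.05)
  expect_equal(nrow(attr(cal, "series")), 26)

  same <- lapply(voltages, function(v)
    gen_channel_image(150, scale, image_size = c(220, 60)))
  expect_equal(expansion_series(voltages, same)$slope_um_per_v, 0)

  expect_error(expansion_series(c(10, 20), images[1:2]),
               class = "pulsephantom_invalid_input") # no baseline image
})

test_that("PGM and CSV image files round-trip through read_channel_image", {
  tmp <- withr::local_tempdir()
  img <- gen_channel_image(80, 4, image_size = c(50, 30), blur_sigma_px = 1)
  p <- file.path(tmp, "ch.pgm")
  write_pgm(img$pixels, p)
  back <- read_channel_image(p, 4)
  expect_equal(back$pixels, img$pixels, tolerance = 1 / 255)
  est <- measure_channel_diameter(back)
  expect_equal(est$diameter_um, 80, tolerance = 4) # within 1 px of truth

  p2 <- file.path(tmp, "ch.csv")
  write.table(img$pixels, p2, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(read_channel_image(p2, 4)$pixels, img$pixels, tolerance = 1e-6)
  expect_error(read_channel_image(file.path(tmp, "x.tiff"), 4),
               class = "pulsephantom_invalid_input")
})
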