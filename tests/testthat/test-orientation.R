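test_that("grating orientation is recovered within 2 degrees at 9 angles", {
  for (a in seq(-80, 80, by = 20)) {
    ph <- make_fiber_phantom(fiber_phantom_spec(width = 96, height = 96,
                                                angles = a, period = 8,
                                                noise_sd = 0))
    of <- orientation_field(ph$image, channel = "SHG")
    m <- modal_angle(orientation_histogram(of))
    expect_lt(abs(angle_diff(m, a)), 2, label = sprintf("angle %d: |err|", a))
  }
})

test_that("orientation field matches a per-pixel brute-force reference", {
  set.seed(5)
  img <- matrix(runif(40 * 40), 40, 40)
  of <- orientation_field(img, sigma = 2, brightness_mask = FALSE,
                          border_exclude = 0)
  ref <- brute_orientation_angle(of$field$sIxx, of$field$sIyy, of$field$sIxy)
  expect_equal(of$angle[of$valid], ref[of$valid], tolerance = 1e-10)
})

test_that("orientation is rotationally equivariant", {
  base_angle <- 10
  ph <- make_fiber_phantom(fiber_phantom_spec(width = 128, height = 128,
                                              angles = base_angle, period = 8,
                                              noise_sd = 0))
  img <- get_channel(ph$image, "SHG")
  for (delta in c(15, 30, 45)) {
    rot <- microtissue:::rotate_raster(img, delta)
    # central crop avoids the empty corners introduced by rotation
    crop <- rot[33:96, 33:96]
    of <- orientation_field(crop)
    m <- modal_angle(orientation_histogram(of))
    expect_lt(abs(angle_diff(m, base_angle + delta)), 3,
              label = sprintf("delta %d: |err|", delta))
  }
})

test_that("vertical flip mirrors the orientation histogram about 0", {
  ph <- make_fiber_phantom(fiber_phantom_spec(width = 96, height = 96,
                                              angles = 35, period = 8,
                                              noise_sd = 0))
  img <- get_channel(ph$image, "SHG")
  h1 <- orientation_histogram(orientation_field(img))
  h2 <- orientation_histogram(orientation_field(img[nrow(img):1, ]))
  expect_lt(abs(angle_diff(modal_angle(h2), -modal_angle(h1))), 2)
  # full histogram reflects within sampling error
  expect_lt(sum(abs(h2$mass - rev(h1$mass))) / sum(h1$mass), 0.05)
})

test_that("a uniform image yields an all-invalid orientation field", {
  of <- orientation_field(matrix(1, 32, 32))
  expect_false(any(of$valid))
  expect_true(all(is.na(of$angle)))
})

test_that("histogram mass equals the masked pixel count or total brightness", {
  ph <- make_fiber_phantom(fiber_phantom_spec(width = 64, height = 64,
                                              angles = c(-45, 45), period = 8,
                                              noise_sd = 0, seed = 2))
  of <- orientation_field(ph$image, channel = "SHG")
  h <- orientation_histogram(of)
  expect_equal(sum(h$mass), sum(of$valid))
  hb <- orientation_histogram(of, weighting = "brightness")
  expect_equal(sum(hb$mass), sum(of$weight[of$valid]))
  # an additional mask restricts the mass
  m <- matrix(FALSE, 64, 64); m[1:32, ] <- TRUE
  hm <- orientation_histogram(of, mask = m)
  expect_equal(sum(hm$mass), sum(of$valid & m))
  # empty mask -> all-zero histogram
  h0 <- orientation_histogram(of, mask = matrix(FALSE, 64, 64))
  expect_true(all(h0$mass == 0))
})

test_that("two equal-weight modes at +/-45 deg give two equal histogram peaks", {
  ph <- make_fiber_phantom(fiber_phantom_spec(width = 256, height = 256,
                                              angles = c(-45, 45),
                                              weights = c(1, 1), period = 8,
                                              noise_sd = 0, seed = 4))
  of <- orientation_field(ph$image, channel = "SHG")
  h <- orientation_histogram(of, bin_width = 10)
  neg <- sum(h$mass[h$bin_mid < 0])
  pos <- sum(h$mass[h$bin_mid > 0])
  expect_lt(abs(neg - pos) / (neg + pos), 0.2)
  peaks <- order(h$mass, decreasing = TRUE)[1:2]
  expect_setequal(h$bin_mid[peaks], c(-45, 45))
})

test_that("single-mode phantom mass concentrates within one bin of the mode", {
  ph <- make_fiber_phantom(fiber_phantom_spec(width = 96, height = 96,
                                              angles = 30, period = 8,
                                              noise_sd = 0))
  of <- orientation_field(ph$image, channel = "SHG")
  h <- orientation_histogram(of, bin_width = 2)
  near <- abs(angle_diff(h$bin_mid, 30)) <= 3
  expect_gt(sum(h$mass[near]) / sum(h$mass), 0.9)
})

test_that("bin width must divide 180 evenly", {
  ph <- make_fiber_phantom(fiber_phantom_spec(width = 32, height = 32))
  of <- orientation_field(ph$image, channel = "SHG")
  expect_error(orientation_histogram(of, bin_width = 7), "180")
})

test_that("symmetry score is 1 for mirror-symmetric, 0 for one-sided histograms", {
  make_hist <- function(mass) {
    edges <- seq(-90, 90, by = 2)
    out <- tibble::tibble(
      bin_left = edges[-length(edges)], bin_right = edges[-1],
      bin_mid = (edges[-length(edges)] + edges[-1]) / 2, mass = mass
    )
    class(out) <- c("orientation_histogram", class(out))
    out
  }
  nb <- 90
  sym <- rep(0, nb)
  sym[abs(seq(-89, 89, by = 2)) == 45] <- 5   # mass m at +45 and -45
  expect_equal(symmetry_score(make_hist(sym)), 1.0)
  onesided <- rep(0, nb)
  onesided[seq(-89, 89, by = 2) == 45] <- 3   # all mass at +45
  expect_equal(symmetry_score(make_hist(onesided)), 0.0)
  # mass 3 at +45, 1 at -45: 1 - 4/8 = 0.5
  lop <- rep(0, nb)
  lop[seq(-89, 89, by = 2) == 45] <- 3
  lop[seq(-89, 89, by = 2) == -45] <- 1
  expect_equal(symmetry_score(make_hist(lop)), 0.5)
  expect_error(symmetry_score(make_hist(rep(0, nb))), "zero-mass")
})

test_that("HSV rendering maps angle to hue and brightness to value", {
  ph <- make_fiber_phantom(fiber_phantom_spec(width = 72, height = 72,
                                              angles = 0, period = 8,
                                              noise_sd = 0))
  of <- orientation_field(ph$image, channel = "SHG")
  rgb <- hsv_render(of, adjust_contrast = FALSE)
  expect_equal(dim(rgb), c(72, 72, 3))
  # constant angle -> one hue among valid bright pixels
  bright <- of$valid & of$weight > 0.99
  hue_ref <- grDevices::rgb2hsv(rgb[, , 1][bright], rgb[, , 2][bright],
                                rgb[, , 3][bright], maxColorValue = 1)["h", ]
  expect_lt(diff(range(hue_ref)), 0.02)
  # angles 90 deg apart -> opposite hues (180 deg apart on the hue circle)
  ph2 <- make_fiber_phantom(fiber_phantom_spec(width = 72, height = 72,
                                               angles = -89.9, period = 8,
                                               noise_sd = 0))
  of2 <- orientation_field(ph2$image, channel = "SHG")
  rgb2 <- hsv_render(of2, adjust_contrast = FALSE)
  bright2 <- of2$valid & of2$weight > 0.99
  hue2 <- grDevices::rgb2hsv(rgb2[, , 1][bright2], rgb2[, , 2][bright2],
                             rgb2[, , 3][bright2], maxColorValue = 1)["h", ]
  dh <- abs(mean(hue_ref) - mean(hue2))
  expect_equal(min(dh, 1 - dh), 0.5, tolerance = 0.02)
  # zero brightness -> black; invalid pixels -> black
  rgb0 <- hsv_render(of, brightness = matrix(0, 72, 72), adjust_contrast = FALSE)
  expect_equal(max(rgb0), 0)
  expect_error(hsv_render(of, brightness = matrix(1, 10, 10)), "dimensions")
})
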