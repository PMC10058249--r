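test_that("an already-aligned image passes through the aligner unchanged", {
  mt <- make_microtissue(quick_tissue_spec())
  al <- align_to_cleft(mt$image, mt$geometry)
  expect_equal(al$rotation, 0)
  expect_identical(al$image$channels, mt$image$channels)
})

test_that("a 90-degree bisector aligns losslessly with the tip on the left", {
  spec <- quick_tissue_spec(bisector_angle = 90, width = 320, height = 320,
                            tip = c(40, 160))
  mt <- make_microtissue(spec)
  al <- align_to_cleft(mt$image, mt$geometry)
  expect_equal(al$rotation, -90)
  expect_equal(al$geometry$bisector_angle, 0)
  # tip back at its aligned-frame position; exact pixels (lossless turn)
  expect_equal(c(al$geometry$tip_x, al$geometry$tip_y), c(40, 160))
  ref <- make_microtissue(quick_tissue_spec(width = 320, height = 320,
                                            tip = c(40, 160)))
  expect_equal(al$image$channels$Fn, ref$image$channels$Fn)
})

test_that("the aligner rejects a tip outside the image", {
  mt <- make_microtissue(quick_tissue_spec())
  bad <- cleft_geometry(-5, 10, 20, 45)
  expect_error(align_to_cleft(mt$image, bad), "outside")
})

test_that("profiles survive an arbitrary-rotation round trip within 2% RMS", {
  spec <- quick_tissue_spec(bisector_angle = 37, width = 360, height = 360,
                            tip = c(60, 180))
  mt <- make_microtissue(spec)
  prof_rot <- extract_profiles(mt$image, mt$geometry)
  direct <- make_microtissue(quick_tissue_spec(width = 360, height = 360,
                                               tip = c(60, 180)))
  prof_dir <- extract_profiles(direct$image, direct$geometry)
  cmp <- dplyr::inner_join(tibble::as_tibble(prof_rot),
                           tibble::as_tibble(prof_dir),
                           by = c("x_px", "channel"),
                           suffix = c("_rot", "_dir"))
  rms <- cmp |>
    dplyr::group_by(channel) |>
    dplyr::summarise(r = sqrt(mean((norm_rot - norm_dir)^2)), .groups = "drop")
  expect_lt(max(rms$r), 0.02)
  expect_lte(abs(front_position(prof_rot) - front_position(prof_dir)), 1)
})

test_that("the symmetry axis lands on the bisector of a symmetric tissue", {
  mt <- make_microtissue(quick_tissue_spec())
  al <- align_to_cleft(mt$image, mt$geometry)
  y <- select_symmetry_axis(al$image, al$geometry)
  expect_lte(abs(y - mt$spec$tip[2]), 1)
  expect_equal(select_symmetry_axis(al$image, al$geometry, override = 99), 99L)
})

test_that("band profile averages exactly the 100 selected rows", {
  # constant image -> constant profile
  cimg <- multichannel_image(list(A = matrix(2.5, 200, 40)), pixel_size = 1)
  p <- band_profile(cimg, y_axis = 100)
  expect_true(all(p$raw == 2.5))
  # band locality: rows outside the band do not contribute
  m <- matrix(0, 200, 30)
  m[50:149, ] <- 1
  p2 <- band_profile(multichannel_image(list(A = m)), y_axis = 100)
  expect_true(all(p2$raw == 1))
  expect_equal(attr(p2, "band_rows"), c(50, 149))
  # brute-force oracle on a random image, exact
  set.seed(21)
  r <- matrix(runif(300 * 50), 300, 50)
  p3 <- band_profile(multichannel_image(list(A = r)), y_axis = 151)
  expect_equal(p3$raw, brute_band_mean(r, 101:200))
  # clipped band rejected, reporting the offending rows
  expect_error(band_profile(cimg, y_axis = 20), "band rows -30..69")
})

test_that("normalization is per-channel, flags zero channels, and is idempotent", {
  m1 <- matrix(200 * c(1, rep(0.5, 19)), 120, 20, byrow = TRUE)
  img <- multichannel_image(list(A = m1, B = m1 / 4, Z = m1 * 0))
  p <- normalize_profile(band_profile(img, y_axis = 60))
  mx <- p |> dplyr::group_by(channel) |> dplyr::summarise(m = max(norm))
  expect_equal(mx$m[mx$channel == "A"], 1)
  expect_equal(mx$m[mx$channel == "B"], 1)
  expect_equal(mx$m[mx$channel == "Z"], 0)
  expect_equal(attr(p, "zero_channels"), "Z")
  p2 <- normalize_profile(p)
  expect_equal(p2$norm, p$norm)
})

test_that("front detection hits a step edge and honors the 25% rule on a ramp", {
  # step profile: tissue occupying x <= 60 of 100
  m <- matrix(0, 120, 100)
  m[, 1:60] <- 1
  p <- multichannel_image(list(A = m)) |>
    band_profile(y_axis = 60) |>
    normalize_profile() |>
    detect_front()
  expect_lte(abs(front_position(p) - 60), 1)
  # distance axis zero at the front, positive into the core (toward the tip)
  expect_equal(p$distance_um[p$x_px == front_position(p)][1], 0)
  expect_gt(p$distance_um[p$x_px == 1][1], 0)
  # monotonic ramp rising from the open side toward the tip
  ramp <- matrix(rep(seq(1, 0, length.out = 100), each = 120), 120, 100)
  pr <- multichannel_image(list(A = ramp)) |>
    band_profile(y_axis = 60) |>
    normalize_profile() |>
    detect_front(threshold_fraction = 0.25)
  f <- front_position(pr)
  frac <- pr$norm[pr$x_px == f][1]
  expect_equal(frac, 0.25, tolerance = 0.02)  # one pixel of quantization
})

test_that("raising the threshold never moves a monotonic front toward the open side", {
  ramp <- matrix(rep(seq(1, 0, length.out = 100), each = 120), 120, 100)
  img <- multichannel_image(list(A = ramp))
  base <- band_profile(img, y_axis = 60) |> normalize_profile()
  fronts <- vapply(c(0.1, 0.25, 0.5, 0.75),
                   function(th) front_position(detect_front(base, th)),
                   numeric(1))
  expect_true(all(diff(fronts) <= 0))
})

test_that("front detection recovers the generator front within 2 px", {
  for (seed in 1:5) {
    mt <- make_microtissue(microtissue_spec(seed = seed))
    prof <- extract_profiles(mt$image, mt$geometry)
    expect_lte(abs(front_position(prof) - mt$truth$front_x), 2,
               label = sprintf("seed %d: front error", seed))
  }
})

test_that("an empty profile raises a no-tissue error", {
  img <- multichannel_image(list(A = matrix(0, 120, 50)))
  p <- normalize_profile(band_profile(img, y_axis = 60))
  expect_error(detect_front(p), "no tissue")
})

test_that("noise-free extraction reproduces the generator profiles exactly", {
  mt <- make_microtissue(quick_tissue_spec())
  prof <- extract_profiles(mt$image, mt$geometry)
  cmp <- dplyr::inner_join(tibble::as_tibble(prof), mt$truth$profiles,
                           by = c("x_px", "channel"))
  expect_lt(max(abs(cmp$raw - cmp$value)), 1e-12)
  # normalized RMS as fraction of peak
  rms <- cmp |>
    dplyr::group_by(channel) |>
    dplyr::summarise(r = sqrt(mean((raw - value)^2)) / max(value), .groups = "drop")
  expect_lt(max(rms$r), 0.02)
})

test_that("front-marker peak widths of 10-20 um are recovered within 10%", {
  for (w in c(10, 15, 20)) {
    spec <- quick_tissue_spec(
      channels = list(
        Fn = front_marker_profile(amp = 1, width_um = w, decay_um = 30,
                                  plateau = 0.1),
        SHG = shg_profile()
      )
    )
    mt <- make_microtissue(spec)
    prof <- extract_profiles(mt$image, mt$geometry)
    expect_lt(abs(peak_fwhm(prof, "Fn") - w) / w, 0.1,
              label = sprintf("width %g um: relative error", w))
  }
})

test_that("integrated intensities equal the raw profile sums", {
  set.seed(31)
  r1 <- matrix(runif(200 * 60), 200, 60)
  r2 <- matrix(runif(200 * 60), 200, 60)
  img <- multichannel_image(list(A = r1, B = r2, Z = r1 * 0))
  p <- band_profile(img, y_axis = 100)
  ii <- integrated_intensity(p)
  expect_equal(ii$integrated[ii$channel == "A"], sum(brute_band_mean(r1, 50:149)))
  expect_equal(ii$integrated[ii$channel == "Z"], 0)
  cimg <- multichannel_image(list(A = matrix(3, 120, 40)))
  ic <- integrated_intensity(band_profile(cimg, y_axis = 60))
  expect_equal(ic$integrated, 3 * 40)
})
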