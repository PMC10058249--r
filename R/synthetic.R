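# run code with a local RNG state fixed by `seed`, restoring the caller's state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Fiber phantom specification
#'
#' Parameters for a synthetic fibrous texture with known per-pixel
#' orientation ground truth, used to validate the orientation pipeline.
#'
#' Two render styles are supported: `"grating"` (oriented sinusoidal
#' gratings, the default for orientation tests because their ground truth is
#' exact) tiles the image into square blocks whose orientations are drawn
#' from the requested distribution; `"segments"` draws anti-aliased oriented
#' line segments on a dark background.
#'
#' @param width,height Image size in pixels.
#' @param angles Orientation modes in degrees, each in `[-90, 90)`; or
#'   `"uniform"` for uniformly distributed orientations.
#' @param weights Non-negative weights of the modes (recycled to
#'   `length(angles)`); must sum to a positive value.
#' @param spread Von-Mises-like angular spread (degrees, s.d. of a wrapped
#'   normal about each mode; 0 = exact modes).
#' @param period Grating period in pixels; must be at least 2.
#' @param style `"grating"` or `"segments"`.
#' @param tile Block size in pixels for the grating style.
#' @param fiber_length,density Segment length (px) and mean number of
#'   segments per 1000 px^2, for the segments style; `density` must be
#'   positive.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units; intensities are in `[0, 1]`).
#' @param seed Random seed; fixes the output bit-exactly.
#' @return An object of class `fiber_phantom_spec`.
#' @export
fiber_phantom_spec <- function(width = 128, height = 128, angles = 0,
                               weights = 1, spread = 0, period = 8,
                               style = c("grating", "segments"), tile = 32,
                               fiber_length = 24, density = 4,
                               noise_sd = 0, seed = 1) {
  style <- match.arg(style)
  uniform <- identical(angles, "uniform")
  if (!uniform) {
    if (!is.numeric(angles) || any(angles < -90 | angles >= 90)) {
      stop("`angles` must lie in [-90, 90) degrees.", call. = FALSE)
    }
    weights <- rep_len(weights, length(angles))
    if (any(weights < 0) || sum(weights) <= 0) {
      stop("`weights` must be non-negative with positive sum.", call. = FALSE)
    }
  }
  if (period < 2) stop("`period` must be at least 2 px.", call. = FALSE)
  if (style == "segments" && density <= 0) {
    stop("`density` must be positive.", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative.", call. = FALSE)
  structure(
    list(width = width, height = height, angles = angles, weights = weights,
         uniform = uniform, spread = spread, period = period, style = style,
         tile = tile, fiber_length = fiber_length, density = density,
         noise_sd = noise_sd, seed = seed),
    class = "fiber_phantom_spec"
  )
}

# oriented sinusoidal grating in [0, 1]; fiber direction = angle (display CCW)
grating_raster <- function(nr, nc, angle, period, rows = seq_len(nr),
                           cols = seq_len(nc)) {
  th <- angle * pi / 180
  # intensity varies along the fiber normal n = (-sin, cos) in (x, y-up)
  r <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  phase <- 2 * pi / period * (cc * (-sin(th)) + (-r) * cos(th))
  0.5 + 0.5 * cos(phase)
}

sample_mode_angles <- function(spec, n) {
  if (spec$uniform) {
    return(stats::runif(n, -90, 90))
  }
  if (spec$spread == 0) {
    # deterministic proportional allocation (largest remainder), then a
    # seeded shuffle: mode masses match the weights exactly, up to one unit
    target <- n * spec$weights / sum(spec$weights)
    counts <- floor(target)
    short <- n - sum(counts)
    if (short > 0) {
      extra <- order(target - counts, decreasing = TRUE)[seq_len(short)]
      counts[extra] <- counts[extra] + 1L
    }
    a <- rep(spec$angles, counts)
    return(a[sample.int(n)])
  }
  a <- spec$angles[sample.int(length(spec$angles), n, replace = TRUE,
                              prob = spec$weights)]
  a <- a + stats::rnorm(n, sd = spec$spread)
  ((a + 90) %% 180) - 90
}

#' Generate a fiber phantom
#'
#' Renders a single-channel (`"SHG"`) fibrous texture with known per-pixel
#' orientation ground truth, per a [fiber_phantom_spec()].
#'
#' @param spec A [fiber_phantom_spec()].
#' @return A list of class `fiber_phantom`: `image` (a
#'   [multichannel_image()]), `truth` with `angle` (degrees, `NA` on
#'   background) and `fiber_mask`, and the `spec`.
#' @export
make_fiber_phantom <- function(spec) {
  stopifnot(inherits(spec, "fiber_phantom_spec"))
  with_local_seed(spec$seed, {
    nr <- spec$height; nc <- spec$width
    if (spec$style == "grating") {
      tiles_r <- ceiling(nr / spec$tile)
      tiles_c <- ceiling(nc / spec$tile)
      n_tiles <- tiles_r * tiles_c
      single <- !spec$uniform && length(spec$angles) == 1L && spec$spread == 0
      tile_angle <- if (single) rep(spec$angles, n_tiles) else
        sample_mode_angles(spec, n_tiles)
      img <- matrix(0, nr, nc)
      truth <- matrix(NA_real_, nr, nc)
      t_idx <- 0L
      for (tr in seq_len(tiles_r)) {
        for (tc in seq_len(tiles_c)) {
          t_idx <- t_idx + 1L
          rows <- ((tr - 1L) * spec$tile + 1L):min(tr * spec$tile, nr)
          cols <- ((tc - 1L) * spec$tile + 1L):min(tc * spec$tile, nc)
          img[rows, cols] <- grating_raster(nr, nc, tile_angle[t_idx],
                                            spec$period, rows, cols)
          truth[rows, cols] <- tile_angle[t_idx]
        }
      }
      fiber_mask <- matrix(TRUE, nr, nc)
    } else {
      img <- matrix(0, nr, nc)
      truth <- matrix(NA_real_, nr, nc)
      n_seg <- max(1L, round(spec$density * nr * nc / 1000))
      ang <- sample_mode_angles(spec, n_seg)
      cx <- stats::runif(n_seg, 1, nc)
      cy <- stats::runif(n_seg, 1, nr)
      half <- spec$fiber_length / 2
      for (s in seq_len(n_seg)) {
        th <- ang[s] * pi / 180
        ux <- cos(th); uy <- -sin(th)          # fiber direction, row coords
        r0 <- max(1L, floor(cy[s] - half - 2)); r1 <- min(nr, ceiling(cy[s] + half + 2))
        c0 <- max(1L, floor(cx[s] - half - 2)); c1 <- min(nc, ceiling(cx[s] + half + 2))
        rows <- r0:r1; cols <- c0:c1
        rr <- matrix(rows, length(rows), length(cols))
        cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
        dx <- cc - cx[s]; dy <- rr - cy[s]
        along <- dx * ux + dy * uy
        perp <- -dx * uy + dy * ux
        d2 <- perp^2 + pmax(abs(along) - half, 0)^2
        val <- exp(-d2 / 2)                    # 1-px Gaussian cross profile
        patch <- img[rows, cols]
        upd <- val > patch
        patch[upd] <- val[upd]
        img[rows, cols] <- patch
        tp <- truth[rows, cols]
        tp[val > 0.5] <- ang[s]                # last-drawn segment wins
        truth[rows, cols] <- tp
      }
      fiber_mask <- !is.na(truth)
    }
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
      img <- pmin(pmax(img, 0), 1)
      dim(img) <- c(nr, nc)
    }
    structure(
      list(image = multichannel_image(list(SHG = img), pixel_size = 1),
           truth = list(angle = truth, fiber_mask = fiber_mask),
           spec = spec),
      class = "fiber_phantom"
    )
  })
}

#' Front-marker and SHG channel profile parameters
#'
#' Helper constructors for the per-channel axial profiles of
#' [microtissue_spec()]. Distances `d` are measured from the growth front
#' into the tissue core, in micrometers.
#'
#' `front_marker_profile()`: a Gaussian peak of full width `width_um`
#' centered `width_um / 2` behind the front (amplitude `amp`), plus a core
#' plateau approached with decay length `decay_um`:
#' `f(d) = amp * exp(-0.5 ((d - width/2) / (width/2.355))^2) +
#'  plateau * (1 - exp(-d / decay))`.
#'
#' `shg_profile()`: a logistic rise behind the front,
#' `f(d) = amp / (1 + exp(-(d - rise_um) / tau_um)) + plateau`.
#'
#' @param amp Peak amplitude (intensity units, image intensities in `[0,1]`).
#' @param width_um Peak full width at half maximum, um (the growth-front
#'   width; 10-20 um for these microtissues).
#' @param decay_um Core decay length, um.
#' @param plateau Core plateau level.
#' @param rise_um Distance behind the front at which the SHG signal reaches
#'   half its amplitude, um.
#' @param tau_um Logistic steepness of the SHG rise, um.
#' @return A list of class `channel_profile` with a `fun(d_um)` element.
#' @export
front_marker_profile <- function(amp = 1, width_um = 15, decay_um = 30,
                                 plateau = 0.15) {
  if (width_um <= 0) stop("`width_um` must be positive.", call. = FALSE)
  sd_um <- width_um / (2 * sqrt(2 * log(2)))
  structure(
    list(type = "front_marker", amp = amp, width_um = width_um,
         decay_um = decay_um, plateau = plateau,
         fun = function(d) {
           ifelse(d >= 0,
                  amp * exp(-0.5 * ((d - width_um / 2) / sd_um)^2) +
                    plateau * (1 - exp(-d / decay_um)),
                  0)
         }),
    class = "channel_profile"
  )
}

#' @rdname front_marker_profile
#' @export
shg_profile <- function(amp = 0.7, rise_um = 15, tau_um = 5, plateau = 0.02) {
  if (tau_um <= 0) stop("`tau_um` must be positive.", call. = FALSE)
  structure(
    list(type = "shg", amp = amp, rise_um = rise_um, tau_um = tau_um,
         plateau = plateau,
         fun = function(d) {
           ifelse(d >= 0, amp / (1 + exp(-(d - rise_um) / tau_um)) + plateau, 0)
         }),
    class = "channel_profile"
  )
}

#' Synthetic microtissue specification
#'
#' Parameters of a synthetic multi-channel microtissue growing in an angular
#' cleft: a wedge-shaped tissue mask advancing along the bisector, ECM /
#' myofibroblast marker channels (`Fn`, `aSMA`, `TNC`) with steep
#' front-localized peaks decaying into the core, an `SHG` collagen channel
#' rising behind the front (optionally with fibrous texture: tangentially
#' aligned near the front, wavy/random in the core), and additive Gaussian
#' noise.
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Pixel size in um/px.
#' @param tip Cleft tip position `c(x, y)` in pixels.
#' @param bisector_angle Bisector direction (degrees CCW from +x, display
#'   convention); 0 = already aligned, tip left.
#' @param cleft_angle Cleft opening angle in degrees (default 45).
#' @param growth_um Growth distance from tip to front, um; must be
#'   non-negative and fit inside the image.
#' @param channels Named list of [front_marker_profile()] /
#'   [shg_profile()] objects; must be non-empty.
#' @param shg_texture Add fibrous texture to the SHG channel.
#' @param texture_period Texture ripple period, px.
#' @param texture_amp Texture ripple amplitude (fraction of local SHG level).
#' @param noise_sd Additive Gaussian noise s.d. (intensity units).
#' @param band_half_width Band half-width (px) used for the ground-truth
#'   band-averaged profiles (matches the analysis default of 50, i.e. a
#'   100-pixel band).
#' @param seed Random seed; fixes the output bit-exactly.
#' @return An object of class `microtissue_spec`.
#' @export
microtissue_spec <- function(width = 320, height = 256, pixel_size = 1,
                             tip = c(40, 128), bisector_angle = 0,
                             cleft_angle = 45, growth_um = 150,
                             channels = list(
                               Fn = front_marker_profile(amp = 1, width_um = 15,
                                                         decay_um = 30, plateau = 0.15),
                               aSMA = front_marker_profile(amp = 0.9, width_um = 18,
                                                           decay_um = 25, plateau = 0.10),
                               TNC = front_marker_profile(amp = 0.8, width_um = 15,
                                                          decay_um = 40, plateau = 0.20),
                               SHG = shg_profile()
                             ),
                             shg_texture = TRUE, texture_period = 8,
                             texture_amp = 0.25, noise_sd = 0.01,
                             band_half_width = 50, seed = 1) {
  if (growth_um < 0) stop("`growth_um` must be non-negative.", call. = FALSE)
  if (length(channels) == 0L || is.null(names(channels))) {
    stop("`channels` must be a non-empty named list.", call. = FALSE)
  }
  for (nm in names(channels)) {
    if (!inherits(channels[[nm]], "channel_profile")) {
      stop(sprintf("channel '%s' must be a channel_profile object.", nm),
           call. = FALSE)
    }
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative.", call. = FALSE)
  # the tissue is rendered in the aligned frame (tip left, growth toward +x)
  # before any de-aligning rotation, so it must fit there
  growth_px <- growth_um / pixel_size
  if (tip[1] + growth_px > width) {
    stop("`growth_um` exceeds the image extent beyond the tip.", call. = FALSE)
  }
  structure(
    list(width = width, height = height, pixel_size = pixel_size,
         tip = tip, bisector_angle = bisector_angle, cleft_angle = cleft_angle,
         growth_um = growth_um, channels = channels, shg_texture = shg_texture,
         texture_period = texture_period, texture_amp = texture_amp,
         noise_sd = noise_sd, band_half_width = band_half_width, seed = seed),
    class = "microtissue_spec"
  )
}

#' Generate a synthetic microtissue image
#'
#' Renders the multi-channel microtissue described by a
#' [microtissue_spec()] and returns it together with its ground truth: the
#' front position, the tissue mask, and the noiseless band-averaged
#' per-channel profiles (the exact oracle for profile extraction with the
#' matching band width), plus the analytic axial profile functions.
#'
#' @param spec A [microtissue_spec()].
#' @return A list of class `microtissue`: `image` ([multichannel_image()]
#'   with tissue mask), `geometry` ([cleft_geometry()]), `truth` (list with
#'   `front_x` in px, `growth_um`, `profiles` tibble of noiseless
#'   band-averaged values, `axial_profiles`), and the `spec`.
#' @export
make_microtissue <- function(spec) {
  stopifnot(inherits(spec, "microtissue_spec"))
  with_local_seed(spec$seed, {
    nr <- spec$height; nc <- spec$width
    geom0 <- cleft_geometry(spec$tip[1], spec$tip[2], 0, spec$cleft_angle)
    growth_px <- spec$growth_um / spec$pixel_size
    front_x <- spec$tip[1] + growth_px
    mask <- wedge_mask(geom0, c(nr, nc), max_axial = growth_px)
    if (growth_px <= 0) mask[] <- FALSE
    cols <- seq_len(nc)
    d_col_um <- (front_x - cols) * spec$pixel_size   # axial distance per column
    texture <- NULL
    if (spec$shg_texture && "SHG" %in% names(spec$channels)) {
      # tangentially aligned (vertical fibers) near the front, wavy in the core
      r <- matrix(seq_len(nr), nr, nc)
      cc <- matrix(cols, nr, nc, byrow = TRUE)
      d_px <- front_x - cc
      wob <- 8 * sin(2 * pi * r / 64) * sin(2 * pi * cc / 48)  # wavy core phase
      front_ph <- 2 * pi * cc / spec$texture_period
      core_ph <- 2 * pi * (cc + wob) / (1.5 * spec$texture_period)
      w_front <- exp(-pmax(d_px, 0) / 40)
      texture <- 1 + spec$texture_amp *
        (w_front * cos(front_ph) + (1 - w_front) * cos(core_ph))
    }
    channels <- lapply(names(spec$channels), function(nm) {
      prof <- spec$channels[[nm]]$fun(d_col_um)
      m <- matrix(prof, nr, nc, byrow = TRUE)
      m[!mask] <- 0
      if (nm == "SHG" && !is.null(texture)) m <- m * texture
      m
    })
    names(channels) <- names(spec$channels)
    # ground truth: exact noiseless band-averaged column means at the bisector
    h <- spec$band_half_width
    band_rows <- (round(spec$tip[2]) - h):(round(spec$tip[2]) + h - 1L)
    band_rows <- band_rows[band_rows >= 1 & band_rows <= nr]
    gt_profiles <- purrr::map_dfr(names(channels), function(nm) {
      tibble::tibble(
        x_px = cols,
        distance_um = d_col_um,
        channel = nm,
        value = colMeans(channels[[nm]][band_rows, , drop = FALSE])
      )
    })
    if (spec$noise_sd > 0) {
      channels <- lapply(channels, function(m) {
        m <- m + stats::rnorm(length(m), sd = spec$noise_sd)
        m <- pmin(pmax(m, 0), 1)
        dim(m) <- c(nr, nc)
        m
      })
    }
    img <- multichannel_image(channels, pixel_size = spec$pixel_size, mask = mask)
    out <- list(
      image = img,
      geometry = geom0,
      truth = list(front_x = front_x, growth_um = spec$growth_um,
                   profiles = gt_profiles,
                   axial_profiles = lapply(spec$channels, `[[`, "fun")),
      spec = spec
    )
    if (abs(spec$bisector_angle) > 1e-9) {
      # de-align: rotate the content by +bisector (exact for 90-degree
      # multiples) by running the aligner with the opposite target angle
      tmp <- cleft_geometry(spec$tip[1], spec$tip[2], -spec$bisector_angle,
                            spec$cleft_angle)
      al <- align_to_cleft(img, tmp)
      out$image <- al$image
      out$geometry <- cleft_geometry(al$geometry$tip_x, al$geometry$tip_y,
                                     spec$bisector_angle, spec$cleft_angle)
    }
    class(out) <- "microtissue"
    out
  })
}

#' @export
print.microtissue <- function(x, ...) {
  cat(sprintf("<microtissue> %d x %d px, growth %.1f um, front at x = %.1f px\n",
              image_dim(x$image)[1], image_dim(x$image)[2],
              x$truth$growth_um, x$truth$front_x))
  invisible(x)
}

#' Generate a growth time series of synthetic microtissues
#'
#' Produces one synthetic microtissue per observation day, with ground-truth
#' growth distance `rate * (day - t0)` clipped at 0 (plus optional Gaussian
#' measurement noise on the distances).
#'
#' @param rate_um_per_day Growth rate in um/day; must be non-negative.
#' @param days Numeric vector of observation days, sorted ascending.
#' @param spec A [microtissue_spec()] used as template (its `growth_um` is
#'   overridden per day).
#' @param t0 Day at which growth starts (default 0).
#' @param distance_noise_sd Gaussian noise s.d. on the rendered distances, um.
#' @param seed Random seed for the distance noise and per-day images.
#' @return A tibble of class `growth_series` with columns `day`,
#'   `distance_um` (the rendered, i.e. per-image ground-truth distance) and
#'   a list-column `tissue` of `microtissue` objects. Empty `days` gives an
#'   empty series.
#' @export
make_growth_series <- function(rate_um_per_day, days,
                               spec = microtissue_spec(), t0 = 0,
                               distance_noise_sd = 0, seed = 1) {
  if (rate_um_per_day < 0) {
    stop("`rate_um_per_day` must be non-negative.", call. = FALSE)
  }
  if (is.unsorted(days, strictly = FALSE)) {
    stop("`days` must be sorted ascending.", call. = FALSE)
  }
  if (length(days) == 0L) {
    out <- tibble::tibble(day = numeric(), distance_um = numeric(),
                          tissue = list())
    class(out) <- c("growth_series", class(out))
    return(out)
  }
  with_local_seed(seed, {
    d_true <- pmax(rate_um_per_day * (days - t0), 0)
    d_render <- d_true
    if (distance_noise_sd > 0) {
      d_render <- pmax(d_true + stats::rnorm(length(days), sd = distance_noise_sd), 0)
    }
    max_px <- (spec$width - spec$tip[1]) * spec$pixel_size
    if (any(d_render > max_px)) {
      stop("growth distance exceeds the image extent; enlarge the spec.",
           call. = FALSE)
    }
    tissues <- purrr::map2(d_render, seq_along(days), function(d, i) {
      s <- spec
      s$growth_um <- d
      s$seed <- spec$seed + i
      make_microtissue(s)
    })
    out <- tibble::tibble(day = days, distance_um = d_render, tissue = tissues)
    class(out) <- c("growth_series", class(out))
    out
  })
}
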