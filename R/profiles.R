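#' Select the symmetry axis of an aligned microtissue
#'
#' Chooses the horizontal line (y position) used for profile extraction: the
#' row, within a window around the cleft bisector, that maximizes the total
#' in-band cumulative channel intensity — an automated surrogate for the
#' visual assessment of a representative symmetry axis. A user-supplied
#' `override` wins unconditionally.
#'
#' @param image An aligned [multichannel_image()] (bisector parallel to +x).
#' @param geometry The aligned [cleft_geometry()].
#' @param window Half-width (px) of the search window around the bisector y.
#' @param band_half_width Band half-width (px) used for the in-band score.
#' @param override Optional fixed y position (px); returned as-is.
#' @return The symmetry-axis y position (integer row index).
#' @export
select_symmetry_axis <- function(image, geometry, window = 20,
                                 band_half_width = 50, override = NULL) {
  stopifnot(inherits(image, "multichannel_image"))
  if (!is.null(override)) return(as.integer(round(override)))
  d <- image_dim(image)
  y0 <- round(geometry$tip_y)
  cand <- (y0 - window):(y0 + window)
  cand <- cand[cand - band_half_width >= 1 & cand + band_half_width - 1 <= d[1]]
  if (length(cand) == 0L) {
    stop("symmetry-axis search window (with its band) lies outside the image.",
         call. = FALSE)
  }
  total <- Reduce(`+`, image$channels)
  row_sums <- rowSums(total)
  score <- vapply(cand, function(y) {
    sum(row_sums[(y - band_half_width):(y + band_half_width - 1L)])
  }, numeric(1))
  as.integer(cand[which.max(score)])
}

#' Band-averaged intensity profile
#'
#' For every x position, averages each channel over a band of `2 *
#' band_half_width` rows equally distributed around the symmetry axis (rows
#' `y - band_half_width` through `y + band_half_width - 1`; 100 rows at the
#' default half-width of 50).
#'
#' @param image An aligned [multichannel_image()].
#' @param y_axis Symmetry-axis row (px).
#' @param band_half_width Band half-width in pixels (default 50).
#' @return A tibble of class `intensity_profile` with columns `x_px`,
#'   `channel`, `raw`; attributes `y_axis`, `band_half_width`, `band_rows`,
#'   `pixel_size`. The distance axis is filled in by [detect_front()].
#' @export
band_profile <- function(image, y_axis, band_half_width = 50) {
  stopifnot(inherits(image, "multichannel_image"))
  d <- image_dim(image)
  rows <- (y_axis - band_half_width):(y_axis + band_half_width - 1L)
  if (rows[1] < 1 || rows[length(rows)] > d[1]) {
    stop(sprintf(
      "band rows %d..%d extend beyond the image rows 1..%d; move the axis or shrink the band.",
      rows[1], rows[length(rows)], d[1]), call. = FALSE)
  }
  out <- purrr::map_dfr(channel_names(image), function(nm) {
    tibble::tibble(
      x_px = seq_len(d[2]),
      channel = nm,
      raw = colMeans(image$channels[[nm]][rows, , drop = FALSE])
    )
  })
  attr(out, "y_axis") <- y_axis
  attr(out, "band_half_width") <- band_half_width
  attr(out, "band_rows") <- range(rows)
  attr(out, "pixel_size") <- image$pixel_size
  class(out) <- c("intensity_profile", class(out))
  out
}

# carry the intensity_profile class and attributes through dplyr verbs
restore_profile_attrs <- function(out, template) {
  for (a in c("y_axis", "band_half_width", "band_rows", "pixel_size",
              "front_x", "threshold_fraction", "zero_channels")) {
    attr(out, a) <- attr(template, a)
  }
  class(out) <- unique(c("intensity_profile", class(out)))
  out
}

#' Normalize an intensity profile per channel
#'
#' Divides each channel's raw profile by its own maximum, so every channel
#' peaks at exactly 1 — the convention enabling interchannel and intertissue
#' comparison. All-zero channels stay zero and are flagged in the
#' `zero_channels` attribute. Normalization is idempotent.
#'
#' @param profile An [band_profile()] result.
#' @return The profile with a `norm` column added (values in `[0, 1]`).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  out <- profile |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(norm = if (max(.data$raw) > 0) .data$raw / max(.data$raw)
                  else .data$raw) |>
    dplyr::ungroup()
  zero <- out |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(z = max(.data$raw) <= 0, .groups = "drop")
  out <- restore_profile_attrs(out, profile)
  attr(out, "zero_channels") <- zero$channel[zero$z]
  out
}

#' Detect the growth front from the cumulated profile
#'
#' Cumulates the per-channel max-normalized profiles into one signal, then —
#' scanning from the open (tissue-medium) side toward the tip — places the
#' tissue boundary at the first x where the cumulative signal exceeds
#' `threshold_fraction` (default 25%) of its maximum. The distance-to-front
#' axis (`distance_um`, 0 at the front, positive into the core) is filled
#' in.
#'
#' @param profile An [normalize_profile()]d profile (normalization is
#'   applied automatically when missing).
#' @param threshold_fraction Fraction of the cumulative-signal maximum
#'   (default 0.25).
#' @return The profile with a `distance_um` column; attributes `front_x`
#'   (px) and `threshold_fraction`. Retrieve the front with
#'   [front_position()].
#' @export
detect_front <- function(profile, threshold_fraction = 0.25) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("`threshold_fraction` must be in (0, 1).", call. = FALSE)
  }
  if (!"norm" %in% names(profile)) profile <- normalize_profile(profile)
  cum <- profile |>
    dplyr::group_by(.data$x_px) |>
    dplyr::summarise(signal = sum(.data$norm), .groups = "drop") |>
    dplyr::arrange(.data$x_px)
  thr <- threshold_fraction * max(cum$signal)
  if (max(cum$signal) <= 0 || !any(cum$signal > thr)) {
    stop("no tissue detected: cumulative signal never exceeds the threshold.",
         call. = FALSE)
  }
  above <- which(cum$signal > thr)
  front_x <- cum$x_px[max(above)]     # first crossing from the open (right) side
  px <- attr(profile, "pixel_size")
  if (is.null(px)) px <- 1
  out <- profile |>
    dplyr::mutate(distance_um = (front_x - .data$x_px) * px)
  out <- restore_profile_attrs(out, profile)
  attr(out, "front_x") <- front_x
  attr(out, "threshold_fraction") <- threshold_fraction
  out
}

#' @rdname detect_front
#' @export
front_position <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  f <- attr(profile, "front_x")
  if (is.null(f)) stop("no front detected yet; run detect_front().", call. = FALSE)
  f
}

#' Integrated raw intensity per channel
#'
#' Sums the raw profile values of each channel over the profiled x range —
#' the absolute-intensity readout that complements the normalized profiles.
#'
#' @param profile An [band_profile()] result.
#' @return A tibble with columns `channel`, `integrated`.
#' @export
integrated_intensity <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  profile |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(integrated = sum(.data$raw), .groups = "drop")
}

#' Full cleft-aligned profile extraction
#'
#' One-stop pipeline: aligns the image to the cleft, selects the symmetry
#' axis, extracts the band-averaged profile, normalizes per channel, and
#' detects the growth front.
#'
#' @param image A [multichannel_image()].
#' @param geometry A [cleft_geometry()].
#' @param band_half_width Band half-width in px (default 50; 100-pixel band).
#' @param threshold_fraction Front-detection threshold (default 0.25).
#' @param axis_window Search half-window for the symmetry axis (px).
#' @param axis_override Optional fixed symmetry-axis y.
#' @return An `intensity_profile` tibble with `raw`, `norm`, `distance_um`;
#'   see [band_profile()], [normalize_profile()], [detect_front()].
#' @export
extract_profiles <- function(image, geometry, band_half_width = 50,
                             threshold_fraction = 0.25, axis_window = 20,
                             axis_override = NULL) {
  al <- align_to_cleft(image, geometry)
  y <- select_symmetry_axis(al$image, al$geometry, window = axis_window,
                            band_half_width = band_half_width,
                            override = axis_override)
  band_profile(al$image, y, band_half_width = band_half_width) |>
    normalize_profile() |>
    detect_front(threshold_fraction = threshold_fraction)
}

#' Full width at half maximum of a channel's front peak
#'
#' Measures the FWHM (in um) of the peak of a normalized channel profile
#' near the growth front, by linear interpolation of the half-maximum
#' crossings around the profile maximum.
#'
#' @param profile A profile with `norm` and `distance_um` columns.
#' @param channel Channel name.
#' @return FWHM in micrometers.
#' @export
peak_fwhm <- function(profile, channel) {
  stopifnot(inherits(profile, "intensity_profile"))
  ch <- profile |>
    dplyr::filter(.data$channel == !!channel, .data$distance_um >= 0) |>
    dplyr::arrange(.data$distance_um)
  if (nrow(ch) == 0L) stop("no in-tissue samples for this channel.", call. = FALSE)
  v <- ch$norm
  d <- ch$distance_um
  i_max <- which.max(v)
  half <- v[i_max] / 2
  cross <- function(idx_range, from_max) {
    below <- idx_range[v[idx_range] < half]
    if (length(below) == 0L) return(d[idx_range[length(idx_range)]])
    i2 <- if (from_max == "left") max(below) else min(below)
    i1 <- if (from_max == "left") i2 + 1L else i2 - 1L
    d[i1] + (d[i2] - d[i1]) * (v[i1] - half) / (v[i1] - v[i2])
  }
  left <- if (i_max > 1) cross(seq_len(i_max - 1L), "left") else d[1]
  right <- if (i_max < length(v)) cross((i_max + 1L):length(v), "right")
           else d[length(v)]
  abs(right - left)
}

#' @export
autoplot.intensity_profile <- function(object, normalized = TRUE, ...) {
  has_d <- "distance_um" %in% names(object)
  xvar <- if (has_d) "distance_um" else "x_px"
  yvar <- if (normalized && "norm" %in% names(object)) "norm" else "raw"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]],
                                            y = .data[[yvar]],
                                            color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (has_d) "distance to growth front (µm)" else "x (px)",
      y = if (yvar == "norm") "normalized intensity" else "raw intensity",
      color = "channel"
    ) +
    ggplot2::theme_minimal()
  if (has_d) p <- p + ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                                          color = "grey40")
  p
}
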