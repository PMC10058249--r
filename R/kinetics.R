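#' Growth distance from cleft tip to tissue front
#'
#' Measures, on an aligned image or mask, the distance from the cleft tip to
#' the tissue-medium interface along the bisector ray: the outermost
#' above-threshold (or masked-in) pixel on the bisector row, converted to
#' micrometers. Returns 0 when no tissue is present on the ray.
#'
#' @param x A logical tissue mask, a numeric single-channel image, or a
#'   [multichannel_image()] (its mask is used when present, otherwise the
#'   first channel thresholded).
#' @param geometry The aligned [cleft_geometry()] (bisector parallel +x).
#' @param pixel_size Pixel size in um/px (taken from a `multichannel_image`
#'   when omitted).
#' @param threshold Intensity threshold for numeric input; default Otsu.
#' @return Growth distance in micrometers.
#' @export
growth_distance <- function(x, geometry, pixel_size = NULL, threshold = NULL) {
  stopifnot(inherits(geometry, "cleft_geometry"))
  if (inherits(x, "multichannel_image")) {
    if (is.null(pixel_size)) pixel_size <- x$pixel_size
    x <- if (!is.null(x$mask)) x$mask else x$channels[[1]]
  }
  if (is.null(pixel_size)) pixel_size <- 1
  if (!is.matrix(x)) stop("`x` must be a matrix or multichannel_image.", call. = FALSE)
  tip_x <- round(geometry$tip_x); tip_y <- round(geometry$tip_y)
  if (tip_y < 1 || tip_y > nrow(x) || tip_x < 1 || tip_x > ncol(x)) {
    stop("geometry tip lies outside the image.", call. = FALSE)
  }
  ray <- x[tip_y, tip_x:ncol(x)]
  tissue <- if (is.logical(ray)) ray else {
    if (is.null(threshold)) {
      rng <- range(x)
      threshold <- if (diff(rng) > 0) {
        rng[1] + diff(rng) *
          EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng)), range = c(0, 1))
      } else Inf
    }
    ray > threshold
  }
  if (!any(tissue)) return(0)
  (max(which(tissue)) - 1) * pixel_size   # offset from tip, px -> um
}

#' Growth record
#'
#' A tidy record of (day, growth distance) observations.
#'
#' @param day Observation days, strictly increasing.
#' @param distance_um Growth distances in micrometers, non-negative.
#' @return A tibble of class `growth_record`.
#' @export
growth_record <- function(day, distance_um) {
  if (length(day) != length(distance_um)) {
    stop("`day` and `distance_um` must have equal length.", call. = FALSE)
  }
  if (is.unsorted(day, strictly = TRUE)) {
    stop("`day` must be strictly increasing.", call. = FALSE)
  }
  if (any(distance_um < 0)) {
    stop("`distance_um` must be non-negative.", call. = FALSE)
  }
  out <- tibble::tibble(day = as.numeric(day), distance_um = as.numeric(distance_um))
  class(out) <- c("growth_record", class(out))
  out
}

#' Measure a growth record from a series of tissues
#'
#' Applies [growth_distance()] to each (aligned) image/mask of a growth
#' series.
#'
#' @param series A `growth_series` from [make_growth_series()], or a list of
#'   `microtissue` objects with a `day` vector.
#' @param day Observation days (when `series` is a plain list).
#' @return A [growth_record()].
#' @export
measure_growth <- function(series, day = NULL) {
  if (inherits(series, "growth_series")) {
    day <- series$day
    tissues <- series$tissue
  } else {
    tissues <- series
  }
  d <- vapply(tissues, function(t) {
    growth_distance(t$image, t$geometry)
  }, numeric(1))
  growth_record(day, d)
}

#' Growth rate by ordinary least squares
#'
#' Fits the growth rate (um/day) as the OLS slope of distance versus day
#' within a fit window. Invariant to adding a constant offset to all
#' distances; reduces to the endpoint formula for two points.
#'
#' @param record A [growth_record()].
#' @param window `c(day_min, day_max)` fit window (inclusive); default all
#'   observations. At least 2 in-window observations are required.
#' @return An object of class `growth_fit`: list with `rate_um_per_day`,
#'   `intercept_um`, `window`, `n`, `residuals_um`, and the underlying `lm`
#'   fit. Supports [generics::tidy()] and [generics::glance()].
#' @export
growth_rate <- function(record, window = NULL) {
  stopifnot(inherits(record, "growth_record"))
  if (is.null(window)) window <- range(record$day)
  sub <- record |>
    dplyr::filter(.data$day >= window[1], .data$day <= window[2])
  if (nrow(sub) < 2L) {
    stop("growth-rate fit needs at least 2 observations inside the window.",
         call. = FALSE)
  }
  fit <- stats::lm(distance_um ~ day, data = sub)
  structure(
    list(rate_um_per_day = unname(stats::coef(fit)["day"]),
         intercept_um = unname(stats::coef(fit)["(Intercept)"]),
         window = window, n = nrow(sub),
         residuals_um = unname(stats::residuals(fit)),
         fit = fit, data = sub),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> rate %.2f um/day over days [%g, %g] (n = %d)\n",
              x$rate_um_per_day, x$window[1], x$window[2], x$n))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept_um", "rate_um_per_day"),
    estimate = c(x$intercept_um, x$rate_um_per_day),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @export
glance.growth_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    rate_um_per_day = x$rate_um_per_day,
    r.squared = s$r.squared,
    sigma_um = s$sigma,
    n = x$n,
    day_min = x$window[1],
    day_max = x$window[2]
  )
}

#' @export
autoplot.growth_record <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$distance_um)) +
    ggplot2::geom_point(color = "darkgreen") +
    ggplot2::labs(x = "time (days)", y = "growth distance (µm)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(slope = fit$rate_um_per_day,
                                  intercept = fit$intercept_um,
                                  linetype = "dashed", color = "darkgreen")
  }
  p
}
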