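#' Percentile contrast adjustment
#'
#' Linearly rescales a raster so that a fixed fraction of pixels saturates
#' (default 0.05%, the convention used for confocal/two-photon overview
#' images), clipping to `[0, 1]`. By default the saturated fraction is split
#' equally between the low and high tails; `tails = "high"` saturates only
#' the bright tail.
#'
#' The clip levels are order statistics: with `n` pixels and per-tail count
#' `k = round(n * fraction_per_tail)`, exactly `k` pixels lie strictly
#' outside each clip level (up to ties), so the saturated fraction matches
#' the request to one-pixel quantization.
#'
#' @param x Numeric matrix (or vector), finite-valued.
#' @param saturate_fraction Total fraction of pixels to saturate (default
#'   `0.0005`, i.e. 0.05%).
#' @param tails `"two"` (default) splits the fraction between both tails;
#'   `"high"` saturates only the high tail.
#' @return Rescaled raster in `[0, 1]`, same shape as `x`, with attribute
#'   `clip = c(lo, hi)`. A constant raster is returned unchanged with a
#'   warning and attribute `constant = TRUE`.
#' @export
percentile_contrast <- function(x, saturate_fraction = 5e-4,
                                tails = c("two", "high")) {
  tails <- match.arg(tails)
  if (!all(is.finite(x))) stop("`x` must be finite-valued.", call. = FALSE)
  if (saturate_fraction < 0 || saturate_fraction >= 1) {
    stop("`saturate_fraction` must be in [0, 1).", call. = FALSE)
  }
  n <- length(x)
  s <- sort(as.numeric(x))
  if (s[1] == s[n]) {
    warning("constant raster: percentile contrast is an identity mapping.")
    out <- x
    attr(out, "constant") <- TRUE
    return(out)
  }
  if (tails == "two") {
    k_lo <- round(n * saturate_fraction / 2)
    k_hi <- round(n * saturate_fraction / 2)
  } else {
    k_lo <- 0L
    k_hi <- round(n * saturate_fraction)
  }
  lo <- s[min(k_lo + 1L, n)]
  hi <- s[max(n - k_hi, 1L)]
  if (hi <= lo) {  # degenerate after clipping; fall back to full range
    lo <- s[1]; hi <- s[n]
  }
  out <- (x - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  attr(out, "clip") <- c(lo = lo, hi = hi)
  out
}

#' Split look-up-table channel overlay
#'
#' Renders a multi-channel image as an RGB composite in which the rows above
#' a split line use one channel-to-color assignment and the rows below use
#' another — the convention used to show two marker sets in one
#' mirror-symmetric tissue. Channels are percentile-contrast adjusted, tinted
#' with their display color, and blended additively with clipping at 1.
#'
#' @param image A [multichannel_image()], already cleft-aligned.
#' @param lut A list with elements `top` and `bottom`, each a named
#'   character vector / list mapping channel names to R colors (e.g.
#'   `list(top = c(aSMA = "orange", SHG = "cyan"), bottom = c(Fn = "green",
#'   TNC = "magenta", SHG = "cyan"))`, and `split_y`, the split row
#'   (typically the symmetry axis; rows `< split_y` use `top`).
#' @param saturate_fraction Passed to [percentile_contrast()].
#' @return An `nrow x ncol x 3` RGB array in `[0, 1]`.
#' @export
split_lut_overlay <- function(image, lut, saturate_fraction = 5e-4) {
  stopifnot(inherits(image, "multichannel_image"))
  if (!all(c("top", "bottom", "split_y") %in% names(lut))) {
    stop("`lut` must have elements `top`, `bottom`, and `split_y`.", call. = FALSE)
  }
  d <- image_dim(image)
  if (lut$split_y < 1 || lut$split_y > d[1]) {
    stop("`split_y` must lie inside the image.", call. = FALSE)
  }
  render_half <- function(assign) {
    chs <- names(assign)
    missing <- setdiff(chs, channel_names(image))
    if (length(missing)) {
      stop(sprintf("unknown channel(s) in LUT: %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    acc <- array(0, dim = c(d, 3L))
    for (ch in chs) {
      raster <- get_channel(image, ch)
      adj <- suppressWarnings(
        percentile_contrast(raster, saturate_fraction = saturate_fraction)
      )
      if (isTRUE(attr(adj, "constant")) && max(raster) == 0) adj <- raster
      col <- grDevices::col2rgb(assign[[ch]])[, 1] / 255
      for (k in 1:3) acc[, , k] <- acc[, , k] + as.numeric(adj) * col[k]
    }
    acc
  }
  top <- render_half(lut$top)
  bottom <- render_half(lut$bottom)
  out <- bottom
  rows_top <- seq_len(max(lut$split_y - 1L, 0L))
  if (length(rows_top)) out[rows_top, , ] <- top[rows_top, , ]
  pmin(out, 1)
}

#' Write an RGB array to PNG
#'
#' @param rgb An `nrow x ncol x 3` array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_render <- function(rgb, path) {
  grDevices::png(path, width = dim(rgb)[2], height = dim(rgb)[1])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(rgb), 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
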