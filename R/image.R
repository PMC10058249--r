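#' Multi-channel image container
#'
#' A lightweight container for a 2D multi-channel micrograph: a named list of
#' numeric matrices (one per marker channel, identical dimensions, indexed
#' `[row = y, col = x]`), a physical pixel size, and an optional logical
#' tissue mask.
#'
#' Coordinate conventions used throughout the package: positions are given as
#' `(x = column index, y = row index)` in pixels, with pixel centers at integer
#' coordinates; angles are measured counter-clockwise from the +x axis in
#' display orientation (y axis pointing up), in degrees.
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions. Typical channel names: `"Fn"`, `"aSMA"`, `"TNC"`, `"SHG"`.
#' @param pixel_size Physical size of one pixel in micrometers per pixel.
#' @param mask Optional logical matrix (same dimensions) marking tissue pixels.
#'
#' @return An object of class `multichannel_image`.
#' @export
#' @examples
#' img <- multichannel_image(list(SHG = matrix(runif(100), 10, 10)), pixel_size = 1)
#' channel_names(img)
multichannel_image <- function(channels, pixel_size = 1, mask = NULL) {
  if (!is.list(channels) || length(channels) == 0L) {
    stop("`channels` must be a non-empty named list of matrices.", call. = FALSE)
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("every element of `channels` must be named.", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), logical(1)))) {
    stop("every channel must be a numeric matrix.", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all channels must share the same dimensions.", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px).", call. = FALSE)
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(channels[[1]]))) {
      stop("`mask` must be a logical matrix matching the channel dimensions.",
           call. = FALSE)
    }
  }
  structure(
    list(channels = channels, pixel_size = pixel_size, mask = mask),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<multichannel_image> %d x %d px (%.3g um/px), channels: %s%s\n",
    d[1], d[2], x$pixel_size, paste(names(x$channels), collapse = ", "),
    if (is.null(x$mask)) "" else ", with mask"
  ))
  invisible(x)
}

#' @rdname multichannel_image
#' @param image A `multichannel_image`.
#' @export
channel_names <- function(image) {
  stopifnot(inherits(image, "multichannel_image"))
  names(image$channels)
}

#' @rdname multichannel_image
#' @param channel Channel name or index.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "multichannel_image"))
  if (is.character(channel) && !channel %in% names(image$channels)) {
    stop(sprintf("channel '%s' not found; available: %s", channel,
                 paste(names(image$channels), collapse = ", ")), call. = FALSE)
  }
  image$channels[[channel]]
}

#' @rdname multichannel_image
#' @export
image_dim <- function(image) {
  stopifnot(inherits(image, "multichannel_image"))
  dim(image$channels[[1]])
}

map_channels <- function(image, f, ...) {
  out <- image
  out$channels <- lapply(image$channels, f, ...)
  out
}

#' Read a multi-channel TIFF image
#'
#' Reads a multi-page TIFF (one page per channel). Channel names are taken
#' from `channels`, or from a YAML sidecar (`<path>.yaml`, written by
#' [write_image()]) when present.
#'
#' @param path Path to a TIFF file.
#' @param channels Optional character vector of channel names, in page order.
#' @param pixel_size Pixel size in um/px; overrides the sidecar value.
#' @return A [multichannel_image()].
#' @export
read_image <- function(path, channels = NULL, pixel_size = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist.", path), call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) {
                      stop(sprintf("failed to read TIFF '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE)
                    })
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  if (is.null(channels)) channels <- meta$channels
  if (is.null(channels)) channels <- paste0("ch", seq_along(pages))
  if (length(channels) != length(pages)) {
    stop(sprintf("TIFF '%s' has %d pages but %d channel names were supplied.",
                 path, length(pages), length(channels)), call. = FALSE)
  }
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size
  if (is.null(pixel_size)) pixel_size <- 1
  chs <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse grayscale-with-alpha
    scale <- meta$intensity_scale
    if (!is.null(scale)) p <- p * scale
    if (isTRUE(meta$integer_data)) p <- round(p)   # restore exact counts
    p
  })
  names(chs) <- channels
  multichannel_image(chs, pixel_size = pixel_size)
}

#' Write a multi-channel image to TIFF with a YAML sidecar
#'
#' Channels are written as one TIFF page each. Integer-valued channels
#' (camera counts up to 65535) are stored as 16-bit samples and round-trip
#' bit-exactly; continuous-valued channels are stored as 32-bit samples
#' (relative quantization 2^-32). The channel names, pixel size and
#' intensity scaling are recorded in a YAML sidecar (`<path>.yaml`) used by
#' [read_image()].
#'
#' @param image A [multichannel_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  mx <- max(vapply(image$channels, max, numeric(1)), 0)
  mn <- min(vapply(image$channels, min, numeric(1)), 0)
  if (mn < 0) stop("cannot write negative intensities to TIFF.", call. = FALSE)
  integer_data <- all(vapply(image$channels,
                             function(m) all(m == round(m)), logical(1))) &&
    mx <= 65535
  if (integer_data) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- if (mx > 1) mx else 1
    bits <- 32L
  }
  pages <- lapply(image$channels, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  yaml::write_yaml(
    list(channels = names(image$channels),
         pixel_size = image$pixel_size,
         intensity_scale = scale,
         integer_data = integer_data),
    paste0(path, ".yaml")
  )
  invisible(path)
}
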