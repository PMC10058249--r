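#' Cleft geometry
#'
#' Describes the angular scaffold cleft in which a microtissue grows: the
#' cleft tip position, the bisector direction (the direction of tissue
#' growth, from the tip toward the cleft opening), and the opening angle
#' (45 degrees for the scaffolds modeled here).
#'
#' @param tip_x,tip_y Tip position in pixel coordinates (`x` = column,
#'   `y` = row).
#' @param bisector_angle Bisector direction in degrees, counter-clockwise
#'   from the +x axis in display orientation (y up). 0 means the cleft opens
#'   toward +x with the tip on the left.
#' @param opening_angle Cleft opening angle in degrees, in `(0, 180)`.
#' @return An object of class `cleft_geometry` with fields `tip_x`, `tip_y`,
#'   `bisector_angle`, `opening_angle`, and derived `edge_angles` (the two
#'   cleft edge directions).
#' @export
cleft_geometry <- function(tip_x, tip_y, bisector_angle = 0, opening_angle = 45) {
  stopifnot(is.numeric(tip_x), is.numeric(tip_y), is.numeric(bisector_angle))
  if (!is.numeric(opening_angle) || opening_angle <= 0 || opening_angle >= 180) {
    stop("`opening_angle` must lie in (0, 180) degrees.", call. = FALSE)
  }
  structure(
    list(tip_x = tip_x, tip_y = tip_y,
         bisector_angle = bisector_angle, opening_angle = opening_angle,
         edge_angles = bisector_angle + c(-1, 1) * opening_angle / 2),
    class = "cleft_geometry"
  )
}

#' @export
print.cleft_geometry <- function(x, ...) {
  cat(sprintf("<cleft_geometry> tip (%.1f, %.1f) px, bisector %.1f deg, opening %.1f deg\n",
              x$tip_x, x$tip_y, x$bisector_angle, x$opening_angle))
  invisible(x)
}

# wrap an angle difference into (-180, 180]
wrap180 <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a
}

#' Wedge mask of a cleft
#'
#' Logical mask of the pixels lying inside the cleft wedge (between the two
#' edge lines, on the opening side of the tip), optionally limited to a
#' maximal distance from the tip measured along the bisector.
#'
#' @param geometry A [cleft_geometry()].
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @param max_axial Optional maximal axial (along-bisector) distance from
#'   the tip, in pixels.
#' @return Logical matrix of dimensions `dim`; contains the tip pixel.
#' @export
wedge_mask <- function(geometry, dim, max_axial = Inf) {
  stopifnot(inherits(geometry, "cleft_geometry"), length(dim) == 2L)
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  dx <- cc - geometry$tip_x
  dy <- -(r - geometry$tip_y)                   # display y points up
  th <- geometry$bisector_angle * pi / 180
  axial <- dx * cos(th) + dy * sin(th)          # along-bisector coordinate
  lateral <- -dx * sin(th) + dy * cos(th)
  half <- tan(geometry$opening_angle / 2 * pi / 180)
  mask <- axial >= 0 & abs(lateral) <= axial * half & axial <= max_axial
  mask[round(geometry$tip_y), round(geometry$tip_x)] <- TRUE
  mask
}

# quarter-turn CCW (display orientation) of a matrix; dims swap
rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# rotate a matrix by `angle` degrees CCW (display orientation) about the
# image center, bilinear interpolation, same output dims, background 0
rotate_raster <- function(m, angle, filter = "bilinear") {
  th <- angle * pi / 180
  M <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  ctr <- c(nrow(m) / 2, ncol(m) / 2)
  aff <- rbind(M, ctr - as.vector(ctr %*% M))
  EBImage::imageData(EBImage::affine(EBImage::Image(m), aff, filter = filter,
                                     bg.col = 0))
}

# forward-transform a pixel-index point (x, y) under the same rotation
rotate_point <- function(x, y, angle, dim_in) {
  th <- angle * pi / 180
  M <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  ctr <- c(dim_in[1] / 2, dim_in[2] / 2)
  p <- c(y - 0.5, x - 0.5)                      # continuous coords (row, col)
  q <- as.vector(p %*% M) + ctr - as.vector(ctr %*% M)
  c(x = q[2] + 0.5, y = q[1] + 0.5)
}

#' Rotate an image to the cleft-aligned frame
#'
#' Rotates all channels (with one shared interpolating transform) so that
#' the cleft bisector is parallel to the +x axis with the tip on the left,
#' and updates the geometry consistently. Rotations by multiples of 90
#' degrees are performed exactly (array reindexing, lossless); other angles
#' use bilinear interpolation about the image center with unchanged output
#' dimensions.
#'
#' @param image A [multichannel_image()].
#' @param geometry A [cleft_geometry()]; the tip must lie inside the image.
#' @return A list with the aligned `image` and the transformed `geometry`
#'   (bisector angle 0) plus `rotation` (the applied angle in degrees CCW).
#' @export
align_to_cleft <- function(image, geometry) {
  stopifnot(inherits(image, "multichannel_image"), inherits(geometry, "cleft_geometry"))
  d <- image_dim(image)
  if (geometry$tip_x < 1 || geometry$tip_x > d[2] ||
      geometry$tip_y < 1 || geometry$tip_y > d[1]) {
    stop("cleft tip lies outside the image.", call. = FALSE)
  }
  rot <- wrap180(-geometry$bisector_angle)
  if (abs(rot) < 1e-9) {
    return(list(image = image, geometry = geometry, rotation = 0))
  }
  if (abs(rot %% 90) < 1e-9) {
    k <- (round(rot / 90)) %% 4
    turn <- function(m) { for (i in seq_len(k)) m <- rot90_ccw(m); m }
    out <- map_channels(image, turn)
    if (!is.null(image$mask)) out$mask <- turn(image$mask)
    # index transform of one CCW quarter turn: (x, y) -> (y, nc + 1 - x)
    tx <- geometry$tip_x; ty <- geometry$tip_y; dd <- d
    for (i in seq_len(k)) {
      new_x <- ty
      new_y <- dd[2] + 1 - tx
      tx <- new_x; ty <- new_y
      dd <- rev(dd)
    }
    geom <- cleft_geometry(tx, ty, 0, geometry$opening_angle)
    return(list(image = out, geometry = geom, rotation = rot))
  }
  out <- map_channels(image, rotate_raster, angle = rot)
  if (!is.null(image$mask)) {
    out$mask <- rotate_raster(image$mask * 1, rot) > 0.5
  }
  tip <- rotate_point(geometry$tip_x, geometry$tip_y, rot, d)
  geom <- cleft_geometry(tip["x"], tip["y"], 0, geometry$opening_angle)
  list(image = out, geometry = geom, rotation = rot)
}
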