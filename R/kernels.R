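#' Kroon second-order derivative operators
#'
#' Builds the 5x5 Gaussian-derivative basic operator optimized by Kroon,
#' its transpose, and the composed second-order operators obtained by
#' sequential application (discrete convolution of the two basic operators,
#' effective support 9x9).
#'
#' The basic operator grid `Hx` is stored exactly as printed, with the
#' differentiation axis running along its rows; `Hy` is its transpose. The
#' composed kernels satisfy `Hxx = Hx * Hx`, `Hyy = Hy * Hy`,
#' `Hxy = Hx * Hy`, where `*` is full discrete convolution, so that one
#' convolution with a composed kernel equals two sequential convolutions
#' with the basic operators.
#'
#' @return An object of class `kroon_kernels`: a list with elements `Hx`,
#'   `Hy` (5x5) and `Hxx`, `Hyy`, `Hxy` (9x9).
#' @export
#' @examples
#' k <- kroon_kernels()
#' k$Hx[2, 3]        # 0.2589
#' sum(k$Hx)         # 0
kroon_kernels <- function() {
  top <- rbind(
    c(0.0007, 0.0052, 0.0370, 0.0052, 0.0007),
    c(0.0037, 0.1187, 0.2589, 0.1187, 0.0037)
  )
  Hx <- rbind(top, rep(0, 5), -top[2:1, , drop = FALSE])
  Hy <- t(Hx)
  structure(
    list(
      Hx  = Hx,
      Hy  = Hy,
      Hxx = kernel_compose(Hx, Hx),
      Hyy = kernel_compose(Hy, Hy),
      Hxy = kernel_compose(Hx, Hy)
    ),
    class = "kroon_kernels"
  )
}

# Full 2D discrete convolution of two small kernels (support adds).
kernel_compose <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- matrix(0, da[1] + db[1] - 1L, da[2] + db[2] - 1L)
  for (i in seq_len(da[1])) {
    for (j in seq_len(da[2])) {
      out[i:(i + db[1] - 1L), j:(j + db[2] - 1L)] <-
        out[i:(i + db[1] - 1L), j:(j + db[2] - 1L)] + a[i, j] * b
    }
  }
  out
}

# Mirror-pad a matrix by (pr, pc) pixels on each side (reflect across the
# edge, edge pixel not duplicated: a b c -> c b | a b c | b a).
pad_reflect <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  if (pr >= nr || pc >= nc) {
    stop(sprintf("image (%d x %d) is smaller than the kernel support requires.",
                 nr, nc), call. = FALSE)
  }
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  m[ri, ci, drop = FALSE]
}

#' 2D convolution with reflect boundary handling
#'
#' Convolves an image with an odd-sized kernel, padding the borders by mirror
#' reflection. The convolution itself is delegated to `EBImage::filter2`
#' (FFT-based true convolution) on the padded image.
#'
#' @param image Numeric matrix.
#' @param kernel Numeric matrix with odd dimensions.
#' @return Numeric matrix, same dimensions as `image`.
#' @export
conv2_reflect <- function(image, kernel) {
  stopifnot(is.matrix(image), is.matrix(kernel))
  if (any(dim(kernel) %% 2L == 0L)) {
    stop("kernel dimensions must be odd.", call. = FALSE)
  }
  pr <- (nrow(kernel) - 1L) %/% 2L
  pc <- (ncol(kernel) - 1L) %/% 2L
  padded <- pad_reflect(image, max(pr, 1L), max(pc, 1L))
  out <- EBImage::imageData(EBImage::filter2(padded, kernel, boundary = "circular"))
  pr2 <- max(pr, 1L); pc2 <- max(pc, 1L)
  out[(pr2 + 1L):(pr2 + nrow(image)), (pc2 + 1L):(pc2 + ncol(image)), drop = FALSE]
}

#' Second-order image derivatives via the Kroon operators
#'
#' Applies the basic 5x5 operators sequentially (or, equivalently, the
#' composed 9x9 operators once) to obtain the raw second-order derivatives
#' `Ixx`, `Iyy`, `Ixy`.
#'
#' The raster is indexed `[row = y, col = x]` while the operator grid is
#' stored with its differentiation axis along rows, so the x-derivative
#' applies the transposed grid. Boundary handling is mirror reflection.
#'
#' @param image Single-channel numeric matrix, finite-valued.
#' @param kernels A [kroon_kernels()] object.
#' @param method `"sequential"` applies the 5x5 operator twice;
#'   `"composed"` applies the composed 9x9 operator once. The two agree to
#'   numerical tolerance away from the border.
#' @return An object of class `derivative_field`: list with raw `Ixx`,
#'   `Iyy`, `Ixy`, the `method`, and `support` (half-width of the effective
#'   kernel support, 4 px).
#' @export
second_derivatives <- function(image, kernels = kroon_kernels(),
                               method = c("sequential", "composed")) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) {
    stop("`image` must be finite-valued.", call. = FALSE)
  }
  if (nrow(image) < 9L || ncol(image) < 9L) {
    stop("image smaller than the 9x9 effective kernel support.", call. = FALSE)
  }
  # x differentiates along columns -> transposed printed grid
  kx <- t(kernels$Hx)
  ky <- t(kernels$Hy)
  if (method == "sequential") {
    Ixx <- conv2_reflect(conv2_reflect(image, kx), kx)
    Iyy <- conv2_reflect(conv2_reflect(image, ky), ky)
    Ixy <- conv2_reflect(conv2_reflect(image, kx), ky)
  } else {
    Ixx <- conv2_reflect(image, t(kernels$Hxx))
    Iyy <- conv2_reflect(image, t(kernels$Hyy))
    Ixy <- conv2_reflect(image, t(kernels$Hxy))
  }
  structure(
    list(Ixx = Ixx, Iyy = Iyy, Ixy = Ixy, method = method, support = 4L,
         sigma = NULL, sIxx = NULL, sIyy = NULL, sIxy = NULL),
    class = "derivative_field"
  )
}

# Discrete 1D Gaussian kernel, radius 5*sigma (tail mass < 1e-6, so the
# semigroup property holds to ~1e-7), normalized to sum 1.
gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(5 * sigma)
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable Gaussian smoothing with reflect boundary.
gaussian_smooth <- function(m, sigma) {
  g <- gaussian_kernel_1d(sigma)
  m <- conv2_reflect(m, matrix(g, ncol = 1))
  conv2_reflect(m, matrix(g, nrow = 1))
}

#' Gaussian smoothing of the derivative field
#'
#' Fills the smoothed derivatives `I*xx`, `I*yy`, `I*xy` by Gaussian
#' filtering of the raw second derivatives at scale `sigma` (default 4 px).
#'
#' @param field A `derivative_field` from [second_derivatives()].
#' @param sigma Gaussian standard deviation in pixels; must be positive.
#' @return The field with `sIxx`, `sIyy`, `sIxy` and `sigma` filled in.
#' @export
smooth_derivatives <- function(field, sigma = 4) {
  stopifnot(inherits(field, "derivative_field"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number of pixels.", call. = FALSE)
  }
  field$sigma <- sigma
  field$sIxx <- gaussian_smooth(field$Ixx, sigma)
  field$sIyy <- gaussian_smooth(field$Iyy, sigma)
  field$sIxy <- gaussian_smooth(field$Ixy, sigma)
  field
}
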