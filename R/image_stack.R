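## The ImageStack container: 5-D pixel data plus spatial/temporal calibration.

DTYPES <- c("uint8", "uint16", "float32")
dtype_max <- c(uint8 = 255, uint16 = 65535, float32 = Inf)

#' Construct a calibrated 5-D image stack
#'
#' The canonical pixel container of the package: a 5-D array ordered
#' `(T, C, Z, Y, X)` (frames, channels, focal planes, rows, columns) with
#' the calibration metadata needed to convert pixel measurements to
#' physical units. All public coordinates in the package are 0-based and
#' ranges are half-open.
#'
#' @param pixels numeric array. Either 5-D `(T, C, Z, Y, X)` or a 2-D
#'   `(Y, X)` frame, which is promoted to `(1, 1, 1, Y, X)`.
#' @param dtype storage type, one of `"uint8"`, `"uint16"`, `"float32"`.
#'   Integer dtypes require whole values within the dtype range.
#' @param pixel_size_um physical pixel size, micrometres per pixel (> 0).
#' @param frame_interval_s time between frames, seconds (> 0).
#' @param z_step_um spacing between focal planes, micrometres (optional).
#' @param channel_names character vector of length `C`.
#' @param origin_t0_s acquisition time assigned to frame 0, seconds.
#' @return an object of class `"ImageStack"`.
#' @examples
#' s <- image_stack(matrix(0, 8, 8), dtype = "uint8")
#' stack_dim(s)
#' @export
image_stack <- function(pixels, dtype = "float32", pixel_size_um = 1.0,
                        frame_interval_s = 1.0, z_step_um = NULL,
                        channel_names = NULL, origin_t0_s = 0.0) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1L, 1L, 1L, nrow(pixels), ncol(pixels)))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 5L)
    input_error("'pixels' must be a 5-D (T,C,Z,Y,X) array or a 2-D frame")
  if (any(dim(pixels) < 1L)) input_error("all five dimensions must be >= 1")
  dtype <- match.arg(dtype, DTYPES)
  if (!all(is.finite(pixels))) input_error("intensities must be finite")
  dim(pixels) <- unname(dim(pixels))
  if (dtype == "float32") {
    ## snap to float32-representable values so disk round trips are
    ## bit-exact by construction
    d5 <- dim(pixels)
    pixels <- bits_to_f32(f32_to_bits(pixels))
    dim(pixels) <- d5
    if (!all(is.finite(pixels)))
      input_error("intensities exceed float32 range")
  }
  if (dtype != "float32") {
    if (any(pixels < 0) || any(pixels > dtype_max[[dtype]]) ||
        any(pixels != round(pixels)))
      input_error("'%s' pixels must be whole numbers in [0, %d]",
                  dtype, dtype_max[[dtype]])
  }
  chk_num1(pixel_size_um, "pixel_size_um", positive = TRUE)
  chk_num1(frame_interval_s, "frame_interval_s", positive = TRUE)
  if (!is.null(z_step_um)) chk_num1(z_step_um, "z_step_um", positive = TRUE)
  chk_num1(origin_t0_s, "origin_t0_s")
  nc <- dim(pixels)[2L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc) - 1L)
  if (length(channel_names) != nc)
    input_error("length(channel_names) must equal C (= %d)", nc)
  structure(list(
    pixels = pixels, dtype = dtype,
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
    z_step_um = z_step_um, channel_names = as.character(channel_names),
    origin_t0_s = origin_t0_s
  ), class = "ImageStack")
}

#' Dimensions of an image stack
#' @param stack an [image_stack()].
#' @return named integer vector `(T, C, Z, Y, X)`.
#' @export
stack_dim <- function(stack) {
  d <- dim(stack$pixels)
  names(d) <- c("T", "C", "Z", "Y", "X")
  d
}

#' Extract one 2-D frame from a stack
#'
#' @param stack an [image_stack()].
#' @param t,channel,z 0-based frame, channel and plane indices.
#' @return a `Y x X` numeric matrix.
#' @export
get_frame <- function(stack, t = 0L, channel = 0L, z = 0L) {
  d <- stack_dim(stack)
  if (t < 0 || t >= d[["T"]]) input_error("frame index %d out of bounds", t)
  if (channel < 0 || channel >= d[["C"]]) input_error("channel %d out of bounds", channel)
  if (z < 0 || z >= d[["Z"]]) input_error("z index %d out of bounds", z)
  stack$pixels[t + 1L, channel + 1L, z + 1L, , ]
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- stack_dim(x)
  cat(sprintf("<ImageStack %s  T=%d C=%d Z=%d Y=%d X=%d>\n", x$dtype,
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  pixel size %g um, frame interval %g s, t0 %g s\n",
              x$pixel_size_um, x$frame_interval_s, x$origin_t0_s))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

## timestamps (seconds) for each frame index 0..T-1
frame_times <- function(stack) {
  (seq_len(stack_dim(stack)[["T"]]) - 1) * stack$frame_interval_s +
    stack$origin_t0_s
}
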