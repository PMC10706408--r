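## Per-frame intensity filters and binary morphology.
##
## The Gaussian kernel is sampled, truncated at 4*sigma and renormalized
## to unit sum, so its impulse response is exactly the sampled kernel;
## all filters use a reflective (edge-mirroring) boundary. Foreground
## morphology uses 8-connectivity, background 4-connectivity.

#' Specify an intensity filter
#'
#' @param kind `"gaussian"`, `"median"` or `"mean"`.
#' @param size odd kernel width in pixels (median/mean; optional for
#'   gaussian, where it is derived from `sigma`).
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return an object of class `"FilterSpec"`.
#' @examples
#' filter_spec("gaussian", sigma = 2)
#' @export
filter_spec <- function(kind = c("gaussian", "median", "mean"),
                        size = NULL, sigma = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(sigma)) input_error("gaussian filter needs 'sigma'")
    chk_num1(sigma, "sigma", positive = TRUE)
  } else {
    if (is.null(size)) input_error("%s filter needs 'size'", kind)
    if (size < 1 || size %% 2 == 0) input_error("'size' must be odd and >= 1")
  }
  structure(list(kind = kind, size = size, sigma = sigma,
                 boundary = "reflect"), class = "FilterSpec")
}

## sampled Gaussian kernel, truncated at 4*sigma, renormalized
gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

## reflect-pad a matrix by r rows/cols on each side (edge-inclusive mirror:
## a b c d padded by 2 -> b a | a b c d | d c)
reflect_pad <- function(m, ry, rx = ry) {
  m[reflect_idx(nrow(m), ry), reflect_idx(ncol(m), rx), drop = FALSE]
}

reflect_idx <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  if (r > n) input_error("kernel radius exceeds frame size")
  c(r:1, seq_len(n), n:(n - r + 1))
}

## separable 1-D convolution along rows then columns with reflect boundary
conv_sep_reflect <- function(m, ky, kx = ky) {
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  p <- reflect_pad(m, ry, rx)
  ny <- nrow(m); nx <- ncol(m)
  ## along y (rows)
  acc <- matrix(0, ny, nx + 2 * rx)
  for (o in seq_along(ky)) acc <- acc + ky[o] * p[(o - 1) + seq_len(ny), , drop = FALSE]
  out <- matrix(0, ny, nx)
  for (o in seq_along(kx)) out <- out + kx[o] * acc[, (o - 1) + seq_len(nx), drop = FALSE]
  out
}

## generic odd-window rank/mean filter with reflect boundary
window_filter <- function(m, size, fun) {
  r <- (size - 1L) %/% 2L
  p <- reflect_pad(m, r, r)
  ny <- nrow(m); nx <- ncol(m)
  n_win <- size * size
  cols <- matrix(0, ny * nx, n_win)
  w <- 0L
  for (dy in 0:(size - 1)) for (dx in 0:(size - 1)) {
    w <- w + 1L
    cols[, w] <- as.vector(p[dy + seq_len(ny), dx + seq_len(nx)])
  }
  matrix(fun(cols), ny, nx)
}

row_medians <- function(x) apply(x, 1L, stats::median)

#' Apply an intensity filter to one channel of a stack
#'
#' Filtering is 2-D, applied independently to every `(T, Z)` frame of the
#' named channel; other channels pass through untouched. The output stack
#' is float32.
#'
#' @param stack an [image_stack()].
#' @param channel 0-based channel index.
#' @param spec a [filter_spec()].
#' @return a new float32 `ImageStack`.
#' @export
apply_filter <- function(stack, channel, spec) {
  d <- stack_dim(stack)
  if (channel < 0 || channel >= d[["C"]]) input_error("invalid channel %d", channel)
  if (!inherits(spec, "FilterSpec")) input_error("'spec' must be a FilterSpec")
  px <- stack$pixels
  for (t in seq_len(d[1])) for (z in seq_len(d[3])) {
    fr <- px[t, channel + 1L, z, , ]
    px[t, channel + 1L, z, , ] <- switch(spec$kind,
      gaussian = {
        k <- gaussian_kernel(spec$sigma)
        conv_sep_reflect(fr, k)
      },
      median = window_filter(fr, spec$size, row_medians),
      mean   = {
        k <- rep(1 / spec$size, spec$size)
        conv_sep_reflect(fr, k)
      })
  }
  image_stack(px, dtype = "float32", pixel_size_um = stack$pixel_size_um,
              frame_interval_s = stack$frame_interval_s,
              z_step_um = stack$z_step_um, channel_names = stack$channel_names,
              origin_t0_s = stack$origin_t0_s)
}

## structuring elements
struct_elem <- function(name = c("cross3", "square3")) {
  name <- match.arg(name)
  if (name == "square3") matrix(1, 3, 3)
  else matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
}

#' Binary morphology on a single frame
#'
#' @param mask binary (0/1 or logical) matrix.
#' @param op one of `"erode"`, `"dilate"`, `"open"`, `"close"`,
#'   `"fill_holes"`, `"invert"`. `fill_holes` fills background components
#'   not connected to the frame border (4-connectivity for background).
#' @param structuring_element `"cross3"` or `"square3"`.
#' @return a 0/1 integer matrix of the same shape.
#' @export
binary_morphology <- function(mask, op = c("erode", "dilate", "open", "close",
                                           "fill_holes", "invert"),
                              structuring_element = c("cross3", "square3")) {
  op <- match.arg(op)
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    input_error("'mask' must be a binary matrix")
  se <- struct_elem(match.arg(structuring_element))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  res <- switch(op,
    erode  = EBImage::erode(m, se),
    dilate = EBImage::dilate(m, se),
    open   = EBImage::dilate(EBImage::erode(m, se), se),
    close  = EBImage::erode(EBImage::dilate(m, se), se),
    fill_holes = fill_holes_border(m),
    invert = 1 - m)
  matrix(as.integer(res > 0.5), nrow(mask), ncol(mask))
}

## fill background components not connected to the border (4-conn background)
fill_holes_border <- function(m) {
  bg <- 1 - m
  lab <- EBImage::bwlabel(bg)                       # 4-connected
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  hole <- bg > 0 & !(lab %in% border_labels)
  out <- m
  out[hole] <- 1
  out
}

## ---- connected-component labeling ----------------------------------------
## 4-connectivity via EBImage::bwlabel; 8-connectivity by merging 4-labels
## that touch diagonally (union-find over label ids).

label_components <- function(mask, connectivity = 8L) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (connectivity == 4L || max(lab) == 0L) return(relabel_by_first_pixel(lab))
  nlab <- max(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ny <- nrow(m); nx <- ncol(m)
  for (sh in list(c(1, 1), c(1, -1))) {
    dy <- sh[1]; dx <- sh[2]
    ys <- seq_len(ny - 1)
    xs <- if (dx == 1) seq_len(nx - 1) else 2:nx
    a <- lab[ys, xs, drop = FALSE]
    b <- lab[ys + dy, xs + dx, drop = FALSE]
    sel <- which(a > 0 & b > 0 & a != b)
    if (length(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  lab[lab > 0] <- roots[lab[lab > 0]]
  relabel_by_first_pixel(lab)
}

## renumber labels 1..n in order of first (column-major) pixel occurrence
relabel_by_first_pixel <- function(lab) {
  u <- unique(lab[lab > 0])
  if (!length(u)) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}
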