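## ROI geometry: circles (optionally with concentric shell layers),
## rectangles, polygons and label-derived regions. Coordinates are
## 0-based pixel centers; a pixel belongs to a disk iff its center lies
## at distance <= radius from the circle center.

#' Circular (optionally layered) ROI
#'
#' With `n_layers >= 2` the ROI is a "stack ROI": an inner disk of radius
#' `radius_px` (layer 0) surrounded by concentric shells of width
#' `layer_width_px` (layers 1..). The inner disk captures bound plus free
#' signal at a focus; the first shell samples the free pool just outside
#' it, which is what the photobleaching compensation in
#' [bleaching_corrected_total()] relies on.
#'
#' @param center_yx numeric `(y, x)` center, 0-based pixel units.
#' @param radius_px inner radius (> 0).
#' @param n_layers total number of layers (>= 1).
#' @param layer_width_px shell width; default `radius_px / 2`.
#' @param role `"tracking"` or `"static"`.
#' @param channel 0-based channel the ROI measures.
#' @return an object of class `"Roi"`.
#' @export
roi_circle <- function(center_yx, radius_px, n_layers = 1L,
                       layer_width_px = NULL, role = "static", channel = 0L) {
  chk_num1(radius_px, "radius_px", positive = TRUE)
  if (n_layers < 1L) input_error("n_layers must be >= 1")
  layer_width_px <- layer_width_px %||% (radius_px / 2)
  if (n_layers > 1L) chk_num1(layer_width_px, "layer_width_px", positive = TRUE)
  structure(list(shape = "circle", center_yx = as.numeric(center_yx),
                 radius_px = radius_px, n_layers = as.integer(n_layers),
                 layer_width_px = layer_width_px, role = role,
                 channel = as.integer(channel)), class = "Roi")
}

#' Rectangular ROI (0-based, half-open pixel ranges)
#' @param y0,x0,y1,x1 rectangle `[y0, y1) x [x0, x1)`.
#' @param role,channel see [roi_circle()].
#' @return an object of class `"Roi"`.
#' @export
roi_rectangle <- function(y0, x0, y1, x1, role = "static", channel = 0L) {
  if (y1 <= y0 || x1 <= x0) input_error("rectangle must have positive extent")
  structure(list(shape = "rectangle", y0 = y0, x0 = x0, y1 = y1, x1 = x1,
                 n_layers = 1L, role = role, channel = as.integer(channel)),
            class = "Roi")
}

#' Polygon ROI
#' @param vertices_yx n x 2 matrix of `(y, x)` vertices (simple polygon).
#' @param role,channel see [roi_circle()].
#' @return an object of class `"Roi"`.
#' @export
roi_polygon <- function(vertices_yx, role = "static", channel = 0L) {
  v <- as.matrix(vertices_yx)
  if (nrow(v) < 3L) input_error("polygon needs >= 3 vertices")
  structure(list(shape = "polygon", vertices_yx = v, n_layers = 1L,
                 role = role, channel = as.integer(channel)), class = "Roi")
}

#' Region ROI from an exact pixel set
#' @param pixels_yx n x 2 integer matrix of 0-based member pixels.
#' @param role,channel see [roi_circle()].
#' @return an object of class `"Roi"`.
#' @export
roi_region <- function(pixels_yx, role = "static", channel = 0L) {
  p <- as.matrix(pixels_yx)
  if (nrow(p) < 1L) input_error("region must contain pixels")
  structure(list(shape = "region", pixels_yx = p, n_layers = 1L,
                 role = role, channel = as.integer(channel)), class = "Roi")
}

#' @export
print.Roi <- function(x, ...) {
  cat(sprintf("<Roi %s, %d layer(s), role %s, channel %d>\n",
              x$shape, x$n_layers, x$role, x$channel))
  invisible(x)
}

## rasterize one layer of an ROI into 0-based pixel coordinates within a
## (ny, nx) frame; layer 0 = inner shape, layer j = j-th concentric shell.
## Returns an n x 2 matrix (y, x), clipped to the frame.
rasterize_roi <- function(roi, ny, nx, layer = 0L, center = NULL) {
  if (layer > 0L && roi$shape != "circle")
    input_error("layers beyond 0 require a circle ROI")
  switch(roi$shape,
    circle = {
      ctr <- center %||% roi$center_yx
      r_out <- roi$radius_px + layer * roi$layer_width_px
      r_in <- if (layer == 0L) -1 else roi$radius_px + (layer - 1L) * roi$layer_width_px
      yy <- max(0L, floor(ctr[1] - r_out)):min(ny - 1L, ceiling(ctr[1] + r_out))
      xx <- max(0L, floor(ctr[2] - r_out)):min(nx - 1L, ceiling(ctr[2] + r_out))
      g <- expand.grid(y = yy, x = xx)
      d <- sqrt((g$y - ctr[1])^2 + (g$x - ctr[2])^2)
      keep <- d <= r_out & d > r_in
      as.matrix(g[keep, c("y", "x"), drop = FALSE])
    },
    rectangle = {
      yy <- max(0, roi$y0):min(ny - 1, roi$y1 - 1)
      xx <- max(0, roi$x0):min(nx - 1, roi$x1 - 1)
      as.matrix(expand.grid(y = yy, x = xx))
    },
    polygon = {
      v <- roi$vertices_yx
      yy <- max(0, floor(min(v[, 1]))):min(ny - 1, ceiling(max(v[, 1])))
      xx <- max(0, floor(min(v[, 2]))):min(nx - 1, ceiling(max(v[, 2])))
      g <- expand.grid(y = yy, x = xx)
      keep <- point_in_polygon(g$y, g$x, v)
      as.matrix(g[keep, c("y", "x"), drop = FALSE])
    },
    region = {
      p <- roi$pixels_yx
      p[p[, 1] >= 0 & p[, 1] < ny & p[, 2] >= 0 & p[, 2] < nx, , drop = FALSE]
    })
}

## even-odd rule point-in-polygon, vectorized over points
point_in_polygon <- function(py, px, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 1]; xi <- v[i, 2]; yj <- v[j, 1]; xj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
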