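## Per-frame ROI photometry and photobleaching-compensated focus totals.
##
## Measurement is always taken on the raw channel (segmentation may have
## run on a filtered copy); Z is handled by measuring the max projection
## by default, or a single plane on request.

#' Measure an ROI or track over all frames
#'
#' Produces one row per frame per layer with min/max/mean/total intensity
#' and areas. `time_s = frame_t * frame_interval_s + origin_t0_s`.
#'
#' @param stack an [image_stack()] (raw data).
#' @param roi a `"Roi"` (static placement) or `"Track"` (per-frame
#'   placement; a circle `roi_template` is centered on the tracked
#'   centroid each frame, region tracks measure the region under the
#'   placement).
#' @param channel 0-based channel to measure; defaults to the ROI's.
#' @param roi_id identifier written into the table.
#' @param z `"max"` (default, max projection) or a 0-based plane index.
#' @return a measurement table (`data.frame`) with columns `frame_t`,
#'   `time_s`, `roi_id`, `layer`, `min`, `max`, `mean`, `total`,
#'   `area_px`, `area_um2`.
#' @export
measure <- function(stack, roi, channel = NULL, roi_id = "roi0", z = "max") {
  d <- stack_dim(stack)
  channel <- channel %||% roi$channel %||% 0L
  if (channel < 0 || channel >= d[["C"]]) input_error("invalid channel %d", channel)
  is_track <- inherits(roi, "Track")
  if (!is_track && !inherits(roi, "Roi")) input_error("'roi' must be a Roi or Track")

  get_plane <- function(t) {
    if (identical(z, "max")) {
      if (d[["Z"]] == 1L) stack$pixels[t, channel + 1L, 1L, , ]
      else {
        cube <- stack$pixels[t, channel + 1L, , , , drop = TRUE]
        dim(cube) <- c(d[3], d[4], d[5])
        apply(cube, c(2, 3), max)
      }
    } else stack$pixels[t, channel + 1L, z + 1L, , ]
  }

  frames <- if (is_track) roi$frames$frame_t else seq_len(d[1]) - 1L
  template <- if (is_track) roi$roi_template else roi
  use_region_track <- is_track && is.null(roi$roi_template)
  if (use_region_track)
    input_error("track has no measurement geometry; use attach_tracking_circle()")
  n_layers <- template$n_layers
  clipped <- FALSE
  rows <- vector("list", length(frames) * n_layers)
  i <- 0L
  for (fi in seq_along(frames)) {
    t0 <- frames[fi]
    fr <- get_plane(t0 + 1L)
    center <- if (is_track) c(roi$frames$y[fi], roi$frames$x[fi]) else NULL
    for (layer in 0:(n_layers - 1L)) {
      px <- rasterize_roi(template, d[4], d[5], layer, center = center)
      if (roi_exceeds_frame(template, layer, center, d[4], d[5])) clipped <- TRUE
      if (nrow(px) == 0L)
        degenerate_error("ROI layer %d empty after clipping in frame %d",
                         layer, t0)
      vals <- fr[cbind(px[, 1] + 1L, px[, 2] + 1L)]
      i <- i + 1L
      rows[[i]] <- data.frame(
        frame_t = t0,
        time_s = t0 * stack$frame_interval_s + stack$origin_t0_s,
        roi_id = roi_id, layer = layer,
        min = min(vals), max = max(vals), mean = mean(vals),
        total = sum(vals), area_px = nrow(px),
        area_um2 = nrow(px) * stack$pixel_size_um^2)
    }
  }
  if (clipped) warning("ROI extended beyond frame bounds; clipped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## does the ROI's outer extent poke outside the frame?
roi_exceeds_frame <- function(roi, layer, center, ny, nx) {
  if (roi$shape != "circle") return(FALSE)
  ctr <- center %||% roi$center_yx
  r <- roi$radius_px + layer * (roi$layer_width_px %||% 0)
  ctr[1] - r < -0.5 || ctr[1] + r > ny - 0.5 ||
    ctr[2] - r < -0.5 || ctr[2] + r > nx - 0.5
}

#' Photobleaching-compensated focus intensity
#'
#' For a layered (stack) ROI, the inner disk (layer 0) holds bound plus
#' free signal and the first shell (layer 1) the free pool alone. The
#' compensated total is the difference of the layer means scaled by the
#' inner area, divided by the shell-estimated bleaching factor
#' `mean_layer1(t) / mean_layer1(t_first)`; the shell thereby cancels
#' both the local free-pool pedestal and the global acquisition/micro-IR
#' bleaching, leaving a series proportional to the bound pool.
#'
#' @param table a measurement table from [measure()] with layers 0 and 1
#'   present at every frame.
#' @return a `data.frame` with `frame_t`, `time_s`, `corrected_total`.
#' @export
bleaching_corrected_total <- function(table) {
  l0 <- table[table$layer == 0L, , drop = FALSE]
  l1 <- table[table$layer == 1L, , drop = FALSE]
  if (nrow(l0) == 0L || nrow(l1) == 0L || nrow(l0) != nrow(l1))
    input_error("table must contain layers 0 and 1 for every frame")
  o0 <- order(l0$frame_t); o1 <- order(l1$frame_t)
  l0 <- l0[o0, ]; l1 <- l1[o1, ]
  if (any(l0$frame_t != l1$frame_t))
    input_error("layers 0 and 1 cover different frames")
  bleach <- l1$mean / l1$mean[1L]
  bleach[!is.finite(bleach) | bleach <= 0] <- NA_real_
  data.frame(frame_t = l0$frame_t, time_s = l0$time_s,
             corrected_total = (l0$mean - l1$mean) * l0$area_px / bleach)
}

#' Write a measurement table as tab-delimited text
#'
#' One file per ROI/channel; formula results can be appended as named
#' columns beforehand.
#'
#' @param table a `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
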