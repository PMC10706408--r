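## Click-seeded object selection and frame-to-frame linking.
##
## Linking is bidirectional greedy nearest-centroid from the seed frame:
## the object in the adjacent frame whose centroid is nearest to the
## current placement is accepted iff it moved at most max_displacement_px;
## otherwise the track coasts (holds the last placement, flagged). Ties
## are broken by larger area, then smaller component id.

#' Select the segmented object under a point ("magic wand")
#'
#' Returns the 8-connected component of pixels with class at least
#' `class_level` that contains the clicked point, as a region ROI
#' delineating its exact shape.
#'
#' @param labels a `"LabelImage"`.
#' @param frame 0-based frame index.
#' @param point_yx numeric `(y, x)`, 0-based.
#' @param class_level minimum class for foreground.
#' @param z 0-based plane index.
#' @return a region [roi_region()] with attribute `"component_id"`.
#' @export
magic_wand_select <- function(labels, frame, point_yx, class_level, z = 0L) {
  cl <- label_frame(labels, frame, z)
  py <- round(point_yx[1]) + 1L; px <- round(point_yx[2]) + 1L
  if (py < 1L || py > nrow(cl) || px < 1L || px > ncol(cl))
    input_error("point outside frame")
  if (cl[py, px] < class_level)
    no_object_error("no segmented object at (%g, %g)", point_yx[1], point_yx[2])
  lab <- label_components(cl >= class_level, 8L)
  id <- lab[py, px]
  idx <- which(lab == id, arr.ind = TRUE)
  roi <- roi_region(cbind(idx[, 1] - 1L, idx[, 2] - 1L), role = "tracking",
                    channel = labels$channel)
  attr(roi, "component_id") <- id
  roi
}

new_track <- function(frames_df, kind, channel, seed, roi_template = NULL) {
  structure(list(frames = frames_df, kind = kind, channel = channel,
                 seed = seed, roi_template = roi_template), class = "Track")
}

#' @export
print.Track <- function(x, ...) {
  n <- nrow(x$frames)
  cat(sprintf("<Track %s, %d frames (%d tracked, %d coasted), channel %d>\n",
              x$kind, n, sum(x$frames$status == "tracked"),
              sum(x$frames$status == "coasted"), x$channel))
  invisible(x)
}

## link within one frame's component table: nearest centroid to (y, x)
## of matching kind; ties by larger area then smaller id
nearest_component <- function(comps, y, x) {
  if (nrow(comps) == 0L) return(NULL)
  d <- sqrt((comps$centroid_y - y)^2 + (comps$centroid_x - x)^2)
  o <- order(d, -comps$area_px, comps$component_id)
  comps[o[1L], , drop = FALSE]
}

#' Track a segmented object through time
#'
#' @param components a component table from [detect_particles()] or
#'   [detect_holes()] covering all frames.
#' @param seed_frame 0-based frame of the seed click.
#' @param seed_point numeric `(y, x)` seed, 0-based; must fall inside a
#'   component's bounding box in its frame (nearest such component wins).
#' @param max_displacement_px linking gate (default 20).
#' @param channel channel recorded on the track.
#' @param t_range optional `c(first, last)` 0-based frame span; default
#'   is the full span of `components`.
#' @return a `"Track"`: per-frame placement `(frame_t, y, x, status,
#'   component_id, area_px)` with `status` `"tracked"` or `"coasted"`.
#' @export
track_object <- function(components, seed_frame, seed_point,
                         max_displacement_px = 20, channel = 0L,
                         t_range = NULL) {
  if (nrow(components) == 0L) no_object_error("empty component table")
  t_range <- t_range %||% range(components$frame_t)
  frames <- t_range[1]:t_range[2]
  seed_comps <- components[components$frame_t == seed_frame, , drop = FALSE]
  inside <- seed_comps[
    seed_comps$bbox_y0 <= seed_point[1] & seed_point[1] < seed_comps$bbox_y1 &
    seed_comps$bbox_x0 <= seed_point[2] & seed_point[2] < seed_comps$bbox_x1, ,
    drop = FALSE]
  if (nrow(inside) == 0L)
    no_object_error("seed point (%g, %g) lies outside all components in frame %d",
                    seed_point[1], seed_point[2], seed_frame)
  start <- nearest_component(inside, seed_point[1], seed_point[2])
  kind <- start$kind

  res <- data.frame(frame_t = frames, y = NA_real_, x = NA_real_,
                    status = "coasted", component_id = NA_integer_,
                    area_px = NA_integer_)
  set_row <- function(ft, comp, status) {
    i <- match(ft, frames)
    res[i, c("y", "x")] <<- c(comp$centroid_y, comp$centroid_x)
    res$status[i] <<- status
    res$component_id[i] <<- comp$component_id
    res$area_px[i] <<- comp$area_px
  }
  set_row(seed_frame, start, "tracked")

  walk <- function(dir) {
    cur <- start
    ft <- seed_frame + dir
    while (ft >= t_range[1] && ft <= t_range[2]) {
      cand <- components[components$frame_t == ft & components$kind == kind, ,
                         drop = FALSE]
      nxt <- nearest_component(cand, cur$centroid_y, cur$centroid_x)
      if (!is.null(nxt) &&
          sqrt((nxt$centroid_y - cur$centroid_y)^2 +
               (nxt$centroid_x - cur$centroid_x)^2) <= max_displacement_px) {
        set_row(ft, nxt, "tracked")
        cur <- nxt
      } else {
        set_row(ft, cur, "coasted")   # hold last placement
      }
      ft <- ft + dir
    }
  }
  walk(+1L)
  walk(-1L)
  new_track(res, kind, as.integer(channel),
            list(frame = seed_frame, point_yx = seed_point))
}

#' Track an intensity hole inside a tracked nucleus
#'
#' Detects holes (per [detect_holes()]) within the nucleus track's region
#' on every frame, then links them exactly as [track_object()] does.
#'
#' @param labels a `"LabelImage"`.
#' @param enclosing_track a `"Track"` of the nucleus (region kind), or a
#'   binary mask/array accepted by [detect_holes()].
#' @param seed_frame,seed_point seed click (0-based).
#' @param class_level hole candidates have class below this level.
#' @param min_area_px minimum hole area.
#' @param max_displacement_px,channel as in [track_object()].
#' @return a `"Track"` with `kind = "hole"`.
#' @export
track_hole <- function(labels, enclosing_track, seed_frame, seed_point,
                       class_level = 1L, min_area_px = 1,
                       max_displacement_px = 20, channel = 0L) {
  mask <- enclosing_mask_from(enclosing_track, labels)
  holes <- detect_holes(labels, class_level, mask, min_area_px)
  if (nrow(holes) == 0L) no_object_error("no holes detected")
  d <- dim(labels$classes)
  track_object(holes, seed_frame, seed_point, max_displacement_px, channel,
               t_range = c(0L, d[1] - 1L))
}

enclosing_mask_from <- function(x, labels) {
  if (is.matrix(x) || is.array(x)) return(x)
  if (!inherits(x, "Track")) input_error("enclosing_track must be a Track or mask")
  d <- dim(labels$classes)
  out <- array(FALSE, dim = d)
  for (i in seq_len(nrow(x$frames))) {
    t <- x$frames$frame_t[i]
    ## region tracks rebuild the component mask from the label image
    cl <- label_frame(labels, t, 0L)
    lab <- label_components(cl >= 1L, 8L)
    py <- round(x$frames$y[i]) + 1L; px <- round(x$frames$x[i]) + 1L
    py <- min(max(py, 1L), d[3]); px <- min(max(px, 1L), d[4])
    id <- lab[py, px]
    m <- if (id > 0) lab == id else cl >= 1L
    out[t + 1L, 1L, , ] <- m
  }
  out
}

#' Copy a track's geometry to other channels
#'
#' Registration between channels is assumed (same optical path): the
#' per-frame geometry is reused verbatim, with no re-segmentation.
#'
#' @param track a `"Track"`.
#' @param target_channels integer vector of 0-based channel indices.
#' @param n_channels total channels available (for validation; optional).
#' @return a list of `"Track"` objects, one per target channel.
#' @export
copy_roi_to_channel <- function(track, target_channels, n_channels = NULL) {
  if (!is.null(n_channels) &&
      any(target_channels < 0 | target_channels >= n_channels))
    input_error("target channel out of range")
  lapply(as.integer(target_channels), function(ch) {
    t2 <- track
    t2$channel <- ch
    if (!is.null(t2$roi_template)) t2$roi_template$channel <- ch
    t2
  })
}

#' Attach a (layered) tracking circle to a track
#'
#' Replaces the track's measurement geometry with a circle of radius
#' `radius_px` centered on the tracked centroid each frame, optionally
#' with concentric shell layers — the "stack ROI" used for FRAP and for
#' photobleaching-compensated focus photometry.
#'
#' @param track a `"Track"`.
#' @param radius_px inner radius (> 0).
#' @param n_layers number of layers (inner disk + shells).
#' @param layer_width_px shell width; default `radius_px / 2`.
#' @return the track with a circle `roi_template` attached.
#' @export
attach_tracking_circle <- function(track, radius_px, n_layers = 1L,
                                   layer_width_px = NULL) {
  track$roi_template <- roi_circle(c(0, 0), radius_px, n_layers,
                                   layer_width_px, role = "tracking",
                                   channel = track$channel)
  track
}
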