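# Shared fixture builders; everything is generated in code at test time.

# wrap a class matrix as a LabelImage (single frame, single plane)
label_image_1f <- function(class_mat, n_classes = max(class_mat) + 1L,
                           channel = 0L) {
  structure(list(
    classes = array(as.integer(class_mat),
                    dim = c(1L, 1L, nrow(class_mat), ncol(class_mat))),
    threshold_set = NULL, per_frame_sets = NULL,
    channel = channel, n_classes = as.integer(n_classes)),
    class = "LabelImage")
}

# stack from a list of Y x X frames (single channel, single plane)
stack_from_frames <- function(frames, ...) {
  Y <- nrow(frames[[1]]); X <- ncol(frames[[1]])
  px <- array(0, dim = c(length(frames), 1L, 1L, Y, X))
  for (i in seq_along(frames)) px[i, 1, 1, , ] <- frames[[i]]
  image_stack(px, ...)
}

# hand-built component table row
comp_row <- function(id, t, y, x, area, kind = "particle") {
  data.frame(component_id = id, frame_t = t, z = 0L,
             centroid_y = y, centroid_x = x, area_px = area,
             bbox_y0 = floor(y) - 2, bbox_x0 = floor(x) - 2,
             bbox_y1 = ceiling(y) + 3, bbox_x1 = ceiling(x) + 3,
             class_level = 1L, kind = kind)
}

# reference flood fill from the border (4-connectivity), used as the
# oracle for fill_holes
flood_fill_holes_oracle <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  bg <- m == 0
  reach <- matrix(FALSE, ny, nx)
  queue <- which(bg & (row(m) %in% c(1, ny) | col(m) %in% c(1, nx)))
  reach[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    y <- (i - 1) %% ny + 1; x <- (i - 1) %/% ny + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      yy <- y + d[1]; xx <- x + d[2]
      if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx) {
        j <- (xx - 1) * ny + yy
        if (bg[j] && !reach[j]) { reach[j] <- TRUE; queue <- c(queue, j) }
      }
    }
  }
  out <- m
  out[bg & !reach] <- 1
  out
}

# Independent ODE oracle for the reaction chain: numerical integration of
# the chain rate equations (removable and non-removable pools).
crc_ode_oracle <- function(t, k, kr, f_rem, A = 1, B = 0) {
  m <- length(k)
  deriv <- function(tt, y, parms) {
    s1 <- y[1:(m + 1)]; s2 <- y[(m + 2):(2 * m + 2)]
    d1 <- numeric(m + 1); d2 <- numeric(m + 1)
    d1[1] <- -k[1] * s1[1]; d2[1] <- -k[1] * s2[1]
    for (i in 2:(m + 1)) {
      out1 <- if (i <= m) k[i] * s1[i] else kr * s1[i]
      out2 <- if (i <= m) k[i] * s2[i] else 0
      d1[i] <- k[i - 1] * s1[i - 1] - out1
      d2[i] <- k[i - 1] * s2[i - 1] - out2
    }
    list(c(d1, d2))
  }
  y0 <- c(1, rep(0, m), 1, rep(0, m))
  sol <- deSolve::ode(y0, t, deriv, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-12)
  B + A * (f_rem * sol[, m + 2] + (1 - f_rem) * sol[, 2 * m + 3])
}

# classical exhaustive single-threshold Otsu on a histogram (oracle)
otsu1_brute <- function(counts, centers) {
  p <- counts / sum(counts)
  best <- -Inf; bi <- 1L
  for (i in seq_len(length(counts) - 1L)) {
    w0 <- sum(p[1:i]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:i] * centers[1:i]) / w0
    mu1 <- sum(p[(i + 1):length(p)] * centers[(i + 1):length(p)]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12 * max(1, v)) { best <- v; bi <- i }
  }
  bi
}

# run the full focus-quantification pipeline on one recruitment movie,
# returning the photobleaching-corrected kinetics curve
pipeline_corrected_curve <- function(scene, seed_frame = 30L,
                                     radius = 6, width = 3) {
  stack <- scene$stack
  filt <- apply_filter(stack, 0, filter_spec("gaussian", sigma = 2))
  labels <- adaptive_focus_labels(filt, 0, z = 5)
  comps <- detect_particles(labels, class_level = 2, min_area_px = 5)
  d <- stack_dim(stack)
  seedp <- as.numeric(scene$truth$focus_centers[seed_frame + 1L, c("y", "x")])
  tr <- track_object(comps, seed_frame, seedp, t_range = c(0L, d[["T"]] - 1L))
  tr <- attach_tracking_circle(tr, radius_px = radius, n_layers = 2,
                               layer_width_px = width)
  corr <- bleaching_corrected_total(measure(stack, tr, channel = 0))
  list(curve = kinetics_curve(
         corr$time_s, corr$corrected_total,
         cell_id = sprintf("cell%d", scene$truth$config$seed),
         event_times_s = c(irradiation = scene$truth$events$irradiation$time_s)),
       track = tr)
}
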