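## Global multi-level thresholding and object detection.
##
## Histograms use 256 bins for uint8 frames (unit-width bins over
## [0, 256)) and 1024 min-max scaled bins otherwise; thresholds are
## reported as bin upper-edge intensity values. Multi-level Otsu uses
## exhaustive search for 1-2 thresholds and dynamic programming over
## cumulative histogram moments for 3-4; ties are broken by the
## lexicographically smallest threshold vector.

frame_histogram <- function(frame, dtype = "float32", n_bins = NULL) {
  v <- as.vector(frame)
  if (identical(dtype, "uint8")) {
    n_bins <- n_bins %||% 256L
    edges <- seq(0, 256, length.out = n_bins + 1L)
  } else {
    n_bins <- n_bins %||% 1024L
    lo <- min(v); hi <- max(v)
    if (hi <= lo) degenerate_error("constant frame has no histogram spread")
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  bin <- findInterval(v, edges, rightmost.closed = TRUE, left.open = FALSE)
  bin[bin < 1L] <- 1L; bin[bin > n_bins] <- n_bins
  counts <- tabulate(bin, nbins = n_bins)
  list(counts = counts, edges = edges,
       centers = (edges[-1] + edges[-length(edges)]) / 2,
       upper = edges[-1], n_bins = n_bins)
}

## between-class variance objective: sum_k W_k * mu_k^2 (constant offset
## -mu^2 dropped). `cuts` are bin indices i meaning "threshold after bin i".
bcv_objective <- function(cw, cm, cuts, n_bins) {
  b <- c(0L, cuts, n_bins)
  tot <- 0
  for (k in seq_len(length(b) - 1L)) {
    w <- cw[b[k + 1L] + 1L] - cw[b[k] + 1L]
    if (w > 0) {
      mu <- (cm[b[k + 1L] + 1L] - cm[b[k] + 1L]) / w
      tot <- tot + w * mu^2
    }
  }
  tot
}

#' Multi-level Otsu thresholding of a frame
#'
#' Finds 1-4 intensity thresholds maximizing the between-class variance
#' of the frame histogram.
#'
#' @param frame 2-D numeric matrix (non-constant).
#' @param n_thresholds number of thresholds, 1..4.
#' @param n_bins histogram bins (default 256 for uint8, 1024 otherwise).
#' @param dtype dtype of the frame's parent stack, controls binning.
#' @return an object of class `"ThresholdSet"`: fields `thresholds`
#'   (increasing intensity cut points, bin upper edges), `n_classes`,
#'   `source = "otsu"`, and the settings needed to recompute per frame.
#' @examples
#' f <- matrix(c(rep(10, 32), rep(200, 32)), 8, 8)
#' otsu_multilevel(f, 1)$thresholds
#' @export
otsu_multilevel <- function(frame, n_thresholds = 1L, n_bins = NULL,
                            dtype = "float32") {
  if (n_thresholds < 1L || n_thresholds > 4L)
    input_error("n_thresholds must be in 1..4")
  if (length(unique(as.vector(frame))) < 2L)
    degenerate_error("cannot threshold a constant frame")
  h <- frame_histogram(frame, dtype, n_bins)
  if (h$n_bins < n_thresholds + 1L) input_error("n_bins must be >= n_thresholds + 1")
  p <- h$counts / sum(h$counts)
  cw <- c(0, cumsum(p))
  cm <- c(0, cumsum(p * h$centers))
  nb <- h$n_bins
  cuts <- switch(as.character(n_thresholds),
    "1" = {
      i <- seq_len(nb - 1L)
      w0 <- cw[i + 1L]; m0 <- cm[i + 1L]
      obj <- ifelse(w0 > 0, m0^2 / w0, 0) +
             ifelse(1 - w0 > 0, (cm[nb + 1L] - m0)^2 / (1 - w0), 0)
      best_cut_1d(obj)
    },
    "2" = {
      best <- -Inf; best_cuts <- NULL
      mT <- cm[nb + 1L]
      for (i in seq_len(nb - 2L)) {
        j <- (i + 1L):(nb - 1L)
        w0 <- cw[i + 1L]; m0 <- cm[i + 1L]
        w1 <- cw[j + 1L] - w0; m1 <- cm[j + 1L] - m0
        w2 <- 1 - cw[j + 1L]; m2 <- mT - cm[j + 1L]
        obj <- ifelse(w0 > 0, m0^2 / w0, 0) +
               ifelse(w1 > 0, m1^2 / w1, 0) +
               ifelse(w2 > 0, m2^2 / w2, 0)
        jbest <- best_cut_1d(obj)
        if (is.null(best_cuts) ||
            obj[jbest] > best + 1e-12 * max(1, abs(obj[jbest]))) {
          best <- obj[jbest]; best_cuts <- c(i, j[jbest])
        }
      }
      best_cuts
    },
    otsu_dp(cw, cm, n_thresholds, nb))
  structure(list(
    thresholds = h$upper[cuts], n_classes = n_thresholds + 1L,
    source = "otsu",
    settings = list(n_thresholds = n_thresholds, n_bins = h$n_bins,
                    dtype = dtype)
  ), class = "ThresholdSet")
}

## first index attaining the maximum within a relative tolerance
best_cut_1d <- function(obj) {
  m <- max(obj)
  which(obj >= m - 1e-12 * max(1, abs(m)))[1L]
}

## dynamic program for 3-4 thresholds: seg(a,b) = (M_b - M_{a-1})^2/(W_b - W_{a-1})
otsu_dp <- function(cw, cm, n_thr, nb) {
  seg <- function(a, b) {            # vectorized over a
    w <- cw[b + 1L] - cw[a]
    m <- cm[b + 1L] - cm[a]
    ifelse(w > 0, m^2 / w, 0)
  }
  n_cls <- n_thr + 1L
  ## best[j, b]: max objective for bins 1..b split into j classes
  best <- matrix(-Inf, n_cls, nb)
  argc <- array(0L, dim = c(n_cls, nb))   # last cut position
  best[1L, ] <- seg(1L, seq_len(nb))
  for (j in 2:n_cls) {
    for (b in j:nb) {
      a <- j:b                              # start bin of class j
      val <- best[j - 1L, a - 1L] + seg(a, b)
      i <- best_cut_1d(val)
      best[j, b] <- val[i]
      argc[j, b] <- a[i] - 1L               # cut after bin a[i]-1
    }
  }
  cuts <- integer(n_thr)
  b <- nb
  for (j in n_cls:2) {
    cuts[j - 1L] <- argc[j, b]
    b <- argc[j, b]
  }
  cuts
}

#' Histogram k-means thresholds
#'
#' 1-D weighted Lloyd iteration on the frame histogram, initialized at
#' `k` evenly spaced quantiles of the intensity distribution;
#' deterministic given the seed. Thresholds are midpoints between sorted
#' adjacent cluster centers.
#'
#' @param frame 2-D numeric matrix with at least `k` distinct values.
#' @param k number of clusters, 2..5.
#' @param seed integer seed (recorded; the quantile initialization is
#'   itself deterministic).
#' @param n_bins,dtype histogram settings as in [otsu_multilevel()].
#' @return a `"ThresholdSet"` with `k - 1` thresholds, `source = "kmeans"`.
#' @export
kmeans_thresholds <- function(frame, k = 2L, seed = 1L, n_bins = NULL,
                              dtype = "float32") {
  if (k < 2L || k > 5L) input_error("k must be in 2..5")
  v <- as.vector(frame)
  if (length(unique(v)) < k) input_error("frame has fewer than k distinct values")
  h <- frame_histogram(frame, dtype, n_bins)
  centers <- with_seed(seed, {
    stats::quantile(v, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  })
  x <- h$centers; w <- h$counts
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  for (it in seq_len(200L)) {
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    assign_ <- max.col(-d2, ties.method = "first")
    newc <- centers
    for (j in seq_len(k)) {
      sel <- assign_ == j
      if (any(sel)) newc[j] <- sum(w[sel] * x[sel]) / sum(w[sel])
    }
    if (max(abs(newc - centers)) < 1e-12 * max(1, max(abs(centers)))) {
      centers <- newc; break
    }
    centers <- newc
  }
  centers <- sort(centers)
  structure(list(
    thresholds = (centers[-1] + centers[-k]) / 2, n_classes = k,
    source = "kmeans",
    settings = list(k = k, seed = seed, n_bins = h$n_bins, dtype = dtype)
  ), class = "ThresholdSet")
}

#' Manual threshold set
#' @param thresholds 1-4 strictly increasing intensity cut points.
#' @return a `"ThresholdSet"` with `source = "manual"`.
#' @export
manual_thresholds <- function(thresholds) {
  if (length(thresholds) < 1L || length(thresholds) > 4L)
    input_error("1 to 4 thresholds required")
  if (is.unsorted(thresholds, strictly = TRUE))
    input_error("thresholds must be strictly increasing")
  structure(list(thresholds = as.numeric(thresholds),
                 n_classes = length(thresholds) + 1L, source = "manual",
                 settings = list()), class = "ThresholdSet")
}

#' @export
print.ThresholdSet <- function(x, ...) {
  cat(sprintf("<ThresholdSet %s: %s (%d classes)>\n", x$source,
              paste(signif(x$thresholds, 6), collapse = ", "), x$n_classes))
  invisible(x)
}

recompute_thresholds <- function(frame, tset) {
  s <- tset$settings
  switch(tset$source,
    otsu   = otsu_multilevel(frame, s$n_thresholds, s$n_bins, s$dtype),
    kmeans = kmeans_thresholds(frame, s$k, s$seed, s$n_bins, s$dtype),
    tset)
}

#' Classify stack pixels by a threshold set
#'
#' Pixel class `k` means `threshold[k] <= intensity < threshold[k+1]`
#' (with -Inf/+Inf sentinels), i.e. class 0 is below the first threshold.
#'
#' @param stack an [image_stack()].
#' @param channel 0-based channel index.
#' @param threshold_set a `"ThresholdSet"`.
#' @param per_frame if `TRUE`, thresholds are recomputed on every frame
#'   with the same method and settings; default uses the fixed set.
#' @return an object of class `"LabelImage"`: integer class array
#'   `(T, Z, Y, X)` plus the threshold set(s) used.
#' @export
apply_thresholds <- function(stack, channel, threshold_set, per_frame = FALSE) {
  d <- stack_dim(stack)
  if (channel < 0 || channel >= d[["C"]]) input_error("invalid channel %d", channel)
  classes <- array(0L, dim = unname(d[c(1, 3, 4, 5)]))
  per_frame_sets <- if (per_frame) vector("list", d[1]) else NULL
  for (t in seq_len(d[1])) {
    tset_t <- threshold_set
    if (per_frame) {
      tset_t <- recompute_thresholds(stack$pixels[t, channel + 1L, 1L, , ],
                                     threshold_set)
      per_frame_sets[[t]] <- tset_t
    }
    for (z in seq_len(d[3])) {
      fr <- stack$pixels[t, channel + 1L, z, , ]
      cl <- findInterval(fr, tset_t$thresholds)
      classes[t, z, , ] <- as.integer(cl)
    }
  }
  structure(list(classes = classes, threshold_set = threshold_set,
                 per_frame_sets = per_frame_sets, channel = channel,
                 n_classes = threshold_set$n_classes),
            class = "LabelImage")
}

#' @export
print.LabelImage <- function(x, ...) {
  d <- dim(x$classes)
  cat(sprintf("<LabelImage %d classes, T=%d Z=%d Y=%d X=%d, channel %d>\n",
              x$n_classes, d[1], d[2], d[3], d[4], x$channel))
  invisible(x)
}

## per-frame class matrix (0-based t, z)
label_frame <- function(labels, t, z = 0L) {
  labels$classes[t + 1L, z + 1L, , ]
}

component_stats <- function(lab, frame_t, z, class_level, kind) {
  n <- max(lab)
  if (n == 0L)
    return(data.frame(component_id = integer(), frame_t = integer(),
                      z = integer(), centroid_y = numeric(), centroid_x = numeric(),
                      area_px = integer(), bbox_y0 = integer(), bbox_x0 = integer(),
                      bbox_y1 = integer(), bbox_x1 = integer(),
                      class_level = integer(), kind = character()))
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  y0 <- idx[, 1] - 1L; x0 <- idx[, 2] - 1L     # 0-based pixel coords
  area <- tabulate(ids, nbins = n)
  cy <- as.vector(tapply(y0, ids, mean))
  cx <- as.vector(tapply(x0, ids, mean))
  data.frame(component_id = seq_len(n), frame_t = frame_t, z = z,
             centroid_y = cy, centroid_x = cx, area_px = area,
             bbox_y0 = as.vector(tapply(y0, ids, min)),
             bbox_x0 = as.vector(tapply(x0, ids, min)),
             bbox_y1 = as.vector(tapply(y0, ids, max)) + 1L,
             bbox_x1 = as.vector(tapply(x0, ids, max)) + 1L,
             class_level = class_level, kind = kind)
}

#' Detect particles (bright connected objects) in a label image
#'
#' 8-connected components of pixels with class `>= class_level`, filtered
#' by area. Centroids are unweighted means of member pixel coordinates
#' (0-based).
#'
#' @param labels a `"LabelImage"` from [apply_thresholds()].
#' @param class_level minimum class for foreground.
#' @param min_area_px,max_area_px inclusive area filter in pixels.
#' @return a component table (`data.frame`), one row per object per frame.
#' @export
detect_particles <- function(labels, class_level, min_area_px = 1,
                             max_area_px = Inf) {
  if (class_level >= labels$n_classes) input_error("class_level out of range")
  d <- dim(labels$classes)
  out <- vector("list", d[1] * d[2])
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    mask <- labels$classes[t, z, , ] >= class_level
    lab <- label_components(mask, 8L)
    tab <- component_stats(lab, t - 1L, z - 1L, class_level, "particle")
    out[[i]] <- tab[tab$area_px >= min_area_px & tab$area_px <= max_area_px, ,
                    drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "connectivity") <- 8L
  res
}

#' Detect intensity holes inside an enclosing mask
#'
#' 4-connected components of pixels with class `< class_level` that lie
#' inside `enclosing_mask` and do not touch its boundary; these are the
#' signal-depletion "holes" left by locally excluded proteins.
#'
#' @param labels a `"LabelImage"`.
#' @param class_level pixels below this class are hole candidates.
#' @param enclosing_mask binary `Y x X` matrix (e.g. the tracked nucleus),
#'   or a `(T, Z, Y, X)`-shaped logical array matching `labels`.
#' @param min_area_px minimum hole area.
#' @return a component table with `kind = "hole"`.
#' @export
detect_holes <- function(labels, class_level, enclosing_mask, min_area_px = 1) {
  d <- dim(labels$classes)
  static_mask <- is.matrix(enclosing_mask)
  if (static_mask && !any(enclosing_mask > 0)) input_error("empty enclosing mask")
  out <- vector("list", d[1] * d[2])
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    msk <- if (static_mask) enclosing_mask > 0 else enclosing_mask[t, z, , ] > 0
    below <- labels$classes[t, z, , ] < class_level
    ## interior of the mask: erode by the mask boundary (pixels whose
    ## 4-neighborhood stays inside the mask)
    inner <- msk & !mask_boundary4(msk)
    cand <- below & msk
    lab <- label_components(cand, 4L)
    if (max(lab) > 0L) {
      ## drop components touching the mask boundary (or frame border)
      touching <- unique(lab[lab > 0 & !inner])
      lab[lab %in% touching] <- 0L
      lab <- relabel_by_first_pixel(lab)
    }
    tab <- component_stats(lab, t - 1L, z - 1L, class_level, "hole")
    out[[i]] <- tab[tab$area_px >= min_area_px, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "connectivity") <- 4L
  res
}

#' Adaptive nucleus + focus segmentation of a time-lapse channel
#'
#' Global Otsu weights classes by pixel count, so a diffraction-limited
#' focus (tens of pixels) inside a nucleus (thousands of pixels) carries
#' too little histogram mass to earn its own threshold. This operation
#' mirrors how focus settings are tailored in practice: per frame, a
#' single Otsu threshold separates nucleus from background, then focus
#' pixels are those exceeding the nucleus population median by `z` robust
#' standard deviations (1.4826 MAD; the median/MAD pair ignores the
#' boundary intensity ramp that blurring paints around the nucleus).
#' Both cuts rescale with any multiplicative intensity decay, so the
#' segmentation is stable under acquisition photobleaching.
#'
#' @param stack an [image_stack()] (typically Gaussian-filtered).
#' @param channel 0-based channel index.
#' @param z robust z-score cut for focus pixels above the nucleus
#'   population.
#' @return a `"LabelImage"` with classes 0 (background), 1 (nucleus),
#'   2 (focus).
#' @export
adaptive_focus_labels <- function(stack, channel = 0L, z = 5) {
  d <- stack_dim(stack)
  if (channel < 0 || channel >= d[["C"]]) input_error("invalid channel %d", channel)
  classes <- array(0L, dim = unname(d[c(1, 3, 4, 5)]))
  sets <- vector("list", d[1])
  for (t in seq_len(d[1])) {
    fr <- stack$pixels[t, channel + 1L, 1L, , ]
    thr_n <- otsu_multilevel(fr, 1L, dtype = stack$dtype)$thresholds
    for (zi in seq_len(d[3])) {
      frz <- stack$pixels[t, channel + 1L, zi, , ]
      nuc <- frz >= thr_n
      med <- stats::median(frz[nuc])
      sdv <- stats::mad(frz[nuc])          # 1.4826 * MAD
      ## noise-free synthetic frames have MAD 0 over the flat nucleoplasm;
      ## floor the scale at 0.1% of the median so the cut stays above it
      sdv <- max(sdv, 1e-3 * max(abs(med), .Machine$double.eps))
      thr_f <- med + z * sdv
      cl <- matrix(0L, d[4], d[5])
      cl[nuc] <- 1L
      cl[nuc & frz >= thr_f] <- 2L
      classes[t, zi, , ] <- cl
    }
    sets[[t]] <- manual_thresholds(sort(c(thr_n, max(thr_n + 1e-9, thr_f))))
  }
  structure(list(classes = classes, threshold_set = sets[[1]],
                 per_frame_sets = sets, channel = channel, n_classes = 3L),
            class = "LabelImage")
}

## pixels of msk having a 4-neighbor outside msk (or on the frame edge)
mask_boundary4 <- function(msk) {
  ny <- nrow(msk); nx <- ncol(msk)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1), 2:(nx + 1)] <- msk
  inside <- pad[2:(ny + 1), 2:(nx + 1)] &
    pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
    pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]
  msk & !inside
}
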