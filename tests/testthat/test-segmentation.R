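test_that("single-threshold Otsu separates a bimodal frame at the smallest maximizing edge", {
  f <- matrix(c(rep(10, 32), rep(200, 32)), 8, 8)
  ts <- otsu_multilevel(f, 1)
  expect_s3_class(ts, "ThresholdSet")
  expect_gt(ts$thresholds, 10)
  expect_lte(ts$thresholds, 200)
  lab <- apply_thresholds(image_stack(f), 0, ts)
  cl <- cellkin:::label_frame(lab, 0)
  expect_true(all(cl[f == 10] == 0))      # both classes pure
  expect_true(all(cl[f == 200] == 1))
  # smallest maximizing bin edge: any cut in (10, 200] maximizes, so the
  # reported threshold is the first bin edge above the low mode
  h <- cellkin:::frame_histogram(f, "float32")
  expect_equal(ts$thresholds, h$upper[1])
  expect_error(otsu_multilevel(matrix(3, 4, 4), 1),
               class = "cellkin_degenerate_error")
})

test_that("otsu n=1 equals classical exhaustive Otsu on random histograms", {
  set.seed(31)
  for (i in 1:10) {
    v <- sample(0:63, 2000, TRUE, prob = runif(64))
    fr <- matrix(v, 40, 50)
    ts <- otsu_multilevel(fr, 1, n_bins = 64)
    h <- cellkin:::frame_histogram(fr, "float32", 64)
    expect_equal(ts$thresholds, h$upper[otsu1_brute(h$counts, h$centers)])
  }
})

test_that("otsu n=2 matches exhaustive search over all threshold pairs", {
  set.seed(32)
  for (i in 1:5) {
    v <- sample(0:63, 2500, TRUE, prob = runif(64))
    fr <- matrix(v, 50, 50)
    ts <- otsu_multilevel(fr, 2, n_bins = 64)
    h <- cellkin:::frame_histogram(fr, "float32", 64)
    p <- h$counts / sum(h$counts)
    cw <- c(0, cumsum(p)); cm <- c(0, cumsum(p * h$centers))
    best <- -Inf; bc <- NULL
    for (a in 1:62) for (b in (a + 1):63) {
      o <- cellkin:::bcv_objective(cw, cm, c(a, b), 64)
      if (o > best + 1e-12) { best <- o; bc <- c(a, b) }
    }
    expect_equal(ts$thresholds, h$upper[bc])
  }
})

test_that("otsu n=2 splits three Gaussian modes between adjacent pairs", {
  set.seed(33)
  v <- c(rnorm(1000, 30, 5), rnorm(1000, 120, 5), rnorm(1000, 220, 5))
  fr <- matrix(v, 60, 50)
  ts <- otsu_multilevel(fr, 2)
  expect_gt(ts$thresholds[1], 30); expect_lt(ts$thresholds[1], 120)
  expect_gt(ts$thresholds[2], 120); expect_lt(ts$thresholds[2], 220)
})

test_that("dynamic-programming Otsu (n=3) separates four clean modes", {
  set.seed(34)
  v <- c(rnorm(800, 20, 3), rnorm(800, 80, 3), rnorm(800, 150, 3),
         rnorm(800, 230, 3))
  fr <- matrix(v, 80, 40)
  ts <- otsu_multilevel(fr, 3)
  expect_length(ts$thresholds, 3)
  expect_true(all(diff(ts$thresholds) > 0))
  modes <- c(20, 80, 150, 230)
  for (i in 1:3) {
    expect_gt(ts$thresholds[i], modes[i]); expect_lt(ts$thresholds[i], modes[i + 1])
  }
})

test_that("kmeans thresholds: midpoints, oracle equivalence, determinism", {
  f <- matrix(c(rep(10, 32), rep(200, 32)), 8, 8)
  tk <- kmeans_thresholds(f, 2)
  expect_equal(tk$thresholds, 105)     # midpoint of the two values

  # k=2 assignment equals exhaustive single-cut sweep minimizing WCSS
  set.seed(35)
  v <- c(rnorm(900, 40, 12), rnorm(1100, 160, 20))
  fr <- matrix(v, 50, 40)
  tk2 <- kmeans_thresholds(fr, 2)
  h <- cellkin:::frame_histogram(fr, "float32")
  keep <- h$counts > 0
  x <- h$centers[keep]; w <- h$counts[keep]
  wcss <- vapply(seq_len(length(x) - 1), function(i) {
    lo <- 1:i; hi <- (i + 1):length(x)
    m0 <- sum(w[lo] * x[lo]) / sum(w[lo]); m1 <- sum(w[hi] * x[hi]) / sum(w[hi])
    sum(w[lo] * (x[lo] - m0)^2) + sum(w[hi] * (x[hi] - m1)^2)
  }, numeric(1))
  cut <- which.min(wcss)
  expect_identical(x <= tk2$thresholds, seq_along(x) <= cut)

  expect_identical(kmeans_thresholds(fr, 3, seed = 7),
                   kmeans_thresholds(fr, 3, seed = 7))
  expect_error(kmeans_thresholds(matrix(c(1, 2), 1, 2), 3),
               class = "cellkin_input_error")
})

test_that("apply_thresholds maps classes monotonically and partitions the frame", {
  f <- matrix(c(50, 150, 120, 30), 2, 2)
  lab <- apply_thresholds(image_stack(f), 0, manual_thresholds(100))
  expect_identical(cellkin:::label_frame(lab, 0),
                   matrix(c(0L, 1L, 1L, 0L), 2, 2))
  set.seed(36)
  f2 <- matrix(runif(400, 0, 255), 20, 20)
  lab5 <- apply_thresholds(image_stack(f2), 0,
                           manual_thresholds(c(50, 100, 150, 200)))
  cl <- cellkin:::label_frame(lab5, 0)
  expect_equal(sum(tabulate(cl + 1L, 5)), 400)        # partition
  expect_true(all(cl[f2 < 50] == 0) && all(cl[f2 >= 200] == 4))
  o <- order(f2)
  expect_true(!is.unsorted(cl[o]))                     # monotone in intensity
})

test_that("per-frame thresholds keep foreground area stable under dimming", {
  # globally dimming movie e^(-beta t), 50 frames, dimming deep enough to
  # cross the frame-0 threshold before the movie ends
  g <- cellkin:::coord_grids(64, 64)
  nuc <- cellkin:::ellipse_mask(g, 32, 32, 14, 17)
  set.seed(37)
  frames <- lapply(0:49, function(t) {
    fr <- matrix(12, 64, 64); fr[nuc] <- 130
    fr * exp(-0.05 * t) + matrix(rnorm(64 * 64, 0, 1.5), 64, 64)
  })
  stk <- stack_from_frames(frames)
  tset <- otsu_multilevel(frames[[1]], 1)
  area_of <- function(lab) vapply(0:49, function(t)
    sum(cellkin:::label_frame(lab, t) == 1), numeric(1))
  fixed <- area_of(apply_thresholds(stk, 0, tset, per_frame = FALSE))
  perfr <- area_of(apply_thresholds(stk, 0, tset, per_frame = TRUE))
  true_area <- sum(nuc)
  expect_true(all(abs(perfr - true_area) / true_area < 0.10))
  expect_gt(max(abs(fixed - true_area)) / true_area, 0.3)  # fixed loses it
})

test_that("detect_particles: geometry, connectivity, area filter", {
  m <- matrix(0L, 20, 20)
  m[5:7, 5:7] <- 1L                      # 3x3 square
  ct <- detect_particles(label_image_1f(m), 1)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$area_px, 9)
  expect_equal(c(ct$centroid_y, ct$centroid_x), c(5, 5))  # 0-based center

  m2 <- matrix(0L, 10, 10); m2[3, 3] <- 1L; m2[4, 4] <- 1L  # diagonal touch
  expect_equal(nrow(detect_particles(label_image_1f(m2), 1)), 1)

  # generator ground truth: disks above min_area kept, smaller dropped
  set.seed(38)
  m3 <- matrix(0L, 120, 120)
  centers <- expand.grid(y = seq(10, 110, 25), x = seq(10, 110, 25))
  keep_n <- 20; small_n <- 5
  g <- cellkin:::coord_grids(120, 120)
  for (i in seq_len(keep_n))
    m3[(g$y - centers$y[i])^2 + (g$x - centers$x[i])^2 <= 16] <- 1L
  for (i in seq_len(small_n))
    m3[(g$y - centers$y[keep_n + i])^2 + (g$x - centers$x[keep_n + i])^2 <= 1] <- 1L
  ct3 <- detect_particles(label_image_1f(m3), 1, min_area_px = 20)
  expect_equal(nrow(ct3), keep_n)
})

test_that("detect_particles is translation-equivariant", {
  set.seed(39)
  m <- matrix(0L, 40, 40)
  m[5:9, 6:10] <- 1L; m[20:26, 18:22] <- 1L
  base <- detect_particles(label_image_1f(m), 1)
  dy <- 7L; dx <- 4L
  m2 <- matrix(0L, 40, 40)
  m2[(1:40) %in% ((5:9) + dy), (1:40) %in% ((6:10) + dx)] <- 1L
  m2[(1:40) %in% ((20:26) + dy), (1:40) %in% ((18:22) + dx)] <- 1L
  shifted <- detect_particles(label_image_1f(m2), 1)
  expect_equal(shifted$centroid_y, base$centroid_y + dy)
  expect_equal(shifted$centroid_x, base$centroid_x + dx)
})

test_that("detect_holes finds interior holes and excludes boundary notches", {
  nuc <- matrix(0L, 30, 30); nuc[5:25, 5:25] <- 1L
  cls <- nuc; cls[12:14, 12:14] <- 0L
  holes <- detect_holes(label_image_1f(cls), 1, nuc > 0)
  expect_equal(nrow(holes), 1)
  expect_equal(holes$area_px, 9)
  expect_identical(holes$kind, "hole")
  expect_equal(c(holes$centroid_y, holes$centroid_x), c(12, 12))

  notch <- nuc; notch[5:10, 15] <- 0L    # open to the nucleus boundary
  expect_equal(nrow(detect_holes(label_image_1f(notch), 1, nuc > 0)), 0)
  expect_error(detect_holes(label_image_1f(cls), 1, matrix(0, 30, 30)),
               class = "cellkin_input_error")
})

test_that("synthetic depletion hole is localized within 1 px of ground truth", {
  scn <- simulate_recruitment_movie(scene_config(
    "recruitment_demo", seed = 2, n_frames = 40L,
    bleach_beta_per_frame = 0, noise = list(gaussian_sd = 0.5, poisson = FALSE)))
  filt <- apply_filter(scn$stack, 1, filter_spec("gaussian", sigma = 1))
  fr <- get_frame(filt, 35, 1)
  tset <- otsu_multilevel(fr, 1, dtype = scn$stack$dtype)
  labels <- apply_thresholds(filt, 1, tset)
  g <- cellkin:::coord_grids(128, 128)
  nucmask <- cellkin:::ellipse_mask(g, 64, 64, 38, 44)
  holes <- detect_holes(labels, 1, nucmask, min_area_px = 4)
  h35 <- holes[holes$frame_t == 35, ]
  expect_equal(nrow(h35), 1)
  truth <- scn$truth$hole_centers[36, ]
  expect_lt(sqrt((h35$centroid_y - truth$y)^2 + (h35$centroid_x - truth$x)^2), 1)
})

test_that("adaptive focus labels expose a small focus inside a large nucleus", {
  scn <- simulate_recruitment_movie(scene_config("recruitment_demo", seed = 3,
                                                 n_frames = 40L))
  filt <- apply_filter(scn$stack, 0, filter_spec("gaussian", sigma = 2))
  labels <- adaptive_focus_labels(filt, 0, z = 5)
  comps <- detect_particles(labels, class_level = 2, min_area_px = 5)
  c35 <- comps[comps$frame_t == 35, ]
  expect_gte(nrow(c35), 1)
  truth <- scn$truth$focus_centers[36, ]
  d <- sqrt((c35$centroid_y - truth$y)^2 + (c35$centroid_x - truth$x)^2)
  expect_lt(min(d), 1)
})
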