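test_that("magic wand returns the exact pixel set of the clicked object", {
  m <- matrix(0L, 20, 20); m[5:9, 7:11] <- 1L
  lab <- label_image_1f(m)
  roi <- magic_wand_select(lab, 0, c(7, 9), 1)
  expect_identical(roi$shape, "region")
  expect_equal(nrow(roi$pixels_yx), 25)
  expect_setequal(paste(roi$pixels_yx[, 1], roi$pixels_yx[, 2]),
                  paste(rep(4:8, 5), rep(6:10, each = 5)))
  expect_error(magic_wand_select(lab, 0, c(1, 1), 1),
               class = "cellkin_no_object_error")
})

test_that("magic wand on a two-nucleus field recovers the generator area", {
  fld <- simulate_field(scene_config(n_nuclei = 2, seed = 4,
    field_size = c(Y = 160L, X = 160L),
    nucleus = list(axes_px = c(16, 19), axes_jitter = 0, intensity = 120,
                   intensity_jitter = 0, channel_scale = c(1, 0.85)),
    noise = list(gaussian_sd = 0, poisson = FALSE)))
  lab <- apply_thresholds(fld$stack, 0, manual_thresholds(70))
  tn <- fld$truth$nuclei
  g <- cellkin:::coord_grids(160, 160)
  for (i in 1:2) {
    roi <- magic_wand_select(lab, 0, c(tn$centroid_y[i], tn$centroid_x[i]), 1)
    true_area <- sum(cellkin:::ellipse_mask(g, tn$centroid_y[i],
                                            tn$centroid_x[i],
                                            tn$axis_y[i], tn$axis_x[i]))
    expect_equal(nrow(roi$pixels_yx), true_area)
  }
})

test_that("tracking follows a drifting focus to sub-pixel accuracy", {
  scn <- simulate_recruitment_movie(scene_config("recruitment_demo", seed = 5,
    n_frames = 34L, drift_px_per_frame = c(1.4, 1.4),
    focus = list(amplitude = 60, sigma_px = 2.5,
                 crc = list(k = c(0.5, 0.1), kr = 0, f_rem = 1),
                 offset_yx = c(-25, -25)),
    bleach_beta_per_frame = 0))
  filt <- apply_filter(scn$stack, 0, filter_spec("gaussian", sigma = 2))
  labels <- adaptive_focus_labels(filt, 0, z = 5)
  comps <- detect_particles(labels, class_level = 2, min_area_px = 5)
  tr <- track_object(comps, 20L,
                     as.numeric(scn$truth$focus_centers[21, c("y", "x")]),
                     t_range = c(0L, 33L))
  post <- tr$frames$frame_t >= 6     # focus well established
  err <- sqrt((tr$frames$y - scn$truth$focus_centers$y)^2 +
              (tr$frames$x - scn$truth$focus_centers$x)^2)
  expect_true(all(tr$frames$status[post] == "tracked"))
  expect_lt(max(err[post]), 1)
})

test_that("static objects track in place; vanishing objects coast", {
  comps <- do.call(rbind, lapply(0:19, function(t) comp_row(1L, t, 30, 40, 25)))
  tr <- track_object(comps, 0L, c(30, 40))
  expect_true(all(tr$frames$status == "tracked"))
  expect_true(all(tr$frames$y == 30 & tr$frames$x == 40))

  # object present only in frames 0..9 of 20
  comps2 <- do.call(rbind, lapply(0:9, function(t) comp_row(1L, t, 30, 40, 25)))
  tr2 <- track_object(comps2, 0L, c(30, 40), t_range = c(0L, 19L))
  expect_true(all(tr2$frames$status[11:20] == "coasted"))
  expect_true(all(tr2$frames$y[11:20] == 30))  # held at frame-9 placement
  expect_error(track_object(comps2, 0L, c(90, 90)),
               class = "cellkin_no_object_error")
})

test_that("linking gate prevents identity swaps for crossing foci", {
  # two foci crossing in x while staying 30 px apart in y (> 20 px gate)
  comps <- do.call(rbind, lapply(0:20, function(t) rbind(
    comp_row(1L, t, 20, 10 + 4 * t, 25),
    comp_row(2L, t, 50, 90 - 4 * t, 25))))
  trA <- track_object(comps, 0L, c(20, 10), max_displacement_px = 20)
  trB <- track_object(comps, 0L, c(50, 90), max_displacement_px = 20)
  expect_equal(trA$frames$y, rep(20, 21))
  expect_equal(trA$frames$x, 10 + 4 * (0:20))
  expect_equal(trB$frames$y, rep(50, 21))
  expect_equal(trB$frames$x, 90 - 4 * (0:20))
})

test_that("tracking is seed-frame symmetric on reversed motion", {
  set.seed(41)
  ys <- 30 + cumsum(runif(15, -2, 2)); xs <- 40 + cumsum(runif(15, -2, 2))
  comps <- do.call(rbind, lapply(0:14, function(t)
    comp_row(1L, t, ys[t + 1], xs[t + 1], 25)))
  fwd <- track_object(comps, 0L, c(ys[1], xs[1]))
  rev_comps <- comps
  rev_comps$frame_t <- 14L - comps$frame_t
  bwd <- track_object(rev_comps, 0L, c(ys[15], xs[15]))
  expect_equal(rev(bwd$frames$y), fwd$frames$y)
  expect_equal(rev(bwd$frames$x), fwd$frames$x)
})

test_that("hole tracking follows the depletion site across frames", {
  scn <- simulate_recruitment_movie(scene_config("recruitment_demo", seed = 6,
    n_frames = 40L, bleach_beta_per_frame = 0,
    noise = list(gaussian_sd = 0.5, poisson = FALSE)))
  filt <- apply_filter(scn$stack, 1, filter_spec("gaussian", sigma = 1))
  tset <- otsu_multilevel(get_frame(filt, 0, 1), 1, dtype = scn$stack$dtype)
  labels <- apply_thresholds(filt, 1, tset)
  g <- cellkin:::coord_grids(128, 128)
  nucmask <- cellkin:::ellipse_mask(g, 64, 64, 38, 44)
  seedp <- as.numeric(scn$truth$hole_centers[36, c("y", "x")])
  tr <- track_hole(labels, nucmask, 35L, seedp, class_level = 1,
                   min_area_px = 4)
  expect_identical(tr$kind, "hole")
  late <- tr$frames$frame_t >= 20      # hole deep enough to segment
  err <- sqrt((tr$frames$y - scn$truth$hole_centers$y)^2 +
              (tr$frames$x - scn$truth$hole_centers$x)^2)
  expect_lt(max(err[late]), 1)
  # movie without depletion: no hole to click
  scn2 <- simulate_recruitment_movie(scene_config("recruitment_demo", seed = 6,
    n_frames = 20L, hole = list(sigma_px = 3, depth_max = 0, rate = 0.01),
    bleach_beta_per_frame = 0, noise = list(gaussian_sd = 0.5, poisson = FALSE)))
  filt2 <- apply_filter(scn2$stack, 1, filter_spec("gaussian", sigma = 2))
  labels2 <- apply_thresholds(filt2, 1,
    otsu_multilevel(get_frame(filt2, 0, 1), 1, dtype = scn2$stack$dtype))
  expect_error(track_hole(labels2, nucmask, 10L, c(64, 64), 1, 4),
               class = "cellkin_no_object_error")
})

test_that("ROI transfer copies geometry verbatim to other channels", {
  comps <- do.call(rbind, lapply(0:9, function(t)
    comp_row(1L, t, 20 + t, 30 + t, 25)))
  tr <- track_object(comps, 0L, c(20, 30), channel = 0L)
  copies <- copy_roi_to_channel(tr, c(0L, 1L))
  expect_equal(copies[[1]]$frames, tr$frames)       # identity copy
  expect_equal(copies[[2]]$frames$y, tr$frames$y)   # same coordinates
  expect_identical(copies[[2]]$channel, 1L)
  expect_error(copy_roi_to_channel(tr, 5L, n_channels = 2L),
               class = "cellkin_input_error")
})

test_that("copied ROI lands on the co-localized structure in channel 1", {
  scn <- simulate_recruitment_movie(scene_config("recruitment_demo", seed = 7,
    n_frames = 40L, bleach_beta_per_frame = 0,
    noise = list(gaussian_sd = 0, poisson = FALSE)))
  filt <- apply_filter(scn$stack, 0, filter_spec("gaussian", sigma = 2))
  labels <- adaptive_focus_labels(filt, 0, z = 5)
  comps <- detect_particles(labels, class_level = 2, min_area_px = 5)
  tr <- track_object(comps, 35L,
                     as.numeric(scn$truth$focus_centers[36, c("y", "x")]),
                     t_range = c(0L, 39L))
  tr1 <- copy_roi_to_channel(attach_tracking_circle(tr, 6), 1L)[[1]]
  fr1 <- get_frame(scn$stack, 35, 1)
  # darkest pixel of the depletion hole lies under the copied circle
  dark <- which(fr1 == min(fr1[cellkin:::ellipse_mask(
    cellkin:::coord_grids(128, 128), 64, 64, 38, 44)]), arr.ind = TRUE) - 1
  d <- sqrt((dark[1] - tr1$frames$y[36])^2 + (dark[2] - tr1$frames$x[36])^2)
  expect_lt(d, 6)
})

test_that("layered tracking circles rasterize with consistent layer areas", {
  tr <- track_object(comp_row(1L, 0L, 20.3, 30.7, 25), 0L, c(20.3, 30.7))
  tr <- attach_tracking_circle(tr, radius_px = 5, n_layers = 2,
                               layer_width_px = 2.5)
  inner <- cellkin:::rasterize_roi(tr$roi_template, 64, 64, 0,
                                   center = c(20.3, 30.7))
  shell <- cellkin:::rasterize_roi(tr$roi_template, 64, 64, 1,
                                   center = c(20.3, 30.7))
  big <- cellkin:::rasterize_roi(roi_circle(c(20.3, 30.7), 7.5), 64, 64, 0)
  # |annulus| = |disk(r+w)| - |disk(r)| under the rasterization rule
  expect_equal(nrow(shell), nrow(big) - nrow(inner))
  expect_equal(nrow(inner) + nrow(shell), nrow(big))
  # centroid of the rasterized disk is the circle center within 0.5 px
  expect_lt(abs(mean(inner[, 1]) - 20.3), 0.5)
  expect_lt(abs(mean(inner[, 2]) - 30.7), 0.5)
})
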