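## Seeded synthetic-movie and synthetic-curve generator with ground truth.
##
## Three scene families mirror the workflows the package quantifies:
## a multi-nucleus field of view, a recruitment-focus/depletion-hole
## movie (two channels, optional drift and acquisition bleaching), and a
## bleach-and-recover (FRAP) experiment emitted either as a rendered
## single-plane movie or directly as a kinetics curve. Foci are isotropic
## 2-D Gaussians on a uniform nucleus (analytic integrals give test
## oracles); holes are multiplicative Gaussian dips; noise is additive
## Gaussian with optional Poisson shot noise; seeds fully determine the
## output.

#' Scene configuration for the synthetic generators
#'
#' Defaults encode the package's reference study conditions; presets
#' override them in a single named bundle.
#'
#' @param preset `"none"`, `"fig2_field"` (11-nucleus two-channel field,
#'   seed 1), `"recruitment_demo"` (two-step recruitment chain with
#'   depletion hole, acquisition bleaching 0.02/frame, 2% amplitude
#'   noise), `"bard1_reference"` (noiseless double-exponential FRAP
#'   reference curve: pre-bleach plateau 1, post-bleach 0.2, mobile
#'   fraction 0.955, recovery half-time 25.68 s, 2 s sampling, bleach at
#'   3600 s, 1400 s post-bleach span) or `"bard1_diffusion"` (companion
#'   uniform-disk diffusion reference: tau_D = 16.89 s, bleach-spot
#'   radius 1 um).
#' @param ... named overrides of any default field.
#' @return an object of class `"SceneConfig"`.
#' @export
scene_config <- function(preset = c("none", "fig2_field", "recruitment_demo",
                                    "bard1_reference", "bard1_diffusion"),
                         ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    field_size = c(Y = 128L, X = 128L),
    n_nuclei = 1L,
    n_channels = 1L,
    nucleus = list(axes_px = c(24, 28), axes_jitter = 0, intensity = 120,
                   intensity_jitter = 0, channel_scale = c(1, 0.85)),
    background = 15,
    focus = list(amplitude = 60, sigma_px = 2.5,
                 crc = list(k = c(0.1, 0.02), kr = 0.005, f_rem = 0.7),
                 offset_yx = c(-6, 5)),
    hole = list(sigma_px = 4, depth_max = 0.85, rate = 0.01),
    drift_px_per_frame = c(0, 0),
    bleach_beta_per_frame = 0,
    noise = list(gaussian_sd = 0, poisson = FALSE),
    n_frames = 50L,
    frame_interval_s = 5,
    pixel_size_um = 0.1,
    events = list(irradiation_frame = NA_integer_, bleach_frame = NA_integer_),
    frap = list(F_pre = 1, F0 = 0.2, mobile_fraction = 0.955,
                half_time_s = 25.68, k2_over_k1 = 0.1, B2_frac = 0.25,
                tau_D = 16.89, w_um = 1.0, pre_span_s = 200,
                post_span_s = 1400, sampling_s = 2, bleach_time_s = 3600,
                model = "frap2"),
    dtype = "float32",
    seed = 1L)
  cfg <- switch(preset,
    none = cfg,
    fig2_field = utils::modifyList(cfg, list(
      field_size = c(Y = 512L, X = 512L), n_nuclei = 11L, n_channels = 2L,
      nucleus = utils::modifyList(cfg$nucleus, list(
        axes_px = c(22, 26), axes_jitter = 5, intensity = 130,
        intensity_jitter = 25)),
      background = 20, noise = list(gaussian_sd = 5, poisson = FALSE),
      n_frames = 1L, dtype = "uint16", seed = 1L)),
    recruitment_demo = utils::modifyList(cfg, list(
      n_channels = 2L, n_frames = 125L,
      nucleus = utils::modifyList(cfg$nucleus, list(axes_px = c(38, 44))),
      noise = list(gaussian_sd = 1.2, poisson = FALSE),   # 2% of amplitude
      bleach_beta_per_frame = 0.02,
      events = list(irradiation_frame = 4L, bleach_frame = NA_integer_))),
    bard1_reference = cfg,
    bard1_diffusion = utils::modifyList(cfg, list(
      frap = utils::modifyList(cfg$frap, list(model = "diffusion")))))
  cfg <- utils::modifyList(cfg, list(...))
  structure(cfg, class = "SceneConfig")
}

## sample non-overlapping nucleus geometry by rejection
place_nuclei <- function(cfg) {
  Y <- cfg$field_size[["Y"]]; X <- cfg$field_size[["X"]]
  n <- cfg$n_nuclei
  ax <- matrix(0, n, 2)
  ctr <- matrix(0, n, 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > 5000L)
      input_error("cannot place %d non-overlapping nuclei; reduce n or sizes", n)
    a <- cfg$nucleus$axes_px + stats::runif(2, -1, 1) * cfg$nucleus$axes_jitter
    margin <- max(a) + 4
    cy <- stats::runif(1, margin, Y - margin)
    cx <- stats::runif(1, margin, X - margin)
    ok <- TRUE
    if (placed > 0L) {
      d <- sqrt((ctr[seq_len(placed), 1] - cy)^2 +
                (ctr[seq_len(placed), 2] - cx)^2)
      ok <- all(d > max(a) + apply(ax[seq_len(placed), , drop = FALSE], 1, max) + 8)
    }
    if (ok) {
      placed <- placed + 1L
      ax[placed, ] <- a
      ctr[placed, ] <- c(cy, cx)
    }
  }
  list(centers = ctr, axes = ax)
}

## additive rendering helpers (0-based pixel-center coordinates)
coord_grids <- function(Y, X) {
  list(y = matrix(0:(Y - 1), Y, X), x = matrix(0:(X - 1), Y, X, byrow = TRUE))
}

ellipse_mask <- function(g, cy, cx, ay, ax) {
  ((g$y - cy) / ay)^2 + ((g$x - cx) / ax)^2 <= 1
}

gauss_bump <- function(g, cy, cx, sigma) {
  exp(-((g$y - cy)^2 + (g$x - cx)^2) / (2 * sigma^2))
}

add_noise <- function(fr, noise) {
  if (isTRUE(noise$poisson)) fr <- stats::rpois(length(fr), pmax(fr, 0)) + 0
  if ((noise$gaussian_sd %||% 0) > 0)
    fr <- fr + stats::rnorm(length(fr), 0, noise$gaussian_sd)
  fr
}

finalize_stack <- function(frames, cfg, channel_names) {
  Tn <- length(frames); Cn <- length(frames[[1]])
  Y <- cfg$field_size[["Y"]]; X <- cfg$field_size[["X"]]
  Z <- 1L
  px <- array(0, dim = c(Tn, Cn, Z, Y, X))
  for (t in seq_len(Tn)) for (ch in seq_len(Cn)) {
    fr <- frames[[t]][[ch]]
    if (cfg$dtype != "float32")
      fr <- pmin(pmax(round(fr), 0), dtype_max[[cfg$dtype]])
    px[t, ch, 1L, , ] <- fr
  }
  image_stack(px, dtype = cfg$dtype, pixel_size_um = cfg$pixel_size_um,
              frame_interval_s = cfg$frame_interval_s,
              channel_names = channel_names)
}

#' Simulate a multi-nucleus field of view
#'
#' Renders `n_nuclei` non-overlapping elliptical nuclei over a uniform
#' background with per-nucleus intensity jitter and Gaussian noise, in
#' one or two channels. The `"fig2_field"` preset produces the package's
#' 11-cell demo field (seed 1).
#'
#' @param config a [scene_config()].
#' @return list with `stack` (an [image_stack()]) and `truth`
#'   (ground-truth nucleus table and the configuration).
#' @export
simulate_field <- function(config = scene_config("fig2_field")) {
  cfg <- config
  with_seed(cfg$seed, {
    geo <- place_nuclei(cfg)
    g <- coord_grids(cfg$field_size[["Y"]], cfg$field_size[["X"]])
    inten <- cfg$nucleus$intensity +
      stats::runif(cfg$n_nuclei, -1, 1) * cfg$nucleus$intensity_jitter
    frames <- vector("list", cfg$n_frames)
    base <- vector("list", cfg$n_channels)
    for (ch in seq_len(cfg$n_channels)) {
      fr <- matrix(cfg$background, cfg$field_size[["Y"]], cfg$field_size[["X"]])
      for (i in seq_len(cfg$n_nuclei)) {
        m <- ellipse_mask(g, geo$centers[i, 1], geo$centers[i, 2],
                          geo$axes[i, 1], geo$axes[i, 2])
        fr[m] <- fr[m] + inten[i] * cfg$nucleus$channel_scale[ch]
      }
      base[[ch]] <- fr
    }
    for (t in seq_len(cfg$n_frames))
      frames[[t]] <- lapply(base, function(fr)
        matrix(add_noise(fr, cfg$noise), nrow(fr), ncol(fr)))
    truth <- data.frame(
      nucleus_id = seq_len(cfg$n_nuclei),
      centroid_y = geo$centers[, 1], centroid_x = geo$centers[, 2],
      axis_y = geo$axes[, 1], axis_x = geo$axes[, 2], intensity = inten)
    list(stack = finalize_stack(frames, cfg,
                                paste0("ch", seq_len(cfg$n_channels) - 1L)),
         truth = list(nuclei = truth, config = cfg))
  })
}

#' Simulate a recruitment-focus / depletion-hole movie
#'
#' Channel 0 carries a bright focus whose amplitude follows the
#' consecutive-reaction-chain recruitment curve after the irradiation
#' frame; channel 1 (if present) carries a co-localized multiplicative
#' depletion hole whose depth approaches `depth_max` exponentially. The
#' whole frame is multiplied by `exp(-beta * t_frame)` to emulate
#' acquisition photobleaching, the focus may drift, and seeded noise is
#' added last.
#'
#' @param config a [scene_config()]; the `"recruitment_demo"` preset
#'   encodes the reference two-step chain (rates 0.1 and 0.02 1/s,
#'   removal 0.005 1/s, removable fraction 0.7) with bleaching
#'   0.02/frame.
#' @return list with `stack` and `truth` (per-frame focus/hole centers,
#'   generating parameters, event times).
#' @export
simulate_recruitment_movie <- function(config = scene_config("recruitment_demo")) {
  cfg <- config
  t_irr <- cfg$events$irradiation_frame
  if (is.na(t_irr)) input_error("config$events$irradiation_frame is required")
  if (t_irr >= cfg$n_frames) input_error("irradiation frame beyond movie end")
  with_seed(cfg$seed, {
    Y <- cfg$field_size[["Y"]]; X <- cfg$field_size[["X"]]
    g <- coord_grids(Y, X)
    ctr <- c(Y, X) / 2
    axes <- cfg$nucleus$axes_px
    nuc <- ellipse_mask(g, ctr[1], ctr[2], axes[1], axes[2])
    p0 <- ctr + cfg$focus$offset_yx
    dt <- cfg$frame_interval_s
    crc <- cfg$focus$crc
    times <- (seq_len(cfg$n_frames) - 1L) * dt
    t_rel <- pmax(times - t_irr * dt, 0)
    amp <- cfg$focus$amplitude *
      crc_model(t_rel, k = crc$k, kr = crc$kr, f_rem = crc$f_rem)
    amp[times < t_irr * dt] <- 0
    depth <- cfg$hole$depth_max * (1 - exp(-cfg$hole$rate * t_rel))
    depth[times < t_irr * dt] <- 0

    frames <- vector("list", cfg$n_frames)
    centers <- matrix(NA_real_, cfg$n_frames, 2)
    for (t in seq_len(cfg$n_frames)) {
      drift_t <- max(0, t - 1L - t_irr)
      p <- p0 + cfg$drift_px_per_frame * drift_t
      centers[t, ] <- p
      bleach <- exp(-cfg$bleach_beta_per_frame * (t - 1L))
      chs <- vector("list", cfg$n_channels)
      fr0 <- matrix(cfg$background, Y, X)
      fr0[nuc] <- fr0[nuc] + cfg$nucleus$intensity
      chs[[1]] <- (fr0 + amp[t] * gauss_bump(g, p[1], p[2],
                                             cfg$focus$sigma_px)) * bleach
      if (cfg$n_channels >= 2L) {
        fr1 <- matrix(cfg$background, Y, X)
        nuc_i <- cfg$nucleus$intensity * cfg$nucleus$channel_scale[2]
        fr1[nuc] <- fr1[nuc] +
          (nuc_i * (1 - depth[t] * gauss_bump(g, p[1], p[2],
                                              cfg$hole$sigma_px)))[nuc]
        chs[[2]] <- fr1 * bleach
      }
      frames[[t]] <- lapply(chs, function(fr)
        matrix(add_noise(fr, cfg$noise), Y, X))
    }
    truth <- list(
      focus_centers = data.frame(frame_t = seq_len(cfg$n_frames) - 1L,
                                 y = centers[, 1], x = centers[, 2]),
      hole_centers = data.frame(frame_t = seq_len(cfg$n_frames) - 1L,
                                y = centers[, 1], x = centers[, 2]),
      nucleus = list(center_yx = ctr, axes_px = axes),
      amplitude_series = amp, depth_series = depth,
      crc = crc, amplitude = cfg$focus$amplitude,
      events = list(irradiation = list(frame = t_irr, time_s = t_irr * dt)),
      config = cfg)
    list(stack = finalize_stack(frames, cfg,
                                paste0("ch", seq_len(cfg$n_channels) - 1L)),
         truth = truth)
  })
}

## solve the fast rate of the double-exponential reference so the
## half-time of recovery matches the requested value
solve_frap_rates <- function(frap) {
  dF <- with(frap, (F_pre - F0) * mobile_fraction)    # Finf - F0
  B2 <- frap$B2_frac * dF
  B1 <- dF - B2
  th <- frap$half_time_s
  q <- frap$k2_over_k1
  f <- function(k1) B1 * exp(-k1 * th) + B2 * exp(-q * k1 * th) - dF / 2
  k1 <- stats::uniroot(f, c(1e-6, 10), tol = 1e-14)$root
  list(F0 = frap$F0, B1 = B1, B2 = B2, k1 = k1, k2 = q * k1,
       Finf = frap$F0 + dF)
}

#' Simulate a FRAP experiment
#'
#' Emits either a kinetics curve (default) or a rendered single-plane
#' movie: a pre-bleach plateau, a sudden drop at the bleach event, and a
#' recovery following either the double-exponential FRAP model or the
#' uniform-disk diffusion model. The `"bard1_reference"` preset encodes
#' the package's reference exchange kinetics (mobile fraction 0.955,
#' half-time 25.68 s); `"bard1_diffusion"` its diffusion companion
#' (tau_D = 16.89 s, bleach-spot radius 1 um, effective diffusion
#' coefficient 0.0148 um^2/s).
#'
#' @param config a [scene_config()].
#' @param output `"curve"` or `"movie"`.
#' @return for `"curve"`: list with `curve` (a [kinetics_curve()] with a
#'   `bleach` event marker) and `truth`; for `"movie"`: list with
#'   `stack`, `curve` and `truth`.
#' @export
simulate_frap_experiment <- function(config = scene_config("bard1_reference"),
                                     output = c("curve", "movie")) {
  cfg <- config
  output <- match.arg(output)
  fp <- cfg$frap
  tb <- fp$bleach_time_s
  tt <- seq(tb - fp$pre_span_s, tb + fp$post_span_s, by = fp$sampling_s)
  post <- tt >= tb
  y <- rep(fp$F_pre, length(tt))
  truth <- list(config = cfg, model = fp$model)
  if (fp$model == "frap2") {
    pars <- solve_frap_rates(fp)
    p <- frap_params("double", F0 = pars$F0, B1 = pars$B1, B2 = pars$B2,
                     k1 = pars$k1, k2 = pars$k2, F_pre = fp$F_pre)
    y[post] <- frap_model(tt[post] - tb, p)
    truth$params <- p
    truth$half_time_s <- frap_half_time(p)
    truth$mobile_fraction <- mobile_fraction(p)
  } else {
    M <- fp$F0 + (fp$F_pre - fp$F0) * fp$mobile_fraction
    y[post] <- diffusion_model(tt[post] - tb, tau_D = fp$tau_D, M = M,
                               F0 = fp$F0)
    truth$params <- list(tau_D = fp$tau_D, M = M, F0 = fp$F0, w_um = fp$w_um)
    truth$d_eff_um2_s <- effective_diffusion(fp$w_um, fp$tau_D)
  }
  y <- with_seed(cfg$seed, add_noise(y, cfg$noise))
  curve <- kinetics_curve(tt, y, cell_id = "frap_reference",
                          event_times_s = c(bleach = tb))
  if (output == "curve") return(list(curve = curve, truth = truth))

  ## movie mode: uniform nucleus with a focus disk following the curve
  with_seed(cfg$seed + 1L, {
    Y <- cfg$field_size[["Y"]]; X <- cfg$field_size[["X"]]
    g <- coord_grids(Y, X)
    ctr <- c(Y, X) / 2
    nuc <- ellipse_mask(g, ctr[1], ctr[2], cfg$nucleus$axes_px[1],
                        cfg$nucleus$axes_px[2])
    bump <- gauss_bump(g, ctr[1], ctr[2], cfg$focus$sigma_px)
    frames <- vector("list", length(tt))
    for (i in seq_along(tt)) {
      fr <- matrix(cfg$background, Y, X)
      fr[nuc] <- fr[nuc] + cfg$nucleus$intensity
      fr <- fr + cfg$focus$amplitude * y[i] * bump
      frames[[i]] <- list(matrix(add_noise(fr, cfg$noise), Y, X))
    }
    cfg2 <- cfg
    cfg2$frame_interval_s <- fp$sampling_s
    stack <- finalize_stack(frames, cfg2, "ch0")
    stack$origin_t0_s <- tt[1]
    truth$focus_center_yx <- ctr
    list(stack = stack, curve = curve, truth = truth)
  })
}

#' Save a simulated scene (stack + ground-truth events) to disk
#'
#' Writes the TIFF, the session sidecar with event markers, and the
#' ground truth as JSON.
#'
#' @param scene output of a `simulate_*` generator (must contain `stack`).
#' @param path TIFF output path.
#' @return `path`, invisibly.
#' @export
save_scene <- function(scene, path) {
  write_stack(scene$stack, path)
  events <- scene$truth$events %||% list()
  write_session(path, list(events = events,
                           generator = scene$truth$config$preset %||% "custom",
                           seed = scene$truth$config$seed))
  invisible(path)
}
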