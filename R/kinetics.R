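## The results-extractor stage: folder-wide curve collection,
## normalization, alignment, averaging and post-event cropping.
## Pipeline order for event-locked ensembles is fixed:
## crop -> normalize -> average.

#' Construct a per-cell kinetics curve
#'
#' @param t numeric time, seconds, strictly increasing.
#' @param y intensity (arbitrary units), finite, same length as `t`.
#' @param cell_id identifier.
#' @param event_times_s named numeric vector of event markers, seconds
#'   (e.g. `c(irradiation = 25, bleach = 3600)`).
#' @param units y-axis unit label.
#' @return an object of class `"KineticsCurve"`.
#' @export
kinetics_curve <- function(t, y, cell_id = "cell0",
                           event_times_s = numeric(), units = "a.u.") {
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y)) input_error("t and y must have equal length")
  if (length(t) < 1L) input_error("empty curve")
  if (is.unsorted(t, strictly = TRUE)) input_error("t must be strictly increasing")
  if (!all(is.finite(y))) input_error("y must be finite")
  structure(list(cell_id = cell_id, t = t, y = y,
                 event_times_s = event_times_s, units = units),
            class = "KineticsCurve")
}

#' @export
print.KineticsCurve <- function(x, ...) {
  cat(sprintf("<KineticsCurve %s: %d points, t in [%g, %g] s%s>\n",
              x$cell_id, length(x$t), min(x$t), max(x$t),
              if (length(x$event_times_s))
                paste0("; events: ", paste(names(x$event_times_s), "=",
                                           x$event_times_s, collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
plot.KineticsCurve <- function(x, ...) {
  graphics::plot(x$t, x$y, type = "l", xlab = "time (s)",
                 ylab = sprintf("intensity (%s)", x$units),
                 main = x$cell_id, ...)
  if (length(x$event_times_s))
    graphics::abline(v = x$event_times_s, lty = 2, col = "grey40")
  invisible(x)
}

#' Write a kinetics curve as tab-delimited text
#'
#' Events are stored in a `# event:` comment header so a round trip
#' through [load_curves()] preserves them.
#' @param curve a `"KineticsCurve"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cell_id: %s", curve$cell_id), con)
  for (nm in names(curve$event_times_s))
    writeLines(sprintf("# event: %s %.10g", nm, curve$event_times_s[[nm]]), con)
  writeLines("time_s\tintensity", con)
  utils::write.table(data.frame(time_s = curve$t, intensity = curve$y), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Load all per-cell kinetics curves from a folder
#'
#' Reads the package's TSV exports (`*.tsv`); malformed rows are skipped
#' with a warning. Time can be reported in seconds, minutes, hours or
#' frame counts.
#'
#' @param folder directory of TSV files.
#' @param time_unit `"s"`, `"min"`, `"h"` or `"frames"`.
#' @param frame_interval_s needed for `time_unit = "frames"`.
#' @param time_col,y_col column selectors (name or 1-based index) for
#'   generic measurement exports; defaults suit [write_curve_tsv()] and
#'   corrected-total exports.
#' @return a list of `"KineticsCurve"` objects, one per file.
#' @export
load_curves <- function(folder, time_unit = c("s", "min", "h", "frames"),
                        frame_interval_s = NULL,
                        time_col = "time_s", y_col = NULL) {
  time_unit <- match.arg(time_unit)
  files <- sort(list.files(folder, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) input_error("no TSV files found in '%s'", folder)
  curves <- list()
  for (f in files) {
    lines <- readLines(f, warn = FALSE)
    hdr <- grep("^#", lines, value = TRUE)
    cell_id <- sub("^# cell_id:\\s*", "",
                   grep("^# cell_id:", hdr, value = TRUE)[1])
    if (is.na(cell_id)) cell_id <- tools::file_path_sans_ext(basename(f))
    ev_lines <- grep("^# event:", hdr, value = TRUE)
    events <- numeric()
    for (el in ev_lines) {
      parts <- strsplit(sub("^# event:\\s*", "", el), "\\s+")[[1]]
      events[parts[1]] <- as.numeric(parts[2])
    }
    body <- lines[!grepl("^#", lines)]
    tab <- tryCatch(
      utils::read.table(text = body, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE),
      error = function(e) NULL)
    if (is.null(tab) || nrow(tab) == 0L) {
      warning(sprintf("skipping unparsable file '%s'", f))
      next
    }
    tc <- if (is.numeric(time_col)) time_col else match(time_col, names(tab))
    yc <- if (is.null(y_col)) {
      cand <- setdiff(names(tab), names(tab)[tc])
      pref <- intersect(c("intensity", "corrected_total", "mean", "total"), cand)
      match(if (length(pref)) pref[1] else cand[1], names(tab))
    } else if (is.numeric(y_col)) y_col else match(y_col, names(tab))
    if (is.na(tc) || is.na(yc)) {
      warning(sprintf("skipping '%s': missing columns", f))
      next
    }
    tv <- suppressWarnings(as.numeric(tab[[tc]]))
    yv <- suppressWarnings(as.numeric(tab[[yc]]))
    bad <- !is.finite(tv) | !is.finite(yv)
    if (any(bad)) {
      warning(sprintf("skipping %d malformed row(s) in '%s'", sum(bad), f))
      tv <- tv[!bad]; yv <- yv[!bad]
    }
    if (!length(tv)) next
    div <- switch(time_unit, s = 1, min = 60, h = 3600,
                  frames = {
                    if (is.null(frame_interval_s))
                      input_error("time_unit='frames' needs frame_interval_s")
                    frame_interval_s
                  })
    curves[[length(curves) + 1L]] <-
      kinetics_curve(tv / div, yv, cell_id = cell_id,
                     event_times_s = events / div)
  }
  if (!length(curves)) input_error("no parsable curves in '%s'", folder)
  curves
}

#' Normalize a curve to the [0, 1] range
#'
#' `y' = (y - min y) / (max y - min y)`; time and events are unchanged.
#' Decreasing (depletion) curves are normalized by the same rule, with no
#' flipping — the fitted model handles direction.
#'
#' @param curve a `"KineticsCurve"` with `max(y) > min(y)`.
#' @return the normalized `"KineticsCurve"`.
#' @export
normalize01 <- function(curve) {
  rng <- range(curve$y)
  if (rng[2] <= rng[1]) degenerate_error("cannot normalize a constant curve")
  curve$y <- (curve$y - rng[1]) / (rng[2] - rng[1])
  curve$units <- "normalized"
  curve
}

#' Keep only the part of a curve after an event
#'
#' @param curve a `"KineticsCurve"`.
#' @param event event name present in `curve$event_times_s`, or a numeric
#'   time in seconds.
#' @param re_zero if `TRUE`, times are shifted so the event is t = 0.
#' @return the cropped `"KineticsCurve"`.
#' @export
crop_after_event <- function(curve, event, re_zero = TRUE) {
  t_ev <- if (is.numeric(event)) event else {
    if (!(event %in% names(curve$event_times_s)))
      input_error("unknown event '%s'", event)
    curve$event_times_s[[event]]
  }
  if (t_ev < curve$t[1] || t_ev > curve$t[length(curve$t)])
    input_error("event time %g outside curve span [%g, %g]", t_ev,
                curve$t[1], curve$t[length(curve$t)])
  keep <- curve$t >= t_ev
  curve$t <- curve$t[keep]
  curve$y <- curve$y[keep]
  if (re_zero) {
    curve$t <- curve$t - t_ev
    curve$event_times_s <- curve$event_times_s - t_ev
  }
  curve
}

#' Average curves into an ensemble
#'
#' Curves are aligned to a common grid — by default the grid of the
#' shortest curve restricted to the overlap of all time supports, other
#' curves linearly interpolated — then averaged pointwise with the sample
#' standard deviation (n - 1 denominator).
#'
#' @param curves list of at least two `"KineticsCurve"` objects with
#'   overlapping time support.
#' @param grid `"intersection"` (default) or `"union"` (union keeps every
#'   grid point covered by at least two curves).
#' @return an object of class `"Ensemble"`: common `t`, `mean`, `sd`,
#'   `n_per_point`, and the aligned curves.
#' @export
average_curves <- function(curves, grid = c("intersection", "union")) {
  grid <- match.arg(grid)
  if (length(curves) < 2L) input_error("need >= 2 curves")
  lo <- max(vapply(curves, function(cv) cv$t[1], numeric(1)))
  hi <- min(vapply(curves, function(cv) cv$t[length(cv$t)], numeric(1)))
  if (grid == "intersection") {
    if (hi <= lo) input_error("curves have disjoint time supports")
    shortest <- curves[[which.min(vapply(curves, function(cv) length(cv$t),
                                         numeric(1)))]]
    tg <- shortest$t[shortest$t >= lo & shortest$t <= hi]
    if (length(tg) < 2L) input_error("overlapping support too small")
    ys <- vapply(curves, function(cv) stats::approx(cv$t, cv$y, xout = tg)$y,
                 numeric(length(tg)))
  } else {
    tg <- sort(unique(unlist(lapply(curves, `[[`, "t"))))
    ys <- vapply(curves, function(cv)
      stats::approx(cv$t, cv$y, xout = tg, rule = 1)$y, numeric(length(tg)))
    cover <- rowSums(!is.na(ys))
    tg <- tg[cover >= 2L]
    ys <- ys[cover >= 2L, , drop = FALSE]
    if (!length(tg)) input_error("curves have disjoint time supports")
  }
  mu <- rowMeans(ys, na.rm = TRUE)
  sdv <- apply(ys, 1L, stats::sd, na.rm = TRUE)
  n <- rowSums(!is.na(ys))
  structure(list(t = tg, mean = mu, sd = sdv, n_per_point = n,
                 curves = curves), class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("<Ensemble of %d curves on %d grid points, t in [%g, %g] s>\n",
              length(x$curves), length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' @export
plot.Ensemble <- function(x, ...) {
  graphics::plot(x$t, x$mean, type = "l", xlab = "time (s)", ylab = "mean",
                 ylim = range(c(x$mean - x$sd, x$mean + x$sd)), ...)
  graphics::polygon(c(x$t, rev(x$t)), c(x$mean - x$sd, rev(x$mean + x$sd)),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(x$t, x$mean)
  invisible(x)
}

#' Convert an ensemble's mean to a kinetics curve
#' @param ensemble an `"Ensemble"`.
#' @param cell_id identifier for the resulting curve.
#' @return a `"KineticsCurve"` of the ensemble mean.
#' @export
ensemble_mean_curve <- function(ensemble, cell_id = "ensemble_mean") {
  kinetics_curve(ensemble$t, ensemble$mean, cell_id = cell_id)
}

#' Write an ensemble as tab-delimited text (t, mean, sd, n)
#' @param ensemble an `"Ensemble"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  utils::write.table(
    data.frame(time_s = ensemble$t, mean = ensemble$mean, sd = ensemble$sd,
               n = ensemble$n_per_point),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
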