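## Multi-page TIFF I/O and the JSON session sidecar.
##
## Pages are written in (T, C, Z) odometer order with T the slowest axis.
## Calibration and session state (thresholds, ROIs, tracks, events,
## protocol steps) live in a JSON sidecar named <image>.celltool.json next
## to the TIFF. float32 stacks are stored bit-exactly by reinterpreting
## each value's IEEE-754 bit pattern as a 32-bit integer sample; the
## sidecar records the encoding. Standard IEEE float TIFFs produced by
## other tools are read transparently.

#' Path of the JSON session sidecar for an image file
#' @param image_path path to a TIFF file.
#' @return the sidecar path `<image>.celltool.json`.
#' @export
sidecar_path <- function(image_path) {
  paste0(tools::file_path_sans_ext(image_path), ".celltool.json")
}

#' Read the session sidecar of an image
#' @param image_path path to the TIFF (not the sidecar itself).
#' @return a named list (empty if no sidecar exists).
#' @export
read_session <- function(image_path) {
  sp <- sidecar_path(image_path)
  if (!file.exists(sp)) return(list())
  jsonlite::fromJSON(sp, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' Write (merge into) the session sidecar of an image
#'
#' Top-level fields in `session` replace fields of the same name in the
#' existing sidecar; other fields are preserved.
#' @param image_path path to the TIFF.
#' @param session named list of fields to store.
#' @return the sidecar path, invisibly.
#' @export
write_session <- function(image_path, session) {
  cur <- read_session(image_path)
  for (nm in names(session)) cur[[nm]] <- session[[nm]]
  jsonlite::write_json(cur, sidecar_path(image_path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(sidecar_path(image_path))
}

## -- float32 <-> uint32 bit reinterpretation ------------------------------

f32_to_bits <- function(x) {
  raw <- writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
  readBin(raw, "integer", n = length(x), size = 4L, endian = "little")
}

bits_to_f32 <- function(b) {
  raw <- writeBin(as.integer(b), raw(), size = 4L, endian = "little")
  readBin(raw, "numeric", n = length(b), size = 4L, endian = "little")
}

## signed int32 sample value -> [0,1] code for writeTIFF, and back
int32_to_code <- function(b) {
  bu <- ifelse(b < 0, b + 2^32, as.numeric(b))
  (bu + 0.5) / (2^32 - 1)
}

#' Write an image stack as a multi-page TIFF
#'
#' Pages are emitted in `(T, C, Z)` odometer order (T slowest). The
#' calibration metadata, axis sizes and dtype are recorded in the JSON
#' session sidecar so that [read_stack()] restores the stack exactly.
#'
#' @param stack an [image_stack()].
#' @param path output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "ImageStack")) input_error("'stack' must be an ImageStack")
  if (!dir.exists(dirname(path))) io_error("directory '%s' does not exist", dirname(path))
  d <- stack_dim(stack)
  pages <- vector("list", prod(d[1:3]))
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    fr <- stack$pixels[t, ch, z, , , drop = TRUE]
    dim(fr) <- d[4:5]
    pages[[i]] <- switch(stack$dtype,
      uint8   = fr / 255,
      uint16  = fr / 65535,
      float32 = matrix(int32_to_code(f32_to_bits(fr)), d[4], d[5]))
  }
  bits <- switch(stack$dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none"),
    error = function(e) io_error("cannot write TIFF '%s': %s", path, conditionMessage(e)))
  write_session(path, list(
    format_version = 1L,
    dims = as.list(d),
    dtype = stack$dtype,
    float_encoding = if (stack$dtype == "float32") "ieee754-bits-in-uint32" else NULL,
    calibration = list(
      pixel_size_um = stack$pixel_size_um,
      frame_interval_s = stack$frame_interval_s,
      z_step_um = stack$z_step_um,
      channel_names = as.list(stack$channel_names),
      origin_t0_s = stack$origin_t0_s)))
  invisible(path)
}

## map odometer page order given axis letters (first = slowest) and sizes
page_index_map <- function(order_letters, sizes) {
  ## returns a matrix [n_pages x 3] of 1-based (t, c, z) per page
  n <- prod(sizes)
  idx <- matrix(1L, n, 3L, dimnames = list(NULL, c("T", "C", "Z")))
  p <- 0:(n - 1)
  rem <- p
  for (k in seq_along(order_letters)) {
    stride <- if (k < length(order_letters)) prod(sizes[(k + 1):length(sizes)]) else 1L
    idx[, order_letters[k]] <- as.integer(rem %/% stride) + 1L
    rem <- rem %% stride
  }
  idx
}

#' Read a multi-page TIFF time-lapse stack
#'
#' Restores calibration, axis sizes and dtype from the JSON session
#' sidecar when present; otherwise pages are interpreted per
#' `axis_order_hint`/`dims` (default: all pages are time frames) and
#' missing metadata falls back to documented defaults
#' (`pixel_size_um = 1`, `frame_interval_s = 1`).
#'
#' @param path path to a single- or multi-page TIFF.
#' @param axis_order_hint string over letters `T`, `C`, `Z` giving the page
#'   odometer order, slowest axis first (e.g. `"TZC"`). Overrides the sidecar.
#' @param dims named sizes for the hinted axes, e.g. `c(T = 3, Z = 2, C = 1)`.
#'   Required with `axis_order_hint` unless stored in the sidecar.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, axis_order_hint = NULL, dims = NULL) {
  if (!file.exists(path)) input_error("file '%s' does not exist", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) tryCatch(
      tiff::readTIFF(path, all = TRUE, info = TRUE),
      error = function(e2) format_error("'%s' is not a readable TIFF: %s",
                                        path, conditionMessage(e2))))
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    format_error("inconsistent page shapes in '%s'", path)
  yx <- shapes[, 1]

  session <- read_session(path)
  cal <- session$calibration %||% list()
  n_pages <- length(pages)

  sizes <- c(T = n_pages, C = 1L, Z = 1L)
  if (!is.null(session$dims) && is.null(axis_order_hint)) {
    sizes <- c(T = session$dims$T, C = session$dims$C, Z = session$dims$Z)
    order_letters <- c("T", "C", "Z")
  } else if (!is.null(axis_order_hint)) {
    order_letters <- strsplit(toupper(axis_order_hint), "")[[1]]
    if (!setequal(order_letters, c("T", "C", "Z")) || length(order_letters) != 3L)
      input_error("axis_order_hint must be a permutation of 'TCZ'")
    if (is.null(dims)) input_error("'dims' is required with axis_order_hint")
    sizes <- c(T = 1L, C = 1L, Z = 1L)
    sizes[names(dims)] <- as.integer(dims)
    sizes <- sizes[order_letters]          # odometer order for the map
  } else {
    order_letters <- c("T", "C", "Z")
  }
  if (prod(sizes) != n_pages)
    format_error("axis sizes (%s) do not match %d pages",
                 paste(sizes, collapse = "x"), n_pages)

  imap <- page_index_map(if (!is.null(axis_order_hint)) order_letters else c("T", "C", "Z"),
                         sizes)
  tcz <- c(T = max(imap[, "T"]), C = max(imap[, "C"]), Z = max(imap[, "Z"]))

  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  sfmt <- attr(pages[[1]], "sample.format") %||% "uint"
  stored_dtype <- session$dtype
  dtype <- if (!is.null(stored_dtype)) stored_dtype
           else if (identical(sfmt, "float")) "float32"
           else if (bits <= 8) "uint8" else if (bits <= 16) "uint16" else "float32"

  px <- array(0, dim = c(tcz[["T"]], tcz[["C"]], tcz[["Z"]], yx[1], yx[2]))
  decode_bits <- identical(session$float_encoding, "ieee754-bits-in-uint32")
  for (p in seq_len(n_pages)) {
    fr <- pages[[p]]
    if (decode_bits) fr <- matrix(bits_to_f32(as.integer(fr)), yx[1], yx[2])
    px[imap[p, "T"], imap[p, "C"], imap[p, "Z"], , ] <- fr
  }
  image_stack(px, dtype = dtype,
              pixel_size_um = cal$pixel_size_um %||% 1.0,
              frame_interval_s = cal$frame_interval_s %||% 1.0,
              z_step_um = cal$z_step_um,
              channel_names = if (!is.null(cal$channel_names))
                unlist(cal$channel_names) else NULL,
              origin_t0_s = cal$origin_t0_s %||% 0.0)
}

## ---------------------------------------------------------------------------

#' Rearrange an image stack
#'
#' Substacks, crops, channel splitting/merging and Z projection. All pixel
#' ranges are 0-based and half-open.
#'
#' @param stack an [image_stack()] (for `mode = "merge_channels"`, a list
#'   of stacks passed as `stacks`).
#' @param mode one of `"substack"`, `"crop"`, `"split_channels"`,
#'   `"merge_channels"`, `"project"`.
#' @param t,c,z for `"substack"`: 0-based index vectors (default: all).
#' @param y,x for `"crop"`: half-open 0-based ranges `c(from, to)`.
#' @param stacks for `"merge_channels"`: list of stacks agreeing on all
#'   dimensions except C and on calibration.
#' @param axis,reducer for `"project"`: `axis = "Z"` and one of
#'   `"max"`, `"mean"`, `"sum"`. Mean projection yields a float32 stack.
#' @return a new `ImageStack`, or a list of them for `"split_channels"`.
#' @export
rearrange <- function(stack, mode = c("substack", "crop", "split_channels",
                                      "merge_channels", "project"),
                      t = NULL, c = NULL, z = NULL, y = NULL, x = NULL,
                      stacks = NULL, axis = "Z",
                      reducer = c("max", "mean", "sum")) {
  mode <- match.arg(mode)
  if (mode == "merge_channels") {
    stacks <- stacks %||% stack
    if (!is.list(stacks) || length(stacks) < 1L)
      input_error("merge_channels needs a list of stacks")
    ref <- stacks[[1]]
    for (s in stacks[-1]) {
      ds <- stack_dim(s); dr <- stack_dim(ref)
      if (any(ds[c(1, 3, 4, 5)] != dr[c(1, 3, 4, 5)]))
        consistency_error("stacks disagree on non-channel dimensions")
      if (s$pixel_size_um != ref$pixel_size_um ||
          s$frame_interval_s != ref$frame_interval_s ||
          !identical(s$z_step_um, ref$z_step_um) ||
          s$origin_t0_s != ref$origin_t0_s)
        consistency_error("stacks disagree on calibration")
      if (s$dtype != ref$dtype) consistency_error("stacks disagree on dtype")
    }
    px <- do.call(abind_c, lapply(stacks, function(s) s$pixels))
    return(image_stack(px, dtype = ref$dtype,
                       pixel_size_um = ref$pixel_size_um,
                       frame_interval_s = ref$frame_interval_s,
                       z_step_um = ref$z_step_um,
                       channel_names = unlist(lapply(stacks, function(s) s$channel_names)),
                       origin_t0_s = ref$origin_t0_s))
  }

  d <- stack_dim(stack)
  meta <- function(px, dtype = stack$dtype, channel_names = stack$channel_names,
                   origin_t0_s = stack$origin_t0_s)
    image_stack(px, dtype = dtype, pixel_size_um = stack$pixel_size_um,
                frame_interval_s = stack$frame_interval_s,
                z_step_um = stack$z_step_um, channel_names = channel_names,
                origin_t0_s = origin_t0_s)

  switch(mode,
    substack = {
      ti <- (t %||% (seq_len(d[1]) - 1L)) + 1L
      ci <- (c %||% (seq_len(d[2]) - 1L)) + 1L
      zi <- (z %||% (seq_len(d[3]) - 1L)) + 1L
      if (any(ti < 1L | ti > d[1]) || any(ci < 1L | ci > d[2]) ||
          any(zi < 1L | zi > d[3]))
        input_error("substack index out of bounds")
      meta(stack$pixels[ti, ci, zi, , , drop = FALSE],
           channel_names = stack$channel_names[ci],
           origin_t0_s = stack$origin_t0_s +
             (min(ti) - 1) * stack$frame_interval_s)
    },
    crop = {
      if (is.null(y) || is.null(x)) input_error("crop needs 'y' and 'x' ranges")
      if (y[1] < 0 || y[2] > d[4] || x[1] < 0 || x[2] > d[5] ||
          y[2] <= y[1] || x[2] <= x[1])
        input_error("crop rectangle out of bounds")
      meta(stack$pixels[, , , (y[1] + 1):y[2], (x[1] + 1):x[2], drop = FALSE])
    },
    split_channels = {
      lapply(seq_len(d[2]), function(ci)
        meta(stack$pixels[, ci, , , , drop = FALSE],
             channel_names = stack$channel_names[ci]))
    },
    project = {
      if (!identical(axis, "Z")) input_error("projection axis must be 'Z'")
      reducer <- match.arg(reducer)
      px <- array(0, dim = c(d[1], d[2], 1L, d[4], d[5]))
      for (t_ in seq_len(d[1])) for (c_ in seq_len(d[2])) {
        cube <- stack$pixels[t_, c_, , , , drop = TRUE]
        dim(cube) <- c(d[3], d[4], d[5])
        px[t_, c_, 1L, , ] <- switch(reducer,
          max  = apply(cube, c(2, 3), max),
          mean = colMeans(cube, dims = 1),
          sum  = colSums(cube, dims = 1))
      }
      dt <- if (reducer == "mean") "float32"
            else if (reducer == "sum" && stack$dtype != "float32") "float32"
            else stack$dtype
      meta(px, dtype = dt)
    })
}

## bind 5-D arrays along dim 2 (channels)
abind_c <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  ctot <- sum(vapply(arrs, function(a) dim(a)[2], numeric(1)))
  out <- array(0, dim = c(d[1], ctot, d[3], d[4], d[5]))
  at <- 0L
  for (a in arrs) {
    nc <- dim(a)[2]
    out[, at + seq_len(nc), , , ] <- a
    at <- at + nc
  }
  out
}
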