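#' Construct a fluorescence movie
#'
#' A `fluor_movie` is the raw input to every analysis stage: a T x H x W
#' stack of fluorescence intensities (arbitrary units) together with the
#' acquisition metadata needed to interpret it physically.
#'
#' Conventions: frame `k` (1-based in R) was acquired at time
#' `(k - 1) / frame_rate` seconds; pixel `(row, col)` is 1-based; intensities
#' are never rescaled on construction or read.
#'
#' @param frames numeric array with `dim = c(T, H, W)`, `T >= 2`.
#' @param frame_rate acquisition rate in frames per second (Hz), `> 0`.
#' @param pixel_pitch physical size of one pixel in cm, `> 0`.
#' @param modality `"voltage"` (e.g. Fluovolt) or `"calcium"` (e.g. Calbryte).
#' @param recording_id identifier carried through all outputs.
#' @return An object of class `fluor_movie`: a list with elements `frames`,
#'   `frame_rate`, `pixel_pitch`, `modality`, `recording_id`.
#' @seealso [read_movie()], [write_movie()], [extract_trace()]
#' @export
fluor_movie <- function(frames, frame_rate, pixel_pitch,
                        modality = c("voltage", "calcium"),
                        recording_id = "recording") {
  modality <- match.arg(modality)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a 3-D array (T x H x W); got ",
         paste(dim(frames), collapse = "x"))
  if (dim(frames)[1] < 2L)
    stop("not a movie stack: fewer than 2 frames")
  if (!all(is.finite(frames)))
    stop("'frames' contains non-finite intensities")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("'frame_rate' must be a single positive number (Hz)")
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0)
    stop("'pixel_pitch' must be a single positive number (cm/pixel)")
  storage.mode(frames) <- "double"
  structure(list(frames = frames,
                 frame_rate = frame_rate,
                 pixel_pitch = pixel_pitch,
                 modality = modality,
                 recording_id = as.character(recording_id)),
            class = "fluor_movie")
}

#' @export
print.fluor_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<fluor_movie '%s'> %d frames of %dx%d px, %g fps (%.2f s), %g cm/px, %s\n",
    x$recording_id, d[1], d[2], d[3], x$frame_rate, movie_duration(x),
    x$pixel_pitch, x$modality))
  invisible(x)
}

#' Movie duration in seconds
#'
#' @param movie a [fluor_movie()].
#' @return `T / frame_rate`, in seconds.
#' @export
movie_duration <- function(movie) {
  dim(movie$frames)[1] / movie$frame_rate
}

#' Frame acquisition times
#'
#' @param movie a [fluor_movie()].
#' @return numeric vector of length `T`; frame `k` at `(k - 1) / frame_rate` s.
#' @export
movie_times <- function(movie) {
  (seq_len(dim(movie$frames)[1]) - 1) / movie$frame_rate
}

#' Construct a fluorescence trace
#'
#' A `fluor_trace` is a single time series (ROI-averaged or single-pixel)
#' sampled at a fixed rate; it is the unit of all per-beat computation.
#'
#' @param values numeric vector of fluorescence values (a.u.), length >= 2.
#' @param frame_rate sampling rate in Hz, `> 0`.
#' @param modality `"voltage"` or `"calcium"`.
#' @param source `"roi_mean"` or `"pixel"`.
#' @param origin free-text provenance (recording id + ROI/pixel coordinates).
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(values, frame_rate,
                        modality = c("voltage", "calcium"),
                        source = c("roi_mean", "pixel"), origin = "") {
  modality <- match.arg(modality)
  source <- match.arg(source)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("trace must have length >= 2")
  if (!all(is.finite(values))) stop("trace contains non-finite values")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("'frame_rate' must be a single positive number (Hz)")
  structure(list(values = values, frame_rate = frame_rate,
                 modality = modality, source = source,
                 origin = as.character(origin)),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d samples @ %g Hz (%.2f s), %s, %s '%s'\n",
              length(x$values), x$frame_rate,
              length(x$values) / x$frame_rate, x$modality, x$source,
              x$origin))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace a [fluor_trace()].
#' @return numeric vector; sample `k` at `(k - 1) / frame_rate` s.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$values) - 1) / trace$frame_rate
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a fluorescence movie from disk
#'
#' Supported containers are multi-frame grayscale TIFF (with a JSON metadata
#' sidecar written by [write_movie()]) and HDF5 (dataset `"frames"` with
#' attributes `frame_rate`, `pixel_pitch`, `modality`, `recording_id`).
#' Intensities are returned as stored, cast to double, never auto-normalized;
#' any TIFF affine packing recorded in the sidecar is undone exactly.
#'
#' Explicit `frame_rate` / `pixel_pitch` / `modality` arguments override
#' values found in the sidecar or HDF5 attributes; for a bare TIFF with no
#' sidecar they are required.
#'
#' @param path file path.
#' @param format `"tiff"` or `"hdf5"`; default guessed from the extension.
#' @param frame_rate,pixel_pitch,modality,recording_id optional metadata
#'   overrides (see Details).
#' @return a [fluor_movie()].
#' @export
read_movie <- function(path, format = c("auto", "tiff", "hdf5"),
                       frame_rate = NULL, pixel_pitch = NULL,
                       modality = NULL, recording_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.h(df)?5$", path, ignore.case = TRUE)) "hdf5"
              else "tiff"
  }
  meta <- list()
  if (format == "tiff") {
    imgs <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(imgs)) imgs <- list(imgs)
    if (length(imgs) < 2L)
      stop("not a movie stack: '", path, "' holds a single image")
    if (length(dim(imgs[[1]])) != 2L)
      stop("not a grayscale movie stack: frames are not 2-D")
    hw <- dim(imgs[[1L]])
    frames <- array(0, c(length(imgs), hw[1L], hw[2L]))
    for (k in seq_along(imgs)) frames[k, , ] <- imgs[[k]]
    sc <- sidecar_path(path)
    if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    scale <- if (!is.null(meta$scale)) meta$scale else 1
    offset <- if (!is.null(meta$offset)) meta$offset else 0
    frames <- offset + scale * frames
  } else {
    frames <- rhdf5::h5read(path, "frames")
    at <- rhdf5::h5readAttributes(path, "frames")
    meta <- lapply(at, function(a) if (length(a) == 1L) a[[1]] else a)
    if (length(dim(frames)) == 2L)
      stop("not a movie stack: 2-D dataset in '", path, "'")
    if (length(dim(frames)) != 3L)
      stop("'frames' dataset in '", path, "' is not 3-D (T x H x W)")
  }
  pick <- function(arg, key) {
    if (!is.null(arg)) arg
    else if (!is.null(meta[[key]])) meta[[key]]
    else stop("'", key, "' not given and not found in metadata of ", path)
  }
  fluor_movie(frames,
              frame_rate = as.numeric(pick(frame_rate, "frame_rate")),
              pixel_pitch = as.numeric(pick(pixel_pitch, "pixel_pitch")),
              modality = as.character(pick(modality, "modality")),
              recording_id = {
                rid <- recording_id
                if (is.null(rid)) rid <- meta[["recording_id"]]
                if (is.null(rid))
                  rid <- tools::file_path_sans_ext(basename(path))
                rid
              })
}

#' Write a fluorescence movie to disk
#'
#' HDF5 output is a lossless round trip with [read_movie()] (double
#' precision, bit-identical). TIFF output stores 32-bit float samples;
#' because the TIFF float range is defined on \[0, 1\], data outside that
#' range are packed affinely (`stored = (value - offset) / scale`) with
#' `offset`/`scale` recorded in the JSON sidecar and undone on read. Data
#' already in \[0, 1\] are stored verbatim (exact float32 values).
#'
#' @param movie a [fluor_movie()].
#' @param path output file path.
#' @param format `"tiff"` or `"hdf5"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, format = c("auto", "tiff", "hdf5")) {
  stopifnot(inherits(movie, "fluor_movie"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.h(df)?5$", path, ignore.case = TRUE)) "hdf5"
              else "tiff"
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "tiff") {
    rng <- range(movie$frames)
    if (rng[1] >= 0 && rng[2] <= 1) {
      offset <- 0; scale <- 1
    } else {
      offset <- rng[1]
      scale <- max(rng[2] - rng[1], .Machine$double.eps)
    }
    stored <- (movie$frames - offset) / scale
    d <- dim(stored)
    imgs <- lapply(seq_len(d[1]), function(k)
      matrix(stored[k, , ], d[2], d[3]))
    ok <- tiff::writeTIFF(imgs, path, bits.per.sample = 32L,
                          compression = "none")
    if (!isTRUE(ok >= 1)) stop("failed to write TIFF: ", path)
    jsonlite::write_json(
      list(frame_rate = movie$frame_rate, pixel_pitch = movie$pixel_pitch,
           modality = movie$modality, recording_id = movie$recording_id,
           offset = offset, scale = scale),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(movie$frames, path, "frames")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "frames")
    rhdf5::h5writeAttribute(movie$frame_rate, did, "frame_rate")
    rhdf5::h5writeAttribute(movie$pixel_pitch, did, "pixel_pitch")
    rhdf5::h5writeAttribute(movie$modality, did, "modality")
    rhdf5::h5writeAttribute(movie$recording_id, did, "recording_id")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Average a movie over a region of interest
#'
#' @param movie a [fluor_movie()].
#' @param roi `"global"` (whole field), a 2-column integer matrix of
#'   `(row, col)` pixel coordinates (1-based), or a length-4 integer vector
#'   `c(row_min, row_max, col_min, col_max)` describing a rectangle.
#' @return a [fluor_trace()] whose value at frame `t` is the mean over the
#'   ROI of `frames[t, , ]`; metadata is propagated.
#' @export
extract_trace <- function(movie, roi = "global") {
  stopifnot(inherits(movie, "fluor_movie"))
  d <- dim(movie$frames)
  if (identical(roi, "global")) {
    idx <- cbind(rep(seq_len(d[2]), d[3]),
                 rep(seq_len(d[3]), each = d[2]))
    lab <- "global"
  } else if (is.matrix(roi)) {
    if (ncol(roi) != 2L || nrow(roi) < 1L)
      stop("pixel-set ROI must be a non-empty 2-column (row, col) matrix")
    idx <- roi
    lab <- sprintf("pixels[%d]", nrow(roi))
  } else if (is.numeric(roi) && length(roi) == 4L) {
    if (roi[1] > roi[2] || roi[3] > roi[4]) stop("empty rectangle ROI")
    idx <- cbind(rep(roi[1]:roi[2], length(roi[3]:roi[4])),
                 rep(roi[3]:roi[4], each = length(roi[1]:roi[2])))
    lab <- sprintf("rect[%d:%d,%d:%d]", roi[1], roi[2], roi[3], roi[4])
  } else stop("unsupported ROI specification")
  if (any(idx[, 1] < 1 | idx[, 1] > d[2] | idx[, 2] < 1 | idx[, 2] > d[3]))
    stop("ROI out of bounds for ", d[2], "x", d[3], " frame")
  flat <- matrix(movie$frames, nrow = d[1])  # T x (H*W), column-major (h, w)
  cols <- (idx[, 2] - 1L) * d[2] + idx[, 1]
  vals <- if (length(cols) == 1L) flat[, cols]
          else rowMeans(flat[, cols, drop = FALSE])
  fluor_trace(vals, movie$frame_rate, movie$modality,
              source = if (length(cols) == 1L) "pixel" else "roi_mean",
              origin = paste0(movie$recording_id, ":", lab))
}

#' Write a trace to CSV
#'
#' Columns `time_s` and `value`; plain text, readable by any tool.
#'
#' @param trace a [fluor_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(time_s = trace_times(trace),
                              value = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Expects columns `time_s` and `value` (as written by [write_trace_csv()]);
#' the sampling rate is recovered from the median time step.
#'
#' @param path CSV path.
#' @param modality `"voltage"` or `"calcium"`.
#' @param origin provenance string; defaults to the file name.
#' @return a [fluor_trace()].
#' @export
read_trace_csv <- function(path, modality = c("voltage", "calcium"),
                           origin = NULL) {
  modality <- match.arg(modality)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace CSV must have columns 'time_s' and 'value': ", path)
  dt <- stats::median(diff(df$time_s))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from ", path)
  fluor_trace(df$value, 1 / dt, modality, source = "roi_mean",
              origin = if (is.null(origin)) basename(path) else origin)
}
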