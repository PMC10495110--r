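#' Fluorescence time-lapse stack
#'
#' A `Movie` is a 3-D numeric array indexed `[row, col, frame]` (0-based pixel
#' coordinates are used in all user-facing tables; R's 1-based indexing is an
#' internal detail) carrying the acquisition constants needed downstream:
#' the frame interval in seconds and the pixel size in micrometers.
#'
#' @param data numeric 3-D array, `rows x cols x frames`. Intensities are
#'   arbitrary camera units; no normalization is applied.
#' @param frame_interval frame interval in seconds (> 0).
#' @param pixel_size pixel size in micrometers per pixel (> 0).
#' @return an object of class `Movie`.
#' @examples
#' m <- Movie(array(100, c(8, 8, 4)), frame_interval = 0.5, pixel_size = 0.2)
#' n_frames(m)
#' frame_times(m)
#' @export
Movie <- function(data, frame_interval, pixel_size = 1) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(frame_interval), frame_interval > 0,
            is.numeric(pixel_size), pixel_size > 0)
  structure(data,
            frame_interval = as.numeric(frame_interval),
            pixel_size = as.numeric(pixel_size),
            class = c("Movie", "array"))
}

#' @export
print.Movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Movie: %d x %d pixels, %d frames @ %.4g s/frame (%.4g um/px)\n",
              d[1], d[2], d[3], frame_interval(x), pixel_size(x)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @rdname Movie
#' @param x a `Movie`.
#' @export
n_frames <- function(x) dim(x)[3]

#' @rdname Movie
#' @export
frame_interval <- function(x) attr(x, "frame_interval")

#' @rdname Movie
#' @export
pixel_size <- function(x) attr(x, "pixel_size")

#' @rdname Movie
#' @return `frame_times()`: acquisition time of each frame in seconds,
#'   starting at 0.
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1) * frame_interval(x)

#' Convert a time window in seconds to frame indices
#'
#' Frames whose acquisition time t satisfies `start <= t < end` (half-open,
#' matching the convention used for all windows in this package).
#'
#' @param movie a `Movie`.
#' @param window numeric length-2, `(start_s, end_s)`.
#' @return integer vector of frame indices (1-based).
#' @export
window_frames <- function(movie, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  t <- frame_times(movie)
  idx <- which(t >= window[1] & t < window[2])
  if (length(idx) == 0)
    stop("window [", window[1], ", ", window[2], ") s contains no frames")
  idx
}

#' Read a multi-page TIFF stack with its JSON sidecar
#'
#' Reads a grayscale multi-page TIFF as acquired (integer values, no
#' rescaling). Acquisition constants come from a JSON sidecar
#' (`<stem>.json` next to the TIFF, or an explicit path) or from the
#' `frame_interval`/`pixel_size` arguments; one of the two sources is
#' required.
#'
#' @param path path to the TIFF stack.
#' @param sidecar path to the JSON sidecar; defaults to `<stem>.json`.
#' @param frame_interval,pixel_size override/fallback acquisition constants.
#' @return a [Movie]. If the sidecar carries `nh4cl_window_s` it is attached
#'   as attribute `nh4cl_window`.
#' @export
read_stack <- function(path, sidecar = NULL,
                       frame_interval = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged page sizes in ", path)
  meta <- list()
  if (is.null(sidecar)) {
    cand <- paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".json")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar)) {
    if (!file.exists(sidecar)) stop("no such sidecar: ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  fi <- frame_interval %||% meta$frame_interval_s
  ps <- pixel_size %||% meta$pixel_size_um %||% 1
  if (is.null(fi))
    stop("frame interval unknown: supply a sidecar with frame_interval_s ",
         "or the frame_interval argument")
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  m <- Movie(arr, frame_interval = fi, pixel_size = ps)
  if (!is.null(meta$nh4cl_window_s))
    attr(m, "nh4cl_window") <- as.numeric(meta$nh4cl_window_s)
  m
}

#' Write a movie as 16-bit multi-page TIFF plus JSON sidecar
#'
#' Values are clamped to `[0, 65535]` and rounded; the sidecar records the
#' frame interval, pixel size and (optionally) the NH4Cl window so the stack
#' round-trips through [read_stack()] without external metadata.
#'
#' @param movie a [Movie].
#' @param path output TIFF path; the sidecar is written to `<stem>.json`.
#' @param nh4cl_window optional `(start_s, end_s)` recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(movie, path, nh4cl_window = NULL) {
  arr <- pmin(pmax(round(unclass(movie)), 0), 65535)
  pages <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(frame_interval_s = frame_interval(movie),
               pixel_size_um = pixel_size(movie))
  if (!is.null(nh4cl_window)) meta$nh4cl_window_s <- as.numeric(nh4cl_window)
  jsonlite::write_json(meta, paste0(sub("\\.tiff?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
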