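#' Build a kymograph along a neurite path
#'
#' The polyline (soma end first) is resampled at 1-pixel arc-length spacing;
#' at each time point and path position the intensity is aggregated across
#' `line_width` samples taken perpendicular to the path (bilinear
#' interpolation), using the maximum by default — the "wide reslice"
#' convention appropriate for punctate signal.
#'
#' @param movie a [Movie].
#' @param path matrix of 0-based `(row, col)` vertices, >= 2 points, soma
#'   end first.
#' @param line_width number of perpendicular samples (odd).
#' @param aggregate `"max"` (default) or `"mean"` across the line width.
#' @return a `Kymograph`: `image` (time rows x position cols), `pixel_size`,
#'   `frame_interval`, `path`, `line_width`.
#' @export
build_kymograph <- function(movie, path, line_width = 3,
                            aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  path <- as.matrix(path)
  stopifnot(nrow(path) >= 2, ncol(path) == 2, line_width %% 2 == 1)
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (total < 2) stop("path shorter than 2 pixels")
  s <- seq(0, floor(total))                      # 1-px arc-length samples
  cum <- c(0, cumsum(seg_len))
  pts <- matrix(0, length(s), 2)
  tang <- matrix(0, length(s), 2)
  for (i in seq_along(s)) {
    j <- max(which(cum <= s[i] + 1e-9)); j <- min(j, nrow(seg))
    frac <- (s[i] - cum[j]) / seg_len[j]
    pts[i, ] <- path[j, ] + frac * seg[j, ]
    tang[i, ] <- seg[j, ] / seg_len[j]
  }
  normal <- cbind(-tang[, 2], tang[, 1])
  offs <- seq(-(line_width - 1) / 2, (line_width - 1) / 2)
  nfr <- n_frames(movie)
  img <- matrix(0, nfr, length(s))
  samp_r <- outer(pts[, 1], rep(1, length(offs))) +
    outer(normal[, 1], offs)
  samp_c <- outer(pts[, 2], rep(1, length(offs))) +
    outer(normal[, 2], offs)
  for (f in seq_len(nfr)) {
    vals <- bilinear_sample(unclass(movie)[, , f], samp_r, samp_c)
    img[f, ] <- if (aggregate == "max") apply(vals, 1, max)
                else rowMeans(vals)
  }
  structure(list(image = img, pixel_size = pixel_size(movie),
                 frame_interval = frame_interval(movie),
                 path = path, line_width = line_width),
            class = "Kymograph")
}

# bilinear interpolation at 0-based (r, c) positions; outside -> 0
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 0 & ri <= nr - 1 & ci >= 0 & ci <= nc - 1
    out <- array(0, dim(ri))
    out[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
    out
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
}

#' @export
print.Kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d frames x %d path px (%.3g um/px, %.3g s/frame)\n",
              nrow(x$image), ncol(x$image), x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Trace particle trajectories on a kymograph
#'
#' Deterministic tracer: in each time row, candidate particle positions are
#' the intensity-weighted centroids of runs of pixels above
#' `row median + threshold_sd * row SD`; candidates are linked across
#' consecutive rows by greedy nearest-neighbor assignment within `max_step`
#' pixels/frame (ties broken toward the smaller displacement, then the
#' smaller position index); tracks shorter than `min_duration` rows are
#' discarded.
#'
#' @param kymo a [build_kymograph()] result.
#' @param threshold_sd detection threshold in row SDs.
#' @param max_step maximum frame-to-frame displacement, pixels.
#' @param min_duration minimum track length, frames.
#' @return data frame `(track_id, frame, position_px)` with 1-based frames
#'   and 0-based positions; zero rows for a blank kymograph.
#' @export
trace_tracks <- function(kymo, threshold_sd = 3, max_step = 15,
                         min_duration = 5) {
  stopifnot(inherits(kymo, "Kymograph"), all(is.finite(kymo$image)))
  img <- kymo$image
  cand <- vector("list", nrow(img))
  for (f in seq_len(nrow(img))) {
    v <- img[f, ]
    thr <- stats::median(v) + threshold_sd * stats::sd(v)
    if (!is.finite(thr)) thr <- Inf
    above <- v > thr
    if (!any(above)) { cand[[f]] <- numeric(); next }
    runs <- rle(above)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    pos <- numeric()
    for (j in which(runs$values)) {
      idx <- starts[j]:ends[j]
      pos <- c(pos, sum((idx - 1) * v[idx]) / sum(v[idx]))
    }
    cand[[f]] <- pos
  }
  # greedy frame-to-frame linking
  tracks <- list()      # each: list(frames, positions, open)
  active <- integer()   # indices into `tracks`
  for (f in seq_len(nrow(img))) {
    pos <- cand[[f]]
    last <- vapply(active, function(i) tail_num(tracks[[i]]$positions),
                   numeric(1))
    used_c <- rep(FALSE, length(pos))
    used_t <- rep(FALSE, length(active))
    if (length(pos) && length(active)) {
      d <- abs(outer(last, pos, "-"))
      repeat {
        d_open <- d
        d_open[used_t, ] <- Inf
        d_open[, used_c] <- Inf
        if (all(!is.finite(d_open)) || min(d_open) > max_step) break
        hit <- which(d_open == min(d_open), arr.ind = TRUE)
        hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE][1, ]
        ti <- active[hit[1]]; ci <- hit[2]
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
        tracks[[ti]]$positions <- c(tracks[[ti]]$positions, pos[ci])
        used_t[hit[1]] <- TRUE; used_c[ci] <- TRUE
      }
    }
    active <- active[used_t]                       # unmatched tracks close
    for (ci in which(!used_c)) {                   # unmatched candidates open
      tracks[[length(tracks) + 1]] <- list(frames = f, positions = pos[ci])
      active <- c(active, length(tracks))
    }
    if (length(pos) == 0) active <- integer()
  }
  keep <- Filter(function(tr) length(tr$frames) >= min_duration, tracks)
  if (!length(keep))
    return(data.frame(track_id = integer(), frame = integer(),
                      position_px = numeric()))
  do.call(rbind, lapply(seq_along(keep), function(i)
    data.frame(track_id = i, frame = keep[[i]]$frames,
               position_px = keep[[i]]$positions)))
}

tail_num <- function(x) x[length(x)]

#' Classify traced tracks by direction and speed
#'
#' Net displacement is `(last - first position) * pixel_size`, signed with
#' the path orientation (soma at position 0, so positive = anterograde).
#' Tracks with `|net| < stationary_threshold` are stationary; speed is
#' `|net| / duration` for moving tracks and 0 for stationary ones.
#'
#' @param track_points data frame from [trace_tracks()].
#' @param kymo the [build_kymograph()] the tracks came from (supplies pixel
#'   size and frame interval).
#' @param stationary_threshold micrometers of net displacement below which a
#'   track is called stationary.
#' @return list with `tracks` (per-track `track_id`, `n_frames`,
#'   `net_displacement_um`, `duration_s`, `speed_um_s`, `direction`) and
#'   direction `fractions_moving` (over moving tracks) and `fractions_all`;
#'   both `NULL` when there are no tracks.
#' @export
classify_tracks <- function(track_points, kymo, stationary_threshold = 2) {
  stopifnot(inherits(kymo, "Kymograph"))
  if (nrow(track_points) == 0)
    return(list(tracks = data.frame(), fractions_moving = NULL,
                fractions_all = NULL))
  sp <- split(track_points, track_points$track_id)
  tr <- do.call(rbind, lapply(sp, function(d) {
    net <- (tail_num(d$position_px) - d$position_px[1]) * kymo$pixel_size
    dur <- (tail_num(d$frame) - d$frame[1]) * kymo$frame_interval
    data.frame(track_id = d$track_id[1], n_frames = nrow(d),
               net_displacement_um = net, duration_s = dur)
  }))
  rownames(tr) <- NULL
  tr$direction <- ifelse(abs(tr$net_displacement_um) < stationary_threshold,
                         "stationary",
                         ifelse(tr$net_displacement_um > 0,
                                "anterograde", "retrograde"))
  tr$speed_um_s <- ifelse(tr$direction == "stationary", 0,
                          abs(tr$net_displacement_um) / tr$duration_s)
  lv <- c("anterograde", "retrograde", "stationary")
  all_n <- table(factor(tr$direction, levels = lv))
  mov <- tr$direction != "stationary"
  list(tracks = tr,
       fractions_moving = if (any(mov))
         prop.table(table(factor(tr$direction[mov], levels = lv[1:2])))
       else NULL,
       fractions_all = prop.table(all_n))
}
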