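#' Count the NH4Cl-dequenched vesicle pool
#'
#' The pool image is the mean of the NH4Cl frames minus the mean of the
#' pre-pulse frames, which isolates vesicles made visible by the dequench
#' from already-bright surface signal. The difference image is band-pass
#' filtered with a difference of Gaussians, binarized at
#' `background mean + threshold_sd * SD` (background = pixels at or below
#' the filtered image's median), and 8-connected components with area inside
#' `area_range` are counted as puncta.
#'
#' @param movie a [Movie].
#' @param nh4cl_window `(start_s, end_s)` of the ammonium pulse.
#' @param pre_window `(start_s, end_s)` of the pre-pulse reference segment;
#'   must not overlap the pulse.
#' @param dog_sigmas `(narrow, wide)` Gaussian sigmas of the band-pass,
#'   pixels.
#' @param threshold_sd binarization threshold in background SDs.
#' @param area_range `(min, max)` component area, pixels.
#' @return a `PoolEstimate`: `raw_count`, `components` (`component_id`,
#'   0-based centroid `row`/`col`, `area_px`), `single_punctum_area` and
#'   `corrected_count` (both `NA` until [corrected_pool_count()]), and the
#'   `nh4cl_image` used.
#' @export
detect_puncta <- function(movie, nh4cl_window, pre_window,
                          dog_sigmas = c(1, 3), threshold_sd = 4,
                          area_range = c(4, 400)) {
  stopifnot(length(dog_sigmas) == 2, dog_sigmas[1] < dog_sigmas[2])
  if (max(pre_window[1], nh4cl_window[1]) <
      min(pre_window[2], nh4cl_window[2]))
    stop("pre_window overlaps nh4cl_window")
  nh_idx <- window_frames(movie, nh4cl_window)
  pre_idx <- window_frames(movie, pre_window)
  img <- apply(unclass(movie)[, , nh_idx, drop = FALSE], c(1, 2), mean) -
    apply(unclass(movie)[, , pre_idx, drop = FALSE], c(1, 2), mean)
  dog <- EBImage::gblur(img, sigma = dog_sigmas[1]) -
    EBImage::gblur(img, sigma = dog_sigmas[2])
  bg <- dog[dog <= stats::median(dog)]
  sd_bg <- stats::sd(bg)
  if (!is.finite(sd_bg)) sd_bg <- 0
  thr <- mean(bg) + threshold_sd * sd_bg
  lab <- label_components_8(dog > thr)
  comp <- component_table(lab)
  comp <- comp[comp$area_px >= area_range[1] & comp$area_px <= area_range[2],
               , drop = FALSE]
  comp$component_id <- seq_len(nrow(comp))
  rownames(comp) <- NULL
  structure(list(raw_count = nrow(comp), components = comp,
                 single_punctum_area = NA_real_,
                 corrected_count = NA_integer_, nh4cl_image = img),
            class = "PoolEstimate")
}

#' Overlap-corrected pool count
#'
#' Fluorescent puncta that touch are counted as one connected component;
#' the correction divides each component's area by the typical area of an
#' isolated punctum. The single-punctum area is the median area of
#' components that look solitary (area <= 1.5 x the median of all areas);
#' each component then contributes `max(1, round(area / single_area))`
#' puncta, and the corrected count is the sum of contributions.
#'
#' @param estimate a [detect_puncta()] result.
#' @return the estimate with `single_punctum_area`, per-component
#'   `contribution` and `corrected_count` filled in. A zero raw count yields
#'   a corrected count of zero.
#' @export
corrected_pool_count <- function(estimate) {
  stopifnot(inherits(estimate, "PoolEstimate"))
  if (estimate$raw_count == 0) {
    estimate$corrected_count <- 0L
    return(estimate)
  }
  areas <- estimate$components$area_px
  med <- stats::median(areas)
  singles <- areas[areas <= 1.5 * med]
  spa <- stats::median(singles)
  contrib <- pmax(1, round(areas / spa))
  estimate$single_punctum_area <- spa
  estimate$components$contribution <- as.integer(contrib)
  estimate$corrected_count <- as.integer(sum(contrib))
  estimate
}

#' @export
print.PoolEstimate <- function(x, ...) {
  cat(sprintf("PoolEstimate: %d raw components", x$raw_count))
  if (!is.na(x$corrected_count))
    cat(sprintf(", %d after overlap correction (single-punctum area %.1f px)",
                x$corrected_count, x$single_punctum_area))
  cat("\n")
  invisible(x)
}

#' Released fraction of the vesicle pool
#'
#' The number of fusion events per neuron divided by its intracellular pool
#' of labeled vesicles.
#'
#' @param n_events fusion events counted in the neuron.
#' @param pool (overlap-corrected) intracellular pool count; must be > 0.
#' @return a `ReleasedFraction` list: `n_events`, `pool`, `fraction`.
#'   Fractions above 1 are permitted (pool undercount) with a warning.
#' @examples
#' released_fraction(8, 100)$fraction   # 0.08
#' @export
released_fraction <- function(n_events, pool) {
  stopifnot(n_events >= 0)
  if (pool <= 0) stop("pool must be positive")
  f <- n_events / pool
  if (f > 1) warning("released fraction > 1: pool likely undercounted")
  structure(list(n_events = n_events, pool = pool, fraction = f),
            class = "ReleasedFraction")
}

# --- 8-connected component labeling -----------------------------------------
# EBImage::bwlabel is 4-connected; the counting convention here is
# 8-connectivity, so 4-connected labels are merged across diagonal contacts
# with a union-find pass over the label graph.

label_components_8 <- function(mask) {
  mask <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (off in list(c(1, 1), c(1, -1))) {  # diagonal neighbor offsets
    a <- lab[seq_len(nr - 1), , drop = FALSE]
    b <- lab[seq_len(nr - 1) + 1, , drop = FALSE]
    if (off[2] == 1) {
      a <- a[, seq_len(nc - 1), drop = FALSE]
      b <- b[, seq_len(nc - 1) + 1, drop = FALSE]
    } else {
      a <- a[, seq_len(nc - 1) + 1, drop = FALSE]
      b <- b[, seq_len(nc - 1), drop = FALSE]
    }
    touch <- a > 0 & b > 0 & a != b
    if (any(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (k in seq_len(nrow(pairs))) union(pairs[k, 1], pairs[k, 2])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nr, nc)
  pos <- lab > 0
  out[pos] <- relab[lab[pos]]
  out
}

component_table <- function(lab) {
  if (max(lab) == 0)
    return(data.frame(component_id = integer(), row = numeric(),
                      col = numeric(), area_px = numeric()))
  idx <- which(lab > 0, arr.ind = TRUE)
  id <- lab[lab > 0]
  area <- tabulate(id)
  data.frame(component_id = seq_along(area),
             row = tapply(idx[, 1], id, mean) - 1,
             col = tapply(idx[, 2], id, mean) - 1,
             area_px = area)
}
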