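# Independent brute-force oracles, deliberately written without reusing the
# package's internals.

# median-of-3 by explicit sorting (ends copied, as in a running median)
median3 <- function(x) {
  n <- length(x)
  out <- x
  for (i in 2:(n - 1)) out[i] <- sort(c(x[i - 1], x[i], x[i + 1]))[2]
  out
}

# frame-by-frame scan applying the event criteria literally: baseline stats
# on raw R, threshold runs on the median-3 trace, onset = last raw frame at
# or below mu + sd before the run, local pre-run floor for the amplitude,
# rise accepted up to max_rise inclusive
brute_force_events <- function(R, dt, baseline_idx, threshold_sd = 2,
                               max_rise = 1, sigma_floor = 0.01) {
  mu <- mean(R[baseline_idx])
  s <- max(sd(R[baseline_idx]), sigma_floor)
  Rf <- median3(R)
  thr <- mu + threshold_sd * s
  events <- NULL
  i <- 1
  while (i <= length(R)) {
    if (Rf[i] > thr) {
      j <- i
      while (j < length(R) && Rf[j + 1] > thr) j <- j + 1
      peak <- i - 1 + which.max(Rf[i:j])
      onset <- NA
      for (k in seq_len(i - 1)) if (R[k] <= mu + s) onset <- k
      if (is.na(onset)) onset <- i
      loc <- if (i > 1) median(R[max(1, i - 5):(i - 1)]) else mu
      rise <- (peak - onset) * dt
      if (Rf[peak] - max(mu, loc) >= threshold_sd * s && rise <= max_rise)
        events <- rbind(events, c(onset = onset, peak = peak, rise = rise))
      i <- j + 1
    } else i <- i + 1
  }
  events
}

# trace with a clean baseline, one injected rectangular excursion
make_step_trace <- function(level = 2, rise_frames = 1, hold_frames = 4,
                            onset_frame = 80, n = 240, dt = 0.5,
                            noise_sd = 0.05, seed = 42) {
  set.seed(seed)
  R <- 1 + rnorm(n, 0, noise_sd)
  ramp <- seq(1, level, length.out = rise_frames + 1)[-1]
  idx <- onset_frame + seq_along(ramp)
  R[idx] <- ramp
  R[(max(idx) + 1):(max(idx) + hold_frames)] <- level
  structure(list(center = c(0, 0), roi_size = 3, F = R, F0 = 1, R = R,
                 frame_interval = dt), class = "RoiTrace")
}

# minimal nested data: one unit per replicate with the given value
nested_df <- function(a_reps, b_reps) {
  rbind(
    do.call(rbind, lapply(seq_along(a_reps), function(r)
      data.frame(group = "a", replicate = r, unit = 1, value = a_reps[r]))),
    do.call(rbind, lapply(seq_along(b_reps), function(r)
      data.frame(group = "b", replicate = r, unit = 1, value = b_reps[r]))))
}

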