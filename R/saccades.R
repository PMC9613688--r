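#' Detect saccades in a gaze trace
#'
#' Velocity-threshold detection: gaze velocity is estimated by central
#' differences and lightly smoothed (moving average over `smooth` samples),
#' contiguous intervals of supra-threshold speed lasting at least
#' `min_duration` become candidate events, and onsets/offsets are refined to
#' the interpolated threshold crossing. Events whose horizontal displacement
#' is below `min_amplitude` (default 1 degree) are discarded as non-saccadic
#' (saccadic intrusions and noise), following the +/-1 degree rule.
#'
#' Invalid samples are linearly interpolated across gaps up to `max_gap`
#' seconds; longer gaps break the trace and no event can span them.
#'
#' @param trace A `gaze_trace` (tibble with `t`, `gaze_h`, `gaze_v`,
#'   optionally `valid`), uniformly sampled.
#' @param velocity_threshold Speed threshold in deg/s (> 0). Default 30.
#' @param min_duration Minimum event duration in seconds. Default 0.010.
#' @param min_amplitude Minimum absolute horizontal amplitude in degrees.
#'   Default 1 (the non-saccadic exclusion rule).
#' @param smooth Moving-average window (samples) applied to the velocity
#'   estimate; odd lengths are symmetric (zero phase); 1 disables smoothing.
#'   Default 3.
#' @param max_gap Longest invalid gap (s) bridged by interpolation.
#' @return A tibble of class `saccade_events` with columns `t_onset`,
#'   `t_offset`, `duration`, `amplitude` (signed deg, + = right),
#'   `peak_speed` (deg/s), `direction` (`"left"`/`"right"`), sorted by onset.
#' @examples
#' sch <- build_schedule("2D-P", seed = 1)
#' sim <- simulate_gaze(sch, subject_model(), seed = 1)
#' detect_saccades(sim$trace)
#' @export
detect_saccades <- function(trace, velocity_threshold = 30,
                            min_duration = 0.010, min_amplitude = 1.0,
                            smooth = 3, max_gap = 0.1) {
  if (velocity_threshold <= 0) abort("`velocity_threshold` must be > 0.")
  empty <- tibble::tibble(t_onset = numeric(), t_offset = numeric(),
                          duration = numeric(), amplitude = numeric(),
                          peak_speed = numeric(), direction = character())
  class(empty) <- c("saccade_events", class(empty))
  n <- nrow(trace)
  if (n < 3) return(empty)
  dt <- check_uniform_time(trace$t)
  valid <- if ("valid" %in% names(trace)) trace$valid else rep(TRUE, n)
  if (!any(valid)) return(empty)

  gh <- fill_gaps(trace$t, trace$gaze_h, valid, max_gap)
  gv <- if ("gaze_v" %in% names(trace)) {
    fill_gaps(trace$t, trace$gaze_v, valid, max_gap)
  } else numeric(n)

  vh <- central_diff(gh, dt)
  vv <- central_diff(gv, dt)
  if (smooth > 1) {
    vh <- moving_average(vh, smooth)
    vv <- moving_average(vv, smooth)
  }
  speed <- sqrt(vh^2 + vv^2)
  above <- !is.na(speed) & speed >= velocity_threshold

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * dt >= min_duration)
  if (!any(keep)) return(empty)

  events <- purrr::map_dfr(which(keep), function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    # refine boundaries to the interpolated threshold crossing
    t_on <- trace$t[i0]
    if (i0 > 1 && !is.na(speed[i0 - 1]) && speed[i0 - 1] < velocity_threshold) {
      frac <- (velocity_threshold - speed[i0 - 1]) /
        (speed[i0] - speed[i0 - 1])
      t_on <- trace$t[i0 - 1] + frac * dt
    }
    # second stage: position-based onset; the interpolated crossing of a
    # 0.5 degree departure from the pre-saccadic baseline is far less
    # noise-sensitive than the velocity crossing at typical amplitudes
    ib0 <- max(i0 - 6L, 1L)
    if (ib0 < i0) {
      b <- median(gh[ib0:(i0 - 1L)], na.rm = TRUE)
      sgn <- if (!is.na(gh[min(i1 + 1L, n)]) &&
                 gh[min(i1 + 1L, n)] >= b) 1 else -1
      disp <- (gh[max(i0 - 2L, 1L):min(i1 + 1L, n)] - b) * sgn
      jx <- which(disp >= 0.5)
      if (length(jx) && jx[1] > 1 && !anyNA(disp[jx[1] - 1:0])) {
        j1 <- max(i0 - 2L, 1L) + jx[1] - 1L
        frac <- (0.5 - disp[jx[1] - 1]) / (disp[jx[1]] - disp[jx[1] - 1])
        t_pos <- trace$t[j1 - 1L] + frac * dt
        if (abs(t_pos - t_on) <= 3 * dt) t_on <- t_pos
      }
    }
    t_off <- trace$t[i1]
    if (i1 < n && !is.na(speed[i1 + 1]) && speed[i1 + 1] < velocity_threshold) {
      frac <- (speed[i1] - velocity_threshold) /
        (speed[i1] - speed[i1 + 1])
      t_off <- trace$t[i1] + frac * dt
    }
    # amplitude from short averages just outside the event, damping noise
    ia <- max(i0 - 1L, 1L)
    ib <- min(i1 + 1L, n)
    amp <- mean(gh[max(ia - 1L, 1L):ia], na.rm = TRUE) * -1 +
      mean(gh[ib:min(ib + 1L, n)], na.rm = TRUE)
    tibble::tibble(
      t_onset = t_on, t_offset = t_off, duration = t_off - t_on,
      amplitude = amp,
      peak_speed = max(speed[i0:i1]),
      direction = ifelse(amp >= 0, "right", "left")
    )
  })
  events <- events[!is.na(events$amplitude) &
                     abs(events$amplitude) >= min_amplitude, ]
  events <- events[order(events$t_onset), ]
  class(events) <- c("saccade_events", class(events))
  events
}

check_uniform_time <- function(t) {
  d <- diff(t)
  dt <- median(d)
  if (dt <= 0 || any(abs(d - dt) > 1e-6 + 1e-4 * dt)) {
    abort("Trace timestamps must be uniform and strictly increasing.")
  }
  dt
}

fill_gaps <- function(t, x, valid, max_gap) {
  x[!valid] <- NA_real_
  if (!anyNA(x)) return(x)
  ok <- !is.na(x)
  if (sum(ok) < 2) return(x)
  filled <- approx(t[ok], x[ok], xout = t, rule = 1)$y
  # re-open gaps longer than max_gap
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- t[2] - t[1]
  for (j in which(r$values & r$lengths * dt > max_gap)) {
    filled[starts[j]:ends[j]] <- NA_real_
  }
  filled
}

central_diff <- function(x, dt) {
  n <- length(x)
  v <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
  v
}

moving_average <- function(x, k) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}
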