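#' Gaze-duration target selection
#'
#' Determines which lateral target the observer selected during a response
#' window by comparing total dwell time of horizontal gaze inside the left
#' and right regions of interest; the side with the strictly longest dwell
#' wins. Used as the authoritative correctness rule in the
#' visuospatial-memory and spatial-orientation tasks.
#'
#' @param trace A `gaze_trace`.
#' @param window Numeric length-2 interval `c(start, end)` in seconds,
#'   within the trace span.
#' @param left_roi,right_roi Length-2 gaze-angle intervals in degrees
#'   defining the regions of interest; must not overlap. Defaults bracket
#'   the +/-8 degree targets with a +/-3 degree half-width.
#' @return One-row tibble: `side` (`"left"`, `"right"`, `"none"`),
#'   `dwell_left`, `dwell_right` (s), `tie` (`TRUE` when both dwells are
#'   equal and nonzero).
#' @examples
#' sch <- build_schedule("VM-P", seed = 2)
#' sim <- simulate_gaze(sch, subject_model(), seed = 2)
#' gaze_duration_target(sim$trace, c(7.5, 10))
#' @export
gaze_duration_target <- function(trace, window,
                                 left_roi = c(-11, -5),
                                 right_roi = c(5, 11)) {
  stopifnot(length(window) == 2, window[2] > window[1])
  if (max(left_roi) > min(right_roi) && max(right_roi) > min(left_roi)) {
    abort("`left_roi` and `right_roi` must not overlap.")
  }
  dt <- check_uniform_time(trace$t)
  if (window[1] < min(trace$t) - 1e-9 ||
      window[2] > max(trace$t) + dt + 1e-9) {
    abort("`window` must lie within the trace span.")
  }
  sel <- trace$t >= window[1] & trace$t < window[2]
  gh <- trace$gaze_h[sel]
  if ("valid" %in% names(trace)) gh[!trace$valid[sel]] <- NA_real_
  dwell_left <- sum(gh >= left_roi[1] & gh <= left_roi[2], na.rm = TRUE) * dt
  dwell_right <- sum(gh >= right_roi[1] & gh <= right_roi[2], na.rm = TRUE) * dt
  tie <- dwell_left == dwell_right && dwell_left > 0
  side <- if (dwell_left == 0 && dwell_right == 0) "none"
          else if (tie) "none"
          else if (dwell_left > dwell_right) "left" else "right"
  tibble::tibble(side = side, dwell_left = dwell_left,
                 dwell_right = dwell_right, tie = tie)
}

#' Score every recorded trial of a session
#'
#' Segments a gaze trace by the schedule's response windows and scores each
#' trial. Latency is the onset of the first detected saccade after the
#' response-frame onset; saccades earlier than `anticipation_floor` mark the
#' trial invalid (`anticipatory`), a window without any qualifying saccade is
#' invalid (`no_saccade`), and an invalid-sample gap longer than `max_gap`
#' inside the window is invalid (`data_gap`). Correctness in 2D/3D tasks is
#' the sign match between the scoring saccade's direction and the expected
#' direction (an initial wrong-direction saccade counts as an error even if
#' corrected later); in VM/SO tasks the gaze-duration rule
#' ([gaze_duration_target()]) is authoritative and the first-saccade
#' direction is recorded alongside.
#'
#' @param trace A `gaze_trace`.
#' @param schedule The `stimulus_schedule` the trace was recorded under
#'   (pro- or anti-saccade task).
#' @param saccades Optional precomputed [detect_saccades()] result; detected
#'   from `trace` when `NULL`.
#' @param recorded_only Score only non-practice trials (default `TRUE`).
#' @param anticipation_floor Seconds; earlier saccades are anticipatory.
#' @param roi_halfwidth Degrees; dwell regions are the target eccentricity
#'   +/- this half-width.
#' @param max_gap Seconds of invalid data tolerated inside a window.
#' @param ... Passed to [detect_saccades()] when `saccades` is `NULL`.
#' @return Tibble of class `trial_scores`, one row per trial: `trial`,
#'   `t_response`, `expected`, `latency`, `peak_speed`, `amplitude`,
#'   `direction`, `dwell_side`, `dwell_tie`, `correct`, `valid`, `reason`
#'   (`ok`, `no_saccade`, `anticipatory`, `data_gap`).
#' @examples
#' sch <- build_schedule("2D-P", seed = 1)
#' sim <- simulate_gaze(sch, subject_model(), seed = 1)
#' score_trials(sim$trace, sch)
#' @export
score_trials <- function(trace, schedule, saccades = NULL,
                         recorded_only = TRUE, anticipation_floor = 0.08,
                         roi_halfwidth = 3, max_gap = 0.1, ...) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (!schedule$condition$oculomotor_task %in% c("pro", "anti")) {
    abort("Scoring requires a pro- or anti-saccade condition.")
  }
  if (is.null(saccades)) saccades <- detect_saccades(trace, max_gap = max_gap, ...)
  resp <- response_events(schedule, recorded_only = recorded_only)
  dt <- check_uniform_time(trace$t)
  use_dwell <- schedule$condition$environment %in% c("VM", "SO")
  valid_col <- if ("valid" %in% names(trace)) trace$valid else rep(TRUE, nrow(trace))

  purrr::map_dfr(seq_len(nrow(resp)), function(i) {
    t0 <- resp$t_onset[i]
    t1 <- t0 + resp$duration[i]
    expected <- resp$expected[i]
    row <- tibble::tibble(
      trial = resp$trial[i], t_response = t0, expected = expected,
      latency = NA_real_, peak_speed = NA_real_, amplitude = NA_real_,
      direction = NA_character_, dwell_side = NA_character_,
      dwell_tie = NA, correct = NA, valid = FALSE, reason = "no_saccade"
    )
    in_win <- trace$t >= t0 & trace$t < t1
    gap_run <- rle(!valid_col[in_win])
    if (any(gap_run$values & gap_run$lengths * dt > max_gap)) {
      row$reason <- "data_gap"
      return(row)
    }
    sac <- saccades[saccades$t_onset >= t0 & saccades$t_onset < t1, ]
    if (nrow(sac) == 0) return(row)
    s <- sac[1, ]
    lat <- s$t_onset - t0
    row$latency <- lat
    row$peak_speed <- s$peak_speed
    row$amplitude <- s$amplitude
    row$direction <- s$direction
    if (lat < anticipation_floor) {
      row$reason <- "anticipatory"
      return(row)
    }
    if (use_dwell) {
      ecc <- resp$eccentricity[i]
      dw <- gaze_duration_target(
        trace, c(t0, min(t1, max(trace$t))),
        left_roi = c(-ecc - roi_halfwidth, -ecc + roi_halfwidth),
        right_roi = c(ecc - roi_halfwidth, ecc + roi_halfwidth)
      )
      row$dwell_side <- dw$side
      row$dwell_tie <- dw$tie
      row$correct <- identical(dw$side, expected)
    } else {
      row$correct <- s$direction == expected
    }
    row$valid <- TRUE
    row$reason <- "ok"
    row
  }) -> scores
  class(scores) <- c("trial_scores", class(scores))
  scores
}

#' Aggregate trial scores into condition-level oculometrics
#'
#' Means and sample SDs (n-1 denominator) of latency and peak speed over
#' valid trials, plus the error rate. By default the error-rate denominator
#' is the number of valid trials (`denominator = "valid"`); `"all"` divides
#' by all scored trials instead.
#'
#' @param scores A `trial_scores` tibble from [score_trials()].
#' @param denominator `"valid"` (default) or `"all"`.
#' @return One-row tibble: `latency_mean`, `latency_sd`, `peak_speed_mean`,
#'   `peak_speed_sd`, `error_rate`, `n_valid`, `n_trials`, `degenerate`
#'   (`TRUE` when there are no valid trials and the summary is undefined).
#' @examples
#' sch <- build_schedule("2D-P", seed = 1)
#' sim <- simulate_gaze(sch, subject_model(), seed = 1)
#' aggregate_condition(score_trials(sim$trace, sch))
#' @export
aggregate_condition <- function(scores, denominator = c("valid", "all")) {
  denominator <- match.arg(denominator)
  ok <- scores[scores$valid, ]
  n_valid <- nrow(ok)
  if (n_valid == 0) {
    return(tibble::tibble(
      latency_mean = NA_real_, latency_sd = NA_real_,
      peak_speed_mean = NA_real_, peak_speed_sd = NA_real_,
      error_rate = NA_real_, n_valid = 0L, n_trials = nrow(scores),
      degenerate = TRUE
    ))
  }
  denom <- if (denominator == "valid") n_valid else nrow(scores)
  tibble::tibble(
    latency_mean = mean(ok$latency),
    latency_sd = if (n_valid >= 2) sd(ok$latency) else NA_real_,
    peak_speed_mean = mean(ok$peak_speed),
    peak_speed_sd = if (n_valid >= 2) sd(ok$peak_speed) else NA_real_,
    error_rate = sum(!ok$correct) / denom,
    n_valid = n_valid, n_trials = nrow(scores),
    degenerate = FALSE
  )
}
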