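#' Stimulus-schedule construction
#'
#' Builds the deterministic, seedable event sequence for one experimental
#' condition. Each environment has a fixed cycle structure:
#'
#' * **2D / 3D** (2 s cycles): 1 s central fixation, then a red target at
#'   +/-8 degrees for the 1 s response window. 10 practice + 30 recorded
#'   trials (80 s total).
#' * **SO** (7.5 s cycles): 2.5 s fixation, 2.5 s combined egocentric /
#'   allocentric view (circle and square markers at +/-2 degrees in the inner
#'   map), 2.5 s response window with the egocentric goal at +/-8 degrees.
#'   5 practice + 15 recorded trials.
#' * **VM** (10 s cycles): 2.5 s fixation, 2.5 s memorise frame with two
#'   distinct red symbols at +2 and -2 degrees, 2.5 s fixation, 2.5 s
#'   response window in which one memorised symbol reappears at +/-8 degrees.
#'   5 practice + 15 recorded trials.
#'
#' Left and right goals are assigned by a seeded permutation of a balanced
#' multiset, with no more than `max_run` consecutive same sides. When the
#' recorded count is odd (VM/SO: 15) the recorded split is ceiling/floor with
#' a seed-determined majority side and the practice trials take the opposite
#' extra, so the schedule as a whole is exactly balanced. Posture recording
#' starts at the end of the last practice cycle; participants are unaware of
#' the boundary, so the event stream is seamless.
#'
#' @param condition Condition name, index, or row from [condition_table()];
#'   must have an oculomotor task (`gaze`, `pro` or `anti`). The eyes-open and
#'   eyes-closed baselines have no visual schedule and are rejected.
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @param n_practice,n_recorded Trial counts; defaults follow the protocol
#'   (10/30 for 2D and 3D, 5/15 for VM and SO).
#' @param max_run Maximum allowed run of consecutive same-side goals
#'   (anticipation mitigation). Default 3.
#' @param target_full_window If `TRUE` (default) the saccade target stays
#'   visible for the whole response window; if `FALSE` its nominal duration
#'   is recorded as half the window. Timing of events is unaffected.
#'
#' @return An object of class `stimulus_schedule`: a list with `condition`
#'   (one-row tibble), `events` (tibble: `trial`, `is_practice`,
#'   `frame_kind`, `t_onset`, `duration`, `side`, `eccentricity`, `symbol`,
#'   `symbol_other`, `expected`), `n_practice`, `n_recorded`,
#'   `cycle_duration`, `posture_recording_start`, `duration`, `seed`.
#' @examples
#' sch <- build_schedule("2D-P", seed = 1)
#' sch$cycle_duration          # 2 s
#' nrow(response_events(sch))  # 30 recorded targets
#' @export
build_schedule <- function(condition, seed, n_practice = NULL,
                           n_recorded = NULL, max_run = 3,
                           target_full_window = TRUE) {
  cond <- as_condition(condition)
  env <- cond$environment
  if (env %in% c("EO", "EC")) {
    abort(paste0("Condition '", cond$name,
                 "' has no visual stimulus schedule (no headset/targets)."))
  }
  if (!cond$oculomotor_task %in% c("gaze", "pro", "anti")) {
    abort("`condition` must have oculomotor task 'gaze', 'pro' or 'anti'.")
  }
  defaults <- schedule_defaults(env)
  n_practice <- as.integer(n_practice %||% defaults$n_practice)
  n_recorded <- as.integer(n_recorded %||% defaults$n_recorded)
  if (n_practice < 0 || n_recorded < 1) {
    abort("`n_practice` must be >= 0 and `n_recorded` >= 1.")
  }
  n_trials <- n_practice + n_recorded
  has_targets <- cond$oculomotor_task %in% c("pro", "anti")

  sides <- if (has_targets) {
    withr::with_seed(seed, draw_balanced_sides(n_practice, n_recorded, max_run))
  } else {
    rep(NA_character_, n_trials)
  }
  symbols <- if (has_targets && env == "VM") {
    withr::with_seed(seed + 1L, draw_symbol_pairs(n_trials))
  } else NULL

  events <- cycle_event_table(env, cond$oculomotor_task, n_trials,
                              defaults$cycle_duration, sides, symbols,
                              target_full_window)
  events$is_practice <- events$trial <= n_practice
  events$expected <- NA_character_
  resp <- events$frame_kind %in% c("target", "response")
  if (has_targets && any(resp)) {
    events$expected[resp] <- expected_direction(cond, events$side[resp])
  }
  events <- events[, c("trial", "is_practice", "frame_kind", "t_onset",
                       "duration", "side", "eccentricity", "symbol",
                       "symbol_other", "expected")]
  structure(
    list(
      condition = cond,
      events = events,
      n_practice = n_practice,
      n_recorded = n_recorded,
      cycle_duration = defaults$cycle_duration,
      posture_recording_start = n_practice * defaults$cycle_duration,
      duration = n_trials * defaults$cycle_duration,
      seed = as.integer(seed)
    ),
    class = "stimulus_schedule"
  )
}

schedule_defaults <- function(env) {
  switch(env,
    "2D" = , "3D" = list(cycle_duration = 2.0, n_practice = 10L,
                         n_recorded = 30L),
    "VM" = list(cycle_duration = 10.0, n_practice = 5L, n_recorded = 15L),
    "SO" = list(cycle_duration = 7.5, n_practice = 5L, n_recorded = 15L),
    abort(paste0("Unknown environment '", env, "'."))
  )
}

vm_symbols <- c("cross", "triangle", "square", "star", "heart", "pentagon")

# Balanced left/right assignment: recorded trials split ceiling/floor (the
# majority side seed-determined when odd), practice trials take the opposite
# extra so the full sequence is exactly balanced; resampled until no side
# repeats more than max_run times in a row.
draw_balanced_sides <- function(n_practice, n_recorded, max_run) {
  sides <- c("left", "right")
  maj <- sample(sides, 1)
  min_ <- setdiff(sides, maj)
  rec_pool <- c(rep(maj, ceiling(n_recorded / 2)),
                rep(min_, floor(n_recorded / 2)))
  pra_pool <- c(rep(min_, ceiling(n_practice / 2)),
                rep(maj, floor(n_practice / 2)))
  for (attempt in 1:1000) {
    seq_ <- c(sample(pra_pool), sample(rec_pool))
    if (max(rle(seq_)$lengths) <= max_run) return(seq_)
  }
  abort("Could not satisfy the consecutive-side constraint; raise `max_run`.")
}

draw_symbol_pairs <- function(n_trials) {
  pairs <- t(replicate(n_trials, sample(vm_symbols, 2)))
  tibble::tibble(symbol = pairs[, 1], symbol_other = pairs[, 2])
}

# Per-environment frame templates, expanded over all cycles at once.
cycle_event_table <- function(env, task, n_trials, cycle_duration, sides,
                              symbols, target_full_window) {
  gaze_only <- !task %in% c("pro", "anti")
  if (gaze_only) {
    tpl <- list(kind = "central_fixation", offset = 0,
                dur = cycle_duration, sided = FALSE, ecc = NA_real_,
                sym = NA_character_)
  } else if (env %in% c("2D", "3D")) {
    tpl <- list(
      kind = c("central_fixation", "target"),
      offset = c(0, 1),
      dur = c(1, if (target_full_window) 1 else 0.5),
      sided = c(FALSE, TRUE), ecc = c(NA, 8),
      sym = c(NA_character_, NA_character_)
    )
  } else if (env == "SO") {
    tpl <- list(
      kind = c("central_fixation", "allocentric_view", "response"),
      offset = c(0, 2.5, 5), dur = c(2.5, 2.5, 2.5),
      sided = c(FALSE, TRUE, TRUE), ecc = c(NA, 2, 8),
      sym = c(NA, "disc", "disc")
    )
  } else if (env == "VM") {
    tpl <- list(
      kind = c("central_fixation", "memorise", "central_fixation",
               "response"),
      offset = c(0, 2.5, 5, 7.5), dur = rep(2.5, 4),
      sided = c(FALSE, TRUE, FALSE, TRUE), ecc = c(NA, 2, NA, 8),
      sym = c(NA, "probe", NA, "probe")
    )
  } else {
    abort(paste0("Unknown environment '", env, "'."))
  }
  m <- length(tpl$kind)
  trial <- rep(seq_len(n_trials), each = m)
  side <- ifelse(rep(tpl$sided, n_trials), sides[trial], NA_character_)
  symbol <- rep(tpl$sym, n_trials)
  symbol_other <- rep(NA_character_, m * n_trials)
  if (!is.null(symbols)) {
    probe <- symbol == "probe" & !is.na(symbol)
    symbol[probe] <- symbols$symbol[trial[probe]]
    mem <- probe & rep(tpl$kind == "memorise", n_trials)
    symbol_other[mem] <- symbols$symbol_other[trial[mem]]
  }
  tibble::tibble(
    trial = trial,
    frame_kind = rep(tpl$kind, n_trials),
    t_onset = (trial - 1) * cycle_duration + rep(tpl$offset, n_trials),
    duration = rep(tpl$dur, n_trials),
    side = side,
    eccentricity = rep(tpl$ecc, n_trials),
    symbol = symbol,
    symbol_other = symbol_other
  )
}

#' Target/response events of a schedule
#'
#' @param schedule A `stimulus_schedule`.
#' @param recorded_only Drop practice trials (default `TRUE`).
#' @return Tibble of the events that open a response window.
#' @export
response_events <- function(schedule, recorded_only = TRUE) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  ev <- schedule$events
  ev <- ev[ev$frame_kind %in% c("target", "response"), ]
  if (recorded_only) ev <- ev[!ev$is_practice, ]
  ev
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat("<stimulus_schedule> condition", x$condition$name,
      sprintf("(%s, %s task)", x$condition$environment,
              x$condition$oculomotor_task), "\n")
  cat(sprintf("  %d practice + %d recorded cycles of %.1f s (%.1f s total)\n",
              x$n_practice, x$n_recorded, x$cycle_duration, x$duration))
  cat(sprintf("  posture recording starts at %.1f s; seed %d\n",
              x$posture_recording_start, x$seed))
  invisible(x)
}

#' Serialize a schedule to a JSON event log
#'
#' @param schedule A `stimulus_schedule`.
#' @param path File path; `.json` event log containing the condition name,
#'   trial counts and the event table.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  payload <- list(
    condition = schedule$condition$name,
    seed = schedule$seed,
    n_practice = schedule$n_practice,
    n_recorded = schedule$n_recorded,
    cycle_duration = schedule$cycle_duration,
    posture_recording_start = schedule$posture_recording_start,
    duration = schedule$duration,
    events = schedule$events
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a schedule from its JSON event log
#'
#' @param path Path written by [write_schedule_json()].
#' @return A `stimulus_schedule`.
#' @export
read_schedule_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- tibble::as_tibble(payload$events)
  for (col in c("side", "symbol", "symbol_other", "expected")) {
    if (!col %in% names(ev)) ev[[col]] <- NA_character_
    ev[[col]] <- as.character(ev[[col]])
  }
  if (!"eccentricity" %in% names(ev)) ev$eccentricity <- NA_real_
  ev$eccentricity <- as.numeric(ev$eccentricity)
  structure(
    list(
      condition = as_condition(payload$condition),
      events = ev,
      n_practice = as.integer(payload$n_practice),
      n_recorded = as.integer(payload$n_recorded),
      cycle_duration = payload$cycle_duration,
      posture_recording_start = payload$posture_recording_start,
      duration = payload$duration,
      seed = as.integer(payload$seed)
    ),
    class = "stimulus_schedule"
  )
}

#' Export schedule events as CSV
#'
#' Same columns as the JSON event log, one row per event.
#'
#' @param schedule A `stimulus_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  write.csv(schedule$events, path, row.names = FALSE)
  invisible(path)
}
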