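#' The eleven experimental conditions of the dual-task battery
#'
#' Returns the condition design of the concurrent posture/saccade assessment:
#' two baselines without a headset (eyes-open, eyes-closed), a gaze-only 2D
#' control, and pro-/anti-saccade tasks in four virtual environments (plain
#' 2D, 3D with visual challenge, visuospatial memory, spatial orientation).
#' Every condition loads posture; conditions 4--11 add a saccade task and,
#' depending on the environment, a visual-challenge (VC), visuospatial-memory
#' (VM) or spatial-orientation (SO) dual task.
#'
#' @return A tibble with one row per condition and columns
#'   `index` (1--11), `name` (e.g. `"2D-P"`), `environment`
#'   (`"EO"`, `"EC"`, `"2D"`, `"3D"`, `"VM"`, `"SO"`),
#'   `oculomotor_task` (`"gaze"`, `"none"`, `"pro"`, `"anti"`) and logical
#'   dual-task flag columns `flag_posture`, `flag_saccade`, `flag_vm`,
#'   `flag_so`, `flag_vc`.
#' @examples
#' condition_table()
#' @export
condition_table <- function() {
  tibble::tibble(
    index = 1:11,
    name = c("EO", "EC", "2D-G", "2D-P", "2D-A", "3D-P", "3D-A",
             "VM-P", "VM-A", "SO-P", "SO-A"),
    environment = c("EO", "EC", "2D", "2D", "2D", "3D", "3D",
                    "VM", "VM", "SO", "SO"),
    oculomotor_task = c("gaze", "none", "gaze", "pro", "anti", "pro", "anti",
                        "pro", "anti", "pro", "anti"),
    flag_posture = TRUE,
    flag_saccade = c(FALSE, FALSE, FALSE, rep(TRUE, 8)),
    flag_vm = c(rep(FALSE, 7), TRUE, TRUE, FALSE, FALSE),
    flag_so = c(rep(FALSE, 9), TRUE, TRUE),
    flag_vc = c(rep(FALSE, 5), TRUE, TRUE, rep(FALSE, 4))
  )
}

#' Resolve a condition argument to a single row of [condition_table()]
#'
#' @param condition A condition name (`"2D-P"`), an index (1--11), or a
#'   one-row tibble as returned by [condition_table()].
#' @return A one-row tibble.
#' @keywords internal
as_condition <- function(condition) {
  tab <- condition_table()
  if (is.data.frame(condition)) {
    if (nrow(condition) != 1L || !all(c("index", "name", "environment",
                                        "oculomotor_task") %in% names(condition))) {
      abort("`condition` data frame must be one row of `condition_table()`.")
    }
    return(tibble::as_tibble(condition))
  }
  if (is.numeric(condition)) {
    if (length(condition) != 1L || !condition %in% tab$index) {
      abort("`condition` index must be a single integer in 1..11.")
    }
    return(tab[tab$index == condition, ])
  }
  if (is.character(condition)) {
    if (length(condition) != 1L || !condition %in% tab$name) {
      abort(paste0("Unknown condition name '", condition, "'. Valid names: ",
                   paste(tab$name, collapse = ", "), "."))
    }
    return(tab[tab$name == condition, ])
  }
  abort("`condition` must be a name, an index, or a row of `condition_table()`.")
}

#' Expected saccade direction for a stimulus event
#'
#' Applies the task rule of each condition: pro-saccades go toward the
#' stimulus side, anti-saccades to the mirror-opposite side. In the
#' visuospatial-memory environment the response target is the side where the
#' memorised probe symbol reappears, and in the spatial-orientation
#' environment the side of the circle target inferred from the allocentric
#' map; in both cases the event's `side` already encodes that goal side, so
#' the pro/anti rule applies to it directly.
#'
#' @param condition Condition name, index, or row (see [condition_table()]).
#' @param side Character vector of stimulus sides, `"left"` or `"right"`
#'   (the `side` column of target/response events in a schedule).
#' @return Character vector of expected gaze directions (`"left"`/`"right"`).
#' @examples
#' expected_direction("2D-A", "right")  # anti-saccade mirrors: "left"
#' expected_direction("2D-P", "left")   # pro-saccade identity: "left"
#' @export
expected_direction <- function(condition, side) {
  cond <- as_condition(condition)
  task <- cond$oculomotor_task
  if (!task %in% c("pro", "anti")) {
    abort(paste0("Condition '", cond$name, "' has oculomotor task '", task,
                 "', which defines no expected saccade direction."))
  }
  if (!all(side %in% c("left", "right"))) {
    abort("`side` must be 'left' or 'right' for target/response events.")
  }
  if (task == "pro") side else ifelse(side == "left", "right", "left")
}

#' Factorial coding of the dual-task conditions 4--11
#'
#' Maps condition indices to the two within-subject factors used by the
#' factorial analyses: `environment` (2D, 3D, VM, SO) and `saccade_task`
#' (pro, anti).
#'
#' @param index Integer vector of condition indices in 4..11.
#' @return A tibble with columns `index`, `environment`, `saccade_task`.
#' @export
condition_factors <- function(index = 4:11) {
  if (!all(index %in% 4:11)) {
    abort("Factorial coding is defined for conditions 4..11 only.")
  }
  tab <- condition_table()
  tibble::tibble(
    index = as.integer(index),
    environment = tab$environment[match(index, tab$index)],
    saccade_task = tab$oculomotor_task[match(index, tab$index)]
  )
}
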