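#' Write / read gaze and COP trace CSVs
#'
#' Traces are interchanged as plain CSV with a leading `# unit:` comment
#' line declaring the measurement unit. Gaze traces carry columns
#' `t, gaze_h, gaze_v, pupil, valid` (degrees / mm), COP traces
#' `t, x_ml, y_ap` (mm or cm; cm values are converted to mm on read).
#'
#' @param trace A `gaze_trace` or `cop_trace` tibble.
#' @param path Output path.
#' @param unit Unit string written to the header (`"deg"` for gaze, `"mm"`
#'   or `"cm"` for COP).
#' @return `path`, invisibly (writers); a trace tibble (readers).
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_gaze_csv <- function(trace, path, unit = "deg") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", unit), con)
  writeLines(paste0("# sample_rate: ", attr(trace, "sample_rate") %||% NA), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
write_cop_csv <- function(trace, path, unit = "mm") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", unit), con)
  writeLines(paste0("# sample_rate: ", attr(trace, "sample_rate") %||% NA), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

read_trace_header <- function(path) {
  lines <- readLines(path, n = 5)
  hdr <- grep("^#", lines, value = TRUE)
  unit <- sub("^# unit:\\s*", "", grep("^# unit:", hdr, value = TRUE))
  rate <- sub("^# sample_rate:\\s*", "",
              grep("^# sample_rate:", hdr, value = TRUE))
  list(unit = if (length(unit)) unit else NA_character_,
       sample_rate = if (length(rate)) suppressWarnings(as.numeric(rate))
                     else NA_real_,
       n_skip = length(hdr))
}

validate_time_column <- function(t, declared_rate = NA_real_) {
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    abort(paste0("Time column is not strictly increasing; first offending ",
                 "data row: ", bad[1] + 1L, " (t = ", t[bad[1] + 1L], ")."))
  }
  if (is.finite(declared_rate) && length(t) > 1) {
    emp <- 1 / median(diff(t))
    if (abs(emp - declared_rate) / declared_rate > 0.001) {
      warn(sprintf(paste0("Declared sample rate %.6g Hz differs from the ",
                          "empirical rate %.6g Hz by more than 0.1%%."),
                   declared_rate, emp))
    }
  }
}

#' @rdname trace_io
#' @export
read_gaze_csv <- function(path) {
  hdr <- read_trace_header(path)
  df <- read.csv(path, comment.char = "#")
  need <- c("t", "gaze_h", "gaze_v", "pupil", "valid")
  if (!all(need %in% names(df))) {
    abort(paste0("Gaze CSV missing columns: ",
                 paste(setdiff(need, names(df)), collapse = ", "), "."))
  }
  validate_time_column(df$t, hdr$sample_rate)
  df$valid <- as.logical(df$valid)
  tibble::new_tibble(df[, need], nrow = nrow(df), class = "gaze_trace",
                     sample_rate = hdr$sample_rate %||% NA_real_)
}

#' @rdname trace_io
#' @export
read_cop_csv <- function(path) {
  hdr <- read_trace_header(path)
  df <- read.csv(path, comment.char = "#")
  need <- c("t", "x_ml", "y_ap")
  if (!all(need %in% names(df))) {
    abort(paste0("COP CSV missing columns: ",
                 paste(setdiff(need, names(df)), collapse = ", "), "."))
  }
  validate_time_column(df$t, hdr$sample_rate)
  if (identical(hdr$unit, "cm")) {
    df$x_ml <- df$x_ml * 10
    df$y_ap <- df$y_ap * 10
  }
  tibble::new_tibble(df[, need], nrow = nrow(df), class = "cop_trace",
                     sample_rate = hdr$sample_rate %||% NA_real_)
}

#' Read a full recorded session (gaze + COP + schedule)
#'
#' @param gaze_path,cop_path,schedule_path Paths to the gaze CSV, COP CSV
#'   and schedule JSON of one session; `NULL` entries are skipped.
#' @return List with `gaze`, `cop`, `schedule` (missing pieces `NULL`).
#' @export
read_traces <- function(gaze_path = NULL, cop_path = NULL,
                        schedule_path = NULL) {
  list(
    gaze = if (!is.null(gaze_path)) read_gaze_csv(gaze_path),
    cop = if (!is.null(cop_path)) read_cop_csv(cop_path),
    schedule = if (!is.null(schedule_path)) read_schedule_json(schedule_path)
  )
}

#' Run configuration
#'
#' Collects every tunable of the pipeline in one serializable list:
#' simulator population parameters, condition effect shifts that the demo
#' cohort applies on top of each subject's baseline (longer latencies and
#' more errors under the memory/orientation dual tasks, higher COP diffusion
#' under high load), detection thresholds, scoring options and statistics
#' options. `save_config()`/`load_config()` round-trip it through JSON.
#'
#' @param seed Master seed; all per-subject/condition seeds derive from it.
#' @param n_subjects Synthetic cohort size.
#' @param conditions Condition indices to run (default all 11).
#' @param ... Overrides for any default field.
#' @return Object of class `run_config` (named list).
#' @examples
#' cfg <- run_config(seed = 1, n_subjects = 4)
#' cfg$detection$velocity_threshold
#' @export
run_config <- function(seed = 1, n_subjects = 20, conditions = 1:11, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    conditions = as.integer(conditions),
    gaze_sample_rate = 120,
    cop_sample_rate = 100,
    eo_ec_duration = 60,
    unit = "mm",
    population = list(
      latency_mean = 0.25, latency_mean_between_sd = 0.03,
      latency_sd = 0.05, error_prob = 0.08,
      main_sequence_vmax = 500, main_sequence_c = 6,
      intrusion_rate = 0.1, gaze_noise_sd = 0.1,
      cop_relaxation = 1, cop_diffusion = 10,
      cop_diffusion_between_sd = 2,
      pupil_base = 3.5, pupil_osc_amp = 0.1, pupil_osc_freq = 0.5,
      pupil_noise_sd = 0.02
    ),
    effects = list(
      latency_shift = c("2D" = 0, "3D" = 0.005, "VM" = 0.09, "SO" = 0.08),
      anti_latency_shift = 0.04,
      error_shift = c("2D" = 0, "3D" = 0.01, "VM" = 0.1, "SO" = 0.08),
      anti_error_shift = 0.04,
      cop_diffusion_scale = c("2D" = 1, "3D" = 1, "VM" = 1.3, "SO" = 1.25)
    ),
    detection = list(velocity_threshold = 30, min_duration = 0.01,
                     min_amplitude = 1, smooth = 3, max_gap = 0.1),
    scoring = list(anticipation_floor = 0.08, roi_halfwidth = 3,
                   error_denominator = "valid"),
    stats = list(adjust = "holm", anova = "art", zero_method = "wilcox"),
    pupil_band = c(0.05, 2)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, list(seed = raw$seed,
                                  n_subjects = raw$n_subjects,
                                  conditions = raw$conditions))
  for (nm in setdiff(names(raw), c("seed", "n_subjects", "conditions"))) {
    if (is.list(cfg[[nm]]) && !is.null(names(raw[[nm]]))) {
      for (k in names(raw[[nm]])) {
        v <- raw[[nm]][[k]]
        if (!is.null(names(cfg[[nm]][[k]])) && is.null(names(v))) {
          names(v) <- names(cfg[[nm]][[k]])
        }
        cfg[[nm]][[k]] <- v
      }
    } else {
      v <- raw[[nm]]
      if (!is.null(names(cfg[[nm]])) && is.null(names(v))) {
        names(v) <- names(cfg[[nm]])
      }
      cfg[[nm]] <- v
    }
  }
  cfg
}
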