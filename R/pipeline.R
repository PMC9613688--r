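derive_seed <- function(master, subject, condition, stream) {
  as.integer((as.numeric(master) * 7919 + subject * 1009 +
                condition * 101 + stream * 13) %% 2147483647)
}

draw_cohort <- function(config) {
  pop <- config$population
  withr::with_seed(derive_seed(config$seed, 0, 0, 1), {
    tibble::tibble(
      subject = seq_len(config$n_subjects),
      latency_mean = pmax(0.12, rnorm(config$n_subjects, pop$latency_mean,
                                      pop$latency_mean_between_sd)),
      cop_diffusion = pmax(1, rnorm(config$n_subjects, pop$cop_diffusion,
                                    pop$cop_diffusion_between_sd))
    )
  })
}

condition_subject <- function(config, cohort_row, cond) {
  pop <- config$population
  eff <- config$effects
  env <- cond$environment
  lat <- cohort_row$latency_mean
  err <- pop$error_prob
  diff_ <- cohort_row$cop_diffusion
  if (env %in% names(eff$latency_shift)) {
    lat <- lat + eff$latency_shift[[env]]
    err <- err + eff$error_shift[[env]]
    diff_ <- diff_ * eff$cop_diffusion_scale[[env]]
  }
  if (identical(cond$oculomotor_task, "anti")) {
    lat <- lat + eff$anti_latency_shift
    err <- err + eff$anti_error_shift
  }
  subject_model(
    latency_mean = lat, latency_sd = pop$latency_sd,
    error_prob = min(max(err, 0), 1),
    main_sequence_vmax = pop$main_sequence_vmax,
    main_sequence_c = pop$main_sequence_c,
    intrusion_rate = pop$intrusion_rate,
    gaze_noise_sd = pop$gaze_noise_sd,
    cop_relaxation = pop$cop_relaxation, cop_diffusion = diff_,
    pupil_base = pop$pupil_base, pupil_osc_amp = pop$pupil_osc_amp,
    pupil_osc_freq = pop$pupil_osc_freq, pupil_noise_sd = pop$pupil_noise_sd
  )
}

#' Run the full simulation / scoring / statistics pipeline
#'
#' Simulates a synthetic cohort through the requested conditions and carries
#' every recording through scoring and aggregation: schedules are built and
#' gaze simulated for the saccade-task conditions (4--11), COP traces for
#' all conditions (the analysis window starting where posture recording
#' starts, i.e. after the practice trials; 60 s for the eyes-open/closed
#' baselines), oculometrics and posturography metrics are computed per
#' subject and condition, and the nonparametric battery (distribution
#' checks, aligned-rank factorial ANOVA, pairwise Wilcoxon with Holm
#' adjustment) is run over conditions 4--11 when they are all present.
#'
#' The run is fully deterministic given `config$seed`: per-subject,
#' per-condition, per-stream seeds are derived from it, and repeated runs
#' write byte-identical numeric outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `trials.csv`,
#'   `summaries.csv`, `long_table.csv`, `anova.csv`, `pairwise.csv`,
#'   `distribution_checks.csv` and `run_log.json`.
#' @return List (invisible when `out_dir` is given): `trials` (per-trial
#'   scores), `summaries` (per subject x condition metrics), `long_table`,
#'   `distribution_checks`, `anova`, `pairwise`, `log`.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(seed = 1, n_subjects = 4,
#'                                conditions = c(1, 2, 4, 5)))
#' head(res$summaries)
#' }
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  tab <- condition_table()
  cohort <- draw_cohort(config)
  det <- config$detection
  sco <- config$scoring

  trials <- list()
  summaries <- list()
  for (s in cohort$subject) {
    for (ci in config$conditions) {
      cond <- tab[tab$index == ci, ]
      subj <- condition_subject(config, cohort[cohort$subject == s, ], cond)
      has_schedule <- !cond$environment %in% c("EO", "EC")
      has_targets <- cond$oculomotor_task %in% c("pro", "anti")
      oc <- NULL
      pupil_band <- NA_real_
      if (has_schedule) {
        sch <- build_schedule(cond, seed = derive_seed(config$seed, s, ci, 2))
        cop_window_len <- sch$duration - sch$posture_recording_start
        sim <- simulate_gaze(sch, subj,
                             sample_rate = config$gaze_sample_rate,
                             seed = derive_seed(config$seed, s, ci, 3))
        psd <- pupil_psd(sim$trace$pupil, config$gaze_sample_rate,
                         band = config$pupil_band)
        pupil_band <- psd$band_mean
        if (has_targets) {
          sc <- score_trials(
            sim$trace, sch,
            anticipation_floor = sco$anticipation_floor,
            roi_halfwidth = sco$roi_halfwidth, max_gap = det$max_gap,
            velocity_threshold = det$velocity_threshold,
            min_duration = det$min_duration,
            min_amplitude = det$min_amplitude, smooth = det$smooth
          )
          trials[[length(trials) + 1L]] <-
            dplyr::mutate(sc, subject = s, condition = ci, .before = 1)
          oc <- aggregate_condition(sc, denominator = sco$error_denominator)
        }
      } else {
        cop_window_len <- config$eo_ec_duration
      }
      cop <- simulate_cop(cop_window_len, subj,
                          sample_rate = config$cop_sample_rate,
                          seed = derive_seed(config$seed, s, ci, 4))
      pm <- compute_posture_metrics(cop)
      row <- tibble::tibble(subject = s, condition = ci, name = cond$name)
      if (!is.null(oc)) {
        row <- dplyr::bind_cols(row, oc[, c("latency_mean", "latency_sd",
                                            "peak_speed_mean",
                                            "peak_speed_sd", "error_rate",
                                            "n_valid")])
      }
      row$pupil_band_mean <- pupil_band
      row <- dplyr::bind_cols(row, pm[, c("sd_ml", "sd_ap", "speed_total",
                                          "speed_ml", "speed_ap", "aec")])
      summaries[[length(summaries) + 1L]] <- row
    }
  }
  trials <- dplyr::bind_rows(trials)
  summaries <- dplyr::bind_rows(summaries)

  stat_params <- intersect(
    c("latency_mean", "latency_sd", "peak_speed_mean", "peak_speed_sd",
      "error_rate", "sd_ml", "sd_ap", "speed_total", "speed_ml", "speed_ap",
      "aec", "pupil_band_mean"),
    names(summaries)
  )
  long_table <- tidyr::pivot_longer(
    summaries[, c("subject", "condition", stat_params)],
    cols = dplyr::all_of(stat_params),
    names_to = "parameter", values_to = "value"
  )
  long_table <- long_table[!is.na(long_table$value), ]

  dist_checks <- anova_res <- pairwise <- NULL
  if (all(4:11 %in% config$conditions)) {
    factorial <- long_table[long_table$condition %in% 4:11, ]
    dist_checks <- check_distributions(factorial)
    anova_res <- if (identical(config$stats$anova, "friedman")) {
      friedman_main_effects(factorial)
    } else {
      rank_factorial_anova(factorial)
    }
    pairwise <- wilcoxon_pairwise(factorial,
                                  adjust = config$stats$adjust,
                                  zero_method = config$stats$zero_method)
  }

  log <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("oculosway")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_subjects = config$n_subjects,
    conditions = config$conditions,
    n_trials_scored = nrow(trials),
    n_trials_invalid = if (nrow(trials)) sum(!trials$valid) else 0L,
    invalid_by_reason = if (nrow(trials)) {
      as.list(table(trials$reason[!trials$valid]))
    } else list()
  )

  res <- list(trials = trials, summaries = summaries,
              long_table = long_table, distribution_checks = dist_checks,
              anova = anova_res, pairwise = pairwise, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
    write.csv(summaries, file.path(out_dir, "summaries.csv"),
              row.names = FALSE)
    write.csv(long_table, file.path(out_dir, "long_table.csv"),
              row.names = FALSE)
    if (!is.null(dist_checks)) {
      write.csv(dist_checks, file.path(out_dir, "distribution_checks.csv"),
                row.names = FALSE)
      write.csv(as.data.frame(anova_res), file.path(out_dir, "anova.csv"),
                row.names = FALSE)
      write.csv(as.data.frame(pairwise), file.path(out_dir, "pairwise.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}

#' Quick synthetic long table for the statistics layer
#'
#' Generates a per-subject x condition x parameter table directly (without
#' running the signal pipeline), with the qualitative effect structure of
#' the dual-task battery: longer and more variable latencies plus more
#' errors under the memory/orientation dual tasks, a small anti-saccade
#' cost, and higher anterior-posterior sway speed under high load.
#' Useful for examples and for power/type-I simulations of the statistical
#' battery.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param environment_shift Named additive latency shifts (s) per
#'   environment; set all zero for a null table.
#' @param null If `TRUE`, removes all condition effects (pure noise around
#'   subject baselines).
#' @return Long tibble (`subject`, `condition` in 4..11, `parameter`,
#'   `value`).
#' @export
demo_long_table <- function(n_subjects = 20, seed = 1,
                            environment_shift = c("2D" = 0, "3D" = 0,
                                                  "VM" = 0.09, "SO" = 0.08),
                            null = FALSE) {
  fac <- condition_factors()
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(subject = seq_len(n_subjects),
                               condition = 4:11)
    grid <- dplyr::left_join(grid, fac, by = c(condition = "index"))
    base_lat <- rnorm(n_subjects, 0.25, 0.03)
    base_sway <- rnorm(n_subjects, 12, 2)
    shift <- if (null) rep(0, nrow(grid)) else
      environment_shift[grid$environment]
    anti <- if (null) 0 else 0.04 * (grid$saccade_task == "anti")
    load <- if (null) 0 else
      2 * (grid$environment %in% c("VM", "SO"))
    dplyr::bind_rows(
      tibble::tibble(subject = grid$subject, condition = grid$condition,
                     parameter = "latency_mean",
                     value = base_lat[grid$subject] + shift + anti +
                       rnorm(nrow(grid), 0, 0.03)),
      tibble::tibble(subject = grid$subject, condition = grid$condition,
                     parameter = "error_rate",
                     value = pmin(1, pmax(0,
                       0.08 + (if (null) 0 else
                                 0.1 * (grid$environment %in% c("VM", "SO"))) +
                         rnorm(nrow(grid), 0, 0.04)))),
      tibble::tibble(subject = grid$subject, condition = grid$condition,
                     parameter = "speed_ap",
                     value = pmax(0.1, base_sway[grid$subject] + load +
                                    rnorm(nrow(grid), 0, 1.5))),
      tibble::tibble(subject = grid$subject, condition = grid$condition,
                     parameter = "aec",
                     value = pmax(1, 100 + 10 * load +
                                    rnorm(nrow(grid), 0, 25)))
    )
  })
}
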