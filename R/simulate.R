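#' Parametric subject model for the simulator
#'
#' Bundles the parameters that govern one synthetic participant: the saccade
#' latency law (shifted log-normal with an 80 ms physiological floor), the
#' direction-error probability, the main-sequence amplitude/peak-velocity
#' relation `v_peak = vmax * (1 - exp(-amplitude / c))`, the rate of sub-1
#' degree saccadic intrusions, gaze measurement noise, a mean-reverting
#' (Ornstein-Uhlenbeck) centre-of-pressure process with relaxation rate
#' `theta` (1/s) and diffusion `D` (mm^2/s) per axis (stationary SD
#' `sqrt(D / (2 theta))`), and a pupil model (baseline + sinusoidal
#' oscillation + white noise).
#'
#' Defaults describe a healthy older adult standing quietly: ~250 ms mean
#' pro-saccade latency with 50 ms spread, 10% direction errors, main
#' sequence saturating at 500 deg/s with a 6 degree constant, COP stationary
#' spread ~2.2 mm per axis, pupil baseline 3.5 mm with a slow 0.5 Hz
#' oscillation.
#'
#' @param latency_mean,latency_sd Mean and SD of saccade latency (s).
#' @param error_prob Probability that the primary saccade goes opposite to
#'   the expected direction.
#' @param main_sequence_vmax,main_sequence_c Main-sequence saturation speed
#'   (deg/s) and amplitude constant (deg).
#' @param intrusion_rate Poisson rate (events/s) of sub-1-degree intrusions.
#' @param gaze_noise_sd Gaussian gaze noise SD (deg).
#' @param cop_relaxation,cop_diffusion OU relaxation rate (1/s) and diffusion
#'   (mm^2/s) for each COP axis.
#' @param pupil_base,pupil_osc_amp,pupil_osc_freq,pupil_noise_sd Pupil
#'   baseline (mm), oscillation amplitude (mm) and frequency (Hz), and white
#'   noise SD (mm).
#' @param latency_floor Physiological latency floor (s); draws are
#'   `floor + log-normal` with the requested mean/SD above the floor.
#' @return An object of class `subject_model` (a validated named list).
#' @examples
#' subject_model(latency_mean = 0.3, error_prob = 0.2)
#' @export
subject_model <- function(latency_mean = 0.25, latency_sd = 0.05,
                          error_prob = 0.1,
                          main_sequence_vmax = 500, main_sequence_c = 6,
                          intrusion_rate = 0.1, gaze_noise_sd = 0.05,
                          cop_relaxation = 1, cop_diffusion = 10,
                          pupil_base = 3.5, pupil_osc_amp = 0.1,
                          pupil_osc_freq = 0.5, pupil_noise_sd = 0.02,
                          latency_floor = 0.08) {
  m <- list(latency_mean = latency_mean, latency_sd = latency_sd,
            error_prob = error_prob,
            main_sequence_vmax = main_sequence_vmax,
            main_sequence_c = main_sequence_c,
            intrusion_rate = intrusion_rate, gaze_noise_sd = gaze_noise_sd,
            cop_relaxation = cop_relaxation, cop_diffusion = cop_diffusion,
            pupil_base = pupil_base, pupil_osc_amp = pupil_osc_amp,
            pupil_osc_freq = pupil_osc_freq, pupil_noise_sd = pupil_noise_sd,
            latency_floor = latency_floor)
  nonneg <- c("latency_sd", "main_sequence_vmax", "main_sequence_c",
              "intrusion_rate", "gaze_noise_sd", "cop_diffusion",
              "pupil_base", "pupil_osc_amp", "pupil_osc_freq",
              "pupil_noise_sd")
  for (f in nonneg) {
    if (!is.numeric(m[[f]]) || length(m[[f]]) != 1L || m[[f]] < 0) {
      abort(paste0("`", f, "` must be a single non-negative number."))
    }
  }
  if (m$error_prob < 0 || m$error_prob > 1) {
    abort("`error_prob` must be in [0, 1].")
  }
  if (m$latency_mean < m$latency_floor) {
    abort("`latency_mean` must be at least the latency floor.")
  }
  structure(m, class = "subject_model")
}

#' Main-sequence peak speed for a saccade amplitude
#'
#' Saturating amplitude/peak-velocity law
#' `v_peak = vmax * (1 - exp(-|amplitude| / c))`.
#'
#' @param amplitude Saccade amplitude (deg, sign ignored).
#' @param vmax Saturation speed (deg/s).
#' @param c Amplitude constant (deg).
#' @return Peak speed (deg/s).
#' @examples
#' main_sequence_peak_speed(8, vmax = 500, c = 6)  # ~368.3 deg/s
#' @export
main_sequence_peak_speed <- function(amplitude, vmax = 500, c = 6) {
  vmax * (1 - exp(-abs(amplitude) / c))
}

# Saccade duration convention (s): 2.2 ms/deg slope + 21 ms intercept.
saccade_duration <- function(amplitude) (2.2 * abs(amplitude) + 21) / 1000

# Normalised sigmoidal displacement profile on [0, duration]: 0 before,
# 1 after, logistic in between with midpoint slope set so that the realized
# peak velocity of `amplitude * profile` equals `peak_speed`.
sigmoid_profile <- function(t, duration, amplitude, peak_speed) {
  # fixed-point solve for k: truncating the logistic to [0, duration]
  # rescales it by 1 / (f1 - f0), so the realized peak velocity is
  # A k / (4 (f1 - f0)); iterate until it equals the requested peak speed
  k <- 4 * peak_speed / abs(amplitude)
  for (i in 1:25) {
    s <- plogis(k * duration / 2) - plogis(-k * duration / 2)
    k_new <- 4 * peak_speed * s / abs(amplitude)
    if (abs(k_new - k) < 1e-10 * k) break
    k <- k_new
  }
  f <- plogis(k * (pmin(pmax(t, 0), duration) - duration / 2))
  f0 <- plogis(-k * duration / 2)
  f1 <- plogis(k * duration / 2)
  out <- (f - f0) / (f1 - f0)
  out[t <= 0] <- 0
  out[t >= duration] <- 1
  out
}

draw_latency <- function(n, subject) {
  mu <- subject$latency_mean - subject$latency_floor
  if (subject$latency_sd == 0 || mu <= 0) {
    return(rep(subject$latency_floor + max(mu, 0), n))
  }
  s2 <- subject$latency_sd^2
  sdlog <- sqrt(log(1 + s2 / mu^2))
  meanlog <- log(mu) - sdlog^2 / 2
  subject$latency_floor + rlnorm(n, meanlog, sdlog)
}

#' Simulate a gaze/pupil recording for a stimulus schedule
#'
#' Produces a uniformly sampled gaze trace with one primary saccade per
#' trial. Saccade onset is the response-frame onset plus a latency drawn
#' from the subject's shifted log-normal law (draws that would exceed the
#' response window are redrawn and counted); direction follows the expected
#' direction with probability `1 - error_prob`, otherwise the opposite side.
#' The displacement profile is sigmoidal with peak velocity given by the
#' main-sequence law, and gaze returns to centre at the following fixation
#' frame. Sub-1-degree intrusions (out-hold-back excursions) are injected as
#' a Poisson process, Gaussian measurement noise is added, and the pupil
#' channel comes from the same model as [simulate_pupil()].
#'
#' @param schedule A `stimulus_schedule` from [build_schedule()].
#' @param subject A [subject_model()].
#' @param sample_rate Sampling rate in Hz (>= 60).
#' @param seed Integer seed; fixed seed gives a bit-identical recording.
#' @param dropout_rate Optional rate (events/s) of blink-like dropouts
#'   marked `valid = FALSE`; 0 (default) disables them.
#' @param dropout_duration Dropout length in seconds.
#' @return A list with
#'   * `trace`: tibble (`t`, `gaze_h`, `gaze_v`, `pupil`, `valid`) of class
#'     `gaze_trace` with attribute `sample_rate` (+ = right / up, degrees);
#'   * `ground_truth`: per-trial tibble (`trial`, `is_practice`,
#'     `t_response`, `latency`, `direction`, `expected`, `correct`,
#'     `amplitude`, `peak_speed`) — `NULL` for gaze-only tasks;
#'   * `n_redraws`: latency draws rejected for exceeding the window;
#'   * `n_intrusions`: number of injected sub-1-degree intrusions.
#' @examples
#' sch <- build_schedule("2D-P", seed = 1)
#' sim <- simulate_gaze(sch, subject_model(), sample_rate = 120, seed = 1)
#' head(sim$trace)
#' @export
simulate_gaze <- function(schedule, subject, sample_rate = 120, seed = 1,
                          dropout_rate = 0, dropout_duration = 0.15) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(subject, "subject_model"))
  if (sample_rate < 60) abort("`sample_rate` must be at least 60 Hz.")
  dt <- 1 / sample_rate
  t <- seq(0, schedule$duration - dt / 2, by = dt)
  n <- length(t)
  has_targets <- schedule$condition$oculomotor_task %in% c("pro", "anti")

  out <- withr::with_seed(seed, {
    gaze_h <- numeric(n)
    gt <- NULL
    n_redraws <- 0L
    if (has_targets) {
      resp <- response_events(schedule, recorded_only = FALSE)
      window <- resp$duration
      nt <- nrow(resp)
      lat <- draw_latency(nt, subject)
      for (i in seq_len(nt)) {
        while (lat[i] >= window[i]) {
          lat[i] <- draw_latency(1, subject)
          n_redraws <- n_redraws + 1L
        }
      }
      err <- runif(nt) < subject$error_prob
      expected <- resp$expected
      direction <- ifelse(err,
                          ifelse(expected == "left", "right", "left"),
                          expected)
      sign_dir <- ifelse(direction == "right", 1, -1)
      amp <- resp$eccentricity
      vp <- main_sequence_peak_speed(amp, subject$main_sequence_vmax,
                                     subject$main_sequence_c)
      # primary saccade out, return saccade at the start of the next cycle
      for (i in seq_len(nt)) {
        t_move <- resp$t_onset[i] + lat[i]
        dur <- saccade_duration(amp[i])
        idx <- which(t >= t_move & t <= t_move + dur + dt)
        if (length(idx)) {
          gaze_h[idx[1]:n] <- gaze_h[idx[1]:n] +
            sign_dir[i] * amp[i] *
              sigmoid_profile(t[idx[1]:n] - t_move, dur, amp[i], vp[i])
        }
        t_back <- resp$t_onset[i] + resp$duration[i] + 0.2
        if (t_back + dur < schedule$duration) {
          ib <- which(t >= t_back)
          gaze_h[ib] <- gaze_h[ib] -
            sign_dir[i] * amp[i] *
              sigmoid_profile(t[ib] - t_back, dur, amp[i], vp[i])
        }
      }
      gt <- tibble::tibble(
        trial = resp$trial, is_practice = resp$is_practice,
        t_response = resp$t_onset, latency = lat,
        direction = direction, expected = expected,
        correct = direction == expected,
        amplitude = sign_dir * amp, peak_speed = vp
      )
    }
    # sub-1-degree intrusions: small sigmoid out, 80 ms hold, sigmoid back;
    # a 250 ms refractory gap keeps intrusions from superposing into
    # supra-degree excursions
    n_intr <- rpois(1, subject$intrusion_rate * schedule$duration)
    if (n_intr > 0) {
      ti <- sort(runif(n_intr, 0, schedule$duration - 0.2))
      keep <- !logical(length(ti))
      last <- -Inf
      for (i in seq_along(ti)) {
        if (ti[i] - last < 0.25) keep[i] <- FALSE else last <- ti[i]
      }
      ti <- ti[keep]
      n_intr <- length(ti)
      ai <- runif(n_intr, 0.3, 0.8) * sample(c(-1, 1), n_intr, replace = TRUE)
      for (i in seq_len(n_intr)) {
        dur <- 0.02
        vp_i <- main_sequence_peak_speed(ai[i], subject$main_sequence_vmax,
                                         subject$main_sequence_c)
        vp_i <- max(vp_i, 4 * abs(ai[i]) / dur * 0.6)
        idx <- which(t >= ti[i] & t <= ti[i] + 0.12 + 2 * dur)
        if (length(idx)) {
          tau <- t[idx] - ti[i]
          gaze_h[idx] <- gaze_h[idx] +
            ai[i] * (sigmoid_profile(tau, dur, ai[i], vp_i) -
                       sigmoid_profile(tau - dur - 0.08, dur, ai[i], vp_i))
        }
      }
    }
    n_intrusions <- n_intr
    gaze_h <- gaze_h + rnorm(n, 0, subject$gaze_noise_sd)
    gaze_v <- rnorm(n, 0, subject$gaze_noise_sd)
    pupil <- subject$pupil_base +
      subject$pupil_osc_amp * sin(2 * pi * subject$pupil_osc_freq * t) +
      rnorm(n, 0, subject$pupil_noise_sd)
    valid <- rep(TRUE, n)
    if (dropout_rate > 0) {
      nb <- rpois(1, dropout_rate * schedule$duration)
      if (nb > 0) {
        tb <- runif(nb, 0, schedule$duration - dropout_duration)
        for (b in tb) valid[t >= b & t < b + dropout_duration] <- FALSE
      }
    }
    list(gaze_h = gaze_h, gaze_v = gaze_v, pupil = pupil, valid = valid,
         gt = gt, n_redraws = n_redraws, n_intrusions = n_intrusions)
  })

  trace <- tibble::new_tibble(
    list(t = t, gaze_h = out$gaze_h, gaze_v = out$gaze_v,
         pupil = out$pupil, valid = out$valid),
    nrow = n, class = "gaze_trace", sample_rate = sample_rate
  )
  list(trace = trace, ground_truth = out$gt, n_redraws = out$n_redraws,
       n_intrusions = out$n_intrusions)
}

#' Simulate a centre-of-pressure recording
#'
#' Two independent mean-reverting (Ornstein-Uhlenbeck) processes, one per
#' sway axis, discretized exactly at the sampling rate:
#' `x[k+1] = x[k] exp(-theta dt) + sqrt(D (1 - exp(-2 theta dt)) / (2 theta)) e[k]`.
#' The process starts from its stationary distribution, so the per-axis
#' stationary SD is `sqrt(D / (2 theta))` from the first sample.
#'
#' @param duration Recording length (s), > 0.
#' @param subject A [subject_model()] supplying `cop_relaxation` (theta) and
#'   `cop_diffusion` (D).
#' @param sample_rate Sampling rate (Hz).
#' @param seed Integer seed.
#' @return A tibble (`t`, `x_ml`, `y_ap`) of class `cop_trace` with
#'   attribute `sample_rate`; units mm (+ = right / anterior).
#' @examples
#' cop <- simulate_cop(60, subject_model(), sample_rate = 100, seed = 1)
#' sd(cop$x_ml)  # ~ sqrt(10 / 2) mm
#' @export
simulate_cop <- function(duration, subject, sample_rate = 100, seed = 1) {
  stopifnot(inherits(subject, "subject_model"))
  if (duration <= 0) abort("`duration` must be positive.")
  theta <- subject$cop_relaxation
  D <- subject$cop_diffusion
  if (D > 0 && theta <= 0) {
    abort("Non-positive `cop_relaxation` with nonzero diffusion is non-stationary.")
  }
  dt <- 1 / sample_rate
  t <- seq(0, duration - dt / 2, by = dt)
  n <- length(t)
  sim_axis <- function() {
    if (D == 0) return(numeric(n))
    sd_stat <- sqrt(D / (2 * theta))
    a <- exp(-theta * dt)
    innov_sd <- sd_stat * sqrt(1 - a^2)
    e <- rnorm(n) * innov_sd
    e[1] <- e[1] / sqrt(1 - a^2) # start from the stationary distribution
    as.numeric(stats::filter(e, a, method = "recursive"))
  }
  xy <- withr::with_seed(seed, list(x = sim_axis(), y = sim_axis()))
  tibble::new_tibble(
    list(t = t, x_ml = xy$x, y_ap = xy$y),
    nrow = n, class = "cop_trace", sample_rate = sample_rate
  )
}

#' Simulate a pupil-diameter series
#'
#' Baseline + sinusoidal oscillation + white noise:
#' `pupil(t) = base + amp * sin(2 pi f t) + e(t)`.
#'
#' @inheritParams simulate_cop
#' @return A tibble (`t`, `pupil`) in mm.
#' @examples
#' p <- simulate_pupil(60, subject_model(pupil_noise_sd = 0), 120, seed = 1)
#' var(p$pupil)  # ~ amp^2 / 2
#' @export
simulate_pupil <- function(duration, subject, sample_rate = 120, seed = 1) {
  stopifnot(inherits(subject, "subject_model"))
  if (duration <= 0) abort("`duration` must be positive.")
  dt <- 1 / sample_rate
  t <- seq(0, duration - dt / 2, by = dt)
  pupil <- withr::with_seed(seed, {
    subject$pupil_base +
      subject$pupil_osc_amp * sin(2 * pi * subject$pupil_osc_freq * t) +
      rnorm(length(t), 0, subject$pupil_noise_sd)
  })
  tibble::tibble(t = t, pupil = pupil)
}
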