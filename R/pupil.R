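#' Normalised pupil power spectral density (Welch's method)
#'
#' De-trends the pupil-diameter series (removes a linear fit), splits it
#' into 50%-overlapping Hann-windowed segments, averages the one-sided
#' periodograms, and rescales the result so that the spectrum integrates
#' exactly to the variance of the de-trended series (Parseval-consistent
#' normalisation). The band summary is the mean density over a configurable
#' frequency band, by default 0.05--2 Hz, the range where task-evoked pupil
#' oscillations live.
#'
#' @param pupil Numeric pupil series (mm), or a tibble with a `pupil` column
#'   (e.g. from [simulate_pupil()] or a gaze trace).
#' @param sample_rate Sampling rate (Hz).
#' @param segment_length Samples per Welch segment; default
#'   `min(n, 2^floor(log2(n / 4)))` giving ~8 half-overlapping segments.
#' @param band Length-2 band (Hz) for `band_mean`.
#' @return An object of class `pupil_psd`: list with `spectrum` (tibble
#'   `frequency` Hz, `density` mm^2/Hz), `band_mean` (mm^2/Hz), `band`,
#'   `variance` (mm^2, of the de-trended series), `sample_rate`. A constant
#'   series yields an all-zero spectrum.
#' @examples
#' p <- simulate_pupil(120, subject_model(), 120, seed = 1)
#' psd <- pupil_psd(p, 120)
#' psd$band_mean
#' @export
pupil_psd <- function(pupil, sample_rate, segment_length = NULL,
                      band = c(0.05, 2)) {
  if (is.data.frame(pupil)) pupil <- pupil$pupil
  pupil <- as.numeric(pupil)
  pupil <- pupil[!is.na(pupil)]
  n <- length(pupil)
  if (n < 8) abort("Pupil series too short for spectral estimation.")
  segment_length <- segment_length %||% min(n, max(8, 2^floor(log2(n / 4))))
  if (n < 2 * segment_length) {
    abort("Series length must be at least twice the segment length.")
  }
  # linear de-trend
  tt <- seq_len(n)
  x <- pupil - fitted_line(tt, pupil)
  v <- sum(x^2) / n
  L <- segment_length
  df <- sample_rate / L
  freq <- (0:(floor(L / 2))) * df
  if (v <= .Machine$double.eps * max(1, mean(pupil)^2)) {
    spec <- tibble::tibble(frequency = freq, density = numeric(length(freq)))
    out <- list(spectrum = spec, band_mean = 0, band = band, variance = 0,
                sample_rate = sample_rate)
    class(out) <- "pupil_psd"
    return(out)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hann
  U <- sum(w^2)
  step <- max(1, floor(L / 2))
  starts <- seq(1, n - L + 1, by = step)
  acc <- numeric(floor(L / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    X <- fft(seg)
    p <- Mod(X[1:(floor(L / 2) + 1)])^2 / (U * sample_rate)
    # one-sided: double everything except DC (and Nyquist for even L)
    sel <- 2:(length(p) - ifelse(L %% 2 == 0, 1, 0))
    p[sel] <- 2 * p[sel]
    acc <- acc + p
  }
  dens <- acc / length(starts)
  # exact variance normalisation
  integral <- sum(dens) * df
  if (integral > 0) dens <- dens * (v / integral)
  spec <- tibble::tibble(frequency = freq, density = dens)
  in_band <- freq >= band[1] & freq <= band[2]
  out <- list(
    spectrum = spec,
    band_mean = if (any(in_band)) mean(dens[in_band]) else NA_real_,
    band = band, variance = v, sample_rate = sample_rate
  )
  class(out) <- "pupil_psd"
  out
}

fitted_line <- function(t, x) {
  tc <- t - mean(t)
  b <- sum(tc * x) / sum(tc^2)
  mean(x) + b * tc
}

#' @export
print.pupil_psd <- function(x, ...) {
  cat("<pupil_psd>", nrow(x$spectrum), "frequency bins up to",
      max(x$spectrum$frequency), "Hz\n")
  cat(sprintf("  variance %.4g mm^2; band mean (%.2f-%.2f Hz) %.4g mm^2/Hz\n",
              x$variance, x$band[1], x$band[2], x$band_mean))
  invisible(x)
}
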