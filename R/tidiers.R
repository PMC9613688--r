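#' Tidy the aligned-rank ANOVA result
#'
#' @param x A `rank_anova` object.
#' @param ... Ignored.
#' @return Tibble with one row per parameter x effect: `parameter`,
#'   `effect`, `df`, `df_error`, `statistic`, `p_value`.
#' @exportS3Method generics::tidy
tidy.rank_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-line summary of the aligned-rank ANOVA
#'
#' @param x A `rank_anova` object.
#' @param alpha Significance level.
#' @param ... Ignored.
#' @return One-row tibble: `n_parameters`, `n_effects`, `n_significant`,
#'   `min_p`.
#' @exportS3Method generics::glance
glance.rank_anova <- function(x, alpha = 0.05, ...) {
  d <- tibble::as_tibble(unclass(x))
  tibble::tibble(
    n_parameters = dplyr::n_distinct(d$parameter),
    n_effects = nrow(d),
    n_significant = sum(d$p_value < alpha, na.rm = TRUE),
    min_p = min(d$p_value, na.rm = TRUE)
  )
}

#' Tidy the pairwise Wilcoxon battery
#'
#' @param x A `pairwise_wilcoxon` tibble.
#' @param ... Ignored.
#' @return The underlying tibble.
#' @exportS3Method generics::tidy
tidy.pairwise_wilcoxon <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-line summary of the pairwise Wilcoxon battery
#'
#' @param x A `pairwise_wilcoxon` tibble.
#' @param alpha Significance level on adjusted p values.
#' @param ... Ignored.
#' @return One-row tibble: `n_tests`, `n_significant`, `n_large`,
#'   `max_effect_size`.
#' @exportS3Method generics::glance
glance.pairwise_wilcoxon <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$p_adjusted < alpha, na.rm = TRUE),
    n_large = sum(x$magnitude == "large", na.rm = TRUE),
    max_effect_size = max(x$effect_size, na.rm = TRUE)
  )
}

#' Tidy an association matrix into long format
#'
#' @param x An `assoc_matrix`.
#' @param ... Ignored.
#' @return Long tibble: `parameter_a`, `parameter_b`, `rho`, `p_value`,
#'   `significant`.
#' @exportS3Method generics::tidy
tidy.assoc_matrix <- function(x, ...) {
  pars <- rownames(x$rho)
  grid <- expand.grid(parameter_a = pars, parameter_b = pars,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    parameter_a = grid$parameter_a,
    parameter_b = grid$parameter_b,
    rho = as.vector(x$rho),
    p_value = as.vector(x$p),
    significant = as.vector(x$significant)
  )
}

#' Tidy a pupil PSD into its spectrum table
#'
#' @param x A `pupil_psd`.
#' @param ... Ignored.
#' @return Tibble `frequency`, `density`.
#' @exportS3Method generics::tidy
tidy.pupil_psd <- function(x, ...) {
  x$spectrum
}

#' One-line summary of a pupil PSD
#'
#' @param x A `pupil_psd`.
#' @param ... Ignored.
#' @return One-row tibble: `variance`, `band_mean`, `band_lo`, `band_hi`,
#'   `peak_frequency`.
#' @exportS3Method generics::glance
glance.pupil_psd <- function(x, ...) {
  nz <- x$spectrum[x$spectrum$frequency > 0, ]
  tibble::tibble(
    variance = x$variance,
    band_mean = x$band_mean,
    band_lo = x$band[1], band_hi = x$band[2],
    peak_frequency = if (nrow(nz) && any(nz$density > 0)) {
      nz$frequency[which.max(nz$density)]
    } else NA_real_
  )
}
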