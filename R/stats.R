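#' Distributional checks per parameter
#'
#' For each measurement parameter in a long table, runs Levene's test in the
#' Brown-Forsythe form (absolute deviations from group medians, via
#' [car::leveneTest()]) across conditions, and the Shapiro-Wilk normality
#' test on the pooled residuals (value minus condition mean). These are the
#' gatekeepers that motivate the nonparametric battery.
#'
#' @param table Long-format data frame with columns `subject`, `condition`,
#'   `parameter`, `value` (one value per subject x condition x parameter).
#' @return Tibble: `parameter`, `levene_p`, `shapiro_p`, `degenerate`
#'   (`TRUE` when all groups are constant so the tests are undefined).
#' @examples
#' tab <- demo_long_table(n_subjects = 8, seed = 1)
#' check_distributions(tab)
#' @export
check_distributions <- function(table) {
  check_long_table(table)
  dplyr::group_by(table, .data$parameter) |>
    dplyr::group_modify(function(d, key) {
      g <- factor(d$condition)
      if (any(table(g) < 3)) {
        abort("Need at least 3 observations per condition group.")
      }
      resid <- d$value - stats::ave(d$value, g)
      if (isTRUE(all(abs(resid) < 1e-12))) {
        return(tibble::tibble(levene_p = NA_real_, shapiro_p = NA_real_,
                              degenerate = TRUE))
      }
      lev_p <- if (nlevels(g) >= 2) {
        car::leveneTest(d$value, g, center = median)[["Pr(>F)"]][1]
      } else NA_real_  # homogeneity undefined for a single group
      sw <- tryCatch(shapiro.test(resid)$p.value, error = function(e) NA_real_)
      tibble::tibble(levene_p = lev_p, shapiro_p = sw,
                     degenerate = FALSE)
    }) |>
    dplyr::ungroup()
}

check_long_table <- function(table) {
  need <- c("subject", "condition", "parameter", "value")
  if (!all(need %in% names(table))) {
    abort(paste0("Long table must have columns: ",
                 paste(need, collapse = ", "), "."))
  }
  dup <- duplicated(table[, c("subject", "condition", "parameter")])
  if (any(dup)) {
    abort("Long table has duplicate (subject, condition, parameter) rows.")
  }
  invisible(table)
}

#' Aligned-rank-transform factorial ANOVA (within subjects)
#'
#' Nonparametric two-way repeated-measures analysis of the dual-task
#' conditions 4--11, coded as environment (2D/3D/VM/SO) x saccade task
#' (pro/anti). For each effect, the response is aligned (everything but the
#' effect of interest stripped via cell means), ranked across the whole
#' sample, and a within-subject ANOVA (`aov` with subject error strata) is
#' fitted on the ranks; only the aligned effect's p value is kept from each
#' fit.
#'
#' @param table Long table (see [check_distributions()]) restricted to, or
#'   filtered here to, conditions 4--11; the design must be complete (every
#'   subject observed in every condition).
#' @return Object of class `rank_anova`: tibble `parameter`, `effect`
#'   (`environment`, `saccade_task`, `environment:saccade_task`), `df`,
#'   `df_error`, `statistic` (F on ranks), `p_value`.
#' @examples
#' tab <- demo_long_table(n_subjects = 10, seed = 1)
#' rank_factorial_anova(tab)
#' @export
rank_factorial_anova <- function(table) {
  check_long_table(table)
  table <- table[table$condition %in% 4:11, ]
  fac <- condition_factors()
  table <- dplyr::left_join(table, fac, by = c(condition = "index"))
  res <- dplyr::group_by(table, .data$parameter) |>
    dplyr::group_modify(function(d, key) art_two_way(d)) |>
    dplyr::ungroup()
  class(res) <- c("rank_anova", class(res))
  res
}

art_two_way <- function(d) {
  d$subject <- factor(d$subject)
  d$A <- factor(d$environment, levels = c("2D", "3D", "VM", "SO"))
  d$B <- factor(d$saccade_task, levels = c("pro", "anti"))
  full <- tidyr::expand_grid(subject = levels(d$subject),
                             A = levels(d$A), B = levels(d$B))
  got <- dplyr::distinct(d[, c("subject", "A", "B")]) |>
    dplyr::mutate(subject = as.character(.data$subject),
                  A = as.character(.data$A), B = as.character(.data$B))
  miss <- dplyr::anti_join(full, got, by = c("subject", "A", "B"))
  if (nrow(miss) > 0) {
    abort(paste0("Incomplete design; missing cells: ",
                 paste(utils::head(paste0("subject ", miss$subject, " (",
                                          miss$A, ",", miss$B, ")"), 5),
                       collapse = "; ")))
  }
  cell <- stats::ave(d$value, d$A, d$B)
  mA <- stats::ave(d$value, d$A)
  mB <- stats::ave(d$value, d$B)
  mu <- mean(d$value)
  resid <- d$value - cell
  aligned <- list(
    environment = resid + (mA - mu),
    saccade_task = resid + (mB - mu),
    `environment:saccade_task` = resid + (cell - mA - mB + mu)
  )
  strata <- c(environment = "subject:A", saccade_task = "subject:B",
              `environment:saccade_task` = "subject:A:B")
  terms <- c(environment = "A", saccade_task = "B",
             `environment:saccade_task` = "A:B")
  purrr::map_dfr(names(aligned), function(eff) {
    # values equal to 10 significant digits are treated as tied so that
    # floating-point noise from the alignment means cannot break exact ties
    d$r <- rank(signif(aligned[[eff]], 10))
    fit <- aov(r ~ A * B + Error(subject / (A * B)), data = d)
    tab <- summary(fit)[[paste0("Error: ", strata[[eff]])]][[1]]
    row <- trimws(rownames(tab)) == terms[[eff]]
    ss <- tab$`Sum Sq`[row]
    f <- tab$`F value`[row]
    p <- tab$`Pr(>F)`[row]
    if (is.finite(ss) && ss <= 1e-8 * max(1, sum(tab$`Sum Sq`))) {
      f <- 0; p <- 1  # no effect variation at all on the aligned ranks
    }
    tibble::tibble(
      effect = eff,
      df = tab$Df[row], df_error = tab$Df[trimws(rownames(tab)) == "Residuals"],
      statistic = f, p_value = p
    )
  })
}

#' Friedman cross-check of the factorial main effects
#'
#' Collapses the 4x2 within-subject design over the other factor (cell means
#' per subject x level) and applies Friedman's test per factor — a simpler
#' nonparametric check on the aligned-rank ANOVA's main effects.
#'
#' @inheritParams rank_factorial_anova
#' @return Tibble: `parameter`, `effect`, `statistic` (chi-squared), `df`,
#'   `p_value`.
#' @export
friedman_main_effects <- function(table) {
  check_long_table(table)
  table <- table[table$condition %in% 4:11, ]
  fac <- condition_factors()
  table <- dplyr::left_join(table, fac, by = c(condition = "index"))
  one <- function(d, factor_col) {
    agg <- dplyr::summarise(
      dplyr::group_by(d, .data$subject, level = .data[[factor_col]]),
      value = mean(.data$value), .groups = "drop"
    )
    ft <- friedman.test(value ~ level | subject,
                        data = as.data.frame(agg))
    tibble::tibble(effect = factor_col,
                   statistic = unname(ft$statistic),
                   df = unname(ft$parameter), p_value = ft$p.value)
  }
  dplyr::group_by(table, .data$parameter) |>
    dplyr::group_modify(function(d, key) {
      dplyr::bind_rows(one(d, "environment"), one(d, "saccade_task"))
    }) |>
    dplyr::ungroup()
}

#' Wilcoxon signed-rank test with effect size
#'
#' Paired signed-rank test returning, besides the exact or approximate
#' p value, the standardized statistic Z and the effect size
#' `r = |Z| / sqrt(n_pairs)`. Zero differences are dropped by Wilcoxon's
#' original rule (default) or kept under Pratt's method; the exact p value
#' (from the null signed-rank distribution) is used for `n <= exact_limit`
#' untied nonzero differences, otherwise a tie- and zero-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y Paired numeric vectors.
#' @param zero_method `"wilcox"` (drop zero differences) or `"pratt"`.
#' @param exact_limit Largest n for the exact null distribution (default 25).
#' @return One-row tibble: `n_pairs`, `n_used`, `statistic` (W+), `z`,
#'   `p_value`, `effect_size`, `magnitude` (`none` < 0.1 <= `small` < 0.3 <=
#'   `moderate` < 0.5 <= `large`), `method`, `degenerate` (all differences
#'   zero).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), c(1, 1, 2, 3, 4, 5))
#' @export
wilcoxon_signed_rank <- function(x, y, zero_method = c("wilcox", "pratt"),
                                 exact_limit = 25) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  d <- (x - y)[keep]
  n_pairs <- length(d)
  if (n_pairs == 0) abort("No complete pairs.")
  if (all(d == 0)) {
    return(tibble::tibble(n_pairs = n_pairs, n_used = 0L, statistic = 0,
                          z = 0, p_value = 1, effect_size = 0,
                          magnitude = "none", method = "degenerate",
                          degenerate = TRUE))
  }
  if (zero_method == "wilcox") {
    dz <- d[d != 0]
    n <- length(dz)
    rk <- rank(abs(dz))
    W <- sum(rk[dz > 0])
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    has_ties <- any(tie_tab > 1)
  } else {
    n <- length(d)
    rk <- rank(abs(d))
    W <- sum(rk[d > 0])
    n0 <- sum(d == 0)
    mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
    tie_tab <- table(rk[d != 0])
    sigma2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    has_ties <- any(tie_tab > 1)
  }
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  exact_ok <- zero_method == "wilcox" && !has_ties && n <= exact_limit && n > 0
  if (exact_ok) {
    p <- min(1, 2 * min(psignrank(W, n), 1 - psignrank(W - 1, n)))
    method <- "exact"
  } else {
    cc <- sign(W - mu) * 0.5
    zc <- if (sigma2 > 0) (W - mu - cc) / sqrt(sigma2) else 0
    p <- min(1, 2 * stats::pnorm(-abs(zc)))
    method <- "normal approximation"
  }
  r <- abs(z) / sqrt(n_pairs)
  tibble::tibble(n_pairs = n_pairs, n_used = as.integer(n), statistic = W,
                 z = z, p_value = p, effect_size = r,
                 magnitude = es_magnitude(r), method = method,
                 degenerate = FALSE)
}

es_magnitude <- function(r) {
  dplyr::case_when(
    r >= 0.5 ~ "large",
    r >= 0.3 ~ "moderate",
    r >= 0.1 ~ "small",
    TRUE ~ "none"
  )
}

#' Default pairwise comparison scheme over conditions 4--11
#'
#' Same saccade task across environments (all environment pairs within pro
#' and within anti) plus pro vs anti within each environment — the
#' post hoc scheme of the factorial battery.
#'
#' @return Tibble with columns `condition_a`, `condition_b`.
#' @export
default_condition_pairs <- function() {
  pro <- c(4, 6, 8, 10)
  anti <- c(5, 7, 9, 11)
  env_pairs <- function(v) {
    cmb <- utils::combn(v, 2)
    tibble::tibble(condition_a = cmb[1, ], condition_b = cmb[2, ])
  }
  dplyr::bind_rows(
    env_pairs(pro), env_pairs(anti),
    tibble::tibble(condition_a = pro, condition_b = anti)
  )
}

#' Pairwise Wilcoxon signed-rank tests with Holm adjustment
#'
#' Runs [wilcoxon_signed_rank()] for each condition pair and parameter,
#' pairing observations by subject, and adjusts p values within each
#' parameter's family of comparisons (Holm by default).
#'
#' @param table Long table (see [check_distributions()]).
#' @param pairs Data frame with `condition_a`, `condition_b`; defaults to
#'   [default_condition_pairs()].
#' @param adjust Adjustment method passed to [adjust_p()].
#' @param zero_method Passed to [wilcoxon_signed_rank()].
#' @return Tibble of class `pairwise_wilcoxon`: `parameter`, `condition_a`,
#'   `condition_b`, `n_pairs`, `statistic`, `z`, `p_raw`, `p_adjusted`,
#'   `effect_size`, `magnitude`, `method`.
#' @examples
#' tab <- demo_long_table(n_subjects = 10, seed = 1)
#' wilcoxon_pairwise(tab)
#' @export
wilcoxon_pairwise <- function(table, pairs = NULL, adjust = "holm",
                              zero_method = "wilcox") {
  check_long_table(table)
  pairs <- pairs %||% default_condition_pairs()
  res <- purrr::map_dfr(unique(table$parameter), function(par) {
    dpar <- table[table$parameter == par, ]
    out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      a <- pairs$condition_a[i]; b <- pairs$condition_b[i]
      da <- dpar[dpar$condition == a, c("subject", "value")]
      db <- dpar[dpar$condition == b, c("subject", "value")]
      m <- dplyr::inner_join(da, db, by = "subject",
                             suffix = c("_a", "_b"))
      w <- wilcoxon_signed_rank(m$value_a, m$value_b,
                                zero_method = zero_method)
      tibble::tibble(parameter = par, condition_a = a, condition_b = b,
                     n_pairs = w$n_pairs, statistic = w$statistic, z = w$z,
                     p_raw = w$p_value, effect_size = w$effect_size,
                     magnitude = w$magnitude, method = w$method)
    })
    out$p_adjusted <- adjust_p(out$p_raw, method = adjust)
    out
  })
  res <- res[, c("parameter", "condition_a", "condition_b", "n_pairs",
                 "statistic", "z", "p_raw", "p_adjusted", "effect_size",
                 "magnitude", "method")]
  class(res) <- c("pairwise_wilcoxon", class(res))
  res
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] for the methods used by the
#' post hoc battery: Holm step-down (default), Bonferroni, and
#' Benjamini-Hochberg.
#'
#' @param p_values Numeric vector of raw p values in `[0, 1]`.
#' @param method `"holm"`, `"bonferroni"` or `"bh"`.
#' @return Adjusted p values (same length and order).
#' @examples
#' adjust_p(c(0.01, 0.04))                      # holm: 0.02, 0.04
#' adjust_p(c(0.02, 0.03, 0.04), "bonferroni")  # 0.06, 0.09, 0.12
#' @export
adjust_p <- function(p_values, method = c("holm", "bonferroni", "bh")) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1].")
  }
  p.adjust(p_values, method = c(holm = "holm", bonferroni = "bonferroni",
                                bh = "BH")[[method]])
}

#' Spearman association matrix within one condition
#'
#' Pairwise Spearman rank correlations (tie-corrected mid-ranks) between
#' measurement parameters across subjects within a single condition, with
#' two-sided p values and a 5% significance flag (unadjusted, matching the
#' usual highlighting of exploratory association grids). Constant columns
#' have undefined rank correlations and are masked with `NA`.
#'
#' @param table Long table (see [check_distributions()]).
#' @param condition Condition index or name.
#' @param parameters Optional character vector restricting/ordering the
#'   parameter set.
#' @param alpha Significance level for the flag. Default 0.05.
#' @return Object of class `assoc_matrix`: list with symmetric matrices
#'   `rho`, `p`, logical `significant`, the subject count `n`, and
#'   `condition`.
#' @examples
#' tab <- demo_long_table(n_subjects = 10, seed = 1)
#' spearman_matrix(tab, condition = 4)
#' @export
spearman_matrix <- function(table, condition, parameters = NULL,
                            alpha = 0.05) {
  check_long_table(table)
  cond <- as_condition(condition)
  d <- table[table$condition == cond$index, ]
  wide <- tidyr::pivot_wider(d[, c("subject", "parameter", "value")],
                             names_from = "parameter",
                             values_from = "value")
  parameters <- parameters %||% setdiff(names(wide), "subject")
  wide <- wide[, c("subject", parameters)]
  wide <- wide[complete.cases(wide), ]
  n <- nrow(wide)
  if (n < 5) abort("Need at least 5 complete subject rows.")
  k <- length(parameters)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(parameters, parameters))
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    p[i, i] <- 0
    for (j in seq_len(k)) {
      if (j <= i) next
      xi <- wide[[parameters[i]]]
      xj <- wide[[parameters[j]]]
      if (sd(xi) == 0 || sd(xj) == 0) next  # masked: rho undefined
      ct <- suppressWarnings(cor.test(xi, xj, method = "spearman",
                                      exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  out <- list(rho = rho, p = p, significant = !is.na(p) & p < alpha,
              n = n, condition = cond$name, alpha = alpha)
  class(out) <- "assoc_matrix"
  out
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat("<assoc_matrix> condition", x$condition, "-", x$n, "subjects\n")
  print(round(x$rho, 2))
  invisible(x)
}

#' @export
print.rank_anova <- function(x, ...) {
  cat("Aligned-rank-transform within-subject ANOVA\n")
  NextMethod()
}
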