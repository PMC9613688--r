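test_that("distribution checks flag variance homogeneity and normality", {
  # identical groups: Levene statistic 0, p = 1
  tab <- tibble::tibble(
    subject = rep(1:6, 2), condition = rep(4:5, each = 6),
    parameter = "latency_mean", value = rep(c(1, 2, 3, 4, 5, 6), 2)
  )
  out <- check_distributions(tab)
  expect_equal(out$levene_p, 1)
  expect_false(out$degenerate)

  # constant everything: degenerate
  const <- dplyr::mutate(tab, value = 1)
  expect_true(check_distributions(const)$degenerate)

  # normal residuals mostly pass Shapiro-Wilk, heavy tails mostly fail
  shapiro_p <- function(gen) {
    vapply(1:100, function(s) {
      withr::with_seed(s, {
        t1 <- tibble::tibble(subject = 1:50, condition = 4,
                             parameter = "x", value = gen(50))
      })
      check_distributions(t1)$shapiro_p
    }, numeric(1))
  }
  expect_gte(mean(shapiro_p(function(n) rnorm(n)) > 0.05), 0.9)
  expect_gte(mean(shapiro_p(function(n) rt(n, df = 1)) < 0.05), 0.9)
})

test_that("aligned-rank ANOVA detects a strong environment effect", {
  tab <- latency_table(20, seed = 1,
                       env_shift = c("2D" = 0, "3D" = 0,
                                     "VM" = 0.15, "SO" = 0.15))
  res <- rank_factorial_anova(tab)
  env <- res[res$effect == "environment", ]
  expect_lt(env$p_value, 0.001)
  expect_equal(env$df, 3)
  expect_equal(env$df_error, 57)
  td <- tidy(res)
  expect_true(all(c("parameter", "effect", "p_value") %in% names(td)))
  g <- glance(res)
  expect_equal(g$n_effects, 3)
})

test_that("a factor with no effect on duplicated data gives p = 1", {
  # values identical across task levels within subject x environment
  withr::with_seed(2, {
    base <- tidyr::expand_grid(subject = 1:10, environment = c("2D", "3D", "VM", "SO"))
    base$value <- rnorm(nrow(base)) + base$subject / 10
  })
  fac <- condition_factors()
  tab <- dplyr::left_join(fac, base, by = "environment",
                          relationship = "many-to-many")
  tab <- tibble::tibble(subject = tab$subject, condition = tab$index,
                        parameter = "x", value = tab$value)
  res <- rank_factorial_anova(tab)
  expect_equal(res$p_value[res$effect == "saccade_task"], 1, tolerance = 1e-9)
})

test_that("incomplete factorial designs are rejected with cell listing", {
  tab <- latency_table(6, seed = 3)
  tab <- tab[!(tab$subject == 2 & tab$condition == 9), ]
  expect_error(rank_factorial_anova(tab), "subject 2")
})

test_that("Friedman cross-check agrees qualitatively with the ART", {
  tab <- latency_table(20, seed = 4,
                       env_shift = c("2D" = 0, "3D" = 0,
                                     "VM" = 0.15, "SO" = 0.15))
  fr <- friedman_main_effects(tab)
  expect_lt(fr$p_value[fr$effect == "environment"], 0.001)
  art <- rank_factorial_anova(tab)
  expect_lt(art$p_value[art$effect == "environment"], 0.001)
})

test_that("exact signed-rank p matches hand enumeration and wilcox.test", {
  # n = 6, all differences positive: two-sided p = 2/64
  x <- c(2, 4, 7, 11, 16, 22); y <- c(1, 2, 4, 7, 11, 16)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$p_value, 2 / 64)
  expect_equal(w$method, "exact")
  expect_equal(w$p_value, wilcox.test(x, y, paired = TRUE)$p.value)

  # enumeration oracle over random untied datasets, n <= 10
  withr::with_seed(10, {
    for (i in 1:100) {
      n <- sample(3:10, 1)
      d <- round(rnorm(n), 6) + (1:n) * 1e-8  # no ties, no zeros
      a <- rnorm(n)
      w <- wilcoxon_signed_rank(a + d, a)
      expect_equal(w$p_value, wilcoxon_enum_p(d), tolerance = 1e-12)
    }
  })
})

test_that("tied and zero-laden data fall back to the corrected normal", {
  x <- c(1, 2, 2, 3, 3, 3, 5, 5, 6, 7)
  y <- c(2, 1, 2, 1, 1, 1, 2, 2, 2, 2)
  w <- wilcoxon_signed_rank(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_equal(w$method, "normal approximation")
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)

  z <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
  expect_equal(z$effect_size, 0)
  expect_equal(z$magnitude, "none")

  pr <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3) + 1:5, 1:5,
                             zero_method = "pratt")
  expect_equal(pr$n_used, 5L)
})

test_that("effect-size magnitudes reproduce the published thresholds", {
  expect_equal(oculosway:::es_magnitude(0.58), "large")
  expect_equal(oculosway:::es_magnitude(0.44), "moderate")
  expect_equal(oculosway:::es_magnitude(0.15), "small")
  expect_equal(oculosway:::es_magnitude(0.05), "none")
  expect_equal(oculosway:::es_magnitude(c(0.5, 0.3, 0.1)),
               c("large", "moderate", "small"))
})

test_that("p-value adjustment matches hand-computed references", {
  expect_equal(adjust_p(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(adjust_p(c(0.02, 0.03, 0.04), "bonferroni"),
               c(0.06, 0.09, 0.12))
  expect_equal(adjust_p(0.03), 0.03)
  expect_equal(adjust_p(numeric(0)), numeric(0))
  expect_error(adjust_p(c(0.5, 1.2)), "0, 1")
  # Holm properties: never below raw, capped at 1, monotone in rank order
  withr::with_seed(20, {
    for (i in 1:25) {
      p <- runif(sample(2:12, 1))
      h <- adjust_p(p)
      expect_true(all(h >= p - 1e-15))
      expect_true(all(h <= 1))
      expect_true(all(diff(h[order(p)]) >= -1e-15))
    }
  })
})

test_that("pairwise battery labels, adjusts, and respects the scheme", {
  tab <- demo_long_table(12, seed = 5)
  res <- wilcoxon_pairwise(tab)
  expect_s3_class(res, "pairwise_wilcoxon")
  pairs <- default_condition_pairs()
  expect_equal(nrow(pairs), 16)
  expect_equal(nrow(res), 16 * dplyr::n_distinct(tab$parameter))
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_equal(res$magnitude, oculosway:::es_magnitude(res$effect_size))
  # adjustment family is per parameter
  one <- res[res$parameter == "latency_mean", ]
  expect_equal(one$p_adjusted, adjust_p(one$p_raw))
  g <- glance(res)
  expect_equal(g$n_tests, nrow(res))
})

test_that("Spearman matrices honour monotone invariance and masking", {
  n <- 12
  withr::with_seed(6, x <- rnorm(n))
  tab <- dplyr::bind_rows(
    tibble::tibble(subject = 1:n, condition = 4, parameter = "a", value = x),
    tibble::tibble(subject = 1:n, condition = 4, parameter = "b",
                   value = x^3),
    tibble::tibble(subject = 1:n, condition = 4, parameter = "c",
                   value = -x),
    tibble::tibble(subject = 1:n, condition = 4, parameter = "d", value = 1)
  )
  m <- spearman_matrix(tab, condition = 4)
  expect_equal(m$rho["a", "b"], 1)
  expect_equal(m$rho["a", "c"], -1)
  expect_true(is.na(m$rho["a", "d"]))  # constant column masked
  expect_equal(m$rho, t(m$rho))
  expect_equal(diag(m$rho), setNames(rep(1, 4), c("a", "b", "c", "d")))
  expect_true(m$significant["a", "b"])
  td <- tidy(m)
  expect_equal(nrow(td), 16)

  # tie-corrected rho equals the mid-rank Pearson definition
  withr::with_seed(7, {
    xt <- sample(1:4, n, replace = TRUE)
    yt <- sample(1:3, n, replace = TRUE)
  })
  tab2 <- dplyr::bind_rows(
    tibble::tibble(subject = 1:n, condition = 4, parameter = "a", value = xt),
    tibble::tibble(subject = 1:n, condition = 4, parameter = "b", value = yt)
  )
  m2 <- spearman_matrix(tab2, condition = 4)
  expect_equal(m2$rho["a", "b"], spearman_midrank(xt, yt), tolerance = 1e-12)

  expect_error(spearman_matrix(tab[tab$subject <= 4, ], condition = 4),
               "at least 5")
})
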