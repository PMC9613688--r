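mk_cop <- function(t, x, y, rate = NULL) {
  if (is.null(rate)) rate <- 1 / median(diff(t))
  tibble::new_tibble(list(t = t, x_ml = x, y_ap = y), nrow = length(t),
                     class = "cop_trace", sample_rate = rate)
}

test_that("hull area matches closed forms for simple polygons", {
  expect_equal(convex_envelope_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))), 1)
  hexa <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
  expect_equal(convex_envelope_area(hexa), 3 * sqrt(3) / 2, tolerance = 1e-12)
  # interior points do not change the hull
  expect_equal(convex_envelope_area(rbind(hexa, c(0, 0), c(0.1, 0.2))),
               3 * sqrt(3) / 2, tolerance = 1e-12)
})

test_that("degenerate point sets enclose zero area", {
  expect_equal(convex_envelope_area(cbind(1, 2)), 0)
  expect_equal(convex_envelope_area(cbind(c(0, 1, 2), c(0, 1, 2))), 0)
  expect_equal(convex_envelope_area(cbind(rep(3, 5), rep(-1, 5))), 0)
  expect_error(convex_envelope_area(cbind(c(0, NA), c(1, 2))), "finite")
})

test_that("hull area equals brute-force and chull oracles on random sets", {
  withr::with_seed(42, {
    for (i in 1:20) {
      pts <- cbind(rnorm(50), rnorm(50))
      mine <- convex_envelope_area(pts)
      expect_equal(mine, brute_hull_area(pts), tolerance = 1e-10)
      ch <- chull(pts)
      expect_equal(mine,
                   abs(sum(pts[ch, 1] * pts[c(ch[-1], ch[1]), 2] -
                             pts[c(ch[-1], ch[1]), 1] * pts[ch, 2])) / 2,
                   tolerance = 1e-10)
    }
  })
})

test_that("straight-line trajectory: pure AP speed, zero area", {
  t <- seq(0, 10, by = 0.01)
  tr <- mk_cop(t, rep(0, length(t)), 10 * t)
  pm <- compute_posture_metrics(tr)
  expect_equal(pm$speed_total, 10)
  expect_equal(pm$speed_ap, 10)
  expect_equal(pm$speed_ml, 0)
  expect_equal(pm$aec, 0)
  expect_true(pm$degenerate)
})

test_that("circle trajectory recovers analytic area and speed", {
  n <- 1000
  t <- (0:(n - 1)) / n * 20
  th <- 2 * pi * t / 20
  tr <- mk_cop(t, 10 * cos(th), 10 * sin(th))
  pm <- compute_posture_metrics(tr)
  expect_equal(pm$aec, pi * 100, tolerance = 1e-3)
  expect_equal(pm$speed_total, 2 * pi * 10 / 20, tolerance = 1e-3)
})

test_that("sinusoidal AP sway has RMS amplitude a/sqrt(2)", {
  t <- seq(0, 30, by = 0.005)
  a <- 4
  tr <- mk_cop(t, rep(0, length(t)), a * sin(2 * pi * 0.8 * t))
  pm <- compute_posture_metrics(tr)
  expect_equal(pm$sd_ap, a / sqrt(2), tolerance = 0.01)
})

test_that("metrics transform correctly under rigid motions and axis swap", {
  withr::with_seed(7, {
    t <- seq(0, 30, by = 0.01)
    x <- cumsum(rnorm(length(t), 0, 0.1))
    y <- cumsum(rnorm(length(t), 0, 0.1))
  })
  base <- compute_posture_metrics(mk_cop(t, x, y))
  shifted <- compute_posture_metrics(mk_cop(t, x + 100, y - 50))
  expect_equal(shifted[, 1:6], base[, 1:6])

  phi <- 0.7
  rot <- compute_posture_metrics(
    mk_cop(t, cos(phi) * x - sin(phi) * y, sin(phi) * x + cos(phi) * y))
  expect_equal(rot$aec, base$aec)
  expect_equal(rot$speed_total, base$speed_total)

  swap <- compute_posture_metrics(mk_cop(t, y, x))
  expect_equal(swap$sd_ml, base$sd_ap)
  expect_equal(swap$sd_ap, base$sd_ml)
  expect_equal(swap$speed_ml, base$speed_ap)
})

test_that("hull area is monotone as points accumulate", {
  withr::with_seed(3, {
    pts <- cbind(rnorm(200), rnorm(200))
    areas <- vapply(seq(10, 200, by = 10),
                    function(k) convex_envelope_area(pts[1:k, ]), numeric(1))
    expect_true(all(diff(areas) >= -1e-12))
  })
})

test_that("path speed of a smooth trajectory is sampling-rate stable", {
  speed_at <- function(dt) {
    t <- seq(0, 20, by = dt)
    th <- 2 * pi * t / 20
    compute_posture_metrics(mk_cop(t, 10 * cos(th), 10 * sin(th)))$speed_total
  }
  expect_lt(abs(speed_at(0.005) / speed_at(0.01) - 1), 0.01)
})

test_that("analysis window restricts the metrics", {
  t <- seq(0, 10, by = 0.01)
  tr <- mk_cop(t, ifelse(t < 5, 0, 50), 0 * t)
  pm <- compute_posture_metrics(tr, window = c(0, 4.99))
  expect_equal(pm$speed_total, 0)
  expect_equal(pm$duration, 4.99, tolerance = 0.01)
  expect_error(compute_posture_metrics(tr[1, ]), "2 samples")
})

test_that("simulated sway recovers the stationary SD through the metrics", {
  s <- subject_model(cop_relaxation = 1, cop_diffusion = 2)
  cop <- simulate_cop(600, s, 100, seed = 11)
  pm <- compute_posture_metrics(cop)
  expect_lt(abs(pm$sd_ml - 1), 0.1)
  expect_lt(abs(pm$sd_ap - 1), 0.1)
})
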