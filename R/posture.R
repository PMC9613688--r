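#' Convex envelope (hull) area of a 2-D point set
#'
#' Builds the convex hull by the monotone-chain (Andrew) construction and
#' returns its area by the shoelace formula. This implements the sway "area
#' of envelope curve" (AEC) as the convex-hull area of the COP trajectory,
#' the standard outer-envelope convention in stabilometry. Fewer than three
#' non-collinear points enclose no area and return 0.
#'
#' @param points A two-column matrix or data frame of coordinates (mm); for
#'   data frames the columns `x_ml`/`y_ap` are used when present, otherwise
#'   the first two columns.
#' @return Area in mm^2.
#' @examples
#' convex_envelope_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square
#' @export
convex_envelope_area <- function(points) {
  xy <- as_xy(points)
  h <- convex_hull(xy)
  if (nrow(h) < 3) return(0)
  shoelace(h[, 1], h[, 2])
}

#' Convex hull vertices (monotone chain)
#'
#' @inheritParams convex_envelope_area
#' @return Matrix of hull vertices in counter-clockwise order (no repeated
#'   closing point). Degenerate inputs return the distinct extreme points.
#' @export
convex_hull <- function(points) {
  xy <- as_xy(points)
  xy <- unique(xy[order(xy[, 1], xy[, 2]), , drop = FALSE])
  n <- nrow(xy)
  if (n <= 2) return(xy)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    out <- integer(0)
    for (i in idx) {
      while (length(out) >= 2 &&
             cross(xy[out[length(out) - 1], ], xy[out[length(out)], ],
                   xy[i, ]) <= 0) {
        out <- out[-length(out)]
      }
      out <- c(out, i)
    }
    out
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  xy[hull, , drop = FALSE]
}

as_xy <- function(points) {
  if (is.data.frame(points)) {
    cols <- if (all(c("x_ml", "y_ap") %in% names(points))) {
      c("x_ml", "y_ap")
    } else names(points)[1:2]
    points <- as.matrix(points[, cols])
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2) abort("`points` must have two coordinate columns.")
  if (!all(is.finite(points))) abort("`points` must be finite.")
  points
}

shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Posturography metrics of a COP trace
#'
#' Computes the standing-balance dependent variables from a centre-of-
#' pressure trajectory: per-axis sample SD of displacement (`sd_ml`,
#' `sd_ap`), mean sway speed as total path length over duration
#' (`speed_total`, with per-axis variants summing absolute axis steps), and
#' the sway area of the envelope curve (`aec`) as the convex-hull area of
#' the windowed trajectory.
#'
#' @param trace A `cop_trace` tibble (`t`, `x_ml`, `y_ap`) in mm.
#' @param window Optional `c(start, end)` analysis window in seconds (e.g.
#'   the posture-recording span that starts after the practice trials);
#'   `NULL` uses the full trace.
#' @return One-row tibble: `sd_ml`, `sd_ap` (mm), `speed_total`, `speed_ml`,
#'   `speed_ap` (mm/s), `aec` (mm^2), `duration` (s), `n_samples`,
#'   `degenerate` (`TRUE` when fewer than 3 non-collinear points: `aec` 0).
#' @examples
#' cop <- simulate_cop(60, subject_model(), 100, seed = 1)
#' compute_posture_metrics(cop)
#' @export
compute_posture_metrics <- function(trace, window = NULL) {
  stopifnot(all(c("t", "x_ml", "y_ap") %in% names(trace)))
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[2] > window[1])
    trace <- trace[trace$t >= window[1] & trace$t <= window[2], ]
  }
  n <- nrow(trace)
  if (n < 2) abort("Need at least 2 samples in the analysis window.")
  duration <- trace$t[n] - trace$t[1]
  dx <- diff(trace$x_ml)
  dy <- diff(trace$y_ap)
  aec <- convex_envelope_area(cbind(trace$x_ml, trace$y_ap))
  hull_n <- nrow(convex_hull(cbind(trace$x_ml, trace$y_ap)))
  tibble::tibble(
    sd_ml = sd(trace$x_ml),
    sd_ap = sd(trace$y_ap),
    speed_total = sum(sqrt(dx^2 + dy^2)) / duration,
    speed_ml = sum(abs(dx)) / duration,
    speed_ap = sum(abs(dy)) / duration,
    aec = aec,
    duration = duration,
    n_samples = n,
    degenerate = hull_n < 3
  )
}
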