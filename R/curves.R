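#' Piecewise-linear plasticity curve
#'
#' The hypothesis object of the curve-induction analysis: a three-segment
#' piecewise-linear function on the normalized evidence axis `[-1, 1]`.
#' Knot x-positions are `(-1, x1, x2, 1)` with `-1 <= x1 <= x2 <= 1`; knot
#' heights are each in `[-1, 1]`.
#'
#' @param knot_x Numeric length 4, sorted, first `-1` and last `1`.
#' @param knot_y Numeric length 4, each in `[-1, 1]`.
#' @return A `plasticity_curve` object.
#' @examples
#' u <- plasticity_curve(c(-1, -0.2, 0.2, 1), c(0.8, -0.8, -0.8, 0.8))
#' curve_eval(u, c(-1, 0, 1))
#' curve_consistency(u) # TRUE: drops below its start, then rises
#' @export
plasticity_curve <- function(knot_x, knot_y) {
  stopifnot(length(knot_x) == 4, length(knot_y) == 4)
  if (knot_x[1] != -1 || knot_x[4] != 1 || is.unsorted(knot_x)) {
    stop_pcitr("knot_x must be sorted with endpoints -1 and 1",
               "pcitr_bad_curve")
  }
  if (any(knot_y < -1 | knot_y > 1)) {
    stop_pcitr("knot_y values must lie in [-1, 1]", "pcitr_bad_curve")
  }
  structure(list(knot_x = as.numeric(knot_x), knot_y = as.numeric(knot_y)),
            class = "plasticity_curve")
}

#' @export
print.plasticity_curve <- function(x, ...) {
  cat("<plasticity_curve>\n")
  cat("  x:", format(x$knot_x, digits = 3), "\n")
  cat("  y:", format(x$knot_y, digits = 3), "\n")
  invisible(x)
}

# internal: one curve as a 6-vector (x1, x2, y0..y3); curve sets are
# n x 6 matrices with these columns
CURVE_COLS <- c("x1", "x2", "y0", "y1", "y2", "y3")

curve_to_row <- function(curve) {
  c(curve$knot_x[2], curve$knot_x[3], curve$knot_y)
}

row_to_curve <- function(row) {
  plasticity_curve(c(-1, row[1], row[2], 1), row[3:6])
}

#' Sample plasticity curves from the prior
#'
#' The prior draws interior knot x-positions as the order statistics of two
#' independent Uniform(-1, 1) variates and all four knot heights as i.i.d.
#' Uniform(-1, 1). Under this prior exactly half the probability mass is
#' theory-consistent (the minimum height must fall on an interior knot).
#'
#' @param n Number of curves.
#' @param seed Seed for the draw.
#' @return A tibble with columns `x1`, `x2`, `y0`, `y1`, `y2`, `y3`, one row
#'   per curve.
#' @export
sample_curves <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  with_stream_seed(seed, 0L, {
    xs <- matrix(runif(2 * n, -1, 1), ncol = 2)
    xs <- cbind(pmin(xs[, 1], xs[, 2]), pmax(xs[, 1], xs[, 2]))
    ys <- matrix(runif(4 * n, -1, 1), ncol = 4)
    out <- tibble::as_tibble(as.data.frame(cbind(xs, ys)),
                             .name_repair = "minimal")
    names(out) <- CURVE_COLS
    out
  })
}

#' Evaluate a plasticity curve
#'
#' Linear interpolation between knots; exact at knots. The evaluation
#' domain is `[-1, 1]`.
#'
#' @param curve A [plasticity_curve()].
#' @param x Evaluation points in `[-1, 1]`.
#' @return Numeric vector of curve values.
#' @export
curve_eval <- function(curve, x) {
  stopifnot(inherits(curve, "plasticity_curve"))
  if (any(x < -1 | x > 1)) {
    stop_pcitr("evaluation points must lie in [-1, 1]", "pcitr_domain")
  }
  approx(curve$knot_x, curve$knot_y, xout = x, ties = "ordered")$y
}

# internal: evaluate a curve matrix (n x 6) at points x -> length(x) x n
# (compiled kernel; approx() over the knots is the reference in tests)
eval_curves <- function(curves, x) {
  cpp_eval_curves(as.matrix(curves), as.numeric(x))
}

#' Theory-consistency label for plasticity curves
#'
#' A curve is consistent with the non-monotonic plasticity hypothesis if it
#' is U-shaped: it drops strictly below its starting height, and after the
#' first knot attaining the minimum it rises strictly above that minimum.
#' Because the curve is piecewise linear, extrema occur at knots, so the
#' label depends only on the four knot heights.
#'
#' @param curves A [plasticity_curve()], or a curve tibble/matrix from
#'   [sample_curves()].
#' @return Logical vector, one label per curve.
#' @export
curve_consistency <- function(curves) {
  if (inherits(curves, "plasticity_curve")) {
    curves <- matrix(curve_to_row(curves), nrow = 1)
  }
  y <- as.matrix(curves)[, 3:6, drop = FALSE]
  n <- nrow(y)
  out <- logical(n)
  mins <- pmin(y[, 1], y[, 2], y[, 3], y[, 4])
  amin <- max.col(-y, ties.method = "first") # first knot attaining the min
  drops <- mins < y[, 1]
  for (j in 1:3) {
    idx <- amin == j
    if (any(idx)) {
      rises <- rep(FALSE, sum(idx))
      after <- y[idx, (j + 1):4, drop = FALSE]
      rises <- apply(after > mins[idx], 1, any)
      out[idx] <- drops[idx] & rises
    }
  }
  # amin == 4: nothing after the minimum, never consistent
  out
}

#' Rescale evidence scores to the curve domain
#'
#' Affine map sending the pooled minimum to -1 and the pooled maximum to 1,
#' applied once over all scores entering an analysis so the `[-1, 1]` curve
#' domain always spans the analyzed data.
#'
#' @param scores Numeric vector with at least two distinct values.
#' @return Rescaled scores in `[-1, 1]`.
#' @export
rescale_evidence <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 2)
  rng <- range(scores)
  if (diff(rng) < 1e-12 * max(1, abs(rng[2]))) {
    stop_pcitr("evidence scores are constant; cannot rescale to [-1, 1]",
               "pcitr_constant_evidence")
  }
  2 * (scores - rng[1]) / diff(rng) - 1
}

#' Partial one evidence score out of another
#'
#' Ordinary least-squares residuals of `target` on `covariate` (with
#' intercept), rescaled to `[-1, 1]`. Used to ask whether one learning
#' window's evidence predicts memory beyond what the other window explains.
#' A constant covariate degenerates to the centered target (documented
#' fallback).
#'
#' @param target,covariate Equal-length numeric vectors (length >= 3).
#' @param rescale Rescale residuals to `[-1, 1]` (default `TRUE`).
#' @return Residualized (and rescaled) scores.
#' @export
partial_out <- function(target, covariate, rescale = TRUE) {
  stopifnot(length(target) == length(covariate), length(target) >= 3)
  if (sd(covariate) < 1e-12) {
    res <- target - mean(target)
  } else {
    res <- unname(residuals(lm(target ~ covariate)))
  }
  if (rescale) rescale_evidence(res) else res
}
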