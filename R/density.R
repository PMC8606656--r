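#' Gaussian kernel configuration
#'
#' Bandwidth and normalization for the isotropic Gaussian kernel used by all
#' density estimates. The normalization constant is the standard Gaussian
#' factor `c_d = (2*pi)^(-d/2)`; for the planar case `d = 2` this is
#' `1/(2*pi)`. The constant only fixes the absolute scale of reported
#' densities -- it cancels in the supervised mean-shift vector.
#'
#' @param h Kernel bandwidth in pixels; must be positive.
#' @param d Dimension of the coordinate space (fixed at 2 for gaze data).
#' @return A list of class `kernel_config` with fields `h`, `d`, `c_d`.
#' @examples
#' cfg <- kernel_config(h = 30)
#' cfg$c_d  # 1/(2*pi)
#' @export
kernel_config <- function(h, d = 2L) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("bandwidth h must be a single positive number")
  if (d != 2L) stop("only d = 2 is supported")
  structure(list(h = as.numeric(h), d = 2L, c_d = (2 * pi)^(-d / 2)),
            class = "kernel_config")
}

# Raw Gaussian kernel weights exp(-||x - x_i||^2 / (2 h^2)) of one query
# against a point matrix. Max-exponent stabilization is unnecessary for the
# Gaussian (exponents are <= 0), so weights are exact.
kernel_weights_ <- function(x, points, h) {
  d2 <- (points[, 1L] - x[1L])^2 + (points[, 2L] - x[2L])^2
  exp(-d2 / (2 * h * h))
}

#' Kernel density estimate at a query point
#'
#' Evaluates `c_d / (N_total * h^d) * sum_i exp(-||x - x_i||^2 / (2 h^2))`
#' over the supplied points. When the points are a class subset of a larger
#' training set, `n_total` must be the size of the *full* set: both class
#' densities share the divisor `N`, which makes their difference
#' proportional to the signed difference of class counts in a local window.
#'
#' @param x Query point, numeric length-2 (pixels).
#' @param points An n x 2 matrix of support points; an empty set yields 0.
#' @param cfg A [kernel_config()].
#' @param n_total Divisor count; defaults to `nrow(points)`.
#' @return A non-negative density value.
#' @export
kde <- function(x, points, cfg, n_total = NULL) {
  stopifnot(inherits(cfg, "kernel_config"))
  stop_if_not_finite_(x, "query point")
  if (is.null(points) || NROW(points) == 0L) return(0)
  points <- as_points_(points)
  if (is.null(n_total)) n_total <- nrow(points)
  w <- kernel_weights_(as.numeric(x), points, cfg$h)
  cfg$c_d / (n_total * cfg$h^cfg$d) * sum(w)
}

#' Signed and absolute quality of a candidate dictionary word
#'
#' The signed quality is the difference between the positive-class and
#' negative-class kernel density estimates (both divided by the full
#' training count `N`), `Q*(x) = p(x | X+) - p(x | X-)`. Its absolute value
#' is the continuous surrogate of word quality (purity times coverage): the
#' landscape of the quality objective equals `|Q*|`.
#'
#' @param x Query point(s): length-2 vector or n x 2 matrix.
#' @param data A [fixation_data()] frame.
#' @param cfg A [kernel_config()].
#' @return A list with numeric `q_signed` and `q_abs` (one entry per query).
#' @export
quality_signed <- function(x, data, cfg) {
  stopifnot(inherits(cfg, "kernel_config"))
  xs <- as_points_(x)
  stop_if_not_finite_(xs, "query point")
  pts <- fixation_points(data)
  pos <- data$label == 1L
  n <- nrow(pts)
  scale <- cfg$c_d / (n * cfg$h^cfg$d)
  q <- vapply(seq_len(nrow(xs)), function(i) {
    w <- kernel_weights_(xs[i, ], pts, cfg$h)
    scale * (sum(w[pos]) - sum(w[!pos]))
  }, numeric(1))
  list(q_signed = q, q_abs = abs(q))
}

#' Kernel-weighted mean of a point set
#'
#' The weighted mean `sum_i w_i x_i / sum_i w_i` with Gaussian kernel
#' weights centred at the query -- the fixed-point map of conventional mean
#' shift. Signals an error when the query is isolated (total weight below
#' `1e-300`), in which case the caller should freeze the kernel.
#'
#' @inheritParams kde
#' @return A length-2 numeric point.
#' @export
weighted_mean <- function(x, points, cfg) {
  stopifnot(inherits(cfg, "kernel_config"))
  points <- as_points_(points)
  if (!nrow(points)) stop("weighted_mean needs a non-empty point set")
  x <- as.numeric(x)
  stop_if_not_finite_(x, "query point")
  w <- kernel_weights_(x, points, cfg$h)
  sw <- sum(w)
  if (!is.finite(sw) || sw < 1e-300)
    stop("isolated query: total kernel weight underflows; freeze the kernel")
  c(sum(w * points[, 1L]), sum(w * points[, 2L])) / sw
}

#' Analytic gradient of the signed quality surface
#'
#' `grad Q*(x) = (1/h^2) [ p(x|X+) (xm+ - x) - p(x|X-) (xm- - x) ]` where
#' `xm+`/`xm-` are the kernel-weighted class means. A weighted combination
#' of the per-class mean-shift vectors, weighted by the class densities.
#'
#' @inheritParams quality_signed
#' @return Length-2 numeric gradient vector.
#' @export
grad_quality_signed <- function(x, data, cfg) {
  stopifnot(inherits(cfg, "kernel_config"))
  x <- as.numeric(x)
  stop_if_not_finite_(x, "query point")
  pts <- fixation_points(data)
  pos <- data$label == 1L
  n <- nrow(pts)
  scale <- cfg$c_d / (n * cfg$h^cfg$d)
  w <- kernel_weights_(x, pts, cfg$h)
  term <- function(keep) {
    sw <- sum(w[keep])
    if (sw < 1e-300) return(c(0, 0))
    xm <- c(sum(w[keep] * pts[keep, 1L]), sum(w[keep] * pts[keep, 2L])) / sw
    (scale * sw) * (xm - x)
  }
  (term(pos) - term(!pos)) / cfg$h^2
}

#' Supervised mean-shift vector
#'
#' The label-signed mean-shift step
#' `m(x) = sum_i y_i k(x, x_i) x_i / sum_i y_i k(x, x_i) - x`, together with
#' the signed kernel-weight sum `s = sum_i y_i k(x, x_i)`. The sign of `s`
#' equals the sign of the signed quality (`s = N h^d Q*(x) / c_d`), so
#' iterating `x + m(x)` ascends `Q*` where it is positive and descends it
#' where it is negative -- dual mode seeking without explicit sign
#' dispatch. When `|s|` falls below `eps_den` (a balanced-density region,
#' where the step would blow up) the function signals an error; the seeking
#' loop then falls back to a normalized gradient step.
#'
#' @inheritParams quality_signed
#' @param eps_den Denominator floor, relative to the maximum single kernel
#'   weight at the query; default `1e-12`.
#' @return A list with `m` (length-2 shift vector) and `s` (signed
#'   kernel-weight sum).
#' @export
supervised_shift_vector <- function(x, data, cfg, eps_den = 1e-12) {
  stopifnot(inherits(cfg, "kernel_config"))
  x <- as.numeric(x)
  stop_if_not_finite_(x, "query point")
  pts <- fixation_points(data)
  pos <- data$label == 1L
  w <- kernel_weights_(x, pts, cfg$h)
  if (max(w, 0) < 1e-300)
    stop("isolated query: total kernel weight underflows; freeze the kernel")
  s <- sum(w[pos]) - sum(w[!pos])
  if (abs(s) < eps_den * max(w))
    stop("balanced-density region: |sum y_i k| below floor; use a normalized gradient step")
  num <- c(sum(w[pos] * pts[pos, 1L]) - sum(w[!pos] * pts[!pos, 1L]),
           sum(w[pos] * pts[pos, 2L]) - sum(w[!pos] * pts[!pos, 2L]))
  list(m = num / s - x, s = s)
}
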