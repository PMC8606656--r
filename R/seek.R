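#' Mode-seeking configuration
#'
#' Iteration controls shared by dual mode seeking and the conventional
#' mean-shift and density-ratio variants.
#'
#' @param max_rounds Cap on accepted shift rounds; default 30.
#' @param tol Convergence displacement threshold in pixels. `NULL` (the
#'   default) resolves to `1e-3 * h` at seek time.
#' @param step_shrink Backtracking multiplier in (0, 1); each rejected step
#'   halves the step size by default.
#' @param max_backtracks Shrink attempts per round before the kernel is
#'   frozen at its current position.
#' @return A list of class `seek_config`.
#' @export
seek_config <- function(max_rounds = 30L, tol = NULL, step_shrink = 0.5,
                        max_backtracks = 20L) {
  stopifnot(max_rounds >= 1L, step_shrink > 0, step_shrink < 1,
            max_backtracks >= 0L)
  if (!is.null(tol)) stopifnot(is.numeric(tol), tol > 0)
  structure(list(max_rounds = as.integer(max_rounds), tol = tol,
                 step_shrink = step_shrink,
                 max_backtracks = as.integer(max_backtracks)),
            class = "seek_config")
}

resolve_tol_ <- function(seek, cfg) {
  if (is.null(seek$tol)) 1e-3 * cfg$h else seek$tol
}

# Shared driver over the compiled batch engine. mode: "dual", "classic",
# "ratio". Returns the raw engine result with objective values rescaled to
# density units (c_d / (N h^d)); for ratio mode values are the guarded
# density ratio itself.
run_seek_ <- function(inits, pts, labels, cfg, seek, mode, record) {
  inits <- as_points_(inits)
  stop_if_not_finite_(inits, "initial position")
  pts <- as_points_(pts)
  if (!nrow(pts)) stop("mode seeking needs a non-empty support set")
  tol <- resolve_tol_(seek, cfg)
  scale <- cfg$c_d / (nrow(pts) * cfg$h^cfg$d)
  cmode <- 0L
  eps_ratio <- 0
  if (mode == "classic") {
    labels <- rep(1L, nrow(pts))
  } else if (mode == "ratio") {
    cmode <- 1L
    neg <- pts[labels == -1L, , drop = FALSE]
    if (nrow(neg)) {
      eps_ratio <- 1e-8 * max(kde_sum_batch_cpp(pts, neg, cfg$h))
    }
    eps_ratio <- max(eps_ratio, 1e-300)
  }
  res <- seek_batch_cpp(inits, pts, as.integer(labels), cfg$h, cmode, tol,
                        seek$max_rounds, seek$step_shrink,
                        seek$max_backtracks, 1e-12, eps_ratio, record)
  if (mode != "ratio") {
    res$q <- res$q * scale
    res$q_signed <- res$q_signed * scale
    if (record) {
      res$trajectories <- lapply(res$trajectories, function(tr) {
        tr$q <- tr$q * scale
        tr$q_signed <- tr$q_signed * scale
        tr
      })
    }
  }
  res
}

traj_from_ <- function(res, k = 1L) {
  tr <- res$trajectories[[k]]
  if (res$failed[k])
    stop("non-finite position encountered during mode seeking (round ",
         res$rounds[k], "); last position: ",
         paste(signif(res$finals[k, ], 6), collapse = ", "))
  structure(list(positions = tr$positions, q_values = tr$q,
                 q_signed = tr$q_signed, converged = res$converged[k],
                 initial_sign = res$initial_sign[k], rounds = res$rounds[k]),
            class = "shift_trajectory")
}

#' Dual mode seeking from a single start
#'
#' Seeks a local extremum of the signed quality surface `Q*` by iterating
#' the supervised mean-shift vector. Because the shift denominator
#' `sum_i y_i k(x, x_i)` carries the sign of `Q*`, the same iteration
#' ascends `Q*` in positive-dominant regions and descends it in
#' negative-dominant ones, i.e. it ascends `|Q*|` everywhere. A step that
#' fails to increase `|Q*|` is shrunk by backtracking line search
#' (multiplying the step by `step_shrink`); in balanced-density regions the
#' shift is replaced by a gradient step normalized to length `tol`.
#' Accepted steps therefore have non-decreasing `|Q*|`, and the starting
#' sign of `Q*` is preserved.
#'
#' @param x0 Starting position (length-2, pixels).
#' @param data A [fixation_data()] frame supplying the class densities.
#' @param cfg A [kernel_config()].
#' @param seek A [seek_config()].
#' @return A `shift_trajectory`: `positions` (accepted positions, first row
#'   is `x0`), `q_values` (`|Q*|`, non-decreasing), `q_signed`, `converged`,
#'   `initial_sign`, `rounds`.
#' @export
dual_mode_seek <- function(x0, data, cfg, seek = seek_config()) {
  res <- run_seek_(x0, fixation_points(data), data$label, cfg, seek,
                   "dual", record = TRUE)
  traj_from_(res)
}

#' Conventional mean shift from a single start
#'
#' Standard density mode seeking: iterates the kernel-weighted mean of the
#' pooled points. Identical to [dual_mode_seek()] with every label positive,
#' in which case the objective is the kernel density itself.
#'
#' @inheritParams dual_mode_seek
#' @param points An n x 2 matrix of support points.
#' @return A `shift_trajectory` with `q_values` holding the density at the
#'   accepted positions.
#' @export
classic_mean_shift <- function(x0, points, cfg, seek = seek_config()) {
  points <- as_points_(points)
  res <- run_seek_(x0, points, rep(1L, nrow(points)), cfg, seek,
                   "classic", record = TRUE)
  traj_from_(res)
}

#' Batch mode seeking over a set of initial kernels
#'
#' Runs independent trajectories from each initial kernel position.
#' Deterministic given its inputs; per-kernel failures (non-finite
#' positions) are flagged, not fatal.
#'
#' @param inits An m x 2 matrix of starting positions.
#' @inheritParams dual_mode_seek
#' @param mode `"dual"` (supervised mean shift on the signed density
#'   difference), `"classic"` (conventional mean shift on the pooled
#'   density, labels ignored), or `"ratio"` (ascent of the guarded class
#'   density ratio `p+ / (p- + eps)`).
#' @param record Keep per-kernel trajectories (memory grows with
#'   `max_rounds`); final positions are always returned.
#' @return A list of class `seek_result`: `finals` (m x 2 converged
#'   positions), `q`, `q_signed`, `rounds`, `converged`, `failed`,
#'   `initial_sign`, and `trajectories` (list of `shift_trajectory` when
#'   `record = TRUE`).
#' @export
seek_all <- function(inits, data, cfg, seek = seek_config(),
                     mode = c("dual", "classic", "ratio"), record = FALSE) {
  mode <- match.arg(mode)
  inits <- as_points_(inits)
  if (!nrow(inits)) stop("seek_all needs at least one initial kernel")
  res <- run_seek_(inits, fixation_points(data), data$label, cfg, seek,
                   mode, record = record)
  trajs <- NULL
  if (record) {
    trajs <- lapply(seq_len(nrow(inits)), function(k) {
      if (res$failed[k]) NULL else traj_from_(res, k)
    })
  }
  structure(list(finals = res$finals, q = res$q, q_signed = res$q_signed,
                 rounds = res$rounds, converged = res$converged,
                 failed = res$failed, initial_sign = res$initial_sign,
                 mode = mode, trajectories = trajs),
            class = "seek_result")
}

#' @export
print.shift_trajectory <- function(x, ...) {
  cat(sprintf(
    "<shift_trajectory> %d accepted rounds | converged: %s | final q = %.4g\n",
    x$rounds, x$converged, x$q_values[length(x$q_values)]))
  invisible(x)
}
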