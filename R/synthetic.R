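# Synthetic gaze cohorts: class-conditional Gaussian-mixture attention maps
# over a face-like stimulus, with subject-level weight jitter so
# leave-one-subject-out evaluation is a meaningful test.

#' Attention model: class-conditional mixture over stimulus regions
#'
#' A set of isotropic Gaussian attention regions on the canvas with one
#' mixing-weight vector per class. Fixations of a subject are i.i.d. draws
#' from the subject's (jittered) class mixture.
#'
#' @param means m x 2 matrix of component centres (pixels, inside canvas).
#' @param sds Length-m isotropic component standard deviations (pixels).
#' @param w_pos,w_neg Non-negative class mixing weights summing to 1.
#' @param canvas Stimulus extent `c(width, height)`.
#' @return A list of class `attention_model`.
#' @export
attention_model <- function(means, sds, w_pos, w_neg, canvas = c(700, 500)) {
  means <- as_points_(means)
  m <- nrow(means)
  stopifnot(length(sds) == m, all(sds > 0),
            length(w_pos) == m, length(w_neg) == m,
            all(w_pos >= 0), all(w_neg >= 0))
  if (abs(sum(w_pos) - 1) > 1e-8 || abs(sum(w_neg) - 1) > 1e-8)
    stop("class weights must sum to 1")
  if (any(means[, 1L] < 0 | means[, 1L] > canvas[1] |
          means[, 2L] < 0 | means[, 2L] > canvas[2]))
    stop("component means must lie inside the canvas")
  structure(list(means = means, sds = as.numeric(sds),
                 w_pos = as.numeric(w_pos), w_neg = as.numeric(w_neg),
                 canvas = as.numeric(canvas)),
            class = "attention_model")
}

#' Default face-viewing attention model
#'
#' Five attention regions on a 700x500 stimulus -- left eye, right eye,
#' nose, mouth, off-face background -- mirroring the face-scanning
#' structure the method targets: controls concentrate on the eyes, while
#' the positive class redistributes a fraction `delta` of its eye mass to
#' the nose and background (eye-contact avoidance). The total-variation
#' distance between the class weight vectors equals `delta`.
#'
#' @param delta Weight gap in `[0, 0.4]` moved off the eye regions for the
#'   positive class.
#' @param sd Common component standard deviation in pixels.
#' @return An `attention_model` with component order left eye, right eye,
#'   nose, mouth, background.
#' @export
default_face_model <- function(delta, sd = 25) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 0.4)
    stop("delta must be a single number in [0, 0.4]")
  means <- rbind(c(245, 175),  # left eye
                 c(455, 175),  # right eye
                 c(350, 270),  # nose
                 c(350, 380),  # mouth
                 c(110, 60))   # off-face background
  w_neg <- c(0.25, 0.25, 0.20, 0.20, 0.10)
  w_pos <- w_neg + c(-delta / 2, -delta / 2, delta / 2, 0, delta / 2)
  attention_model(means, sds = rep(sd, 5L), w_pos = w_pos, w_neg = w_neg)
}

#' Cohort specification
#'
#' @param n_pos,n_neg Subject counts per class.
#' @param n_images Images viewed per subject.
#' @param fixations_per_image Fixations recorded per image.
#' @param subject_effect Dirichlet concentration multiplier for
#'   subject-level mixing-weight jitter (subject weights ~
#'   Dirichlet(class weights x concentration)); `Inf` switches jitter off.
#'   Larger values mean subjects closer to their class mean. The default
#'   (12) puts the per-subject weight spread on the scale of the class
#'   weight gap, so the two subject populations overlap as real cohorts
#'   do rather than being trivially separable.
#' @param seed Integer seed; the cohort is a pure function of (model, spec).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pos = 30L, n_neg = 30L, n_images = 6L,
                        fixations_per_image = 40L, subject_effect = 12,
                        seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, n_images >= 1L,
            fixations_per_image >= 1L, subject_effect > 0)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_images = as.integer(n_images),
                 fixations_per_image = as.integer(fixations_per_image),
                 subject_effect = subject_effect, seed = as.integer(seed)),
            class = "cohort_spec")
}

rdirichlet_ <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) {  # extreme concentration underflow: fall back to mean
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

#' Generate a synthetic fixation cohort
#'
#' For each subject: draw subject-level mixing weights by Dirichlet jitter
#' around the class weights, then draw i.i.d. fixations per image from the
#' subject's Gaussian mixture, clipped to the canvas (clipping keeps counts
#' exact; the clipped fraction is recorded in the `clip_fraction`
#' attribute). Positive-class subjects are named `pos_01, ...`, controls
#' `neg_01, ...`. Fully reproducible from the spec's seed.
#'
#' @param model An [attention_model()].
#' @param spec A [cohort_spec()].
#' @return A [fixation_data()] frame with an extra `component` column
#'   (generator truth: which region each fixation was drawn from) and
#'   attribute `clip_fraction`.
#' @export
generate_cohort <- function(model, spec) {
  stopifnot(inherits(model, "attention_model"), inherits(spec, "cohort_spec"))
  m <- nrow(model$means)
  n_sub <- spec$n_pos + spec$n_neg
  per_sub <- spec$n_images * spec$fixations_per_image
  out <- with_seed_(spec$seed, {
    subs <- c(sprintf("pos_%02d", seq_len(spec$n_pos)),
              sprintf("neg_%02d", seq_len(spec$n_neg)))
    labs <- rep(c(1L, -1L), c(spec$n_pos, spec$n_neg))
    rows <- vector("list", n_sub)
    n_clipped <- 0L
    for (i in seq_len(n_sub)) {
      w_class <- if (labs[i] == 1L) model$w_pos else model$w_neg
      w_sub <- if (is.finite(spec$subject_effect)) {
        rdirichlet_(w_class * spec$subject_effect)
      } else w_class
      comp <- sample.int(m, per_sub, replace = TRUE, prob = w_sub)
      x <- rnorm(per_sub, model$means[comp, 1L], model$sds[comp])
      y <- rnorm(per_sub, model$means[comp, 2L], model$sds[comp])
      clipped <- x < 0 | x > model$canvas[1] | y < 0 | y > model$canvas[2]
      n_clipped <- n_clipped + sum(clipped)
      x <- pmin(pmax(x, 0), model$canvas[1])
      y <- pmin(pmax(y, 0), model$canvas[2])
      rows[[i]] <- data.frame(
        subject_id = subs[i],
        image_id = rep(sprintf("img_%02d", seq_len(spec$n_images)),
                       each = spec$fixations_per_image),
        x = x, y = y, label = labs[i], component = comp,
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    attr(df, "clip_fraction") <- n_clipped / nrow(df)
    df
  })
  comp <- out$component
  clip <- attr(out, "clip_fraction")
  fx <- validate_fixation_data(out)
  fx$component <- comp
  attr(fx, "clip_fraction") <- clip
  fx
}

#' Expected quality extrema of an attention model
#'
#' Evaluates the *expected* signed quality surface analytically: the
#' kernel-smoothed expectation of the class density difference is the
#' mixture difference with each component's variance inflated by the
#' kernel, `sum_j (pi+ w+_j - pi- w-_j) N(x; mu_j, (sd_j^2 + h^2) I)`
#' where `pi+`/`pi-` are the class shares of the pooled sample. Local
#' extrema of its absolute value above 10% of the global maximum are
#' located by grid search; this is the data-free oracle for where dual
#' mode seeking should converge.
#'
#' @param model An [attention_model()].
#' @param h Kernel bandwidth in pixels.
#' @param resolution Grid spacing in pixels.
#' @param class_share Length-2 positive/negative shares of the pooled
#'   sample (default balanced).
#' @return A data frame of extrema: `x`, `y`, `q_signed`; zero rows when
#'   the expected surface is flat.
#' @export
oracle_modes <- function(model, h, resolution = 0.5,
                         class_share = c(0.5, 0.5)) {
  stopifnot(inherits(model, "attention_model"), h > 0, resolution > 0)
  gx <- seq(0, model$canvas[1], by = resolution)
  gy <- seq(0, model$canvas[2], by = resolution)
  dw <- class_share[1] * model$w_pos - class_share[2] * model$w_neg
  q <- matrix(0, nrow = length(gx), ncol = length(gy))
  for (j in seq_len(nrow(model$means))) {
    v <- model$sds[j]^2 + h^2
    dx2 <- (gx - model$means[j, 1L])^2
    dy2 <- (gy - model$means[j, 2L])^2
    q <- q + dw[j] / (2 * pi * v) *
      outer(exp(-dx2 / (2 * v)), exp(-dy2 / (2 * v)))
  }
  aq <- abs(q)
  qmax <- max(aq)
  if (qmax == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), q_signed = numeric(0)))
  }
  nx <- length(gx); ny <- length(gy)
  inner_i <- 2:(nx - 1); inner_j <- 2:(ny - 1)
  centre <- aq[inner_i, inner_j]
  is_max <- centre > 0.1 * qmax
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (centre >= aq[inner_i + di, inner_j + dj])
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(x = gx[inner_i][idx[, 1L]], y = gy[inner_j][idx[, 2L]],
             q_signed = q[cbind(inner_i[idx[, 1L]], inner_j[idx[, 2L]])])
}
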