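test_that("kde matches the closed form and handles edge cases", {
  cfg <- kernel_config(h = 1)
  # one support point at the query: c_d / (N h^d) * 1 = 1/(2*pi)
  expect_equal(kde(c(0, 0), rbind(c(0, 0)), cfg), 1 / (2 * pi))
  # empty support set
  expect_identical(kde(c(0, 0), matrix(numeric(0), 0, 2), cfg), 0)
  expect_identical(kde(c(0, 0), NULL, cfg), 0)
  # Gaussian tail: negligible at 20 bandwidths
  expect_lt(kde(c(20, 0), rbind(c(0, 0)), cfg), 1e-12)
  # invalid inputs
  expect_error(kernel_config(h = 0), "positive")
  expect_error(kde(c(NA, 0), rbind(c(0, 0)), cfg), "finite")
})

test_that("kde agrees with a brute-force oracle and is translation-equivariant", {
  set.seed(42)
  for (h in c(10, 30)) {
    cfg <- kernel_config(h)
    pts <- cbind(runif(30, 0, 700), runif(30, 0, 500))
    x <- c(runif(1, 0, 700), runif(1, 0, 500))
    expect_equal(kde(x, pts, cfg, n_total = 60),
                 brute_kde(x, pts, h, n_total = 60), tolerance = 1e-12)
    shift <- c(123.4, -55.2)
    expect_equal(kde(x + shift, sweep(pts, 2, -shift), cfg),
                 kde(x, pts, cfg), tolerance = 1e-12)
  }
})

test_that("signed quality matches brute force, is antisymmetric, and reduces", {
  data <- make_gauss_data(20, 20, sd = 40, seed = 7)
  cfg <- kernel_config(30)
  pts <- cbind(data$x, data$y)
  n <- nrow(data)
  for (i in 1:5) {
    x <- pts[i, ] + c(5, -3)
    q <- quality_signed(x, data, cfg)
    ref <- brute_kde(x, pts[data$label == 1L, , drop = FALSE], 30, n) -
      brute_kde(x, pts[data$label == -1L, , drop = FALSE], 30, n)
    expect_equal(q$q_signed, ref, tolerance = 1e-12)
    expect_identical(q$q_abs, abs(q$q_signed))
  }
  # swapping classes negates q_signed, preserves q_abs
  swapped <- data
  swapped$label <- -swapped$label
  qs <- quality_signed(pts[1:5, ], swapped, cfg)
  qo <- quality_signed(pts[1:5, ], data, cfg)
  expect_equal(qs$q_signed, -qo$q_signed, tolerance = 1e-14)
  expect_equal(qs$q_abs, qo$q_abs)
  # identical point sets in both classes: zero everywhere
  dup <- fixation_data(x = rep(data$x, 2), y = rep(data$y, 2),
                       label = rep(c(1L, -1L), each = n),
                       subject_id = rep(c("a", "b"), each = n),
                       image_id = "i")
  expect_equal(quality_signed(rbind(c(100, 100), c(300, 250)), dup, cfg)$q_signed,
               c(0, 0), tolerance = 1e-18)
  # negative class empty: q_signed is the positive-class density
  ponly <- data[data$label == 1L, ]
  class(ponly) <- c("fixation_data", "data.frame")
  expect_equal(quality_signed(c(100, 100), ponly, cfg)$q_signed,
               kde(c(100, 100), cbind(ponly$x, ponly$y), cfg))
  expect_gt(quality_signed(c(100, 100), ponly, cfg)$q_signed, 0)
})

test_that("weighted_mean matches the direct formula and its fixed points", {
  cfg <- kernel_config(5)
  # single support point: mean is that point from anywhere
  expect_equal(weighted_mean(c(50, 50), rbind(c(3, 4)), cfg), c(3, 4))
  # symmetric configuration about the query: query is the fixed point
  sym <- rbind(c(-2, 0), c(2, 0), c(0, -2), c(0, 2))
  expect_equal(weighted_mean(c(0, 0), sym, cfg), c(0, 0), tolerance = 1e-14)
  # direct-formula oracle on a random instance
  set.seed(3)
  pts <- cbind(rnorm(25, 10, 4), rnorm(25, -5, 4))
  x <- c(9, -4)
  w <- exp(-rowSums(sweep(pts, 2, x)^2) / (2 * 25))
  expect_equal(weighted_mean(x, pts, cfg),
               colSums(w * pts) / sum(w), tolerance = 1e-12)
  # isolated query signals an error
  expect_error(weighted_mean(c(1e6, 1e6), pts, cfg), "isolated")
})

test_that("analytic quality gradient matches central finite differences", {
  for (seed in 1:20) {
    set.seed(seed)
    h <- sample(c(10, 30, 60), 1)
    cfg <- kernel_config(h)
    data <- make_gauss_data(sample(20:100, 1), sample(20:100, 1),
                            centre_pos = runif(2, 100, 400),
                            centre_neg = runif(2, 200, 500),
                            sd = runif(1, 20, 80), seed = seed + 100)
    x <- c(data$x[1], data$y[1]) + rnorm(2, 0, h / 2)
    g <- grad_quality_signed(x, data, cfg)
    eps <- 1e-5 * h
    fd <- c(
      (quality_signed(x + c(eps, 0), data, cfg)$q_signed -
         quality_signed(x - c(eps, 0), data, cfg)$q_signed) / (2 * eps),
      (quality_signed(x + c(0, eps), data, cfg)$q_signed -
         quality_signed(x - c(0, eps), data, cfg)$q_signed) / (2 * eps)
    )
    expect_lt(sqrt(sum((g - fd)^2)) / sqrt(sum(fd^2)), 1e-6)
  }
})

test_that("quality gradient vanishes where it must", {
  cfg <- kernel_config(50)
  data <- make_gauss_data(60, 0, centre_pos = c(300, 250), sd = 20, seed = 5)
  # single-class cloud: near-zero gradient at the KDE mode (near the mean)
  tr <- classic_mean_shift(c(mean(data$x), mean(data$y)),
                           cbind(data$x, data$y), cfg)
  mode_x <- tr$positions[nrow(tr$positions), ]
  g <- grad_quality_signed(mode_x, data, cfg)
  dens <- kde(mode_x, cbind(data$x, data$y), cfg)
  expect_lt(sqrt(sum(g^2)), 1e-2 * dens / cfg$h)
  # X+ == X-: exactly zero everywhere
  n <- nrow(data)
  dup <- fixation_data(x = rep(data$x, 2), y = rep(data$y, 2),
                       label = rep(c(1L, -1L), each = n),
                       subject_id = rep(c("a", "b"), each = n),
                       image_id = "i")
  expect_equal(grad_quality_signed(c(310, 240), dup, cfg), c(0, 0),
               tolerance = 1e-20)
})

test_that("supervised shift vector: reductions, identity, ascent direction", {
  cfg <- kernel_config(30)
  data <- make_gauss_data(30, 30, sd = 50, seed = 11)
  pts <- cbind(data$x, data$y)
  # all labels positive: reduces to the classic mean-shift vector
  ponly <- data
  ponly$label <- 1L
  x <- c(150, 150)
  sv <- supervised_shift_vector(x, ponly, cfg)
  expect_equal(x + sv$m, weighted_mean(x, pts, cfg), tolerance = 1e-12)
  # denominator identity: s = (N h^d / c_d) * Q*(x), tested at many points
  n <- nrow(data)
  for (i in seq(1, 60, by = 7)) {
    x <- pts[i, ] + c(3, 3)
    sv <- supervised_shift_vector(x, data, cfg)
    q <- quality_signed(x, data, cfg)$q_signed
    expect_equal(sv$s, n * cfg$h^2 / cfg$c_d * q, tolerance = 1e-10)
    # moving by m goes in the dual ascent/descent direction of Q*
    g <- grad_quality_signed(x, data, cfg)
    expect_gte(sign(sv$s) * sum(sv$m * g), 0)
  }
  # balanced-density region is signalled
  n1 <- nrow(data)
  dup <- fixation_data(x = rep(data$x, 2), y = rep(data$y, 2),
                       label = rep(c(1L, -1L), each = n1),
                       subject_id = rep(c("a", "b"), each = n1),
                       image_id = "i")
  expect_error(supervised_shift_vector(c(150, 150), dup, cfg), "balanced")
})
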