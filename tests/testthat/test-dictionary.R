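test_that("learn_dictionary recovers well-separated class modes", {
  data <- make_gauss_data(100, 100, centre_pos = c(100, 100),
                          centre_neg = c(500, 400), sd = 10, seed = 1)
  cfg <- kernel_config(30)
  d <- learn_dictionary(data, cfg, K = 2, subsample_rate = 0.5, seed = 3)
  o_pos <- grid_argmax_q(data, cfg, c(100, 100), radius = 60)
  o_neg <- grid_argmax_q(data, cfg, c(500, 400), radius = 60)
  d_pos <- min(sqrt(rowSums(sweep(d$centroids, 2, o_pos$x)^2)))
  d_neg <- min(sqrt(rowSums(sweep(d$centroids, 2, o_neg$x)^2)))
  expect_lt(d_pos, 0.1 * 30)
  expect_lt(d_neg, 0.1 * 30)
  # determinism under a fixed seed
  d2 <- learn_dictionary(data, cfg, K = 2, subsample_rate = 0.5, seed = 3)
  expect_identical(d$centroids, d2$centroids)
})

test_that("subsample_rate = 1 with K = N returns the converged kernels", {
  data <- make_gauss_data(20, 20, centre_pos = c(150, 150),
                          centre_neg = c(450, 350), sd = 60, seed = 5)
  cfg <- kernel_config(80)
  res <- seek_all(cbind(data$x, data$y), data, cfg, mode = "dual")
  finals <- unique(res$finals)
  K <- nrow(finals)
  expect_gte(K, 2L)  # broad bandwidth still leaves distinct stop positions
  d <- learn_dictionary(data, cfg, K = K, subsample_rate = 1, seed = 2)
  # same point set, up to ordering
  ord_a <- order(d$centroids[, 1], d$centroids[, 2])
  ord_b <- order(finals[, 1], finals[, 2])
  expect_equal(d$centroids[ord_a, ], unname(finals[ord_b, ]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # asking for more words than distinct converged kernels errors
  expect_error(learn_dictionary(data, cfg, K = nrow(data), subsample_rate = 0.5,
                                seed = 1), "smaller K|support")
})

test_that("assign_words implements nearest-centroid with low-index ties", {
  dict <- new_dictionary(rbind(c(0, 0), c(10, 0), c(5, 5), c(2, 8), c(10, 10)))
  expect_identical(assign_words(c(10, 0), dict), 2L)
  # equidistant between words 1 and 2: lowest index wins
  expect_identical(assign_words(c(5, 0), dict), 1L)
  # brute-force scan oracle
  set.seed(8)
  pts <- cbind(runif(50, -2, 12), runif(50, -2, 12))
  brute <- apply(pts, 1, function(p) {
    which.min(sqrt(rowSums(sweep(dict$centroids, 2, p)^2)))
  })
  expect_identical(assign_words(pts, dict), as.integer(brute))
})

test_that("bag-of-words encoding is a normalized count histogram", {
  dict <- new_dictionary(rbind(c(0, 0), c(100, 0), c(0, 100)))
  # assignments (3,3,1,2,3) -> histogram (0.2, 0.2, 0.6)
  pts <- rbind(c(1, 99), c(0, 101), c(1, 1), c(99, 0), c(-1, 100))
  hb <- encode_bow(pts, dict)
  expect_equal(as.numeric(hb), c(0.2, 0.2, 0.6))
  expect_identical(attr(hb, "n_fixations"), 5L)
  # all fixations at one centroid: one-hot
  expect_equal(as.numeric(encode_bow(rbind(c(100, 0), c(100, 0)), dict)),
               c(0, 1, 0))
  # concatenation invariance
  expect_equal(as.numeric(encode_bow(rbind(pts, pts), dict)),
               as.numeric(hb))
  # counts are recovered exactly
  expect_identical(as.numeric(hb) * attr(hb, "n_fixations"), c(1, 1, 3))
  expect_error(encode_bow(matrix(numeric(0), 0, 2), dict), "no fixations")
})

test_that("word quality table implements the purity/coverage identities", {
  # 8 positives and 2 negatives in word 1, rest in word 2
  data <- fixation_data(
    x = c(rep(0, 10), rep(100, 6)), y = c(rep(0, 10), rep(100, 6)),
    label = c(rep(1L, 8), rep(-1L, 2), rep(1L, 3), rep(-1L, 3)),
    subject_id = rep(c("a", "b", "c", "d"), c(8, 2, 3, 3)),
    image_id = "i")
  dict <- new_dictionary(rbind(c(0, 0), c(100, 100)))
  wq <- word_quality_table(data, dict)
  expect_equal(wq$purity_pos[1], 0.8)
  expect_equal(wq$purity_abs[1], 0.6)
  expect_equal(wq$coverage[1], 10)
  expect_equal(wq$quality[1], 6)
  # balanced word: zero purity and quality
  expect_equal(wq$purity_abs[2], 0)
  expect_equal(wq$quality[2], 0)
  # conservation and the quality identity on random dictionaries
  for (seed in 1:4) {
    cohort <- small_cohort(delta = 0.2, seed = seed, n_per_class = 4L,
                           n_images = 2L, fpi = 20L)
    d <- kmeans_dictionary(cohort, K = 7, seed = seed)
    wq <- word_quality_table(cohort, d)
    expect_identical(sum(wq$coverage), nrow(cohort))
    ok <- wq$coverage > 0
    expect_equal(wq$quality[ok], wq$purity_abs[ok] * wq$coverage[ok])
    expect_equal(wq$purity_pos[ok] + wq$purity_neg[ok], rep(1, sum(ok)))
  }
})

test_that("purity profiles sort descending with length K", {
  wq <- data.frame(word = 1:3, purity_pos = c(0.5, 0.9, 0.7),
                   purity_neg = c(0.5, 0.1, 0.3))
  expect_equal(purity_profile(wq, "pos"), c(0.9, 0.7, 0.5))
  expect_equal(purity_profile(wq, "neg"), c(0.5, 0.3, 0.1))
  wq2 <- data.frame(word = 1:4, purity_pos = rep(0.25, 4))
  expect_equal(purity_profile(wq2, "pos"), rep(0.25, 4))
  expect_length(purity_profile(wq, "pos"), 3L)
})

test_that("quality heat maps locate extrema and respect antisymmetry", {
  data <- make_gauss_data(80, 80, centre_pos = c(200, 150),
                          centre_neg = c(500, 400), sd = 10, seed = 9)
  cfg <- kernel_config(30)
  qm <- quality_heatmap(data, cfg, nx = 71, ny = 51)
  i <- which(qm$q_abs == max(qm$q_abs), arr.ind = TRUE)[1, ]
  peak <- c(qm$x[i[1]], qm$y[i[2]])
  cell <- c(diff(qm$x[1:2]), diff(qm$y[1:2]))
  # the absolute peak sits within one grid cell of a cluster centre region
  best <- grid_argmax_q(data, cfg, c(200, 150), radius = 60)
  best_neg <- grid_argmax_q(data, cfg, c(500, 400), radius = 60)
  ref <- if (best$q_abs >= best_neg$q_abs) best$x else best_neg$x
  expect_true(all(abs(peak - ref) <= cell + 0.5))
  # swapped classes negate the signed map
  swapped <- data
  swapped$label <- -swapped$label
  qm2 <- quality_heatmap(swapped, cfg, nx = 71, ny = 51)
  expect_equal(qm2$q_signed, -qm$q_signed, tolerance = 1e-14)
  # identical classes: all-zero map
  dup <- fixation_data(x = rep(data$x, 2), y = rep(data$y, 2),
                       label = rep(c(1L, -1L), each = nrow(data)),
                       subject_id = rep(c("a", "b"), each = nrow(data)),
                       image_id = "i")
  qm3 <- quality_heatmap(dup, cfg, nx = 31, ny = 21)
  expect_true(all(qm3$q_abs == 0))
})
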