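# Shared fixtures and independent oracles, built in code at test time.

# Two-class Gaussian blobs: n per class around the given centres.
make_gauss_data <- function(n_pos, n_neg, centre_pos = c(100, 100),
                            centre_neg = c(500, 400), sd = 10, seed = 1,
                            n_images = 1L) {
  set.seed(seed)
  n <- n_pos + n_neg
  lab <- rep(c(1L, -1L), c(n_pos, n_neg))
  mx <- ifelse(lab == 1L, centre_pos[1], centre_neg[1])
  my <- ifelse(lab == 1L, centre_pos[2], centre_neg[2])
  fixation_data(
    x = rnorm(n, mx, sd), y = rnorm(n, my, sd), label = lab,
    subject_id = ifelse(lab == 1L, "sp", "sn"),
    image_id = rep_len(sprintf("img%d", seq_len(n_images)), n)
  )
}

# Brute-force double-loop KDE oracle (Eq.-by-Eq. literal sum).
brute_kde <- function(x, pts, h, n_total, c_d = 1 / (2 * pi), d = 2) {
  acc <- 0
  for (i in seq_len(nrow(pts))) {
    acc <- acc + exp(-sum((x - pts[i, ])^2) / (2 * h^2))
  }
  c_d / (n_total * h^d) * acc
}

# Grid-argmax oracle: exhaustive search of |Q*| at `res`-px resolution over
# a window around `centre`, returning the best grid point and its signed q.
grid_argmax_q <- function(data, cfg, centre, radius, res = 0.5) {
  gx <- seq(centre[1] - radius, centre[1] + radius, by = res)
  gy <- seq(centre[2] - radius, centre[2] + radius, by = res)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  q <- quality_signed(grid, data, cfg)
  i <- which.max(q$q_abs)
  list(x = grid[i, ], q_signed = q$q_signed[i], q_abs = q$q_abs[i])
}

# Mann-Whitney oracle for AUC: explicit pair counting, ties as 1/2.
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1L]
  sn <- scores[labels == -1L]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Small benchmark cohort used by dictionary/evaluation tests.
small_cohort <- function(delta = 0.3, seed = 1, n_per_class = 10L,
                         n_images = 3L, fpi = 25L, subject_effect = 12,
                         sd = 25) {
  generate_cohort(
    default_face_model(delta, sd = sd),
    cohort_spec(n_pos = n_per_class, n_neg = n_per_class,
                n_images = n_images, fixations_per_image = fpi,
                subject_effect = subject_effect, seed = seed)
  )
}

# Single-cell evaluation grid used where hyperparameter search is not the
# thing under test.
one_cell <- function(K = 40L, h = 30, gamma = 2^-3, C = 2^13) {
  eval_config(K_grid = K, h_grid = h, gamma_grid = gamma, C_grid = C)
}
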