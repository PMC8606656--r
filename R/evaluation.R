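#' Evaluation configuration
#'
#' Hyperparameter grids and threshold rule for the leave-one-subject-out
#' protocol. Default grids follow the published search ranges: word counts
#' 35--70 in steps of 5, SVM `gamma` in `2^-6..2^0` and cost `C` in
#' `2^6..2^16` (integer exponents). The bandwidth grid is the package's own
#' choice of plausible pixel scales on a 700x500 stimulus.
#'
#' @param K_grid Candidate word counts.
#' @param h_grid Candidate bandwidths in pixels (ignored by k-means
#'   learners).
#' @param gamma_grid,C_grid RBF-SVM hyperparameter candidates.
#' @param threshold_rule `"best_global"` (threshold maximizing LOSO
#'   accuracy; optimistic, reported alongside the threshold-free AUC) or a
#'   fixed numeric threshold.
#' @param subsample_rate Kernel-initialization subsample fraction passed to
#'   the mode-seeking learners.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(K_grid = seq(35L, 70L, by = 5L),
                        h_grid = c(20, 30, 40, 60),
                        gamma_grid = 2^(-6:0),
                        C_grid = 2^(6:16),
                        threshold_rule = "best_global",
                        subsample_rate = 1 / 20) {
  stopifnot(length(K_grid) >= 1L, length(h_grid) >= 1L,
            length(gamma_grid) >= 1L, length(C_grid) >= 1L)
  if (!identical(threshold_rule, "best_global") &&
      !(is.numeric(threshold_rule) && length(threshold_rule) == 1L))
    stop("threshold_rule must be \"best_global\" or a single number")
  structure(list(K_grid = as.integer(K_grid), h_grid = as.numeric(h_grid),
                 gamma_grid = gamma_grid, C_grid = C_grid,
                 threshold_rule = threshold_rule,
                 subsample_rate = subsample_rate),
            class = "eval_config")
}

#' Leave-one-subject-out folds over encoded features
#'
#' One fold per subject: the test side holds every image of that subject,
#' the train side everything else. The test sides partition the feature
#' set and no subject appears on both sides of a fold.
#'
#' @param features A `bow_features` frame (or any frame with a
#'   `subject_id` column).
#' @return A list of folds, each `list(subject, train, test)` with integer
#'   row indices.
#' @export
loso_split <- function(features) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2L) stop("leave-one-subject-out needs >= 2 subjects")
  lapply(subjects, function(s) {
    test <- which(features$subject_id == s)
    list(subject = s, train = which(features$subject_id != s), test = test)
  })
}

# Mean image score per subject.
aggregate_subject_scores_ <- function(image_scores, subject_ids) {
  m <- tapply(image_scores, subject_ids, mean)
  setNames(as.numeric(m), names(m))
}

# Fit an RBF SVM on training image features and return signed decision
# scores for the test images, oriented so larger = more positive-class.
svm_image_scores_ <- function(train_x, train_lab, test_x, gamma, cost) {
  yf <- factor(ifelse(train_lab == 1L, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(x = train_x, y = yf, kernel = "radial", gamma = gamma,
                    cost = cost, scale = FALSE)
  pr <- predict(fit, test_x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (identical(colnames(dv), "neg/pos")) dv <- -dv
  as.numeric(dv)
}

#' Leave-one-subject-out evaluation of a dictionary learner
#'
#' For every fold (held-out subject) and every `(K, h)` cell: a dictionary
#' is learned from the training subjects' fixations only, train and test
#' images are encoded as bag-of-words histograms, an RBF-kernel SVM is fit
#' per `(gamma, C)` cell, and the held-out subject's score is the mean
#' signed decision value over their images. The grid cell maximizing LOSO
#' accuracy (at the configured threshold rule) is reported; AUC,
#' sensitivity and specificity are computed from the winning cell's
#' subject scores.
#'
#' @param data A [fixation_data()] frame.
#' @param method Dictionary learner name, see [fit_dictionary()].
#' @param eval_cfg An [eval_config()].
#' @param seek A [seek_config()] for the mode-seeking learners.
#' @param seed Integer seed; per-fold dictionary seeds are derived from it.
#' @return A list of class `eval_result`: `subject_scores`,
#'   `subject_labels`, `threshold`, `confusion` (TP/FP/TN/FN), `accuracy`,
#'   `auc`, `sensitivity`, `specificity`, `roc`, `best` (winning
#'   hyperparameters), `grid` (per-cell accuracy/AUC table), `method`, and
#'   `folds` (per-fold provenance: held-out subject and training subjects).
#' @export
score_subjects <- function(data, method, eval_cfg = eval_config(),
                           seek = seek_config(), seed = 1L) {
  stopifnot(inherits(data, "fixation_data"), inherits(eval_cfg, "eval_config"))
  labs <- subject_labels(data)
  subjects <- names(labs)
  if (length(subjects) < 2L) stop("need at least two subjects")
  if (length(unique(labs)) < 2L) stop("need both classes among subjects")

  uses_h <- method %in% c("proposed", "meanshift", "class_meanshift", "ratio")
  h_grid <- if (uses_h) eval_cfg$h_grid else NA_real_
  cells <- expand.grid(gamma = eval_cfg$gamma_grid, C = eval_cfg$C_grid,
                       K = eval_cfg$K_grid, h = h_grid,
                       KEEP.OUT.ATTRS = FALSE)
  scores <- matrix(NA_real_, nrow = length(subjects), ncol = nrow(cells),
                   dimnames = list(subjects, NULL))
  fold_prov <- vector("list", length(subjects))

  for (si in seq_along(subjects)) {
    s <- subjects[si]
    train <- data[data$subject_id != s, ]
    class(train) <- c("fixation_data", "data.frame")
    test <- data[data$subject_id == s, ]
    class(test) <- c("fixation_data", "data.frame")
    if (length(unique(train$label)) < 2L)
      stop("degenerate fold: training side of subject ", s, " is single-class")
    fold_seed <- as.integer((seed + 7919 * si) %% .Machine$integer.max)
    fold_prov[[si]] <- list(subject = s,
                            train_subjects = unique(train$subject_id))
    for (h in unique(cells$h)) {
      cfg <- if (uses_h) kernel_config(h) else NULL
      for (K in unique(cells$K)) {
        dict <- fit_dictionary(train, method, K, cfg, seek,
                               eval_cfg$subsample_rate, fold_seed)
        ftr <- encode_dataset(train, dict)
        fte <- encode_dataset(test, dict)
        wcols <- paste0("w", seq_len(K))
        xtr <- as.matrix(ftr[, wcols])
        xte <- as.matrix(fte[, wcols])
        sel <- which((cells$K == K) & (is.na(h) | cells$h == h))
        for (ci in sel) {
          img <- svm_image_scores_(xtr, ftr$label, xte,
                                   cells$gamma[ci], cells$C[ci])
          scores[si, ci] <- mean(img)
        }
      }
    }
  }

  per_cell <- lapply(seq_len(nrow(cells)), function(ci) {
    sc <- scores[, ci]
    th <- if (identical(eval_cfg$threshold_rule, "best_global"))
      best_threshold_(sc, labs) else eval_cfg$threshold_rule
    m <- compute_metrics(sc, labs, th)
    c(accuracy = m$accuracy, auc = compute_auc(sc, labs), threshold = th)
  })
  grid_tab <- cbind(cells, do.call(rbind, per_cell))
  best_i <- which.max(grid_tab$accuracy)
  sc <- scores[, best_i]
  th <- grid_tab$threshold[best_i]
  m <- compute_metrics(sc, labs, th)

  structure(list(subject_scores = sc, subject_labels = labs, threshold = th,
                 confusion = m$confusion, accuracy = m$accuracy,
                 auc = compute_auc(sc, labs),
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 roc = roc_curve(sc, labs),
                 best = as.list(cells[best_i, , drop = FALSE]),
                 grid = grid_tab, method = method, folds = fold_prov,
                 note = "accuracy uses the LOSO-optimal global threshold (optimistically biased); AUC is threshold-free"),
            class = "eval_result")
}

# Accuracy-maximizing global threshold over subject scores (prediction is
# positive when score >= T); candidates are midpoints between sorted
# unique scores plus the two outer extremes. Ties take the lowest T.
best_threshold_ <- function(scores, labels) {
  us <- sort(unique(scores))
  cand <- c(us[1L] - 1, if (length(us) > 1L) (us[-1L] + us[-length(us)]) / 2,
            us[length(us)] + 1)
  acc <- vapply(cand, function(t) mean((scores >= t) == (labels == 1L)),
                numeric(1))
  cand[which.max(acc)]
}

#' Thresholded classification metrics
#'
#' Predictions are positive when `score >= T`. Sensitivity is the true
#' positive rate `TP / (TP + FN)`, specificity the true negative rate
#' `TN / (TN + FP)`; either is `NA` when its class is absent.
#'
#' @param scores Numeric subject scores.
#' @param labels Subject labels in \{+1, -1\}.
#' @param T Decision threshold.
#' @return A list: `accuracy`, `sensitivity`, `specificity`, `confusion`
#'   (named TP/FP/TN/FN counts).
#' @export
compute_metrics <- function(scores, labels, T) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1L, 1L)))
  pred <- scores >= T
  pos <- labels == 1L
  TP <- sum(pred & pos); FN <- sum(!pred & pos)
  TN <- sum(!pred & !pos); FP <- sum(pred & !pos)
  list(accuracy = (TP + TN) / length(labels),
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       confusion = c(TP = TP, FP = FP, TN = TN, FN = FN))
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic (probability that a
#' random positive outscores a random negative, ties counted one half),
#' which equals the trapezoidal area under the threshold-swept ROC curve.
#'
#' @inheritParams compute_metrics
#' @return AUC in `[0, 1]`; `NA` when a class is absent.
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1L, 1L)))
  np <- sum(labels == 1L); nn <- sum(labels == -1L)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve by global threshold sweep
#'
#' True and false positive rates as the decision threshold sweeps over the
#' score values, from (0, 0) to (1, 1); tied scores move diagonally. The
#' trapezoidal area equals [compute_auc()].
#'
#' @inheritParams compute_metrics
#' @return A data frame with columns `fpr`, `tpr` and attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1L, 1L)))
  np <- sum(labels == 1L); nn <- sum(labels == -1L)
  if (np == 0L || nn == 0L) stop("roc_curve needs both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- labels[ord] == 1L
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  attr(pts, "auc") <- auc
  pts
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> method = %s | %d subjects\n", x$method,
              length(x$subject_scores)))
  cat(sprintf("  best cell: K = %s, h = %s, gamma = %g, C = %g\n",
              format(x$best$K), format(x$best$h), x$best$gamma, x$best$C))
  cat(sprintf("  Acc = %.4f  AUC = %.4f  Sens = %.4f  Spec = %.4f  (T = %.4g)\n",
              x$accuracy, x$auc, x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}
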