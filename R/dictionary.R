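#' Dictionary of gaze words
#'
#' A dictionary is a set of K word centroids in stimulus coordinates; the
#' induced clustering (nearest-centroid rule) turns fixation sequences into
#' bag-of-words histograms. Words are stored in a reproducible order:
#' descending training-word quality, ties broken by x then y.
#'
#' @param centroids K x 2 numeric matrix of word locations (pixels).
#' @param method_tag Provenance label of the learner that produced it.
#' @param h Bandwidth used during learning (NA for k-means learners).
#' @param seed Seed recorded for provenance.
#' @return A list of class `gaze_dictionary` with fields `centroids`, `K`,
#'   `method_tag`, `h`, `seed`.
#' @export
new_dictionary <- function(centroids, method_tag = "custom", h = NA_real_,
                           seed = NA_integer_) {
  centroids <- as_points_(centroids)
  stop_if_not_finite_(centroids, "centroids")
  if (nrow(centroids) < 1L) stop("a dictionary needs at least one word")
  if (anyDuplicated(centroids)) stop("dictionary centroids must be distinct")
  dimnames(centroids) <- list(NULL, c("x", "y"))
  structure(list(centroids = centroids, K = nrow(centroids),
                 method_tag = method_tag, h = h, seed = seed),
            class = "gaze_dictionary")
}

#' @export
print.gaze_dictionary <- function(x, ...) {
  cat(sprintf("<gaze_dictionary> K = %d | method = %s | h = %s | seed = %s\n",
              x$K, x$method_tag, format(x$h), format(x$seed)))
  invisible(x)
}

# Order centroids by descending word quality on the training data
# (ties by x then y) and wrap as a dictionary. Class-wise learners can
# emit exactly coincident centroids on (near-)identical class data; such
# duplicates are displaced by a sub-pixel offset to keep word identities
# distinct without affecting any assignment in practice.
finalize_dictionary_ <- function(centroids, train, method_tag, h, seed) {
  centroids <- as_points_(centroids)
  dup <- duplicated(centroids)
  if (any(dup)) {
    centroids[dup, 1L] <- centroids[dup, 1L] + 1e-6 * seq_len(sum(dup))
  }
  d <- new_dictionary(centroids, method_tag = method_tag, h = h, seed = seed)
  wq <- word_quality_table(train, d)
  ord <- order(-wq$quality, d$centroids[, 1L], d$centroids[, 2L])
  new_dictionary(d$centroids[ord, , drop = FALSE], method_tag = method_tag,
                 h = h, seed = seed)
}

# Seeded Lloyd-style k-means with multiple restarts, keeping the best
# within-cluster sum of squares. Initial centers are sampled from the
# distinct points (mode-seeking outputs collapse onto shared modes, so
# plain row sampling would propose duplicate centers). Errors when K
# exceeds the number of distinct points.
kmeans_centroids_ <- function(points, K, seed, nstart = 10L) {
  points <- as_points_(points)
  upts <- unique(points)
  if (K > nrow(upts)) {
    stop(sprintf("K = %d exceeds the %d distinct positions available; choose a smaller K",
                 K, nrow(upts)))
  }
  if (K == nrow(upts)) {
    # one cluster per distinct point is the exact optimum
    return(unname(upts))
  }
  with_seed_(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      init <- upts[sample.int(nrow(upts), K), , drop = FALSE]
      km <- tryCatch(
        suppressWarnings(kmeans(points, centers = init, iter.max = 100L)),
        error = function(e) tryCatch(  # Hartigan-Wong can hit empty clusters
          suppressWarnings(kmeans(points, centers = init, iter.max = 100L,
                                  algorithm = "MacQueen")),
          error = function(e) NULL))
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss)) best <- km
    }
    if (is.null(best)) stop("k-means failed for every restart")
    unname(best$centers)
  })
}

#' Learn a discriminative dictionary by dual mode seeking
#'
#' The full proposed pipeline: (1) a seeded uniform subsample of training
#' fixations (default 1 in 20) initializes the kernels; (2) each kernel is
#' shifted by dual mode seeking to a local extremum of the signed density
#' difference; (3) k-means with K clusters summarizes the converged kernels
#' into word centroids.
#'
#' @param train A [fixation_data()] frame with both classes present.
#' @param cfg A [kernel_config()].
#' @param seek A [seek_config()].
#' @param K Number of dictionary words.
#' @param subsample_rate Fraction of training fixations used as initial
#'   kernels.
#' @param seed Integer seed controlling the subsample and the k-means
#'   restarts; recorded in the dictionary.
#' @return A `gaze_dictionary` with `method_tag = "proposed"`.
#' @export
learn_dictionary <- function(train, cfg, seek = seek_config(), K,
                             subsample_rate = 1 / 20, seed = 1L) {
  seek_dictionary_(train, cfg, seek, K, subsample_rate, seed,
                   mode = "dual", method_tag = "proposed")
}

# Shared subsample -> seek -> k-means pipeline (proposed + mode-seeking
# baselines). `mode` selects the seeking objective.
seek_dictionary_ <- function(train, cfg, seek, K, subsample_rate, seed,
                             mode, method_tag, pool = NULL) {
  stopifnot(inherits(train, "fixation_data"), K >= 1L,
            subsample_rate > 0, subsample_rate <= 1)
  if (mode == "dual" && length(unique(train$label)) < 2L &&
      any(train$label == -1L)) {
    stop("dual mode seeking needs positive-class fixations")
  }
  n <- nrow(train)
  n_init <- ceiling(n * subsample_rate)
  if (n_init < K)
    stop(sprintf("subsample of %d kernels cannot support K = %d words", n_init, K))
  idx <- with_seed_(seed, sample.int(n, n_init))
  inits <- fixation_points(train)[idx, , drop = FALSE]
  res <- seek_all(inits, train, cfg, seek, mode = mode)
  finals <- res$finals[!res$failed, , drop = FALSE]
  centroids <- kmeans_centroids_(finals, K, seed)
  finalize_dictionary_(centroids, train, method_tag, h = cfg$h, seed = seed)
}

#' Assign fixations to their nearest dictionary word
#'
#' Nearest-centroid rule in Euclidean pixel distance; ties go to the
#' lowest word index.
#'
#' @param points n x 2 coordinate matrix (or length-2 vector).
#' @param dict A `gaze_dictionary`.
#' @return Integer vector of word indices in `1..K`.
#' @export
assign_words <- function(points, dict) {
  stopifnot(inherits(dict, "gaze_dictionary"))
  points <- as_points_(points)
  cx <- dict$centroids[, 1L]
  cy <- dict$centroids[, 2L]
  d2 <- outer(points[, 1L], cx, "-")^2 + outer(points[, 2L], cy, "-")^2
  max.col(-d2, ties.method = "first")
}

#' Encode a fixation sequence as a bag-of-words histogram
#'
#' Counts fixations per word and L1-normalizes, giving the frequency with
#' which the sequence visits each word region.
#'
#' @param points n x 2 fixation coordinates of one subject-image sequence.
#' @param dict A `gaze_dictionary`.
#' @return Numeric length-K histogram summing to 1, with attribute
#'   `n_fixations`.
#' @export
encode_bow <- function(points, dict) {
  points <- as_points_(points)
  if (!nrow(points)) stop("no fixations for subject-image: cannot encode")
  a <- assign_words(points, dict)
  counts <- tabulate(a, nbins = dict$K)
  structure(counts / nrow(points), n_fixations = nrow(points))
}

#' Encode every subject-image sequence of a dataset
#'
#' @param data A [fixation_data()] frame.
#' @param dict A `gaze_dictionary`.
#' @return A data frame of class `bow_features`: `subject_id`, `image_id`,
#'   `label`, `n_fixations`, and histogram columns `w1..wK`.
#' @export
encode_dataset <- function(data, dict) {
  stopifnot(inherits(dict, "gaze_dictionary"))
  a <- assign_words(fixation_points(data), dict)
  key <- paste(data$subject_id, data$image_id, sep = "\r")
  tab <- table(key, factor(a, levels = seq_len(dict$K)))
  counts <- matrix(as.numeric(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), NULL))
  n_fix <- rowSums(counts)
  hist <- counts / n_fix
  first <- !duplicated(key)
  meta <- data.frame(subject_id = data$subject_id[first],
                     image_id = data$image_id[first],
                     label = data$label[first], stringsAsFactors = FALSE)
  meta <- meta[match(rownames(hist),
                     paste(meta$subject_id, meta$image_id, sep = "\r")), ]
  colnames(hist) <- paste0("w", seq_len(dict$K))
  out <- cbind(meta, n_fixations = n_fix, as.data.frame(hist))
  rownames(out) <- NULL
  class(out) <- c("bow_features", "data.frame")
  out
}

#' Word purity, coverage and quality diagnostics
#'
#' For each word k with per-class member counts `n+` and `n-`:
#' positive purity `n+ / (n+ + n-)`, negative purity `n- / (n+ + n-)`,
#' absolute purity `|n+ - n-| / (n+ + n-)`, coverage `n+ + n-`, and
#' quality = purity x coverage = `|n+ - n-|`. Words covering no training
#' fixation report purities as `NA`.
#'
#' @param train A [fixation_data()] frame.
#' @param dict A `gaze_dictionary`.
#' @return A data frame with one row per word: `word`, `n_pos`, `n_neg`,
#'   `purity_pos`, `purity_neg`, `purity_abs`, `coverage`, `quality`.
#' @export
word_quality_table <- function(train, dict) {
  a <- assign_words(fixation_points(train), dict)
  af <- factor(a, levels = seq_len(dict$K))
  n_pos <- as.integer(table(af[train$label == 1L]))
  n_neg <- as.integer(table(af[train$label == -1L]))
  coverage <- n_pos + n_neg
  purity_pos <- ifelse(coverage > 0, n_pos / coverage, NA_real_)
  purity_neg <- ifelse(coverage > 0, n_neg / coverage, NA_real_)
  purity_abs <- ifelse(coverage > 0, abs(n_pos - n_neg) / coverage, NA_real_)
  data.frame(word = seq_len(dict$K), n_pos = n_pos, n_neg = n_neg,
             purity_pos = purity_pos, purity_neg = purity_neg,
             purity_abs = purity_abs, coverage = coverage,
             quality = abs(n_pos - n_neg))
}

#' Sorted purity profile of a dictionary
#'
#' Purities of the chosen class sorted from high to low, as used to compare
#' the discriminativeness of dictionary learners word-by-word.
#'
#' @param qualities Output of [word_quality_table()].
#' @param cls `"pos"` or `"neg"`.
#' @return Numeric vector of length K, descending (`NA` purities last).
#' @export
purity_profile <- function(qualities, cls = c("pos", "neg")) {
  cls <- match.arg(cls)
  p <- qualities[[paste0("purity_", cls)]]
  p[order(-p, na.last = TRUE)]
}

#' Quality surface on a stimulus grid
#'
#' Evaluates the signed and absolute density-difference quality on a
#' regular grid over the canvas -- the heat map showing where the two
#' classes' attention densities differ.
#'
#' @param data A [fixation_data()] frame.
#' @param cfg A [kernel_config()].
#' @param nx,ny Grid resolution along x and y.
#' @param canvas Stimulus extent `c(width, height)` in pixels.
#' @return A list of class `quality_map`: grid coordinate vectors `x`, `y`
#'   and matrices `q_signed`, `q_abs` with `q[i, j]` evaluated at
#'   `(x[i], y[j])`.
#' @export
quality_heatmap <- function(data, cfg, nx = 141L, ny = 101L,
                            canvas = c(700, 500)) {
  stopifnot(inherits(cfg, "kernel_config"), nx >= 2L, ny >= 2L)
  gx <- seq(0, canvas[1], length.out = nx)
  gy <- seq(0, canvas[2], length.out = ny)
  queries <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  pos <- fixation_points(data, "pos")
  neg <- fixation_points(data, "neg")
  n <- nrow(data)
  scale <- cfg$c_d / (n * cfg$h^cfg$d)
  sp <- if (nrow(pos)) kde_sum_batch_cpp(queries, pos, cfg$h) else 0
  sm <- if (nrow(neg)) kde_sum_batch_cpp(queries, neg, cfg$h) else 0
  q <- matrix(scale * (sp - sm), nrow = nx, ncol = ny)
  structure(list(x = gx, y = gy, q_signed = q, q_abs = abs(q)),
            class = "quality_map")
}

#' Dictionary and feature serialization
#'
#' Dictionaries are written as delimited text: comment header lines record
#' the method, bandwidth, K and seed, followed by a CSV body with one row
#' per word (`word`, `x`, `y`).
#'
#' @param dict A `gaze_dictionary`.
#' @param path Output file path.
#' @export
write_dictionary <- function(dict, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# method: %s", dict$method_tag),
               sprintf("# h: %s", format(dict$h)),
               sprintf("# K: %d", dict$K),
               sprintf("# seed: %s", format(dict$seed)),
               "word,x,y"), con)
  writeLines(sprintf("%d,%.17g,%.17g", seq_len(dict$K),
                     dict$centroids[, 1L], dict$centroids[, 2L]), con)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("# ", key, ":"), "", ln[1L], fixed = TRUE))
  }
  body <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                     sep = ",")
  new_dictionary(cbind(body$x, body$y), method_tag = get("method"),
                 h = as.numeric(get("h")), seed = as.integer(get("seed")))
}

#' @rdname write_dictionary
#' @param features A `bow_features` frame from [encode_dataset()].
#' @export
write_bow_features <- function(features, path) {
  write.table(as.data.frame(features), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
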