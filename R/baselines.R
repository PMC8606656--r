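# Baseline dictionary learners. All emit the same gaze_dictionary object as
# the proposed learner, so assignment, encoding and evaluation treat them
# identically; method_tag records provenance.

#' K-means dictionary (pooled classes)
#'
#' Plain k-means on all fixation coordinates, the conventional bag-of-words
#' codebook. Density-driven: it favours regions of high pooled fixation
#' concentration regardless of class.
#'
#' @param train A [fixation_data()] frame.
#' @param K Number of words.
#' @param seed Seed for the k-means restarts.
#' @return A `gaze_dictionary` with `method_tag = "kmeans"`.
#' @export
kmeans_dictionary <- function(train, K, seed = 1L) {
  stopifnot(inherits(train, "fixation_data"))
  centroids <- kmeans_centroids_(fixation_points(train), K, seed)
  finalize_dictionary_(centroids, train, "kmeans", h = NA_real_, seed = seed)
}

# Split K across classes: positive class gets ceiling(K/2), negative
# floor(K/2), preserving the total so class-aware and pooled dictionaries
# are comparable at equal K.
class_split_ <- function(K) c(pos = ceiling(K / 2), neg = floor(K / 2))

#' Class-wise k-means dictionary
#'
#' K-means run separately on the positive and negative fixations with
#' approximately equal shares of K, union of centroids. A simple way to
#' inject class structure without changing the clustering objective.
#'
#' @inheritParams kmeans_dictionary
#' @return A `gaze_dictionary` with `method_tag = "class_kmeans"`.
#' @export
class_kmeans_dictionary <- function(train, K, seed = 1L) {
  stopifnot(inherits(train, "fixation_data"), K >= 2L)
  ks <- class_split_(K)
  pos <- fixation_points(train, "pos")
  neg <- fixation_points(train, "neg")
  if (nrow(pos) < ks["pos"] || nrow(neg) < ks["neg"])
    stop("a class has fewer fixations than its share of K")
  centroids <- rbind(kmeans_centroids_(pos, ks["pos"], seed),
                     kmeans_centroids_(neg, ks["neg"], seed + 1L))
  finalize_dictionary_(centroids, train, "class_kmeans", h = NA_real_,
                       seed = seed)
}

#' Mean-shift dictionary (pooled classes)
#'
#' Conventional mean shift on the pooled fixations (subsampled kernel
#' initialization as in the proposed pipeline), followed by k-means on the
#' shifted kernels. Finds pooled density modes with no class information.
#'
#' @inheritParams learn_dictionary
#' @return A `gaze_dictionary` with `method_tag = "meanshift"`.
#' @export
meanshift_dictionary <- function(train, cfg, seek = seek_config(), K,
                                 subsample_rate = 1 / 20, seed = 1L) {
  seek_dictionary_(train, cfg, seek, K, subsample_rate, seed,
                   mode = "classic", method_tag = "meanshift")
}

#' Class-wise mean-shift dictionary
#'
#' Conventional mean shift run within each class, k-means with the class
#' split of K on each set of shifted kernels, union of centroids.
#'
#' @inheritParams learn_dictionary
#' @return A `gaze_dictionary` with `method_tag = "class_meanshift"`.
#' @export
class_meanshift_dictionary <- function(train, cfg, seek = seek_config(), K,
                                       subsample_rate = 1 / 20, seed = 1L) {
  stopifnot(inherits(train, "fixation_data"), K >= 2L)
  ks <- class_split_(K)
  one_class <- function(which, k, s) {
    sub <- train[train$label == if (which == "pos") 1L else -1L, ]
    class(sub) <- c("fixation_data", "data.frame")
    n_init <- ceiling(nrow(sub) * subsample_rate)
    if (n_init < k)
      stop("a class subsample cannot support its share of K; reduce K")
    idx <- with_seed_(s, sample.int(nrow(sub), n_init))
    res <- seek_all(fixation_points(sub)[idx, , drop = FALSE], sub, cfg,
                    seek, mode = "classic")
    kmeans_centroids_(res$finals[!res$failed, , drop = FALSE], k, s)
  }
  centroids <- rbind(one_class("pos", ks["pos"], seed),
                     one_class("neg", ks["neg"], seed + 1L))
  finalize_dictionary_(centroids, train, "class_meanshift", h = cfg$h,
                       seed = seed)
}

#' Density-ratio mode-seeking dictionary
#'
#' Discriminative mode seeking by ascending the guarded class density
#' ratio `p(x | X+) / (p(x | X-) + eps)`, followed by k-means on the
#' shifted kernels. The additive guard (1e-8 times the largest
#' negative-class density over the training points) caps the blow-up of
#' the raw ratio where the denominator vanishes; beyond that the known
#' weaknesses of the ratio objective (no coverage weighting, instability
#' at sparse negative support) are deliberately retained for comparison.
#'
#' @inheritParams learn_dictionary
#' @return A `gaze_dictionary` with `method_tag = "ratio"`.
#' @export
ratio_modeseek_dictionary <- function(train, cfg, seek = seek_config(), K,
                                      subsample_rate = 1 / 20, seed = 1L) {
  seek_dictionary_(train, cfg, seek, K, subsample_rate, seed,
                   mode = "ratio", method_tag = "ratio")
}

#' Fit a dictionary by name
#'
#' Dispatcher over the proposed learner and the five baselines, used by the
#' evaluation protocol and the command line.
#'
#' @inheritParams learn_dictionary
#' @param method One of `"proposed"`, `"kmeans"`, `"class_kmeans"`,
#'   `"meanshift"`, `"class_meanshift"`, `"ratio"`.
#' @return A `gaze_dictionary`.
#' @export
fit_dictionary <- function(train, method, K, cfg = NULL,
                           seek = seek_config(), subsample_rate = 1 / 20,
                           seed = 1L) {
  method <- match.arg(method, c("proposed", "kmeans", "class_kmeans",
                                "meanshift", "class_meanshift", "ratio"))
  if (method %in% c("proposed", "meanshift", "class_meanshift", "ratio") &&
      !inherits(cfg, "kernel_config"))
    stop("method '", method, "' needs a kernel_config bandwidth")
  switch(method,
    proposed = learn_dictionary(train, cfg, seek, K, subsample_rate, seed),
    kmeans = kmeans_dictionary(train, K, seed),
    class_kmeans = class_kmeans_dictionary(train, K, seed),
    meanshift = meanshift_dictionary(train, cfg, seek, K, subsample_rate, seed),
    class_meanshift = class_meanshift_dictionary(train, cfg, seek, K,
                                                 subsample_rate, seed),
    ratio = ratio_modeseek_dictionary(train, cfg, seek, K, subsample_rate,
                                      seed)
  )
}
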