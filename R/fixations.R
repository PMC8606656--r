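#' Labeled fixation dataset
#'
#' Container for 2D eye-fixation records. Each row is one fixation with the
#' stimulus coordinates in pixels, the viewing subject, the viewed image, and
#' the subject's diagnostic label (+1 for the positive class, -1 for the
#' control class). The label is a subject-level attribute and must be
#' constant within each subject.
#'
#' @param x,y Numeric vectors of fixation coordinates (pixels, origin
#'   top-left).
#' @param label Integer vector in \{+1, -1\}, one entry per fixation,
#'   constant within subject.
#' @param subject_id,image_id Vectors (coerced to character) keying the
#'   subject and the viewed image.
#'
#' @return A `data.frame` of class `fixation_data` with columns
#'   `subject_id`, `image_id`, `x`, `y`, `label`.
#' @examples
#' fx <- fixation_data(x = c(10, 20), y = c(5, 6),
#'                     label = c(1, -1),
#'                     subject_id = c("s1", "s2"),
#'                     image_id = c("im1", "im1"))
#' @export
fixation_data <- function(x, y, label, subject_id, image_id) {
  df <- data.frame(
    subject_id = as.character(subject_id),
    image_id   = as.character(image_id),
    x = as.numeric(x), y = as.numeric(y),
    label = as.integer(label),
    stringsAsFactors = FALSE
  )
  validate_fixation_data(df)
}

#' @rdname fixation_data
#' @param df A data frame with the five `fixation_data` columns.
#' @export
validate_fixation_data <- function(df) {
  need <- c("subject_id", "image_id", "x", "y", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing fixation columns: ", paste(miss, collapse = ", "))
  stop_if_not_finite_(df$x, "x")
  stop_if_not_finite_(df$y, "y")
  if (!all(df$label %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  bad <- tapply(df$label, df$subject_id, function(l) length(unique(l)) > 1L)
  if (any(bad)) {
    stop("inconsistent labels within subject(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  df <- df[, need]
  class(df) <- c("fixation_data", "data.frame")
  df
}

# n x 2 coordinate matrix of (a subset of) a fixation dataset.
fixation_points <- function(data, which = c("all", "pos", "neg")) {
  which <- match.arg(which)
  keep <- switch(which,
    all = rep(TRUE, nrow(data)),
    pos = data$label == 1L,
    neg = data$label == -1L
  )
  cbind(x = data$x, y = data$y)[keep, , drop = FALSE]
}

# Subject-level label table: named integer vector, one entry per subject.
subject_labels <- function(data) {
  lab <- tapply(data$label, data$subject_id, function(l) l[1L])
  setNames(as.integer(lab), names(lab))
}

#' @export
print.fixation_data <- function(x, n = 6L, ...) {
  cat(sprintf(
    "<fixation_data> %d fixations | %d subjects (%d pos / %d neg) | %d images\n",
    nrow(x), length(unique(x$subject_id)),
    sum(subject_labels(x) == 1L), sum(subject_labels(x) == -1L),
    length(unique(paste(x$subject_id, x$image_id)))
  ))
  print.data.frame(head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat(sprintf("# ... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Read and write fixation tables
#'
#' Reads a delimited fixation table (comma or tab separated, auto-detected)
#' with a header row and columns `subject_id`, `image_id`, `x`, `y`,
#' `label`. Rows falling outside the stimulus canvas are dropped; the drop
#' count is recorded in the `n_dropped` attribute. Per-subject label
#' consistency is enforced.
#'
#' @param path File path.
#' @param canvas Stimulus extent `c(width, height)` in pixels; fixations
#'   outside `[0, width] x [0, height]` are dropped.
#' @return A `fixation_data` frame with attribute `n_dropped`.
#' @export
read_fixations <- function(path, canvas = c(700, 500)) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) stop("empty fixation file: ", path)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   colClasses = NA)
  if (!nrow(df)) stop("fixation file has a header but no rows: ", path)
  inside <- df$x >= 0 & df$x <= canvas[1] & df$y >= 0 & df$y <= canvas[2]
  n_drop <- sum(!inside)
  df <- df[inside, , drop = FALSE]
  if (!nrow(df)) stop("no fixations remain inside the canvas: ", path)
  out <- validate_fixation_data(df)
  attr(out, "n_dropped") <- n_drop
  out
}

#' @rdname read_fixations
#' @param data A `fixation_data` frame.
#' @param sep Field delimiter, `","` or `"\t"`.
#' @export
write_fixations <- function(data, path, sep = ",") {
  write.table(as.data.frame(data)[, c("subject_id", "image_id", "x", "y", "label")],
              path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
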