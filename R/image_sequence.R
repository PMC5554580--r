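#' Construct an image sequence
#'
#' Bundles an ordered set of grayscale frames into the container used
#' throughout the package. Frames are numeric matrices of identical size with
#' finite intensities in \[0, 1\] (microscopy frames are rescaled to this
#' range on load so that the smoothness weight `alpha` keeps a fixed
#' meaning).
#'
#' @param frames List of numeric matrices (identical dimensions, values in
#'   \[0, 1\]), or a 3-D array with frames along the third dimension.
#' @param frame_interval_s Optional physical time between frames in seconds;
#'   metadata only, never used in computations.
#' @return An object of class `image_sequence`: a list with elements
#'   `frames` (list of matrices) and `frame_interval_s`.
#' @examples
#' f <- matrix(runif(64), 8, 8)
#' seq2 <- image_sequence(list(f, f))
#' length(seq2$frames)
#' @export
image_sequence <- function(frames, frame_interval_s = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  if (!is.list(frames) || length(frames) < 2L) {
    stop("an image sequence needs at least 2 frames", call. = FALSE)
  }
  dims <- vapply(frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f)) {
      stop("each frame must be a numeric matrix", call. = FALSE)
    }
    dim(f)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same height and width", call. = FALSE)
  }
  for (f in frames) {
    if (!all(is.finite(f))) stop("frame intensities must be finite", call. = FALSE)
    if (min(f) < 0 || max(f) > 1) {
      stop("frame intensities must lie in [0, 1]; rescale on load", call. = FALSE)
    }
  }
  structure(
    list(frames = frames, frame_interval_s = frame_interval_s),
    class = "image_sequence"
  )
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<image_sequence> %d frames of %d x %d%s\n",
    length(x$frames), d[1], d[2],
    if (is.null(x$frame_interval_s)) "" else
      sprintf(", frame interval %gs", x$frame_interval_s)
  ))
  invisible(x)
}

#' @export
length.image_sequence <- function(x) length(x$frames)

#' Temporally subsample an image sequence
#'
#' Keeps frames `1, 1 + interval, 1 + 2*interval, ...`. Sampling a video at
#' increasing intervals scales the apparent per-pair displacement, which is
#' the construction behind the frame-interval velocity experiments (e.g. a
#' 500-frame clip at interval 25 gives the 20-frame working sequence).
#'
#' @param seq An [image_sequence()].
#' @param interval Positive integer sampling stride in frames.
#' @return A new `image_sequence` with the retained frames.
#' @examples
#' fr <- replicate(100, matrix(0.5, 4, 4), simplify = FALSE)
#' length(subsample(image_sequence(fr), 40)$frames)  # frames 1, 41, 81
#' @export
subsample <- function(seq, interval) {
  stopifnot(inherits(seq, "image_sequence"))
  if (!is.numeric(interval) || length(interval) != 1L || interval < 1 ||
      interval != round(interval)) {
    stop("`interval` must be a positive integer", call. = FALSE)
  }
  keep <- seq.int(1L, length(seq$frames), by = as.integer(interval))
  if (length(keep) < 2L) {
    stop("subsampling leaves fewer than 2 frames", call. = FALSE)
  }
  image_sequence(seq$frames[keep], frame_interval_s =
                   if (is.null(seq$frame_interval_s)) NULL else
                     seq$frame_interval_s * interval)
}
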