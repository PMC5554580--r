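#' Histogram of oriented optical flow (HOOF)
#'
#' Bins every flow vector by its angle from the horizontal axis,
#' `theta = atan2(v, u)` mapped to `[0, 2*pi)`, into `L` half-open bins
#' `[2*pi*(k-1)/L, 2*pi*k/L)`, weighting each vector by its magnitude
#' `sqrt(u^2 + v^2)`; the histogram is then normalized to sum 1. Zero
#' vectors carry no weight. Note the binning covers the full circle, so the
#' descriptor is direction-sensitive (not mirror-symmetrized).
#'
#' An all-zero flow field yields an all-zero histogram with
#' `normalized = FALSE`, so that distances to it still quantify motion
#' onset.
#'
#' @param flow A [flow_field()].
#' @param L Number of orientation bins (default 16).
#' @param mask Optional logical matrix; if given, only pixels where `mask`
#'   is `TRUE` (e.g. the segmented cell) contribute.
#' @return Object of class `hoof`: numeric vector of `L` bin heights with
#'   attributes `L` and `normalized`.
#' @examples
#' f <- flow_field(matrix(1, 2, 2), matrix(0, 2, 2))
#' hoof(f, L = 16)[1]  # all mass at angle 0
#' @export
hoof <- function(flow, L = 16L, mask = NULL) {
  stopifnot(inherits(flow, "flow_field"))
  if (!is.numeric(L) || length(L) != 1L || L < 2 || L != round(L)) {
    stop("`L` must be an integer >= 2", call. = FALSE)
  }
  L <- as.integer(L)
  u <- flow$u; v <- flow$v
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), identical(dim(mask), dim(u)))
    u <- u[mask]; v <- v[mask]
  }
  mag <- sqrt(u^2 + v^2)
  keep <- mag > 0
  heights <- numeric(L)
  if (any(keep)) {
    ang <- atan2(v[keep], u[keep]) %% (2 * pi)
    bin <- floor(ang / (2 * pi / L)) + 1L
    bin[bin > L] <- 1L  # angle numerically equal to 2*pi wraps to bin 1
    agg <- rowsum(mag[keep], group = bin)
    heights[as.integer(rownames(agg))] <- agg[, 1]
    heights <- heights / sum(heights)
    normalized <- TRUE
  } else {
    normalized <- FALSE
  }
  structure(heights, L = L, normalized = normalized, class = "hoof")
}

#' @export
print.hoof <- function(x, ...) {
  cat(sprintf("<hoof> %d bins%s\n", attr(x, "L"),
              if (attr(x, "normalized")) "" else " (zero flow, unnormalized)"))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Euclidean distance between two HOOFs
#'
#' The motility descriptor compares successive histograms by their plain
#' Euclidean (L2) distance, which is a metric on the normalized histograms.
#'
#' @param a,b `hoof` objects with the same number of bins.
#' @return Non-negative scalar.
#' @export
hoof_distance <- function(a, b) {
  stopifnot(inherits(a, "hoof"), inherits(b, "hoof"))
  if (attr(a, "L") != attr(b, "L")) {
    stop("histograms have different bin counts", call. = FALSE)
  }
  sqrt(sum((unclass(a) - unclass(b))^2))
}

#' Instantaneous mean velocity over the moving support
#'
#' Restricts the flow field to the support `Omega1` of pixels whose
#' magnitude `sqrt(u^2 + v^2)` reaches `threshold` (default 1e-4, which in
#' practice excludes only numerically still background) and returns the mean
#' magnitude over that support together with its area. Because videos are
#' often analyzed after temporal subsampling, this mean velocity grows with
#' the sampling interval on steadily moving content.
#'
#' @param flow A [flow_field()].
#' @param threshold Non-negative magnitude cutoff defining the support.
#' @return List of class `velocity_stats`: `mean_velocity` (px/frame),
#'   `support_area` (pixel count), `threshold`, and `flagged` (`TRUE` when
#'   the support is empty, in which case `mean_velocity` is 0).
#' @examples
#' f <- flow_field(matrix(3, 10, 10), matrix(4, 10, 10))
#' mean_velocity(f)$mean_velocity  # 5
#' @export
mean_velocity <- function(flow, threshold = 1e-4) {
  stopifnot(inherits(flow, "flow_field"), threshold >= 0)
  mag <- sqrt(flow$u^2 + flow$v^2)
  sel <- mag >= threshold
  n <- sum(sel)
  structure(
    list(
      mean_velocity = if (n > 0) mean(mag[sel]) else 0,
      support_area = n,
      threshold = threshold,
      flagged = n == 0
    ),
    class = "velocity_stats"
  )
}

#' @export
print.velocity_stats <- function(x, ...) {
  cat(sprintf("<velocity_stats> mean %.4g px/frame over %d px (threshold %g)%s\n",
              x$mean_velocity, x$support_area, x$threshold,
              if (x$flagged) " [empty support]" else ""))
  invisible(x)
}

#' Motility feature vector of a video
#'
#' The per-video descriptor: the sequence is temporally subsampled, the flow
#' field of every consecutive frame pair is solved, each field is reduced to
#' its HOOF, and the Euclidean distances between consecutive HOOFs are
#' collected in order. A 20-frame working sequence thus yields 19 flow
#' fields, 19 histograms and an 18-element feature vector. Small distances
#' indicate steady/slight intracellular motion; large distances indicate
#' changing, dramatic motion.
#'
#' @param seq An [image_sequence()].
#' @param cfg A [solver_config()].
#' @param sample_interval Temporal subsampling stride (frames) applied
#'   before flow computation; 1 keeps every frame.
#' @param L Number of HOOF bins.
#' @param mask Optional logical matrix restricting the histograms to the
#'   cell region.
#' @return Object of class `motility_features`: numeric vector of
#'   successive-HOOF distances with attributes `n_flows` and `L`.
#' @export
feature_vector <- function(seq, cfg = solver_config(), sample_interval = 1L,
                           L = 16L, mask = NULL) {
  stopifnot(inherits(seq, "image_sequence"))
  sub <- subsample(seq, sample_interval)
  n <- length(sub$frames)
  if (n < 3L) {
    stop("need at least 3 frames after subsampling to form HOOF distances",
         call. = FALSE)
  }
  hoofs <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    fl <- solve_flow(sub, k, cfg)
    hoofs[[k]] <- hoof(fl, L = L, mask = mask)
  }
  d <- vapply(seq_len(n - 2L),
              function(k) hoof_distance(hoofs[[k]], hoofs[[k + 1L]]),
              numeric(1))
  structure(d, n_flows = n - 1L, L = as.integer(L),
            class = "motility_features")
}

#' @export
print.motility_features <- function(x, ...) {
  cat(sprintf("<motility_features> %d successive-HOOF distances from %d flow fields\n",
              length(x), attr(x, "n_flows")))
  print(round(unclass(x), 4))
  invisible(x)
}
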