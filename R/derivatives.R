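# clamped (replicate / Neumann) shifts; x = column index j, y = row index i
shift_right <- function(m) m[, c(2:ncol(m), ncol(m)), drop = FALSE]  # j + 1
shift_left  <- function(m) m[, c(1, 1:(ncol(m) - 1)), drop = FALSE]  # j - 1
shift_down  <- function(m) m[c(2:nrow(m), nrow(m)), , drop = FALSE]  # i + 1
shift_up    <- function(m) m[c(1, 1:(nrow(m) - 1)), , drop = FALSE]  # i - 1

#' Spatio-temporal image derivatives over a 2x2x2 cube
#'
#' Estimates the partial derivatives `Ix`, `Iy`, `It` of image brightness
#' between frames `k` and `k + 1` by the classic four-term cube averages:
#' each derivative is the mean of the four first differences available along
#' its axis within the 2x2x2 cell spanned by pixels `(i, j)`, `(i+1, j+1)`
#' and the two frames. `x` is the column direction, `y` the row direction.
#' Out-of-range neighbors at the last row/column replicate the border value,
#' so the returned grids match the frame size.
#'
#' @param seq An [image_sequence()].
#' @param k Index of the first frame of the pair (`1 <= k <= nframes - 1`).
#' @return An object of class `gradient_triple`: list with matrices
#'   `Ix`, `Iy`, `It`.
#' @examples
#' ramp <- matrix(rep(seq_len(8) / 8, each = 8), 8, 8)
#' g <- compute_derivatives(image_sequence(list(ramp, ramp)), 1)
#' g$Ix[4, 4] * 8  # interior x-slope recovered as 1
#' @export
compute_derivatives <- function(seq, k) {
  stopifnot(inherits(seq, "image_sequence"))
  n <- length(seq$frames)
  if (!is.numeric(k) || length(k) != 1L || k != round(k)) {
    stop("`k` must be a single integer frame index", call. = FALSE)
  }
  if (k < 1 || k > n - 1) {
    stop(sprintf("`k` must be in 1..%d (pairs of consecutive frames)", n - 1),
         call. = FALSE)
  }
  i1 <- seq$frames[[k]]
  i2 <- seq$frames[[k + 1]]
  # forward difference in j applied to the sum over the other two cube axes
  sx <- i1 + shift_down(i1) + i2 + shift_down(i2)
  sy <- i1 + shift_right(i1) + i2 + shift_right(i2)
  dt <- i2 - i1
  structure(
    list(
      Ix = (shift_right(sx) - sx) / 4,
      Iy = (shift_down(sy) - sy) / 4,
      It = (dt + shift_down(dt) + shift_right(dt) + shift_down(shift_right(dt))) / 4
    ),
    class = "gradient_triple"
  )
}

#' Weighted 8-neighbor average
#'
#' The local average used by the discrete Laplacian of the flow solver:
#' weight 1/6 on the four axial neighbors and 1/12 on the four diagonal
#' neighbors (weights sum to 1). Borders replicate the nearest in-range
#' pixel, which keeps the associated Laplacian `avg(u) - u` symmetric, i.e.
#' the gradient of a discrete Dirichlet energy with natural boundary
#' conditions.
#'
#' @param field Numeric matrix with finite entries.
#' @return Matrix of the same size.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 1
#' neighbor_average(m)[3, 2]  # axial weight 1/6
#' @export
neighbor_average <- function(field) {
  if (!is.matrix(field) || !is.numeric(field) || !all(is.finite(field))) {
    stop("`field` must be a finite numeric matrix", call. = FALSE)
  }
  (shift_up(field) + shift_down(field) + shift_left(field) + shift_right(field)) / 6 +
    (shift_up(shift_left(field)) + shift_up(shift_right(field)) +
       shift_down(shift_left(field)) + shift_down(shift_right(field))) / 12
}
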