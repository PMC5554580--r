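#' Solver configuration
#'
#' Parameters of the variational flow solver. Defaults follow the model's
#' reference settings: smoothness weight `alpha = 15` (for intensities in
#' \[0, 1\]), a 5x5 Gaussian mask with `sigma = 1` for the exponent map,
#' `epsilon = 1e-6` perturbing the TV norm `|grad u|_eps = sqrt(|grad u|^2 +
#' eps)`, iteration step `gamma = 0.1`, and an iteration cap of 500 with a
#' relative-change stopping tolerance of 1e-4.
#'
#' @param alpha Positive weight between the data term and the smoothness
#'   term.
#' @param gamma Positive iteration step. The update is applied in a
#'   diagonally semi-implicit form, so any `gamma` is stable; larger values
#'   converge faster (the limit `gamma -> Inf` is the classic Jacobi
#'   fixed-point iteration).
#' @param epsilon Small positive perturbation of the TV norm.
#' @param sigma Gaussian scale (pixels) for the exponent map.
#' @param gauss_size Odd Gaussian mask width (pixels), >= 3.
#' @param max_iter Iteration cap, >= 1.
#' @param tol Positive relative-change stopping tolerance.
#' @param mode One of `"adaptive"` (per-pixel L1/L2 blend), `"hs"` (pure
#'   quadratic / Horn-Schunck), `"tv"` (pure perturbed total variation).
#' @param intensity_scale Gray-level scale on which the model is evaluated.
#'   Frames are stored in \[0, 1\], but the reference parameter values
#'   (`alpha = 15`, the unit constant in the exponent-map denominator) are
#'   calibrated to native 8-bit gray levels, so the solver multiplies
#'   intensities by this factor (default 255) before forming derivatives
#'   and the exponent map. Set to 1 to work directly on \[0, 1\]
#'   intensities (then `alpha` must be recalibrated accordingly).
#' @param blend For `mode = "adaptive"`: `"convex"` blends the two updates
#'   with weights `(2 - p)` on TV and `(p - 1)` on quadratic; `"hard"`
#'   switches at `p = 1.5`.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(alpha = 15, gamma = 0.1, epsilon = 1e-6,
                          sigma = 1.0, gauss_size = 5L, max_iter = 500L,
                          tol = 1e-4, mode = c("adaptive", "hs", "tv"),
                          blend = c("convex", "hard"),
                          intensity_scale = 255) {
  mode <- match.arg(mode)
  blend <- match.arg(blend)
  stopifnot(
    alpha > 0, gamma > 0, epsilon > 0, sigma > 0,
    gauss_size >= 3, gauss_size %% 2 == 1, max_iter >= 1, tol > 0,
    intensity_scale > 0
  )
  structure(
    list(alpha = alpha, gamma = gamma, epsilon = epsilon, sigma = sigma,
         gauss_size = as.integer(gauss_size), max_iter = as.integer(max_iter),
         tol = tol, mode = mode, blend = blend,
         intensity_scale = intensity_scale),
    class = "solver_config"
  )
}

#' Construct a flow field
#'
#' @param u,v Numeric matrices of equal size: horizontal (x, columns) and
#'   vertical (y, rows) displacement components in pixels/frame.
#' @return Object of class `flow_field`: list with `u` and `v`.
#' @export
flow_field <- function(u, v) {
  if (!is.matrix(u) || !is.matrix(v) || !identical(dim(u), dim(v))) {
    stop("`u` and `v` must be numeric matrices of identical size", call. = FALSE)
  }
  if (!all(is.finite(u)) || !all(is.finite(v))) {
    stop("flow components must be finite", call. = FALSE)
  }
  structure(list(u = u, v = v), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("<flow_field> %d x %d, |mean| = %.4g, max |.| = %.4g px/frame\n",
              nrow(x$u), ncol(x$u), mean(mag), max(mag)))
  invisible(x)
}

# weight matrix on the quadratic (HS) update: p - 1; TV weight is 1 - that
blend_weights <- function(p, blend) {
  w <- p - 1
  if (blend == "hard") w <- ifelse(p >= 1.5, 1, 0)
  w
}


run_kernel <- function(flow, grads, w_hs, cfg, max_iter, tol) {
  res <- flow_iterate_cpp(
    grads$Ix, grads$Iy, grads$It, flow$u, flow$v, w_hs,
    cfg$alpha, cfg$gamma, cfg$epsilon, as.integer(max_iter), tol
  )
  out <- flow_field(res$u, res$v)
  attr(out, "iterations") <- res$iterations
  attr(out, "converged") <- res$converged
  out
}

#' One quadratic (Horn-Schunck) flow update
#'
#' Applies a single step of the gradient-descent iteration for the
#' quadratically regularized energy: data residual `(Ix u + Iy v + It)`
#' driven against the discrete Laplacian `avg(u) - u` (see
#' [neighbor_average()]). The step is applied in diagonally semi-implicit
#' form — the terms diagonal in the updated pixel are evaluated at the new
#' value — which leaves the fixed points (the Euler-Lagrange system)
#' untouched while being stable for every step size `gamma`.
#'
#' @param flow A [flow_field()] (current iterate).
#' @param grads A `gradient_triple` from [compute_derivatives()].
#' @param cfg A [solver_config()].
#' @return Updated `flow_field`.
#' @export
hs_update <- function(flow, grads, cfg = solver_config(mode = "hs")) {
  w <- matrix(1, nrow(flow$u), ncol(flow$u))
  run_kernel(flow, grads, w, cfg, max_iter = 1L, tol = 0)
}

#' One perturbed total-variation flow update
#'
#' Single step of the gradient-descent iteration for the TV-regularized
#' energy, with the curvature term `div(grad u / |grad u|_eps)` discretized
#' by the adjoint forward-gradient / backward-divergence pair and
#' `|grad u|_eps = sqrt(|grad u|^2 + epsilon)`. Applied in the same
#' diagonally semi-implicit form as [hs_update()], which is what makes the
#' step usable at small `epsilon` (the explicit step would demand
#' `gamma = O(sqrt(epsilon)/alpha)`).
#'
#' @inheritParams hs_update
#' @return Updated `flow_field`.
#' @export
tv_update <- function(flow, grads, cfg = solver_config(mode = "tv")) {
  w <- matrix(0, nrow(flow$u), ncol(flow$u))
  run_kernel(flow, grads, w, cfg, max_iter = 1L, tol = 0)
}

#' Solve for dense optical flow between two frames
#'
#' Iterates the variational flow updates from a zero initial field until the
#' relative flow change drops below `cfg$tol` or `cfg$max_iter` is reached.
#' `mode = "hs"` uses the quadratic update only, `mode = "tv"` the perturbed
#' TV update only; `mode = "adaptive"` computes the exponent map
#' [compute_p_map()] from frame `k` and blends the two updates per pixel
#' with convex weights `(p - 1)` (quadratic) and `(2 - p)` (TV), so flat
#' regions get smooth flow detail and edges keep motion discontinuities.
#'
#' The data term is linearized (brightness constancy to first order), so
#' displacements should be small — a fraction of the texture scale, in
#' practice up to roughly 1 pixel. No coarse-to-fine pyramid is applied.
#'
#' @param seq An [image_sequence()].
#' @param k Index of the first frame of the pair.
#' @param cfg A [solver_config()].
#' @return A [flow_field()] with attributes `iterations` (count used),
#'   `converged` (logical; `FALSE` means the cap was hit, which is reported
#'   via a warning but not an error), and for adaptive mode `p_map`.
#' @examples
#' fr <- matrix(rep(sin(seq_len(32) / 3), each = 32), 32, 32) / 4 + 0.5
#' s <- image_sequence(list(fr, fr))
#' f <- solve_flow(s, 1)           # identical frames: exactly zero flow
#' max(abs(f$u))
#' @export
solve_flow <- function(seq, k, cfg = solver_config()) {
  stopifnot(inherits(seq, "image_sequence"), inherits(cfg, "solver_config"))
  grads <- compute_derivatives(seq, k)
  if (cfg$intensity_scale != 1) {
    grads$Ix <- grads$Ix * cfg$intensity_scale
    grads$Iy <- grads$Iy * cfg$intensity_scale
    grads$It <- grads$It * cfg$intensity_scale
  }
  frame <- seq$frames[[k]]
  pm <- NULL
  w <- switch(cfg$mode,
    hs = matrix(1, nrow(frame), ncol(frame)),
    tv = matrix(0, nrow(frame), ncol(frame)),
    adaptive = {
      pm <- compute_p_map(frame, cfg)
      blend_weights(unclass(pm), cfg$blend)
    }
  )
  zero <- matrix(0, nrow(frame), ncol(frame))
  out <- run_kernel(flow_field(zero, zero), grads, w, cfg,
                    max_iter = cfg$max_iter, tol = cfg$tol)
  if (!attr(out, "converged")) {
    warning(sprintf(
      "flow solve did not reach tol = %g within %d iterations; returning current iterate",
      cfg$tol, cfg$max_iter), call. = FALSE)
  }
  if (!is.null(pm)) attr(out, "p_map") <- pm
  out
}
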