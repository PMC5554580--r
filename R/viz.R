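#' Color-code a flow field
#'
#' Two renderings of a dense flow field:
#' * `mode = "wheel"` — direction maps to hue around the color wheel and
#'   magnitude to saturation (zero flow is white), the usual optical-flow
#'   wheel coding;
#' * `mode = "magnitude"` — speed only, on a blue (slow) to red (fast)
#'   ramp, as used for velocity maps.
#'
#' @param flow A [flow_field()].
#' @param max_magnitude Magnitude mapped to full saturation/red. `NULL`
#'   (auto) uses the field's own maximum, making the wheel rendering
#'   invariant to uniform flow scaling.
#' @param mode `"wheel"` or `"magnitude"`.
#' @return Object of class `flow_color_image`: array height x width x 3 of
#'   RGB in \[0, 1\].
#' @export
color_code <- function(flow, max_magnitude = NULL,
                       mode = c("wheel", "magnitude")) {
  stopifnot(inherits(flow, "flow_field"))
  mode <- match.arg(mode)
  h <- nrow(flow$u); w <- ncol(flow$u)
  mag <- sqrt(flow$u^2 + flow$v^2)
  if (is.null(max_magnitude)) max_magnitude <- max(mag)
  rel <- if (max_magnitude > 0) pmin(mag / max_magnitude, 1) else mag * 0
  if (mode == "wheel") {
    ang <- atan2(flow$v, flow$u) %% (2 * pi)
    hue <- as.vector(ang) / (2 * pi)
    hue[hue >= 1] <- 0
    cols <- hsv(h = hue, s = as.vector(rel), v = 1)
    rgbm <- col2rgb(cols) / 255
  } else {
    ramp <- colorRamp(c("#0000FF", "#00FFFF", "#FFFF00", "#FF0000"))
    rgbm <- t(ramp(as.vector(rel))) / 255
  }
  out <- array(0, dim = c(h, w, 3))
  for (c in 1:3) out[, , c] <- matrix(rgbm[c, ], h, w)
  structure(out, mode = mode, max_magnitude = max_magnitude,
            class = "flow_color_image")
}

#' Write a color-coded flow image as PNG
#'
#' @param img A `flow_color_image` from [color_code()].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_flow_png <- function(img, path) {
  stopifnot(inherits(img, "flow_color_image"))
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' Quiver plot of a flow field
#'
#' Draws the flow as arrows on a subsampled pixel grid, optionally over the
#' source frame; arrow direction is the motion direction and arrow length
#' the (scaled) magnitude.
#'
#' @param flow A [flow_field()].
#' @param frame Optional background intensity matrix.
#' @param step Arrow grid stride in pixels.
#' @param scale Arrow length multiplier.
#' @param ... Passed to [graphics::arrows()].
#' @return The flow, invisibly.
#' @export
plot_flow <- function(flow, frame = NULL, step = 4L, scale = 5, ...) {
  stopifnot(inherits(flow, "flow_field"))
  h <- nrow(flow$u); w <- ncol(flow$u)
  plot.new()
  plot.window(xlim = c(1, w), ylim = c(h, 1), asp = 1)
  if (!is.null(frame)) {
    rasterImage(frame, 1, h, w, 1, interpolate = FALSE)
  }
  ys <- seq(1L, h, by = step)
  xs <- seq(1L, w, by = step)
  gy <- rep(ys, times = length(xs))
  gx <- rep(xs, each = length(ys))
  du <- flow$u[cbind(gy, gx)] * scale
  dv <- flow$v[cbind(gy, gx)] * scale
  keep <- sqrt(du^2 + dv^2) > 1e-8
  if (any(keep)) {
    arrows(gx[keep], gy[keep], gx[keep] + du[keep], gy[keep] + dv[keep],
           length = 0.03, col = if (is.null(frame)) "black" else "yellow", ...)
  }
  invisible(flow)
}

#' @export
plot.hoof <- function(x, ...) {
  L <- attr(x, "L")
  barplot(unclass(x), names.arg = round(360 * (seq_len(L) - 1) / L),
          xlab = "orientation (degrees)", ylab = "normalized weight", ...)
  invisible(x)
}
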