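#' Specification of a synthetic cell video
#'
#' Describes a single-cell microscopy-like clip: a band-limited random
#' texture inside an elliptical cell on a flat background, whose interior
#' texture is advected frame to frame by a chosen motion model while the
#' cell outline stays fixed (intracellular motion, not whole-cell
#' migration). Displacements are tapered smoothly to zero at the cell
#' boundary so the texture never crosses it.
#'
#' Defaults are the package's reference study conditions: 64 x 64 frames,
#' 10 frames, cell radius 24 px, texture correlation scale 3 px, additive
#' Gaussian sensor noise with sd 0.01 (about 2.5 gray levels of an 8-bit
#' camera), and the `"random_smooth"` motion model, which draws a fresh
#' Gaussian-smoothed random internal displacement field for every frame
#' pair — the closest simple analog of incoherent intracellular motion.
#'
#' @param height,width Frame size in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param cell_radius Semi-major axis of the cell ellipse in pixels; the
#'   ellipse is slightly anisotropic (minor axis 0.8 of this) and must fit
#'   the frame with a margin of at least 2 pixels.
#' @param texture_scale Correlation length of the interior texture in
#'   pixels.
#' @param motion_model One of `"random_smooth"`, `"translation"`,
#'   `"swirl"`.
#' @param motion_magnitude Nominal displacement per frame in pixels: the
#'   uniform speed for `"translation"`, the rim speed for `"swirl"`, the
#'   RMS in-cell speed for `"random_smooth"`. Must stay well below a pixel
#'   for the linearized flow model to apply.
#' @param noise_sd Standard deviation of i.i.d. Gaussian intensity noise.
#' @param seed Integer seed; videos are reproducible bit for bit.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 64L, width = 64L, n_frames = 10L,
                           cell_radius = 24, texture_scale = 3,
                           motion_model = c("random_smooth", "translation", "swirl"),
                           motion_magnitude = 0.5, noise_sd = 0.01,
                           seed = 1L) {
  motion_model <- match.arg(motion_model)
  stopifnot(
    height >= 8, width >= 8, n_frames >= 2, cell_radius > 2,
    texture_scale > 0, motion_magnitude >= 0, noise_sd >= 0
  )
  if (cell_radius > min(height, width) / 2 - 2) {
    stop("cell must fit the frame with a margin of at least 2 pixels",
         call. = FALSE)
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_frames = as.integer(n_frames), cell_radius = cell_radius,
         texture_scale = texture_scale, motion_model = motion_model,
         motion_magnitude = motion_magnitude, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# geometry helpers -----------------------------------------------------------

# normalized elliptical radius (1 on the cell outline) at every pixel
cell_rho <- function(spec) {
  cy <- (spec$height + 1) / 2
  cx <- (spec$width + 1) / 2
  yy <- matrix(seq_len(spec$height) - cy, spec$height, spec$width)
  xx <- matrix(rep(seq_len(spec$width) - cx, each = spec$height),
               spec$height, spec$width)
  list(rho = sqrt((xx / spec$cell_radius)^2 + (yy / (0.8 * spec$cell_radius))^2),
       xx = xx, yy = yy)
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# 1 in the cell core (rho <= 0.6), 0 outside rho >= 0.95
motion_taper <- function(rho) smoothstep((0.95 - rho) / 0.35)

# bilinear sample of matrix `m` at continuous positions (rows yq, cols xq),
# clamped to the image domain
bilinear_sample <- function(m, yq, xq) {
  h <- nrow(m); w <- ncol(m)
  yq <- pmin(pmax(yq, 1), h)
  xq <- pmin(pmax(xq, 1), w)
  y0 <- pmin(floor(yq), h - 1); x0 <- pmin(floor(xq), w - 1)
  fy <- yq - y0; fx <- xq - x0
  idx <- function(r, c) m[cbind(as.vector(r), as.vector(c))]
  out <- (1 - fy) * (1 - fx) * idx(y0, x0) +
    (1 - fy) * fx * idx(y0, x0 + 1) +
    fy * (1 - fx) * idx(y0 + 1, x0) +
    fy * fx * idx(y0 + 1, x0 + 1)
  matrix(out, h, w)
}

# band-limited standardized random field
smooth_noise_field <- function(h, w, scale) {
  gauss_blur(matrix(rnorm(h * w), h, w), sigma = scale)
}

# per-pair displacement field (u = x, v = y) for frame pair k -> k + 1
motion_displacement <- function(spec, geom, k, direction = NULL) {
  taper <- motion_taper(geom$rho)
  m <- spec$motion_magnitude
  switch(spec$motion_model,
    translation = {
      list(u = m * direction[1] * taper, v = m * direction[2] * taper)
    },
    swirl = {
      # rim speed m at the core edge (rho = 0.6), solid-body inside
      omega <- m / (0.6 * spec$cell_radius)
      list(u = -omega * geom$yy * taper, v = omega * geom$xx * taper)
    },
    random_smooth = {
      fu <- smooth_noise_field(spec$height, spec$width, 2 * spec$texture_scale)
      fv <- smooth_noise_field(spec$height, spec$width, 2 * spec$texture_scale)
      core <- geom$rho <= 0.95
      rms <- sqrt(mean(fu[core]^2 + fv[core]^2))
      list(u = m * fu / rms * taper, v = m * fv / rms * taper)
    }
  )
}

#' Generate a synthetic cell video with ground-truth motion
#'
#' Renders the textured cell of a [synthetic_spec()] and advects its
#' interior texture frame by frame, returning both the image sequence and
#' the true per-pair displacement fields. For `"translation"` and
#' `"swirl"` every frame is sampled directly from the base texture through
#' the accumulated backward map, so no interpolation blur builds up; the
#' time-varying `"random_smooth"` model warps frame to frame with bilinear
#' interpolation. Sensor noise is added last. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_video`: `seq` (an
#'   [image_sequence()]), `flows` (list of `n_frames - 1` ground-truth
#'   [flow_field()]s), `mask` (logical cell-interior matrix),
#'   `core` (logical matrix of the untapered core, where the nominal
#'   motion applies exactly), and `spec`.
#' @export
generate_video <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  drift <- spec$motion_magnitude * (spec$n_frames - 1)
  if (spec$motion_model == "translation" && drift > 0.5 * spec$cell_radius) {
    stop("cumulative translation would carry the texture out of the cell",
         call. = FALSE)
  }
  if (spec$motion_magnitude > 0.5 * spec$cell_radius) {
    stop("per-frame motion exceeds half the cell radius", call. = FALSE)
  }
  geom <- cell_rho(spec)
  with_seed(spec$seed, {
    tex <- smooth_noise_field(spec$height, spec$width, spec$texture_scale)
    tex <- tex / max(stats::sd(tex), 1e-12)
    interior <- pmin(pmax(0.55 + 0.22 * tex, 0.05), 0.95)
    mask_soft <- smoothstep((1 - geom$rho) / 0.08)  # 1 inside, 0 outside
    bg <- 0.15
    compose <- function(inside) bg + mask_soft * (inside - bg)

    direction <- NULL
    if (spec$motion_model == "translation") {
      th <- stats::runif(1, 0, 2 * pi)
      direction <- c(cos(th), sin(th))
    }

    rows0 <- matrix(seq_len(spec$height), spec$height, spec$width)
    cols0 <- matrix(rep(seq_len(spec$width), each = spec$height),
                    spec$height, spec$width)

    frames <- vector("list", spec$n_frames)
    flows <- vector("list", spec$n_frames - 1L)
    if (spec$motion_model %in% c("translation", "swirl")) {
      d1 <- motion_displacement(spec, geom, 1L, direction)
      for (k in seq_len(spec$n_frames)) {
        # accumulated backward map: k-1 applications of the per-pair field
        warped <- bilinear_sample(interior,
                                  rows0 - (k - 1) * d1$v,
                                  cols0 - (k - 1) * d1$u)
        frames[[k]] <- compose(warped)
        if (k < spec$n_frames) flows[[k]] <- flow_field(d1$u, d1$v)
      }
    } else {
      cur <- interior
      frames[[1]] <- compose(cur)
      for (k in seq_len(spec$n_frames - 1L)) {
        d <- motion_displacement(spec, geom, k)
        cur <- bilinear_sample(cur, rows0 - d$v, cols0 - d$u)
        frames[[k + 1]] <- compose(cur)
        flows[[k]] <- flow_field(d$u, d$v)
      }
    }
    if (spec$noise_sd > 0) {
      frames <- lapply(frames, function(f) {
        pmin(pmax(f + matrix(rnorm(length(f), sd = spec$noise_sd),
                             nrow(f), ncol(f)), 0), 1)
      })
    }
    structure(
      list(seq = image_sequence(frames),
           flows = flows,
           mask = geom$rho <= 1,
           core = geom$rho <= 0.6,
           spec = spec),
      class = "synthetic_video"
    )
  })
}

#' Generate a labeled three-class motility cohort
#'
#' Builds `n_per_class` videos for each of three motility grades (slight,
#' moderate, dramatic) by drawing each video's motion magnitude near its
#' class magnitude with a +/-10% uniform jitter, under per-video seeds
#' derived from `seed`. The default magnitudes (0.2, 0.6, 1.2) px/frame
#' keep all classes within the solver's small-displacement regime while
#' spanning an order of magnitude of motility, emulating a 3 x 40 cohort
#' design.
#'
#' @param n_per_class Videos per class (>= 2).
#' @param class_magnitudes Three strictly increasing nominal magnitudes
#'   (px/frame).
#' @param base_spec Template [synthetic_spec()]; its magnitude and seed are
#'   overridden per video.
#' @param seed Integer master seed.
#' @return List of class `synthetic_cohort`: `videos` (list of
#'   `synthetic_video`), `labels` (factor with levels slight/moderate/
#'   dramatic), `magnitudes` (per-video numeric).
#' @export
generate_cohort <- function(n_per_class = 40L,
                            class_magnitudes = c(0.2, 0.6, 1.2),
                            base_spec = synthetic_spec(),
                            seed = 1L) {
  stopifnot(inherits(base_spec, "synthetic_spec"))
  if (length(class_magnitudes) != 3L || any(diff(class_magnitudes) <= 0)) {
    stop("`class_magnitudes` must be three strictly increasing values",
         call. = FALSE)
  }
  if (n_per_class < 2L) stop("`n_per_class` must be >= 2", call. = FALSE)
  n_total <- 3L * n_per_class
  lv <- c("slight", "moderate", "dramatic")
  labels <- factor(rep(lv, each = n_per_class), levels = lv)
  with_seed(seed, {
    video_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    jitter <- stats::runif(n_total, 0.9, 1.1)
  })
  magnitudes <- rep(class_magnitudes, each = n_per_class) * jitter
  videos <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sp <- base_spec
    sp$motion_magnitude <- magnitudes[i]
    sp$seed <- video_seeds[i]
    videos[[i]] <- generate_video(sp)
  }
  structure(
    list(videos = videos, labels = labels, magnitudes = magnitudes),
    class = "synthetic_cohort"
  )
}
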