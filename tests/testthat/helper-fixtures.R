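# Shared fixtures, all generated in code.

# smooth band-limited texture in [0.05, 0.95], analytic (sum of incommensurate
# sinusoids) so that translated copies can be rendered without interpolation
analytic_texture <- function(h, w, shift_x = 0, shift_y = 0) {
  yy <- matrix(seq_len(h) - shift_y, h, w)
  xx <- matrix(rep(seq_len(w), each = h), h, w) - shift_x
  t <- sin(xx / 2.1) + cos(yy / 2.7) + sin((xx + yy) / 3.9) +
    cos((2 * xx - yy) / 5.3)
  0.5 + 0.2 * t / 2
}

# frame pair translated by (dx, dy), rendered exactly from the analytic form
analytic_pair <- function(h, w, dx, dy) {
  image_sequence(list(
    analytic_texture(h, w),
    analytic_texture(h, w, shift_x = dx, shift_y = dy)
  ))
}

# brute-force loop implementation of the 2x2x2 cube derivatives, clamped
loop_derivatives <- function(i1, i2) {
  h <- nrow(i1); w <- ncol(i1)
  at <- function(m, i, j) m[min(i, h), min(j, w)]
  Ix <- Iy <- It <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    Ix[i, j] <- (at(i1, i, j + 1) - at(i1, i, j) +
                 at(i1, i + 1, j + 1) - at(i1, i + 1, j) +
                 at(i2, i, j + 1) - at(i2, i, j) +
                 at(i2, i + 1, j + 1) - at(i2, i + 1, j)) / 4
    Iy[i, j] <- (at(i1, i + 1, j) - at(i1, i, j) +
                 at(i1, i + 1, j + 1) - at(i1, i, j + 1) +
                 at(i2, i + 1, j) - at(i2, i, j) +
                 at(i2, i + 1, j + 1) - at(i2, i, j + 1)) / 4
    It[i, j] <- (at(i2, i, j) - at(i1, i, j) +
                 at(i2, i + 1, j) - at(i1, i + 1, j) +
                 at(i2, i, j + 1) - at(i1, i, j + 1) +
                 at(i2, i + 1, j + 1) - at(i1, i + 1, j + 1)) / 4
  }
  list(Ix = Ix, Iy = Iy, It = It)
}

# brute-force loop implementation of the weighted 8-neighbor average, clamped
loop_neighbor_average <- function(m) {
  h <- nrow(m); w <- ncol(m)
  cl <- function(a, n) min(max(a, 1), n)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    out[i, j] <-
      (m[cl(i - 1, h), j] + m[cl(i + 1, h), j] +
       m[i, cl(j - 1, w)] + m[i, cl(j + 1, w)]) / 6 +
      (m[cl(i - 1, h), cl(j - 1, w)] + m[cl(i - 1, h), cl(j + 1, w)] +
       m[cl(i + 1, h), cl(j - 1, w)] + m[cl(i + 1, h), cl(j + 1, w)]) / 12
  }
  out
}

# brute-force per-vector HOOF tally
loop_hoof <- function(u, v, L) {
  heights <- numeric(L)
  for (i in seq_along(u)) {
    mag <- sqrt(u[i]^2 + v[i]^2)
    if (mag == 0) next
    ang <- atan2(v[i], u[i]) %% (2 * pi)
    b <- floor(ang / (2 * pi / L)) + 1
    if (b > L) b <- 1
    heights[b] <- heights[b] + mag
  }
  if (sum(heights) > 0) heights / sum(heights) else heights
}

# discrete quadratic (p = 2) flow energy matching the solver's stencils:
# data term 1/2 (Ix u + Iy v + It)^2 plus alpha/4 * sum of weighted squared
# differences to the 8 clamped neighbors (weights 1/6 axial, 1/12 diagonal)
hs_energy <- function(u, v, grads, alpha) {
  pair_energy <- function(m) {
    h <- nrow(m); w <- ncol(m)
    cl <- function(a, n) pmin(pmax(a, 1), n)
    e <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      wgt <- if (di == 0 || dj == 0) 1 / 6 else 1 / 12
      nb <- m[cbind(as.vector(cl(row(m) + di, h)), as.vector(cl(col(m) + dj, w)))]
      e <- e + wgt * sum((nb - as.vector(m))^2)
    }
    e / 4
  }
  r <- grads$Ix * u + grads$Iy * v + grads$It
  sum(r^2) / 2 + alpha * (pair_energy(u) + pair_energy(v))
}

# sparse direct solve of the quadratic Euler-Lagrange system
# (Ix^2 + alpha L) u + Ix Iy v = -Ix It (and symmetrically for v),
# with L = I - W, W the clamped weighted-average stencil
direct_hs_solve <- function(grads, alpha) {
  h <- nrow(grads$Ix); w <- ncol(grads$Ix); N <- h * w
  idx <- matrix(seq_len(N), h, w)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    wgt <- if (di == 0 || dj == 0) 1 / 6 else 1 / 12
    ii <- pmin(pmax(row(idx) + di, 1), h)
    jj <- pmin(pmax(col(idx) + dj, 1), w)
    rows <- c(rows, as.vector(idx))
    cols <- c(cols, idx[cbind(as.vector(ii), as.vector(jj))])
    vals <- c(vals, rep(wgt, N))
  }
  W <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
  L <- Matrix::Diagonal(N) - W
  A <- rbind(
    cbind(Matrix::Diagonal(N, x = as.vector(grads$Ix^2)) + alpha * L,
          Matrix::Diagonal(N, x = as.vector(grads$Ix * grads$Iy))),
    cbind(Matrix::Diagonal(N, x = as.vector(grads$Ix * grads$Iy)),
          Matrix::Diagonal(N, x = as.vector(grads$Iy^2)) + alpha * L)
  )
  b <- -c(as.vector(grads$Ix * grads$It), as.vector(grads$Iy * grads$It))
  sol <- Matrix::solve(A, b)
  list(u = matrix(sol[1:N], h, w), v = matrix(sol[N + 1:N], h, w))
}

# frame pair with piecewise-constant motion: the left half translates by
# dx pixels, the right half is static (smooth random texture, seeded by caller)
two_region_pair <- function(h, w, dx) {
  tex <- motiflow:::gauss_blur(matrix(rnorm(h * w), h, w), 2.5)
  tex <- pmin(pmax(0.5 + 0.2 * tex / stats::sd(tex), 0.05), 0.95)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  rows0 <- matrix(seq_len(h), h, w)
  move <- ifelse(xs <= w / 2, dx, 0)
  f2 <- motiflow:::bilinear_sample(tex, rows0, xs - move)
  image_sequence(list(tex, f2))
}

# evaluate `code` under a temporary seed without disturbing the session RNG
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# small labeled cohort with extracted features, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

small_cohort_features <- function() {
  if (is.null(.fixture_cache$small_cf)) {
    coh <- generate_cohort(
      n_per_class = 12,
      base_spec = synthetic_spec(height = 48L, width = 48L, n_frames = 8L,
                                 cell_radius = 17),
      seed = 42
    )
    fvs <- lapply(coh$videos,
                  function(v) suppressWarnings(feature_vector(v$seq)))
    .fixture_cache$small_cf <- list(
      cf = cohort_features(fvs, coh$labels),
      cohort = coh
    )
  }
  .fixture_cache$small_cf
}
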