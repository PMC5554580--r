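flow_from <- function(u, v) flow_field(matrix(u, 1), matrix(v, 1))

test_that("single vectors land in the expected bins with magnitude weights", {
  f <- flow_field(matrix(1, 1, 1), matrix(0, 1, 1))
  h <- hoof(f, L = 16)
  expect_equal(as.numeric(h), c(1, rep(0, 15)))
  expect_true(attr(h, "normalized"))

  # (1,0) and (-2,0): bin at angle pi holds 2/3, bin at angle 0 holds 1/3
  f2 <- flow_field(matrix(c(1, -2), 1, 2), matrix(0, 1, 2))
  h2 <- as.numeric(hoof(f2, L = 16))
  expect_equal(h2[1], 1 / 3)
  expect_equal(h2[9], 2 / 3)
  expect_equal(sum(h2 != 0), 2)
})

test_that("hoof matches a brute-force per-vector tally on random fields", {
  set.seed(41)
  for (rep in 1:5) {
    u <- matrix(rnorm(10), 2, 5)
    v <- matrix(rnorm(10), 2, 5)
    expect_equal(as.numeric(hoof(flow_field(u, v), L = 16)), loop_hoof(u, v, 16))
    expect_equal(as.numeric(hoof(flow_field(u, v), L = 7)), loop_hoof(u, v, 7))
  }
})

test_that("an all-zero flow yields the flagged zero histogram", {
  h <- hoof(flow_field(matrix(0, 3, 3), matrix(0, 3, 3)))
  expect_equal(as.numeric(h), rep(0, 16))
  expect_false(attr(h, "normalized"))
})

test_that("histograms normalize to one and are scale invariant", {
  set.seed(42)
  u <- matrix(rnorm(64), 8, 8); v <- matrix(rnorm(64), 8, 8)
  h1 <- hoof(flow_field(u, v))
  expect_equal(sum(h1), 1)
  for (c in c(0.01, 3, 250)) {
    expect_equal(as.numeric(hoof(flow_field(c * u, c * v))), as.numeric(h1))
  }
})

test_that("rotating all vectors by one bin width cyclically shifts the bins", {
  set.seed(43)
  u <- matrix(rnorm(36), 6, 6); v <- matrix(rnorm(36), 6, 6)
  L <- 16
  th <- 2 * pi / L
  ur <- cos(th) * u - sin(th) * v
  vr <- sin(th) * u + cos(th) * v
  h <- as.numeric(hoof(flow_field(u, v), L))
  hr <- as.numeric(hoof(flow_field(ur, vr), L))
  expect_equal(hr, h[c(L, 1:(L - 1))])
})

test_that("hoof_distance is the Euclidean metric on histograms", {
  set.seed(44)
  mk <- function() hoof(flow_field(matrix(rnorm(25), 5), matrix(rnorm(25), 5)))
  a <- mk(); b <- mk(); c <- mk()
  expect_equal(hoof_distance(a, a), 0)
  expect_equal(hoof_distance(a, b), sqrt(sum((as.numeric(a) - as.numeric(b))^2)))
  expect_equal(hoof_distance(a, b), hoof_distance(b, a))
  expect_lte(hoof_distance(a, c), hoof_distance(a, b) + hoof_distance(b, c))

  # unit mass in adjacent bins: distance sqrt(2)
  e1 <- hoof(flow_field(matrix(1, 1, 1), matrix(0, 1, 1)))
  e2 <- hoof(flow_field(matrix(cos(pi / 8), 1, 1), matrix(sin(pi / 8), 1, 1)))
  expect_equal(hoof_distance(e1, e2), sqrt(2))

  bad <- hoof(flow_field(matrix(1, 1, 1), matrix(0, 1, 1)), L = 8)
  expect_error(hoof_distance(e1, bad), "different bin counts")
})

test_that("mean velocity averages magnitudes over the thresholded support", {
  f <- flow_field(matrix(3, 10, 10), matrix(4, 10, 10))
  vs <- mean_velocity(f)
  expect_equal(vs$mean_velocity, 5)
  expect_equal(vs$support_area, 100)
  expect_false(vs$flagged)

  z <- mean_velocity(flow_field(matrix(0, 4, 4), matrix(0, 4, 4)))
  expect_true(z$flagged)
  expect_equal(z$support_area, 0)
  expect_equal(z$mean_velocity, 0)

  # half the pixels at magnitude 2, half below threshold
  u <- matrix(c(2, 1e-6), 4, 4)
  vs2 <- mean_velocity(flow_field(u, 0 * u), threshold = 1e-4)
  expect_equal(vs2$mean_velocity, 2)
  expect_equal(vs2$support_area, 8)
})

test_that("a restriction mask limits the histogram support", {
  u <- rbind(c(1, 0), c(0, 0))
  v <- rbind(c(0, 0), c(0, 1))
  mask <- rbind(c(TRUE, TRUE), c(TRUE, FALSE))
  h <- as.numeric(hoof(flow_field(u, v), L = 4, mask = mask))
  expect_equal(h, c(1, 0, 0, 0))  # the (0,1) pixel is masked out
})
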