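test_that("distance matrix matches a brute-force double loop", {
  set.seed(51)
  x <- matrix(rnorm(5 * 4), 5, 4)
  cf <- cohort_features(x, c("a", "a", "b", "b", "b"))
  D <- distance_matrix(cf)
  expect_equal(dim(D), c(5L, 5L))
  expect_equal(diag(D), rep(0, 5), ignore_attr = TRUE)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(D[i, j], sqrt(sum((x[i, ] - x[j, ])^2)))
    expect_equal(D[i, j], D[j, i])
  }
  # unit axis vectors are sqrt(2) apart
  e <- diag(2)
  De <- distance_matrix(cohort_features(e, c("a", "b")))
  expect_equal(De[1, 2], sqrt(2))
})

test_that("cohort_features validates shapes and labels", {
  expect_error(cohort_features(list(1:3, 1:4), c("a", "b")), "same length")
  expect_error(cohort_features(list(1:3, 1:3), c("a", "a")), "two classes")
  expect_error(cohort_features(matrix(0, 3, 2), c("a", "b")), "one entry per")
})

test_that("classical MDS reconstructs exact low-rank configurations", {
  # equilateral triangle of side 1
  D3 <- matrix(1, 3, 3) - diag(3)
  emb <- mds_embed(D3, 2)
  expect_equal(as.matrix(stats::dist(emb)), D3, ignore_attr = TRUE,
               tolerance = 1e-9)

  # collinear points embed on one axis
  xs <- c(0, 1, 2.5, 4)
  Dl <- abs(outer(xs, xs, "-"))
  el <- mds_embed(Dl, 2)
  expect_lt(max(abs(el[, 2])), 1e-6)
  expect_true(attr(el, "flagged"))  # only one positive eigenvalue

  # random planar configurations are reproduced to numerical accuracy
  set.seed(52)
  pts <- matrix(rnorm(14), 7, 2)
  Dp <- as.matrix(stats::dist(pts))
  ep <- mds_embed(Dp, 2)
  expect_equal(as.matrix(stats::dist(ep)), Dp, ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_false(attr(ep, "flagged"))
})

test_that("mds_embed rejects malformed distance matrices", {
  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(mds_embed(matrix(c(1, 0, 0, 1), 2, 2)), "zero diagonal")
})

test_that("duplicated train/test structure is classified perfectly", {
  base <- rbind(matrix(0, 10, 3), matrix(5, 10, 3), matrix(-5, 10, 3))
  cf <- cohort_features(base + 0.01 * matrix(rnorm(90), 30, 3),
                        rep(c("s", "m", "d"), each = 10))
  res <- classify_cohort(cf, n_train_per_class = 5, n_test_per_class = 5,
                         seed = 3)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_train, 15)
  expect_equal(res$n_test, 15)
  expect_error(classify_cohort(cf, 20, 20), "at least 40")
})

test_that("splits are seeded and train/test are disjoint by construction", {
  set.seed(53)
  cf <- cohort_features(matrix(rnorm(40 * 4), 40, 4), rep(c("a", "b"), each = 20))
  r1 <- classify_cohort(cf, 8, 8, seed = 11)
  r2 <- classify_cohort(cf, 8, 8, seed = 11)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("label-shuffled motility features classify near chance", {
  sc <- small_cohort_features()
  cf <- sc$cf
  accs <- vapply(1:20, function(s) {
    shuffled <- with_seed_local(1000 + s, sample(cf$labels))
    classify_cohort(cohort_features(cf$x, shuffled), 6, 6, seed = s)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.15)
  expect_lte(mean(accs), 0.55)
})

test_that("true motility labels of the synthetic cohort are separable", {
  sc <- small_cohort_features()
  accs <- vapply(1:5, function(s) {
    classify_cohort(sc$cf, 6, 6, seed = s)$accuracy
  }, numeric(1))
  expect_gte(stats::median(accs), 0.7)

  # and the classes separate in the MDS plane
  skip_if_not_installed("cluster")
  emb <- mds_embed(distance_matrix(sc$cf), 2)
  sil <- cluster::silhouette(as.integer(sc$cf$labels), stats::dist(emb))
  expect_gt(mean(sil[, 3]), 0)
})
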