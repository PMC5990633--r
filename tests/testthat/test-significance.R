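test_that("random rotations are orthogonal, proper and seeded", {
  set.seed(4)
  for (i in 1:20) {
    Q <- random_rotation()
    expect_lt(max(abs(crossprod(Q) - diag(3))), 1e-12)
    expect_equal(det(Q), 1, tolerance = 1e-12)
  }
  set.seed(99); Q1 <- random_rotation()
  set.seed(99); Q2 <- random_rotation()
  expect_identical(Q1, Q2)
})

test_that("rotations are uniform: rotated fixed vector has zero-mean components", {
  set.seed(1234)
  v <- c(1, 0, 0)
  m <- colMeans(t(vapply(1:10000, function(i) as.numeric(random_rotation() %*% v),
                         numeric(3))))
  # component sd of a uniform unit vector is 1/sqrt(3); 3 standard errors
  expect_true(all(abs(m) < 3 * (1 / sqrt(3)) / 100))
})

test_that("label rotation: identity invariance, near-invertibility, area preservation", {
  p4 <- ico(4)$param
  map <- sector_map(p4)
  expect_identical(rotate_labels(map, p4, diag(3))$labels, map$labels)
  set.seed(5)
  Q <- random_rotation()
  there_back <- rotate_labels(rotate_labels(map, p4, Q), p4, t(Q))
  expect_gte(mean(there_back$labels == map$labels), 0.95)
  rot <- rotate_labels(map, p4, Q)
  sz0 <- tabulate(map$labels, 6L)
  sz1 <- tabulate(rot$labels, 6L)
  expect_true(all(abs(sz1 - sz0) / sz0 < 0.10))
})

test_that("identical maps give observed 0 and p = 0 with positive null floor", {
  p3 <- ico(3)$param
  map <- sector_map(p3)
  st <- significance_test(map, map, p3, n_rot = 100, seed = 2)
  expect_equal(st$observed, 0)
  expect_equal(st$p_value, 0)
  expect_gt(min(st$null_distances), 0)
  expect_length(st$null_distances, 100L)
})

test_that("the statistic is invariant to relabeling and supports K != L", {
  p3 <- ico(3)$param
  auto <- sector_map(p3, 6L)
  ref <- sector_map(p3, 4L)  # different cluster count
  st1 <- significance_test(auto, ref, p3, n_rot = 50, seed = 3)
  perm <- parcellation(c(4L, 6L, 1L, 3L, 2L, 5L)[auto$labels])
  st2 <- significance_test(perm, ref, p3, n_rot = 50, seed = 3)
  expect_equal(st1$observed, st2$observed)
  expect_equal(st1$null_distances, st2$null_distances)
  expect_equal(st1$p_value, st2$p_value)
})

test_that("a matched map is more significant than an unrelated one", {
  p3 <- ico(3)$param
  ref <- sector_map(p3)
  near <- ref$labels
  set.seed(8)
  flip <- sample(length(near), 30L)
  near[flip] <- sample(1:6, 30L, replace = TRUE)
  p_near <- significance_test(parcellation(near), ref, p3, n_rot = 100,
                              seed = 5)$p_value
  set.seed(77)
  unrelated <- rotate_labels(ref, p3, random_rotation())
  p_far <- significance_test(unrelated, ref, p3, n_rot = 100,
                             seed = 5)$p_value
  expect_lt(p_near, p_far)
})

test_that("the conservative estimator shifts p by 1/(n_rot + 1)", {
  p3 <- ico(3)$param
  map <- sector_map(p3)
  st <- significance_test(map, map, p3, n_rot = 50, seed = 1,
                          estimator = "conservative")
  expect_equal(st$p_value, 1 / 51)
  expect_error(significance_test(map, map, p3, n_rot = 0), "n_rot")
})

test_that("area distortion warns only for distorted parameterizations", {
  fe <- make_folded_ellipsoid(c(3, 1, 1), 0, seed = 1, subdivisions = 2)
  expect_warning(area_distortion(fe$mesh, fe$param, warn_factor = 1.2),
                 "distortion")
  sph <- ico(2)
  expect_silent(area_distortion(sph$mesh, sph$param))
})
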