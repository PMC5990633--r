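test_that("contingency tables count joint labels exactly", {
  tab <- contingency(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  expect_equal(unname(tab$counts), matrix(1L, 2L, 2L))
  expect_equal(tab$n, 4L)
  self <- contingency(c(1L, 2L, 2L, 3L), c(1L, 2L, 2L, 3L))
  expect_true(all(self$counts[upper.tri(self$counts)] == 0L))
  set.seed(1)
  l1 <- sample(1:3, 50L, TRUE); l2 <- sample(1:4, 50L, TRUE)
  tb <- contingency(l1, l2)
  expect_equal(unname(rowSums(tb$counts)), unname(tabulate(l1, 3L)))
  expect_equal(unname(colSums(tb$counts)), unname(tabulate(l2, 4L)))
  expect_error(contingency(1:3, 1:4), "vertex set")
})

test_that("label 0 is kept only when present in both maps", {
  l1 <- c(0L, 0L, 1L, 2L)
  l2 <- c(0L, 1L, 1L, 2L)
  both <- contingency(l1, l2)
  expect_equal(both$n, 4L)
  expect_true("0" %in% rownames(both$counts))
  one <- contingency(l1, c(3L, 1L, 1L, 2L))
  expect_equal(one$n, 2L)  # the two label-0 vertices of map1 are dropped
})

test_that("rand distance reproduces the worked pair-counting case", {
  rd <- rand_distance(contingency(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L)))
  expect_equal(rd$a, 0)
  expect_equal(rd$b, 2)
  expect_equal(rd$rand_distance, 2 / 3)
  expect_equal(rand_distance(contingency(c(1L, 2L, 1L), c(2L, 1L, 2L)))$rand_distance, 0)
  expect_error(rand_distance(contingency(1L, 1L)), "at least 2")
})

test_that("rand distance agrees exactly with O(n^2) pair enumeration", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(10:200, 1L)
    l1 <- sample(seq_len(sample(2:8, 1L)), n, replace = TRUE)
    l2 <- sample(seq_len(sample(2:8, 1L)), n, replace = TRUE)
    rd <- rand_distance(contingency(l1, l2))
    or <- rand_oracle(l1, l2)
    expect_identical(rd$a, as.numeric(or$a))
    expect_identical(rd$b, as.numeric(or$b))
    expect_equal(rd$rand_distance, or$rand)
  }
})

test_that("rand distance is a metric, invariant to relabeling", {
  set.seed(14)
  rd <- function(a, b) rand_distance(contingency(a, b))$rand_distance
  for (i in 1:50) {
    n <- 60L
    a <- sample(1:4, n, TRUE); b <- sample(1:3, n, TRUE); c <- sample(1:5, n, TRUE)
    expect_equal(rd(a, b), rd(b, a))
    expect_lte(rd(a, c), rd(a, b) + rd(b, c) + 1e-12)
    p <- sample(4L)
    expect_equal(rd(p[a], b), rd(a, b))
  }
})

test_that("Dice coefficients handle full, empty and partial overlap", {
  expect_equal(unname(dice_per_label(c(1L, 1L, 2L), c(1L, 1L, 2L))), c(1, 1))
  expect_equal(unname(dice_per_label(c(1L, 1L, 2L, 2L), c(2L, 2L, 1L, 1L))),
               c(0, 0))
  l1 <- rep(c(1L, 2L), each = 4L)
  l2 <- c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L)
  expect_equal(unname(dice_per_label(l1, l2)), c(0.5, 0.5))
})

test_that("boundary vertices straddle label changes; constraint borders optional", {
  m <- ico(3)$mesh
  z <- m$vertices[, 3L]
  const <- parcellation(rep(1L, length(z)))
  expect_length(boundary_set(m, const), 0L)
  map <- parcellation(ifelse(z > 0, 1L, 2L))
  bd <- boundary_set(m, map)
  expect_gt(length(bd), 0L)
  expect_true(all(abs(z[bd]) < 0.2))
  capped <- parcellation(ifelse(z > 0.8, 0L, ifelse(z > 0, 1L, 2L)))
  b1 <- boundary_set(m, capped)
  b2 <- boundary_set(m, capped, include_constraint = TRUE)
  expect_gt(length(b2), length(b1))
  expect_true(all(abs(z[b1]) < 0.2))
})

test_that("sulcus-boundary distance is 0 on the boundary and exact in percent", {
  m <- ico(3)$mesh
  z <- m$vertices[, 3L]
  map <- parcellation(ifelse(z > 0, 1L, 2L))
  bd <- boundary_set(m, map)
  # a line that runs inside the boundary band has distance 0
  line_in <- make_synthetic_sulcus(m, c(0, 0, 1), 0)
  expect_true(all(line_in$vertex_indices %in% bd))
  r0 <- sulcus_boundary_distance(m, line_in, map, normalizer = pi)
  expect_equal(r0$mean_mm, 0)
  expect_equal(r0$percent, 0)
  line30 <- make_synthetic_sulcus(m, c(0, 0, 1), 0.5)
  r <- sulcus_boundary_distance(m, line30, map, normalizer = 2)
  expect_equal(r$percent, 100 * r$mean_mm / 2)
  expect_error(sulcus_boundary_distance(m, line30, parcellation(rep(1L, length(z)))),
               "no boundary")
})
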