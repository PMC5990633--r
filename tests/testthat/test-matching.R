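ct <- function(m) structure(list(counts = m, n = sum(m)),
                            class = "contingency_table")

test_that("diagonal-dominant and permutation tables match trivially", {
  D <- diag(c(10, 8, 6)) + 1
  expect_identical(match_labels(ct(D))$sigma, 1:3)
  P <- 5 * rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_identical(match_labels(ct(P))$sigma, c(2L, 3L, 1L))
})

test_that("matching objective equals the exhaustive permutation maximum", {
  set.seed(20)
  for (i in 1:200) {
    Tm <- matrix(sample(0:30, 25L, replace = TRUE), 5L)
    m <- match_labels(ct(Tm))
    expect_equal(m$objective,
                 assignment_oracle(Tm))
    expect_equal(sum(Tm[cbind(1:5, m$sigma)]), m$objective)
  }
})

test_that("ties resolve to the lexicographically smallest permutation", {
  U <- matrix(1, 3L, 3L)  # every permutation is optimal
  expect_identical(match_labels(ct(U))$sigma, 1:3)
  Tm <- rbind(c(5, 5, 0), c(5, 5, 0), c(0, 0, 5))  # sigma (1,2,3) and (2,1,3) tie
  expect_identical(match_labels(ct(Tm))$sigma, 1:3)
})

test_that("rectangular tables are padded with zero rows/columns", {
  Tm <- rbind(c(9, 0), c(0, 7), c(1, 1))  # K = 3 rows, L = 2 columns
  m <- match_labels(ct(Tm))
  expect_identical(sort(m$sigma), 1:3)
  expect_equal(m$objective, 16)
})

test_that("relabeling lines a moving map up with its reference", {
  set.seed(7)
  ref <- parcellation(sample(1:4, 300L, replace = TRUE))
  perm <- c(3L, 1L, 4L, 2L)
  mov <- parcellation(perm[ref$labels])
  rel <- match_labels(contingency(ref, mov))
  out <- apply_relabeling(mov, rel)
  expect_identical(out$labels, ref$labels)
})

test_that("Dice after matching is at least Dice under random permutations", {
  set.seed(9)
  l1 <- sample(1:5, 400L, replace = TRUE)
  l2 <- l1
  flip <- sample(400L, 80L)
  l2[flip] <- sample(1:5, 80L, replace = TRUE)
  l2 <- c(4L, 5L, 1L, 2L, 3L)[l2]
  m <- match_labels(contingency(l1, l2))
  matched <- mean(dice_per_label(l1, l2, m))
  for (i in 1:100) {
    p <- sample(5L)
    rnd <- mean(dice_per_label(l1, l2,
                               structure(list(sigma = p), class = "relabeling")))
    expect_lte(rnd, matched + 1e-12)
  }
})
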