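test_that("prolate ellipsoid splits into two balanced halves at the Fiedler zero", {
  fe <- fixture("prolate3", make_folded_ellipsoid(c(3, 1, 1), 0, seed = 1,
                                                  subdivisions = 4))
  b <- spectrum_fixture("prolate3", fe$mesh, 3)
  p <- spectral_parcellate(fe$mesh, b, 2, n_eigs_used = 2, seed = 0)
  sizes <- tabulate(p$labels, 2L)
  expect_lt(abs(diff(sizes)) / mean(sizes), 0.10)
  bd <- boundary_set(fe$mesh, p)
  # interface within one (x-stretched) local edge of the symmetry plane
  expect_lt(max(abs(fe$mesh$vertices[bd, 1L])), 0.35)
})

test_that("parcellation is bitwise deterministic for a fixed seed", {
  fe <- cohort_fixture()$subjects[[1L]]
  b <- cohort_fixture()$bases[[1L]]
  p1 <- spectral_parcellate(fe$mesh, b, 4, seed = 11)
  p2 <- spectral_parcellate(fe$mesh, b, 4, seed = 11)
  expect_identical(p1$labels, p2$labels)
  # canonical ordering: label sizes non-increasing
  expect_true(all(diff(tabulate(p1$labels, 4L)) <= 0))
})

test_that("constraint vertices get label 0, exclusively", {
  fe <- cohort_fixture()$subjects[[2L]]
  cap <- make_constraint_cap(fe$param, c(0, 0, 1), 25)
  b <- compute_spectrum(assemble_fem(fe$mesh), 5)
  p <- spectral_parcellate(fe$mesh, b, 4, constraint = cap, seed = 0)
  expect_identical(which(p$labels == 0L), cap$vertex_indices)
  expect_true(all(tabulate(p$labels, 4L) > 0L))
  expect_true(p$constrained)
})

test_that("sign alignment undoes column negation and is idempotent", {
  cf <- cohort_fixture()
  tmpl <- ico(3)$param
  params <- lapply(cf$subjects, `[[`, "param")
  flipped <- cf$bases[[1L]]
  flipped$vectors <- -flipped$vectors
  al <- sign_align(list(cf$bases[[1L]], flipped),
                   params[c(1L, 1L)], tmpl)
  expect_equal(al[[2L]]$vectors, cf$bases[[1L]]$vectors)
  al2 <- sign_align(al, params[c(1L, 1L)], tmpl)
  expect_identical(al2, al)
})

test_that("after alignment all cross-subject mode correlations are nonnegative", {
  cf <- cohort_fixture()
  tmpl <- ico(3)$param
  params <- lapply(cf$subjects, `[[`, "param")
  al <- sign_align(cf$bases, params, tmpl)
  res <- lapply(seq_along(al), function(s) {
    idx <- nearest_vertex(params[[s]]$sphere_vertices, tmpl$sphere_vertices)
    al[[s]]$vectors[idx, ]
  })
  for (s in 2:length(res))
    for (j in 2:ncol(res[[1L]]))
      expect_gte(stats::cor(res[[s]][, j], res[[1L]][, j]), 0)
})

test_that("identical subjects get identical group labels; bookkeeping is lossless", {
  b <- cohort_fixture()$bases[[1L]]
  gp <- group_spectral_parcellate(list(b, b, b), 4, seed = 0)
  expect_identical(gp[[1L]]$labels, gp[[2L]]$labels)
  expect_identical(gp[[2L]]$labels, gp[[3L]]$labels)
  expect_length(gp[[1L]]$labels, nrow(b$vectors))
})

test_that("group clustering is invariant to pre-alignment sign flips", {
  cf <- cohort_fixture()
  tmpl <- ico(3)$param
  params <- lapply(cf$subjects, `[[`, "param")[1:2]
  bases <- cf$bases[1:2]
  gp0 <- group_spectral_parcellate(sign_align(bases, params, tmpl), 4,
                                   seed = 0)
  flipped <- bases
  flipped[[2L]]$vectors <- -flipped[[2L]]$vectors
  gp1 <- group_spectral_parcellate(sign_align(flipped, params, tmpl), 4,
                                   seed = 0)
  expect_identical(lapply(gp0, `[[`, "labels"), lapply(gp1, `[[`, "labels"))
})

test_that("permuting subject order only permutes labels (rand distance 0)", {
  cf <- cohort_fixture()
  tmpl <- ico(3)$param
  al <- sign_align(cf$bases, lapply(cf$subjects, `[[`, "param"), tmpl)
  gp <- group_spectral_parcellate(al, 4, seed = 0)
  ord <- c(3L, 1L, 5L, 2L, 4L)
  gp2 <- group_spectral_parcellate(al[ord], 4, seed = 0)
  for (s in seq_along(ord))
    expect_equal(rand_distance(contingency(gp[[ord[s]]],
                                           gp2[[s]]))$rand_distance, 0)
})

test_that("consensus is the majority vote with smallest-label tie-break", {
  m1 <- parcellation(c(1L, 1L, 2L, 2L))
  m2 <- parcellation(c(1L, 2L, 2L, 1L))
  m3 <- parcellation(c(1L, 1L, 2L, 1L))
  cs <- consensus(list(m1, m2, m3))
  expect_identical(cs$map$labels, c(1L, 1L, 2L, 1L))
  expect_identical(consensus(list(m1, m1))$map$labels, m1$labels)
  # 2-2 tie goes to the smaller label
  tie <- consensus(list(m1, m1, m2, m2))
  expect_identical(tie$map$labels[2L], 1L)
  expect_error(consensus(list()), "empty")
})

test_that("disconnected cluster fragments can be reabsorbed", {
  m <- ico(2)$mesh
  z <- m$vertices[, 3L]
  labels <- ifelse(z > 0, 1L, 2L)
  frag <- which(z < -0.9)  # far fragment relabeled as 1: disconnects cluster 1
  labels[frag] <- 1L
  fixed <- enforce_connectivity(m, parcellation(labels))
  expect_identical(fixed$labels[frag], rep(2L, length(frag)))
})
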