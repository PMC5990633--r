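# Memoized fixtures shared across test files (built in code, never stored).
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

ico <- function(s) fixture(paste0("ico", s), make_icosphere(s))

spectrum_fixture <- function(key, mesh, k) {
  fixture(paste0("spec_", key, "_", k),
          compute_spectrum(assemble_fem(mesh), k))
}

# standard folded-ellipsoid cohort used by the group-consistency checks:
# elongated enough that the k-means optimum is determined by global shape
cohort_fixture <- function() fixture("cohort5", {
  subs <- lapply(101:105, function(sd)
    make_folded_ellipsoid(c(4, 1.2, 0.9), amplitude = 0.1, frequency = 4L,
                          subdivisions = 3L, seed = sd))
  bases <- lapply(subs, function(s) compute_spectrum(assemble_fem(s$mesh), 4))
  list(subjects = subs, bases = bases)
})

# independent edge extraction (mirrors the package's definition)
mesh_edges_test <- function(m) {
  tr <- m$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
}

# 6 longitude sectors on an icosphere template (orange-slice parcellation)
sector_map <- function(param, K = 6L) {
  sv <- param$sphere_vertices
  parcellation(1L + as.integer((atan2(sv[, 2L], sv[, 1L]) + pi) %/%
                                 (2 * pi / K)) %% K)
}

# O(n^2) pair-enumeration oracle for the rand distance
rand_oracle <- function(l1, l2) {
  n <- length(l1)
  same1 <- outer(l1, l1, "==")
  same2 <- outer(l2, l2, "==")
  up <- upper.tri(same1)
  a <- sum(same1[up] & same2[up])
  b <- sum(!same1[up] & !same2[up])
  list(a = a, b = b, rand = 1 - (a + b) / (n * (n - 1) / 2))
}

# all permutations of 1..n (n small), as a list
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# exhaustive assignment oracle: max over permutations of sum T[k, sigma(k)]
assignment_oracle <- function(Tm) {
  k <- nrow(Tm)
  max(vapply(all_perms(k), function(p)
    sum(Tm[cbind(seq_len(k), p)]), numeric(1)))
}
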