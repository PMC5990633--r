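#' Contingency table between two parcellations
#'
#' Joint label counts `T[k, l]` = number of vertices labeled `k` in the
#' first map and `l` in the second.  The constraint label 0 is kept as a
#' row/column only when both maps use it; otherwise vertices labeled 0 in
#' either map are excluded symmetrically.
#'
#' @param map1,map2 [parcellation] objects on the same vertex set (or plain
#'   integer label vectors).
#' @return list of class `contingency_table` with integer matrix `counts`
#'   (dimnames = labels) and `n` (total vertices counted).
#' @export
contingency <- function(map1, map2) {
  l1 <- if (inherits(map1, "parcellation")) map1$labels else as.integer(map1)
  l2 <- if (inherits(map2, "parcellation")) map2$labels else as.integer(map2)
  if (length(l1) != length(l2))
    stop("maps must share the same vertex set (lengths ", length(l1),
         " vs ", length(l2), ")")
  both0 <- any(l1 == 0L) && any(l2 == 0L)
  if (!both0) {
    keep <- l1 != 0L & l2 != 0L
    l1 <- l1[keep]; l2 <- l2[keep]
  }
  tab <- table(factor(l1), factor(l2))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  structure(list(counts = counts, n = sum(counts)),
            class = "contingency_table")
}

#' Rand distance between two partitions
#'
#' Pair-counting partition distance: with `a` the number of vertex pairs
#' co-clustered in both partitions and `b` the number separated in both,
#' the distance is `1 - (a + b) / C(n, 2)`.  Both counts come from the
#' contingency table: `a = sum C(T_kl, 2)` and
#' `b = C(n,2) - sum C(row,2) - sum C(col,2) + a`.  The result is a true
#' metric on partitions, invariant to relabeling, and accepts rectangular
#' tables (different cluster counts `K != L`).
#'
#' @param table a `contingency_table` from [contingency()].
#' @return list of class `partition_distance` with `a`, `b`,
#'   `rand_distance` and `n`.
#' @examples
#' rand_distance(contingency(c(1, 1, 2, 2), c(1, 2, 1, 2)))$rand_distance  # 2/3
#' @export
rand_distance <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  Tm <- table$counts
  n <- table$n
  if (n < 2L) stop("need at least 2 vertices to count pairs")
  choose2 <- function(x) x * (x - 1) / 2
  a <- sum(choose2(Tm))
  pairs1 <- sum(choose2(rowSums(Tm)))
  pairs2 <- sum(choose2(colSums(Tm)))
  total <- choose2(n)
  b <- total - pairs1 - pairs2 + a
  structure(list(a = a, b = b, n = n,
                 rand_distance = 1 - (a + b) / total),
            class = "partition_distance")
}

#' @export
print.partition_distance <- function(x, ...) {
  cat(sprintf("partition_distance: rand = %.6g (a=%g, b=%g, n=%d)\n",
              x$rand_distance, x$a, x$b, x$n))
  invisible(x)
}

#' Optimal label matching (Hungarian assignment)
#'
#' Permutation `sigma` of `{1..K}` maximizing the total overlap
#' `sum_k T[k, sigma(k)]` of a (padded-to-square) contingency table, via
#' the Hungarian algorithm; among co-optimal permutations the
#' lexicographically smallest is returned.
#'
#' @param table a `contingency_table` (label 0, if present, is excluded
#'   from the assignment) or a plain count matrix.
#' @return list of class `relabeling` with integer vector `sigma`
#'   (`sigma[k] = l`), the matched `objective`, and the label name maps
#'   `from`, `to`.
#' @export
match_labels <- function(table) {
  Tm <- if (inherits(table, "contingency_table")) table$counts else
    as.matrix(table)
  from <- rownames(Tm); to <- colnames(Tm)
  if (!is.null(from) && "0" %in% from) Tm <- Tm[from != "0", , drop = FALSE]
  if (!is.null(to) && "0" %in% to) Tm <- Tm[, to != "0", drop = FALSE]
  from <- rownames(Tm); to <- colnames(Tm)
  k <- max(nrow(Tm), ncol(Tm))
  M <- matrix(0, k, k)
  M[seq_len(nrow(Tm)), seq_len(ncol(Tm))] <- Tm
  best_value <- function(mat) {
    if (nrow(mat) == 0L) return(0)
    if (nrow(mat) == 1L) return(mat[1L, 1L])
    sol <- clue::solve_LSAP(mat, maximum = TRUE)
    sum(mat[cbind(seq_len(nrow(mat)), as.integer(sol))])
  }
  V <- best_value(M)
  # lexicographically smallest optimum: fix rows in order, smallest feasible l
  sigma <- integer(k)
  avail <- seq_len(k)
  rows <- seq_len(k)
  acc <- 0
  for (r in rows) {
    rest_rows <- rows[rows > r]
    for (l in avail) {
      rest <- M[rest_rows, setdiff(avail, l), drop = FALSE]
      if (acc + M[r, l] + best_value(rest) >= V - 1e-9) {
        sigma[r] <- l
        acc <- acc + M[r, l]
        avail <- setdiff(avail, l)
        break
      }
    }
  }
  structure(list(sigma = sigma, objective = V, from = from, to = to),
            class = "relabeling")
}

#' Apply a relabeling permutation to a parcellation
#'
#' Renames cluster `k` of `map` to `sigma(k)` so its labels line up with the
#' reference map the matching was computed against.  Label 0 is untouched.
#'
#' @param map a [parcellation].
#' @param relabeling a `relabeling` from [match_labels()] computed from
#'   `contingency(reference, map)`.
#' @return a [parcellation].
#' @export
apply_relabeling <- function(map, relabeling) {
  # contingency(ref, map) matches ref row k -> map column sigma(k);
  # to express map in ref labels invert: map label sigma(k) becomes k
  inv <- integer(length(relabeling$sigma))
  inv[relabeling$sigma] <- seq_along(relabeling$sigma)
  labels <- map$labels
  nz <- labels != 0L
  labels[nz] <- inv[labels[nz]]
  parcellation(labels, max(map$n_clusters, length(inv)), map$constrained)
}

#' Per-label Dice coefficients under a matching
#'
#' For each label `k`, `2 |A n B| / (|A| + |B|)` with `A` the region `k` of
#' `map1` and `B` the region `sigma(k)` of `map2`.  If both regions are
#' empty the value is `NA`.
#'
#' @param map1,map2 [parcellation] objects (or label vectors) on one vertex
#'   set.
#' @param matching optional `relabeling`; default matches `k` to `k`.
#' @return named numeric vector of Dice coefficients in `[0, 1]`.
#' @export
dice_per_label <- function(map1, map2, matching = NULL) {
  l1 <- if (inherits(map1, "parcellation")) map1$labels else as.integer(map1)
  l2 <- if (inherits(map2, "parcellation")) map2$labels else as.integer(map2)
  if (length(l1) != length(l2)) stop("maps must share the same vertex set")
  ks <- sort(setdiff(unique(l1), 0L))
  sigma <- if (is.null(matching)) stats::setNames(ks, ks) else
    stats::setNames(matching$sigma, seq_along(matching$sigma))
  out <- vapply(ks, function(k) {
    l <- unname(sigma[as.character(k)])
    if (is.na(l)) return(NA_real_)
    A <- l1 == k
    B <- l2 == l
    if (!any(A) && !any(B)) return(NA_real_)
    2 * sum(A & B) / (sum(A) + sum(B))
  }, numeric(1))
  stats::setNames(out, ks)
}

#' Boundary vertices of a parcellation
#'
#' Vertices having an edge neighbour with a different nonzero label.  By
#' default borders with the constraint label 0 are not boundaries (the
#' cingulate border is a segmentation artifact, not an anatomical one);
#' set `include_constraint = TRUE` to count them.
#'
#' @param mesh a [triangle_mesh].
#' @param map a [parcellation].
#' @param include_constraint logical.
#' @return sorted integer vector of boundary vertex indices (empty iff the
#'   map is constant).
#' @export
boundary_set <- function(mesh, map, include_constraint = FALSE) {
  labels <- map$labels
  e <- mesh_edges(mesh)
  diff <- labels[e[, 1L]] != labels[e[, 2L]]
  if (!include_constraint)
    diff <- diff & labels[e[, 1L]] != 0L & labels[e[, 2L]] != 0L
  sort(unique(as.integer(e[diff, ])))
}

#' Mean geodesic distance from a sulcal line to parcellation boundaries
#'
#' The mean over line vertices of the geodesic distance to the boundary
#' vertex set of the map, in mm, and as a percentage of a mesh-size
#' normalizer (the Fiedler-extremal geodesic length, see
#' [fiedler_extremal_geodesic()]).
#'
#' @param mesh a [triangle_mesh].
#' @param line a [sulcal_line].
#' @param map a non-constant [parcellation].
#' @param normalizer length in mm (e.g. `fiedler_extremal_geodesic()$length_mm`);
#'   `NA` to skip the percentage.
#' @param method geodesic scheme, see [geodesic_distance_map()].
#' @return list of class `sulcus_distance` with `mean_mm` and `percent`.
#' @export
sulcus_boundary_distance <- function(mesh, line, map, normalizer = NA,
                                     method = "fast_marching") {
  stopifnot(inherits(line, "sulcal_line"))
  B <- boundary_set(mesh, map)
  if (length(B) == 0L)
    stop("parcellation has no boundary (constant map)")
  d <- geodesic_distance_map(mesh, B, method = method)
  mean_mm <- mean(d[line$vertex_indices])
  structure(list(mean_mm = mean_mm,
                 percent = if (is.na(normalizer)) NA_real_ else
                   100 * mean_mm / normalizer),
            class = "sulcus_distance")
}
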