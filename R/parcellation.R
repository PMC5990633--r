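#' Per-vertex parcellation map
#'
#' Integer labels per vertex: `0` is reserved for the constraint region
#' (cingulate-pole analogue) in constrained maps, and `1..K` are the
#' unsupervised clusters.
#'
#' @param labels integer vector of per-vertex labels.
#' @param n_clusters number of unsupervised clusters `K`.
#' @param constrained logical; whether label 0 is in use.
#' @return object of class `parcellation`.
#' @export
parcellation <- function(labels, n_clusters = length(setdiff(unique(labels), 0L)),
                         constrained = any(labels == 0L)) {
  labels <- as.integer(labels)
  if (any(labels < 0L)) stop("labels must be >= 0")
  structure(list(labels = labels, n_clusters = as.integer(n_clusters),
                 constrained = isTRUE(constrained)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d vertices, K=%d%s\n  sizes: %s\n",
              length(x$labels), x$n_clusters,
              if (x$constrained) " (constrained, label 0)" else "",
              paste(tabulate(x$labels + 1L, nbins = x$n_clusters + 1L),
                    collapse = " ")))
  invisible(x)
}

# seeded k-means++ initialization: distinct data rows, D^2 sampling
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    tot <- sum(d2)
    if (tot <= 0)
      stop("fewer than ", k, " distinct points: cannot seed k-means++")
    i <- sample.int(n, 1L, prob = d2 / tot)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

# k-means with k-means++ seeding and `restarts` seeded replicates;
# returns the assignment with smallest total within-cluster sum of squares
kmeans_pp <- function(X, k, seed, restarts = 20L, iter.max = 100L) {
  with_rng(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      km <- suppressWarnings(
        stats::kmeans(X, centers = kmeanspp_centers(X, k),
                      iter.max = iter.max, algorithm = "Hartigan-Wong"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
}

# relabel clusters 1..K by decreasing size; ties by smallest first vertex
canonical_relabel <- function(cl, k) {
  sizes <- tabulate(cl, nbins = k)
  if (any(sizes == 0L))
    stop("k-means produced an empty cluster; try a different seed or more restarts")
  first <- vapply(seq_len(k), function(j) match(j, cl), integer(1))
  ord <- order(-sizes, first)   # ord[1] = old label renamed to 1, etc.
  perm <- integer(k)
  perm[ord] <- seq_len(k)
  perm[cl]
}

#' Spectral parcellation of a single mesh
#'
#' k-means clustering of the first `n_eigs_used` Laplace-Beltrami
#' eigenvectors (including the trivial constant one) into `n_clusters`
#' regions.  In constrained mode the eigenfunctions are those of the entire
#' mesh, but constraint vertices are excluded from the clustering and
#' receive label 0; this whole-mesh-eigenfunctions heuristic deliberately
#' avoids boundary-condition spectra.  The eigenvector array is fed to
#' k-means as is (no row normalization), with seeded k-means++
#' initialization and 20 restarts; clusters are then relabeled `1..K` by
#' decreasing size so repeated runs are bitwise identical.
#'
#' @param mesh a [triangle_mesh].
#' @param basis a `spectral_basis` for the mesh.
#' @param n_clusters number of unsupervised clusters `K >= 2`.
#' @param n_eigs_used eigenvectors used; default `n_clusters`
#'   (unconstrained) or `n_clusters + 1` (constrained).
#' @param constraint optional [constraint_region] excluded from clustering.
#' @param seed integer seed for k-means.
#' @param restarts number of k-means++ restarts.
#' @param connectivity if `TRUE`, reassign each non-largest connected
#'   component of every cluster to the neighbouring label sharing the
#'   longest boundary (off by default; k-means itself gives no connectivity
#'   guarantee).
#' @return a [parcellation].
#' @examples
#' fe <- make_folded_ellipsoid(c(3, 1.5, 1), amplitude = 0.1, seed = 3)
#' basis <- compute_spectrum(assemble_fem(fe$mesh), 4)
#' p <- spectral_parcellate(fe$mesh, basis, n_clusters = 4, seed = 0)
#' @export
spectral_parcellate <- function(mesh, basis, n_clusters, n_eigs_used = NULL,
                                constraint = NULL, seed = 0L, restarts = 20L,
                                connectivity = FALSE) {
  stopifnot(inherits(basis, "spectral_basis"))
  n <- nrow(mesh$vertices)
  constrained <- !is.null(constraint) && length(constraint$vertex_indices) > 0L
  if (is.null(n_eigs_used))
    n_eigs_used <- if (constrained) n_clusters + 1L else n_clusters
  if (n_eigs_used > ncol(basis$vectors))
    stop("`n_eigs_used` exceeds the number of computed eigenvectors")
  if (n_clusters < 2L) stop("`n_clusters` must be >= 2")
  X <- basis$vectors[, seq_len(n_eigs_used), drop = FALSE]
  keep <- rep(TRUE, n)
  if (constrained) {
    ci <- constraint$vertex_indices
    if (min(ci) < 1L || max(ci) > n) stop("constraint indices out of range")
    keep[ci] <- FALSE
  }
  km <- kmeans_pp(X[keep, , drop = FALSE], n_clusters, seed, restarts)
  labels <- integer(n)
  labels[keep] <- canonical_relabel(km$cluster, n_clusters)
  out <- parcellation(labels, n_clusters, constrained)
  if (connectivity) out <- enforce_connectivity(mesh, out)
  out
}

#' Reassign disconnected cluster fragments
#'
#' Optional post-pass: every connected component of a cluster except its
#' largest is merged into the neighbouring label with which it shares the
#' longest boundary (most cut edges).  Iterates until all clusters are
#' connected.
#'
#' @param mesh a [triangle_mesh].
#' @param map a [parcellation].
#' @return a [parcellation] whose nonzero clusters are connected.
#' @export
enforce_connectivity <- function(mesh, map) {
  e <- mesh_edges(mesh)
  labels <- map$labels
  repeat {
    same <- labels[e[, 1L]] == labels[e[, 2L]]
    g <- igraph::graph_from_edgelist(e[same, , drop = FALSE], directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(labels) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_along(labels)]
    changed <- FALSE
    for (k in seq_len(map$n_clusters)) {
      in_k <- which(labels == k)
      if (length(in_k) == 0L) next
      comps <- comp[in_k]
      tab <- table(comps)
      if (length(tab) <= 1L) next
      main <- names(tab)[which.max(tab)]
      for (cid in setdiff(names(tab), main)) {
        frag <- in_k[comps == as.integer(cid)]
        touch <- c(e[e[, 1L] %in% frag, 2L], e[e[, 2L] %in% frag, 1L])
        nb <- labels[touch]
        nb <- nb[!(touch %in% frag) & nb != k & nb != 0L]
        if (length(nb) == 0L) next
        labels[frag] <- as.integer(names(which.max(table(nb))))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  parcellation(labels, map$n_clusters, map$constrained)
}

#' Sign alignment of eigenvector bases across subjects
#'
#' Eigenfunctions are defined up to sign.  Each subject's column `j` is
#' resampled on a common spherical template (nearest template-vertex lookup
#' through the subject's spherical parameterization) and negated if its
#' correlation with the reference subject's resampled column `j` is
#' negative.  The first subject is the reference and is returned unchanged.
#'
#' @param bases list of `spectral_basis`, equal column counts.
#' @param params list of [spherical_param], index-aligned with each basis.
#' @param template a [spherical_param] for the common template (e.g. from
#'   [make_icosphere()]).
#' @return list of sign-aligned `spectral_basis` objects.
#' @export
sign_align <- function(bases, params, template) {
  stopifnot(length(bases) == length(params), length(bases) >= 1L)
  if (!inherits(template, "spherical_param"))
    stop("`template` must be a spherical_param")
  k <- ncol(bases[[1L]]$vectors)
  if (!all(vapply(bases, function(b) ncol(b$vectors), 0L) == k))
    stop("all bases must share the same column count")
  tv <- template$sphere_vertices
  res <- lapply(seq_along(bases), function(s) {
    idx <- nearest_vertex(params[[s]]$sphere_vertices, tv)
    bases[[s]]$vectors[idx, , drop = FALSE]
  })
  ref <- res[[1L]]
  out <- bases
  for (s in seq_along(bases)[-1L]) {
    for (j in seq_len(k)) {
      a <- res[[s]][, j]
      b <- ref[, j]
      # near-constant columns (the trivial eigenvector) have no meaningful
      # correlation; compare by the sign of the inner product instead
      const_a <- stats::sd(a) <= 1e-8 * sqrt(mean(a^2))
      const_b <- stats::sd(b) <= 1e-8 * sqrt(mean(b^2))
      if (const_a || const_b) {
        dp <- sum(a * b)
        if (dp == 0)
          stop("zero-variance resampled eigenvector (subject ", s,
               ", column ", j, "): cannot sign-align")
        if (dp < 0) out[[s]]$vectors[, j] <- -out[[s]]$vectors[, j]
      } else if (stats::cor(a, b) < 0) {
        out[[s]]$vectors[, j] <- -out[[s]]$vectors[, j]
      }
    }
  }
  out
}

#' Group spectral co-parcellation
#'
#' Pools the (sign-aligned) eigenvector blocks of all subjects into one
#' row-concatenated array and runs a single k-means on it, so corresponding
#' regions across subjects receive the same label with no matching step.
#' Constraint rows are excluded and restored as label 0 per subject; labels
#' are split back by block offsets.
#'
#' @param bases list of sign-aligned `spectral_basis` objects.
#' @param n_clusters number of clusters `K >= 2`.
#' @param constraints optional list of [constraint_region] (or `NULL`
#'   entries), one per subject.
#' @param n_eigs_used eigenvector columns used (default: as
#'   [spectral_parcellate()], based on whether any subject is constrained).
#' @param seed integer seed.
#' @param restarts k-means++ restarts.
#' @return list of [parcellation], one per subject, consistently labeled.
#' @export
group_spectral_parcellate <- function(bases, n_clusters, constraints = NULL,
                                      n_eigs_used = NULL, seed = 0L,
                                      restarts = 20L) {
  S <- length(bases)
  if (S < 1L) stop("need at least one subject")
  k <- ncol(bases[[1L]]$vectors)
  if (!all(vapply(bases, function(b) ncol(b$vectors), 0L) == k))
    stop("all bases must share the same column count")
  if (is.null(constraints)) constraints <- vector("list", S)
  constrained <- any(vapply(constraints, function(cr)
    !is.null(cr) && length(cr$vertex_indices) > 0L, TRUE))
  if (is.null(n_eigs_used))
    n_eigs_used <- if (constrained) n_clusters + 1L else n_clusters
  if (n_eigs_used > k) stop("`n_eigs_used` exceeds the basis column count")
  ns <- vapply(bases, function(b) nrow(b$vectors), 0L)
  keeps <- lapply(seq_len(S), function(s) {
    keep <- rep(TRUE, ns[s])
    cr <- constraints[[s]]
    if (!is.null(cr) && length(cr$vertex_indices)) keep[cr$vertex_indices] <- FALSE
    keep
  })
  X <- do.call(rbind, lapply(seq_len(S), function(s)
    bases[[s]]$vectors[keeps[[s]], seq_len(n_eigs_used), drop = FALSE]))
  km <- kmeans_pp(X, n_clusters, seed, restarts)
  cl <- canonical_relabel(km$cluster, n_clusters)
  offsets <- c(0L, cumsum(vapply(keeps, sum, 0L)))
  lapply(seq_len(S), function(s) {
    labels <- integer(ns[s])
    labels[keeps[[s]]] <- cl[(offsets[s] + 1L):offsets[s + 1L]]
    parcellation(labels, n_clusters,
                 constrained = !all(keeps[[s]]))
  })
}

#' Resample a parcellation onto a spherical template
#'
#' Extends a subject's map to the common sphere: each template vertex takes
#' the label of the nearest subject sphere vertex under the subject's
#' spherical parameterization.
#'
#' @param map a [parcellation] on the subject mesh.
#' @param param the subject's [spherical_param].
#' @param template the template [spherical_param].
#' @return a [parcellation] on the template vertices.
#' @export
resample_to_template <- function(map, param, template) {
  idx <- nearest_vertex(param$sphere_vertices, template$sphere_vertices)
  parcellation(map$labels[idx], map$n_clusters, map$constrained)
}

#' Majority-vote consensus parcellation
#'
#' Per-vertex majority vote across maps sharing a template vertex set; ties
#' broken by the smallest label index.
#'
#' @param maps nonempty list of [parcellation] on a common template.
#' @return list of class `consensus_map` with `map` (a [parcellation]) and
#'   `votes` (vertices x labels count matrix; columns named by label).
#' @export
consensus <- function(maps) {
  if (length(maps) == 0L) stop("empty map list")
  n <- length(maps[[1L]]$labels)
  if (!all(vapply(maps, function(m) length(m$labels), 0L) == n))
    stop("all maps must share the template vertex set")
  labs <- sort(unique(unlist(lapply(maps, function(m) unique(m$labels)))))
  votes <- sapply(labs, function(l)
    Reduce(`+`, lapply(maps, function(m) as.integer(m$labels == l))))
  colnames(votes) <- labs
  win <- labs[max.col(votes, ties.method = "first")]
  structure(list(map = parcellation(win,
                                    n_clusters = max(c(0L, setdiff(labs, 0L))),
                                    constrained = any(win == 0L)),
                 votes = votes),
            class = "consensus_map")
}
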