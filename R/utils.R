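# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Nearest-vertex lookup
#'
#' Index of the nearest row of `data` for each row of `query` (Euclidean,
#' kd-tree).  Used for all template resampling: label pullback under
#' rotations, cross-subject eigenfunction comparison, and contingency tables
#' on a common sphere.
#'
#' @param data `m x d` matrix of reference points.
#' @param query `n x d` matrix of query points.
#' @return integer vector of length `n` with 1-based row indices into `data`.
#' @export
nearest_vertex <- function(data, query) {
  as.integer(RANN::nn2(data, query, k = 1L)$nn.idx[, 1L])
}

# derive a bounded per-stage seed from a top-level seed (documented scheme:
# stage seeds are (seed * 1000003 + offset) mod 2^31-1)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}
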