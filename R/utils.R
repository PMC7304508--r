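# Internal helpers.

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr with a local RNG state seeded by `seed`, restoring caller state.
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Coerce a 4D array or voxels x time matrix to voxels x time.
as_voxel_matrix <- function(x, mask = NULL) {
  if (is.matrix(x)) {
    if (!is.null(mask)) x <- x[as.logical(mask), , drop = FALSE]
    return(x)
  }
  d <- dim(x)
  if (length(d) != 4)
    stop("expected a voxels x time matrix or a 4D array")
  m <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
  if (!is.null(mask)) m <- m[as.logical(mask), , drop = FALSE]
  m
}

# Third standardized moment (population denominators).
skewness <- function(x) {
  x <- x - mean(x)
  s2 <- mean(x^2)
  if (s2 == 0) return(0)
  mean(x^3) / s2^1.5
}

# Maximum-weight bipartite assignment between rows and columns of a
# nonnegative weight matrix; returns, for each row, the matched column.
hungarian_match <- function(w) {
  q1 <- nrow(w); q2 <- ncol(w)
  stopifnot(q1 >= 1, q2 >= 1, all(is.finite(w)))
  g <- igraph::make_empty_graph(n = q1 + q2, directed = FALSE)
  edges <- rbind(rep(seq_len(q1), each = q2),
                 q1 + rep(seq_len(q2), times = q1))
  g <- igraph::add_edges(g, as.vector(edges))
  igraph::V(g)$type <- c(rep(FALSE, q1), rep(TRUE, q2))
  m <- igraph::max_bipartite_match(
    g, weights = as.vector(t(w)) + 1e-9)
  as.integer(m$matching[seq_len(q1)]) - q1
}

# Stable hash of an R object (for config provenance in sidecars).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
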