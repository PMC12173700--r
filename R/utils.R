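#' Number of unordered node pairs in a parcellation
#'
#' For an atlas of `n` parcels there are `n * (n - 1) / 2` unique node pairs
#' (potential edges); a 333-parcel atlas has 55,278.
#'
#' @param n Parcel count, an integer >= 2.
#' @return A single integer-valued double.
#' @export
#' @examples
#' n_node_pairs(333)
n_node_pairs <- function(n) {
  if (length(n) != 1 || !is.finite(n) || n != round(n) || n < 2) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  n * (n - 1) / 2
}

# Edge enumeration follows the column-major upper triangle, i.e. the order of
# m[upper.tri(m)]: (1,2), (1,3), (2,3), (1,4), ... Every per-edge vector in
# the package uses this order.
edge_pairs <- function(n) {
  j <- rep(seq_len(n), each = n)[upper.tri(diag(n))]
  idx <- which(upper.tri(diag(n)))
  tibble::tibble(
    i = as.integer((idx - 1L) %% n + 1L),
    j = as.integer((idx - 1L) %/% n + 1L)
  )
}

# index of unordered pair (i, j), i < j, in edge_pairs() order
edge_index <- function(i, j, n) {
  stopifnot(all(i >= 1), all(j <= n))
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  if (any(i == j)) stop("self-loops have no edge index", call. = FALSE)
  as.integer((j - 1) * (j - 2) / 2 + i)
}

upper_values <- function(m) m[upper.tri(m)]

matrix_from_upper <- function(values, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  m + t(m)
}

# Deterministic per-stage child seeds so pipeline stages can be replayed
# independently; kept below 2^31.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
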