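# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration, brute-force definitions, and dense
# linear algebra.

# Exact Mann-Whitney by full enumeration of group labelings. Returns the
# observed U for the a-first labeling and the exact two-sided p: the
# fraction of labelings whose U is at least as far from nA*nB/2 as observed.
oracle_mwu_exact <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a); N <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nA * (nA + 1) / 2
  }
  u_obs <- u_of(seq_len(nA))
  mu <- nA * (N - nA) / 2
  labelings <- utils::combn(N, nA)
  u_all <- apply(labelings, 2, u_of)
  list(U = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu)))
}

# Connected components by breadth-first search over an edge list.
oracle_components_bfs <- function(edges) {
  nodes <- sort(unique(c(edges$i, edges$j)))
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges$j[edges$i == v], edges$i[edges$j == v])
  })
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (s in nodes) {
    if (seen[as.character(s)]) next
    queue <- s; members <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[as.character(v)]) next
      seen[as.character(v)] <- TRUE
      members <- c(members, v)
      queue <- c(queue, adj[[as.character(v)]])
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# Brute-force Benjamini-Hochberg step-up from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (k in seq_len(m)) {
    q_sorted[k] <- min(1, min((m / (k:m)) * p[ord][k:m]))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Leading eigenvector of the binary adjacency by dense eigendecomposition.
oracle_eigcent <- function(edges) {
  nodes <- sort(unique(c(edges$i, edges$j)))
  k <- length(nodes)
  A <- matrix(0, k, k)
  ii <- match(edges$i, nodes); jj <- match(edges$j, nodes)
  A[cbind(ii, jj)] <- 1; A[cbind(jj, ii)] <- 1
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  v <- abs(v) / sqrt(sum(v^2))
  stats::setNames(v, nodes)
}

# Two-sided Fisher exact p by enumerating all tables with fixed margins
# (point-probability criterion).
oracle_fisher_exact <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- stats::dhyper(a_range, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# random edge list over n nodes guaranteed connected (path + extras)
random_connected_edges <- function(n, extra = n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(n)
  e <- data.frame(i = ord[-n], j = ord[-1])
  if (extra > 0) {
    cand <- which(upper.tri(diag(n)))
    pick <- sample(cand, min(extra, length(cand)))
    e <- rbind(e, data.frame(i = (pick - 1) %% n + 1, j = (pick - 1) %/% n + 1))
  }
  e <- e[e$i != e$j, ]
  ii <- pmin(e$i, e$j); jj <- pmax(e$i, e$j)
  unique(tibble::tibble(i = as.integer(ii), j = as.integer(jj)))
}
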