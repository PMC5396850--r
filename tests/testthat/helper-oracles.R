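# Independent brute-force oracles used to cross-check the package's graph
# metrics. These deliberately use the slowest, most literal formulation.

# Hop-count all-pairs shortest paths by Floyd-Warshall on a 0/1 adjacency.
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Local clustering by explicit neighbour-pair enumeration.
oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in nb) for (b in nb) if (a != b && A[a, b] > 0) links <- links + 1
    links / (k * (k - 1))
  })
}

# Network cost by double loop over the upper triangle.
oracle_network_cost <- function(W, D) {
  n <- nrow(W)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (W[i, j] > 0) total <- total + D[i, j] * W[i, j]
    }
  }
  total
}

# Global efficiency by enumerating pair distances.
oracle_efficiency <- function(dmat) {
  n <- nrow(dmat)
  acc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.finite(dmat[i, j]) && dmat[i, j] > 0) acc <- acc + 1 / dmat[i, j]
    }
  }
  2 / (n * (n - 1)) * acc
}

# Weighted all-pairs shortest paths, literal Floyd-Warshall on a distance
# matrix where 0 off-diagonal means no edge.
oracle_weighted_paths <- function(dist_mat) {
  n <- nrow(dist_mat)
  d <- ifelse(dist_mat > 0, dist_mat, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Random weighted network with edge density p.
random_network <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  on <- runif(sum(ut)) < p
  w <- ifelse(on, runif(sum(ut), 0.05, 1), 0)
  W[ut] <- w
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  weighted_network(W)
}

# Small ROI set with fixed, well-spread coordinates.
random_rois <- function(n, seed = 1, n_subsystems = min(4, n)) {
  set.seed(seed)
  coords <- matrix(runif(3 * n, -70, 70), ncol = 3)
  roi_set(coords, subsystem = sprintf("S%02d", rep_len(seq_len(n_subsystems), n)))
}

# Network from an explicit edge list (i, j, weight) over n nodes.
edge_network <- function(n, edges, weights = rep(0.5, nrow(edges))) {
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    W[edges[r, 1], edges[r, 2]] <- weights[r]
    W[edges[r, 2], edges[r, 1]] <- weights[r]
  }
  weighted_network(W)
}
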