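test_that("edge cost is the length-strength product", {
  expect_equal(edge_cost(40, 0.6), 24)
  expect_equal(edge_cost(60, 0.4), 24)
  expect_equal(edge_cost(0, 0.9), 0)
  expect_error(edge_cost(-1, 0.5), ">= 0")
  expect_error(edge_cost(10, 1.2), "0, 1")
  # iso-cost contour symmetry: scaling length by k and strength by 1/k
  for (k in c(0.5, 2, 3)) {
    s <- 0.9 / k
    if (s <= 1) expect_equal(edge_cost(30 * k, s), edge_cost(30, 0.9))
  }
})

test_that("network, ROI cost and strength satisfy hand-computed cases", {
  # 2 ROIs at distance 10 with weight 0.5 -> cost 5
  rois2 <- roi_set(matrix(c(0, 0, 0, 10, 0, 0), 2, byrow = TRUE), c("A", "A"))
  net2 <- edge_network(2, cbind(1, 2), 0.5)
  expect_equal(network_cost(net2, rois2), 5)

  # star centre: 3 edges of weight 0.5 at distances 10, 20, 30
  rois4 <- roi_set(
    matrix(c(0, 0, 0, 10, 0, 0, 0, 20, 0, 0, 0, 30), 4, byrow = TRUE),
    rep("A", 4)
  )
  star <- edge_network(4, rbind(c(1, 2), c(1, 3), c(1, 4)), rep(0.5, 3))
  expect_equal(unname(roi_strength(star)[1]), 1.5)
  expect_equal(unname(roi_cost(star, rois4)[1]), 5 + 10 + 15)
  # isolated ROI in a larger graph
  iso <- edge_network(4, cbind(1, 2), 0.7)
  expect_equal(unname(roi_strength(iso)[3]), 0)
  expect_equal(unname(roi_cost(iso, rois4)[3]), 0)
  expect_error(roi_cost(star, rois4, roi_id = 99), "unknown roi_id")

  # empty network
  empty <- weighted_network(matrix(0, 4, 4))
  expect_equal(network_cost(empty, rois4), 0)
})

test_that("handshake identities hold on random networks", {
  for (seed in 1:20) {
    net <- random_network(sample(5:15, 1), p = runif(1, 0.2, 0.7), seed = seed)
    rois <- random_rois(net$n_roi, seed = seed + 100)
    expect_equal(sum(roi_strength(net)), 2 * network_strength(net))
    expect_equal(sum(roi_cost(net, rois)), 2 * network_cost(net, rois))
  }
})

test_that("clustering matches enumeration and handles canonical graphs", {
  tri <- edge_network(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(clustering_coefficient(tri), rep(1, 3))
  star <- edge_network(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(clustering_coefficient(star)[1], 0) # no neighbour-neighbour edges
  expect_equal(clustering_coefficient(star)[2], 0) # degree 1 -> 0 by convention
  # 4-node: edges (1-2, 1-3, 2-3, 3-4); node 3 has one of three neighbour pairs linked
  g4 <- edge_network(4, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4)))
  expect_equal(clustering_coefficient(g4)[3], 1 / 3)
  # weighted form reduces to unweighted on equal weights
  expect_equal(
    clustering_coefficient(g4, mode = "weighted"),
    clustering_coefficient(g4, mode = "unweighted")
  )
})

test_that("paths and efficiency match hand-derived values", {
  path3 <- edge_network(3, rbind(c(1, 2), c(2, 3)))
  d <- shortest_paths_unweighted(path3)
  expect_equal(d[1, 3], 2)
  expect_equal(global_efficiency(path3), (2 / (3 * 2)) * (1 + 1 + 1 / 2))

  disc <- edge_network(4, cbind(1, 2))
  expect_equal(shortest_paths_unweighted(disc)[3, 4], Inf)

  complete5 <- weighted_network({
    W <- matrix(0.8, 5, 5)
    diag(W) <- 0
    W
  })
  expect_equal(global_efficiency(complete5), 1)
  expect_equal(global_efficiency(weighted_network(matrix(0, 4, 4))), 0)
})

test_that("graph metrics agree with brute-force oracles on random graphs", {
  for (seed in 1:30) {
    n <- sample(5:20, 1)
    net <- random_network(n, p = runif(1, 0.15, 0.8), seed = seed)
    rois <- random_rois(n, seed = seed + 500)
    A <- (net$weights > 0) + 0
    D <- roi_distances(rois)

    expect_equal(shortest_paths_unweighted(net), oracle_floyd_warshall(A),
      ignore_attr = TRUE
    )
    expect_equal(clustering_coefficient(net), oracle_clustering(A))
    expect_equal(network_cost(net, rois), oracle_network_cost(net$weights, D))
    expect_equal(global_efficiency(net), oracle_efficiency(oracle_floyd_warshall(A)))
  }
})

test_that("weighted shortest paths match the literal Floyd-Warshall", {
  for (seed in 1:10) {
    net <- random_network(12, p = 0.4, seed = seed)
    inv <- inverse_network(net)
    expect_equal(shortest_paths_weighted(inv$dist), oracle_weighted_paths(inv$dist),
      ignore_attr = TRUE
    )
  }
})

test_that("edge removal never increases efficiency or cost", {
  for (seed in 1:10) {
    net <- random_network(10, p = 0.5, seed = seed)
    rois <- random_rois(10, seed = seed)
    e0 <- global_efficiency(net)
    c0 <- network_cost(net, rois)
    idx <- which(upper.tri(net$weights) & net$weights > 0)
    drop <- idx[sample(length(idx), 1)]
    W <- net$weights
    W[drop] <- 0
    W[matrix(rev(arrayInd(drop, dim(W))), 1)] <- 0
    net1 <- weighted_network(W)
    expect_lte(global_efficiency(net1), e0)
    expect_lte(network_cost(net1, rois), c0)
  }
})

test_that("connectivity profiles assemble all metrics coherently", {
  sp <- cohort_spec(
    n_roi = 20, n_subsystems = 4, n_volumes = 120,
    subjects_per_group = c(G = 1), time_points = list(G = "T1"), seed = 3
  )
  co <- generate_cohort(sp)
  net <- correlation_network(co$panels[[1]])
  prof <- connectivity_profile(net, co$ground_truth$rois)
  s <- prof$scalars
  expect_equal(sum(prof$per_roi$strength), 2 * s$network_strength)
  expect_equal(sum(prof$per_roi$cost), 2 * s$network_cost)
  expect_equal(s$total_links, sum(net$weights[upper.tri(net$weights)] > 0))
  expect_true(s$avg_clustering_unweighted >= 0 && s$avg_clustering_unweighted <= 1)
  expect_true(s$global_efficiency >= 0 && s$global_efficiency <= 1)

  emptyp <- connectivity_profile(weighted_network(matrix(0, 6, 6)), random_rois(6))
  expect_equal(emptyp$scalars$total_links, 0)
  expect_equal(emptyp$scalars$network_cost, 0)
  expect_equal(emptyp$scalars$global_efficiency, 0)
  expect_true(is.na(emptyp$scalars$avg_shortest_path_unweighted))
})
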