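#' Cost of a functional connection
#'
#' The cost of an edge is the product of the Euclidean distance between its
#' ROI pair (mm) and the absolute correlation weight of the connection
#' (unitless), so a 40 mm connection of strength 0.6 costs 24 -- the same as
#' a 60 mm connection of strength 0.4. Cost thereby folds connection count,
#' strength and physical length into a single metabolically motivated
#' quantity.
#'
#' @param length_mm Euclidean connection length(s), mm, `>= 0`.
#' @param abs_weight absolute connection strength(s) in `[0, 1]`.
#' @return `length_mm * abs_weight` (vectorised).
#' @export
#' @examples
#' edge_cost(40, 0.6) # 24
#' edge_cost(60, 0.4) # also 24: same iso-cost contour
edge_cost <- function(length_mm, abs_weight) {
  if (any(length_mm < 0)) stop_netcost("length_mm must be >= 0")
  if (any(abs_weight < 0 | abs_weight > 1)) stop_netcost("abs_weight must lie in [0, 1]")
  length_mm * abs_weight
}

#' Total network cost
#'
#' Sums [edge_cost] over every retained edge (each undirected edge counted
#' once).
#'
#' @param net a [weighted_network].
#' @param rois a [roi_set] aligned with `net` (same size, same order).
#' @return Total cost, mm x unitless.
#' @export
network_cost <- function(net, rois) {
  stopifnot(inherits(net, "weighted_network"))
  if (nrow(rois) != net$n_roi) stop_netcost("net and rois sizes disagree")
  D <- roi_distances(rois)
  sum((D * net$weights)[upper_tri(net$n_roi)])
}

#' Total network strength
#'
#' Sum of absolute weights over retained edges (each counted once).
#' @inheritParams network_cost
#' @return Total strength (unitless).
#' @export
network_strength <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  sum(net$weights[upper_tri(net$n_roi)])
}

#' Per-ROI cost and strength
#'
#' `roi_cost` totals the cost of all retained edges incident on each ROI;
#' `roi_strength` totals their absolute weights. Summing either over all
#' ROIs counts every edge twice (the handshake identity), so
#' `sum(roi_cost) == 2 * network_cost`.
#'
#' @inheritParams network_cost
#' @param roi_id optional ROI id(s) to return; default all, in ROI order.
#' @return Named numeric vector.
#' @export
roi_cost <- function(net, rois, roi_id = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (nrow(rois) != net$n_roi) stop_netcost("net and rois sizes disagree")
  D <- roi_distances(rois)
  out <- rowSums(D * net$weights)
  names(out) <- rois$roi_id
  pick_roi(out, rois, roi_id)
}

#' @rdname roi_cost
#' @param net a [weighted_network].
#' @export
roi_strength <- function(net, rois = NULL, roi_id = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  out <- rowSums(net$weights)
  if (!is.null(rois)) names(out) <- rois$roi_id
  pick_roi(out, rois, roi_id)
}

pick_roi <- function(values, rois, roi_id) {
  if (is.null(roi_id)) return(values)
  ids <- if (is.null(rois)) seq_along(values) else rois$roi_id
  pos <- match(roi_id, ids)
  if (anyNA(pos)) stop_netcost("unknown roi_id: ", paste(roi_id[is.na(pos)], collapse = ", "))
  values[pos]
}

#' Local clustering coefficient
#'
#' Unweighted: the fraction of a node's neighbour pairs that are themselves
#' connected, `C_i = 2 T_i / (k_i (k_i - 1))` with `T_i` the number of
#' triangles through `i` on the binarised retained-edge graph (the
#' ordered-pair reading of the neighbourhood edge count). Weighted: the
#' Onnela geometric-mean generalisation on weights normalised by the maximum
#' weight. Nodes with fewer than two neighbours return 0.
#'
#' @param net a [weighted_network].
#' @param roi_id optional node subset (positional ids `1:n`).
#' @param mode `"unweighted"` or `"weighted"`.
#' @return Numeric vector of clustering coefficients in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, roi_id = NULL,
                                   mode = c("unweighted", "weighted")) {
  stopifnot(inherits(net, "weighted_network"))
  mode <- match.arg(mode)
  A <- (net$weights > 0) + 0
  k <- rowSums(A)
  denom <- k * (k - 1)
  if (mode == "unweighted") {
    tri2 <- diag(A %*% A %*% A) # 2 * triangles per node
  } else {
    mx <- max(net$weights)
    if (mx == 0) return(rep(0, if (is.null(roi_id)) net$n_roi else length(roi_id)))
    Wh <- (net$weights / mx)^(1 / 3)
    tri2 <- diag(Wh %*% Wh %*% Wh)
  }
  cc <- ifelse(denom > 0, tri2 / denom, 0)
  if (is.null(roi_id)) cc else cc[roi_id]
}

#' Unweighted shortest path lengths
#'
#' Breadth-first hop distances between all ROI pairs on the binarised
#' retained-edge graph; unreachable pairs are `Inf`.
#'
#' @param net a [weighted_network].
#' @return `n x n` matrix of hop counts (0 on the diagonal).
#' @export
shortest_paths_unweighted <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  g <- igraph::graph_from_adjacency_matrix((net$weights > 0) + 0,
    mode = "undirected", diag = FALSE
  )
  igraph::distances(g, weights = NA)
}

# Weighted shortest paths over an explicit distance matrix; a zero
# off-diagonal entry means "no edge". Used for the inverse-distance network.
# Compiled Floyd-Warshall: the averaged networks are near-complete, where the
# dense sweep beats repeated Dijkstra.
shortest_paths_weighted <- function(dist_mat) {
  cpp_apsp(as.matrix(dist_mat))
}

#' Global efficiency
#'
#' The average inverse shortest-path distance over all node pairs,
#' `E(G) = 2 / (n (n - 1)) * sum_{i<j} 1 / d(i, j)`, with unreachable pairs
#' contributing 0 (harmonic convention). `mode = "unweighted"` uses hop
#' counts; `mode = "inverse_weighted"` uses Dijkstra distances over an
#' inverse-strength distance network (see [inverse_network]).
#'
#' @param net a [weighted_network] or [inverse_network].
#' @param mode distance convention.
#' @return Efficiency in `[0, 1]` for unweighted mode.
#' @export
#' @examples
#' # path graph 1-2-3: (2/(3*2)) * (1 + 1 + 1/2) = 0.8333
global_efficiency <- function(net, mode = c("unweighted", "inverse_weighted")) {
  mode <- match.arg(mode)
  if (mode == "unweighted") {
    stopifnot(inherits(net, "weighted_network"))
    if (net$n_roi < 2) stop_netcost("need at least 2 ROIs")
    Dsp <- shortest_paths_unweighted(net)
  } else {
    inv <- if (inherits(net, "inverse_network")) net else inverse_network(net)
    if (inv$n_roi < 2) stop_netcost("need at least 2 ROIs")
    Dsp <- shortest_paths_weighted(inv$dist)
  }
  efficiency_from_distances(Dsp)
}

# E = 2/(n(n-1)) * sum_{i<j} 1/d, unreachable pairs contribute 0.
efficiency_from_distances <- function(Dsp) {
  n <- nrow(Dsp)
  inv <- 1 / Dsp[upper_tri(n)]
  inv[!is.finite(inv)] <- 0
  2 / (n * (n - 1)) * sum(inv)
}

#' Subject-specific connectivity profile
#'
#' Assembles the per-network summary used for group comparison: retained
#' link count, network strength, network cost, mean unweighted and weighted
#' local clustering (averaged over all nodes), mean unweighted shortest path
#' length (over reachable pairs; `NA` if none), unweighted global
#' efficiency, plus the per-ROI strength and cost vectors.
#'
#' @inheritParams network_cost
#' @return An object of class `connectivity_profile`: a list with `scalars`
#'   (one-row data frame) and `per_roi` (data frame `roi_id`, `strength`,
#'   `cost`).
#' @export
connectivity_profile <- function(net, rois) {
  stopifnot(inherits(net, "weighted_network"))
  if (nrow(rois) != net$n_roi) stop_netcost("net and rois sizes disagree")
  n <- net$n_roi
  ut <- upper_tri(n)
  Dsp <- shortest_paths_unweighted(net)
  finite <- is.finite(Dsp[ut]) & Dsp[ut] > 0
  scalars <- data.frame(
    n_roi = n,
    total_links = sum(net$weights[ut] > 0),
    network_strength = network_strength(net),
    network_cost = network_cost(net, rois),
    avg_clustering_unweighted = mean(clustering_coefficient(net, mode = "unweighted")),
    avg_clustering_weighted = mean(clustering_coefficient(net, mode = "weighted")),
    avg_shortest_path_unweighted = if (any(finite)) mean(Dsp[ut][finite]) else NA_real_,
    global_efficiency = efficiency_from_distances(Dsp)
  )
  prov <- net$provenance
  for (nm in c("subject_id", "group", "time_point", "scanner")) {
    scalars[[nm]] <- prov[[nm]] %||% NA_character_
  }
  structure(
    list(
      scalars = scalars,
      per_roi = data.frame(
        roi_id = rois$roi_id,
        strength = unname(roi_strength(net)),
        cost = unname(roi_cost(net, rois))
      )
    ),
    class = "connectivity_profile"
  )
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat("Connectivity profile\n")
  s <- x$scalars
  cat(sprintf(
    "  %d ROIs, %d links | strength %.2f | cost %.2f\n",
    s$n_roi, s$total_links, s$network_strength, s$network_cost
  ))
  cat(sprintf(
    "  clustering U/W %.3f/%.3f | path length %.3f | efficiency %.3f\n",
    s$avg_clustering_unweighted, s$avg_clustering_weighted,
    s$avg_shortest_path_unweighted, s$global_efficiency
  ))
  invisible(x)
}

#' Profile a list of networks into one table
#'
#' @param nets list of [weighted_network].
#' @param rois the shared [roi_set].
#' @return List with `scalars` (one row per network) and `per_roi`
#'   (long format: subject, time point, roi_id, strength, cost).
#' @export
profile_table <- function(nets, rois) {
  profs <- lapply(nets, connectivity_profile, rois = rois)
  scalars <- do.call(rbind, lapply(profs, function(p) p$scalars))
  per_roi <- do.call(rbind, lapply(profs, function(p) {
    cbind(
      subject_id = p$scalars$subject_id, group = p$scalars$group,
      time_point = p$scalars$time_point, p$per_roi,
      stringsAsFactors = FALSE
    )
  }))
  list(scalars = scalars, per_roi = per_roi)
}
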