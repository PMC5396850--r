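#' Group-averaged weighted network
#'
#' Entrywise mean of absolute weights across subjects, counting an absent
#' edge as weight 0; an averaged edge exists iff it is present in at least
#' one subject. All networks must share the node count.
#'
#' @param nets non-empty list of [weighted_network].
#' @return A [weighted_network] of averaged weights.
#' @export
group_average_network <- function(nets) {
  if (length(nets) == 0) stop_netcost("need at least one network")
  n <- nets[[1]]$n_roi
  acc <- matrix(0, n, n)
  for (net in nets) {
    stopifnot(inherits(net, "weighted_network"))
    if (net$n_roi != n) stop_netcost("networks differ in size")
    acc <- acc + net$weights
  }
  prov <- nets[[1]]$provenance
  weighted_network(acc / length(nets),
    provenance = list(
      group = prov$group %||% NA_character_,
      time_point = prov$time_point %||% NA_character_,
      n_subjects = length(nets)
    )
  )
}

#' Inverse (distance) network
#'
#' Maps each connected edge's average absolute weight `w` to a distance
#' `1.01 - w`, so the strongest possible correlation (`w = 1`) becomes a
#' short but non-zero distance of 0.01 and weak correlations become long
#' distances. Pairs disconnected in the source network stay disconnected
#' (entry 0, meaning "no edge", in both).
#'
#' @param avg a [weighted_network] (typically from [group_average_network]).
#' @return An object of class `inverse_network`: list with `dist`
#'   (symmetric matrix; 0 = disconnected, otherwise in `[0.01, 1.01]`),
#'   `n_roi`, `provenance`.
#' @export
#' @examples
#' w <- matrix(0, 2, 2); w[1, 2] <- w[2, 1] <- 1
#' inverse_network(weighted_network(w))$dist[1, 2] # 0.01
inverse_network <- function(avg) {
  stopifnot(inherits(avg, "weighted_network"))
  if (any(avg$weights > 1)) stop_netcost("weights must not exceed 1")
  dist <- ifelse(avg$weights > 0, 1.01 - avg$weights, 0)
  structure(
    list(dist = dist, n_roi = avg$n_roi, provenance = avg$provenance),
    class = "inverse_network"
  )
}

#' @export
print.inverse_network <- function(x, ...) {
  m <- sum(x$dist[upper_tri(x$n_roi)] > 0)
  cat("Inverse distance network:", x$n_roi, "ROIs,", m, "edges\n")
  invisible(x)
}

#' Random edge-deletion cost-efficiency simulation
#'
#' Traces the cost-efficiency trade-off of a group-averaged network: for
#' each deletion percentage `X` in `pct` and each of `reps` repetitions,
#' deletes a uniformly random `floor(X/100 * |E|)`-edge subset (without
#' replacement; edges are restored between repetitions), then records the
#' surviving network's total cost (sum of distance x weight over surviving
#' edges) and its global efficiency over weighted shortest paths on the
#' surviving inverse-network distances. The default grid (`pct = 1:99`,
#' `reps = 50`) yields 4950 records.
#'
#' With `nested = TRUE` each repetition instead fixes one random edge
#' permutation and deletes prefixes of it, so the deleted sets are nested
#' across `X` -- along such a sequence both cost and efficiency are
#' non-increasing, which makes the mode useful for monotonicity checks.
#'
#' @param avg group-averaged [weighted_network].
#' @param rois aligned [roi_set] (for edge lengths).
#' @param inv matching [inverse_network]; computed from `avg` if omitted.
#' @param reps repetitions per percentage (>= 1).
#' @param pct integer deletion percentages, each in 1..99.
#' @param seed RNG seed; the full table is reproducible bit-for-bit.
#' @param nested use nested (prefix) deletion sequences instead of
#'   independent draws.
#' @param efficiency `"weighted"` (Dijkstra on inverse distances, default)
#'   or `"unweighted"` (hop counts on the surviving topology).
#' @return A data frame of class `cost_efficiency_table` with columns
#'   `pct`, `rep`, `cost`, `efficiency`.
#' @export
run_attack_simulation <- function(avg, rois, inv = inverse_network(avg),
                                  reps = 50, pct = 1:99, seed = 1,
                                  nested = FALSE,
                                  efficiency = c("weighted", "unweighted")) {
  stopifnot(inherits(avg, "weighted_network"), inherits(inv, "inverse_network"))
  efficiency <- match.arg(efficiency)
  if (reps < 1) stop_netcost("reps must be >= 1")
  if (any(pct < 1 | pct > 99)) stop_netcost("pct values must lie in 1..99")
  n <- avg$n_roi
  if (nrow(rois) != n) stop_netcost("net and rois sizes disagree")
  if (!identical(inv$dist > 0, avg$weights > 0)) {
    stop_netcost("inverse network disconnection pattern disagrees with avg")
  }
  ut_idx <- which(upper_tri(n) & avg$weights > 0)
  m <- length(ut_idx)
  if (m == 0) stop_netcost("empty network: no edges to delete")
  D <- roi_distances(rois)
  cost_vec <- D[ut_idx] * avg$weights[ut_idx]
  total_cost <- sum(cost_vec)
  ij <- arrayInd(ut_idx, c(n, n))
  lo_idx <- ij[, 2] + n * (ij[, 1] - 1L) # mirror entries in the lower triangle
  base_dist <- if (efficiency == "weighted") inv$dist else (avg$weights > 0) + 0
  eval_one <- function(del) {
    dd <- base_dist
    dd[ut_idx[del]] <- 0
    dd[lo_idx[del]] <- 0
    c(
      cost = total_cost - sum(cost_vec[del]),
      efficiency = cpp_efficiency(dd)
    )
  }
  recs <- with_seed(seed, {
    if (nested) {
      do.call(rbind, lapply(seq_len(reps), function(r) {
        perm <- sample.int(m)
        t(vapply(pct, function(X) {
          k <- floor(X / 100 * m)
          c(pct = X, rep = r, eval_one(perm[seq_len(k)]))
        }, numeric(4)))
      }))
    } else {
      do.call(rbind, lapply(pct, function(X) {
        k <- floor(X / 100 * m)
        t(vapply(seq_len(reps), function(r) {
          del <- if (k > 0) sample.int(m, k) else integer(0)
          c(pct = X, rep = r, eval_one(del))
        }, numeric(4)))
      }))
    }
  })
  out <- as.data.frame(recs)
  names(out) <- c("pct", "rep", "cost", "efficiency")
  attr(out, "provenance") <- c(avg$provenance, list(seed = seed, nested = nested))
  class(out) <- c("cost_efficiency_table", "data.frame")
  out
}

#' @export
print.cost_efficiency_table <- function(x, ...) {
  cat(
    "Cost-efficiency table:", nrow(x), "records,",
    length(unique(x$pct)), "deletion percentages x",
    length(unique(x$rep)), "repetitions\n"
  )
  cat(sprintf(
    "  cost range [%.1f, %.1f]; efficiency range [%.4f, %.4f]\n",
    min(x$cost), max(x$cost), min(x$efficiency), max(x$efficiency)
  ))
  invisible(x)
}

#' Plot the cost-efficiency trade-off
#'
#' @param x a `cost_efficiency_table` (or several, passed as `others`).
#' @param others optional named list of further tables to overlay.
#' @param ... passed to [graphics::plot].
#' @export
plot.cost_efficiency_table <- function(x, others = NULL, ...) {
  cols <- c("black", "firebrick", "steelblue", "darkgreen")
  graphics::plot(x$cost, x$efficiency,
    pch = 16, cex = 0.3, col = cols[1],
    xlab = "network cost (mm x weight)", ylab = "global efficiency", ...
  )
  if (!is.null(others)) {
    for (i in seq_along(others)) {
      graphics::points(others[[i]]$cost, others[[i]]$efficiency,
        pch = 16, cex = 0.3, col = cols[1 + i]
      )
    }
    graphics::legend("bottomright",
      legend = c("main", names(others)),
      col = cols[seq_len(1 + length(others))], pch = 16, bty = "n"
    )
  }
  invisible(x)
}

#' Compare efficiency between two simulations within cost bands
#'
#' Bins both tables' records into half-open cost bands
#' `[k*band_width, (k+1)*band_width)` anchored at zero, and within each band
#' runs an independent two-sample t-test (pooled variance) on the efficiency
#' values, Bonferroni-adjusting p over the number of tested bands, with
#' Cohen's d (pooled SD). Bands with fewer than two records on either side
#' are skipped with a message.
#'
#' @param tableA,tableB `cost_efficiency_table` objects (e.g. two time
#'   points).
#' @param band_width cost-band width (default 50000).
#' @return Data frame: `band_lo`, `band_hi`, `n_a`, `n_b`, `t`, `p_raw`,
#'   `p_bonf`, `cohens_d`.
#' @export
band_compare <- function(tableA, tableB, band_width = 50000) {
  if (nrow(tableA) == 0 || nrow(tableB) == 0) stop_netcost("empty table")
  top <- max(tableA$cost, tableB$cost)
  n_bands <- max(1L, ceiling(top / band_width + 1e-12))
  band_of <- function(cost) pmin(floor(cost / band_width), n_bands - 1L)
  ba <- band_of(tableA$cost)
  bb <- band_of(tableB$cost)
  rows <- list()
  for (k in 0:(n_bands - 1L)) {
    ea <- tableA$efficiency[ba == k]
    eb <- tableB$efficiency[bb == k]
    if (length(ea) < 2 || length(eb) < 2) {
      if (length(ea) + length(eb) > 0) {
        message(sprintf(
          "band [%g, %g): fewer than 2 records on one side, skipped",
          k * band_width, (k + 1) * band_width
        ))
      }
      next
    }
    if (stats::sd(c(ea, eb)) == 0) { # all efficiencies identical in this band
      tstat <- 0
      praw <- 1
      d <- 0
    } else {
      tt <- stats::t.test(ea, eb, var.equal = TRUE)
      tstat <- unname(tt$statistic)
      praw <- tt$p.value
      d <- cohens_d(ea, eb)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      band_lo = k * band_width, band_hi = (k + 1) * band_width,
      n_a = length(ea), n_b = length(eb),
      t = tstat, p_raw = praw, cohens_d = d
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_netcost("no cost band had >= 2 records in both tables")
  out$p_bonf <- pmin(1, out$p_raw * nrow(out))
  out[, c("band_lo", "band_hi", "n_a", "n_b", "t", "p_raw", "p_bonf", "cohens_d")]
}
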