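#' Table of connections incident on a subsystem
#'
#' For each network (one per subject), lists every retained edge with at
#' least one endpoint in `subsystem` as a (length, strength) pair; an edge
#' joining two subsystem ROIs appears once. Rows pool across subjects.
#'
#' @param nets list of [weighted_network] (or a single network).
#' @param rois shared [roi_set].
#' @param subsystem subsystem label.
#' @param subsystem_map optional subsystem label per ROI; defaults to
#'   `rois$subsystem`.
#' @return Data frame: `subject`, `length_mm`, `strength`.
#' @export
incident_edge_table <- function(nets, rois, subsystem,
                                subsystem_map = rois$subsystem) {
  if (inherits(nets, "weighted_network")) nets <- list(nets)
  if (!subsystem %in% subsystem_map) stop_netcost("unknown subsystem '", subsystem, "'")
  D <- roi_distances(rois)
  member <- subsystem_map == subsystem
  incident <- outer(member, member, "|")
  rows <- lapply(seq_along(nets), function(i) {
    net <- nets[[i]]
    stopifnot(inherits(net, "weighted_network"))
    sel <- which(upper_tri(net$n_roi) & net$weights > 0 & incident)
    data.frame(
      subject = rep(net$provenance$subject_id %||% sprintf("net%02d", i), length(sel)),
      length_mm = D[sel], strength = net$weights[sel],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' 2-D length-by-strength histogram of connections
#'
#' Bins connection (length, strength) pairs into rectangular bins; bins are
#' half-open on the right except the last, which is closed. Rows falling
#' outside the bin range are counted in the nearest edge bin with a warning,
#' so the total count always equals the number of rows.
#'
#' @param table data frame with columns `length_mm` and `strength`
#'   (e.g. from [incident_edge_table]).
#' @param length_bins increasing length bin edges, mm (default 0-180 by 10).
#' @param strength_bins increasing strength bin edges (default 0-1 by 0.05;
#'   computed as `(0:20)/20` so round strengths land on exact bin edges).
#' @param provenance named list recorded on the object.
#' @return Object of class `histogram2d`: list with `counts`
#'   (length-bins x strength-bins), `length_edges`, `strength_edges`,
#'   `provenance`.
#' @export
histogram2d <- function(table, length_bins = seq(0, 180, by = 10),
                        strength_bins = (0:20) / 20,
                        provenance = list()) {
  if (is.unsorted(length_bins, strictly = TRUE) ||
    is.unsorted(strength_bins, strictly = TRUE)) {
    stop_netcost("bin edges must be strictly increasing")
  }
  nl <- length(length_bins) - 1L
  ns <- length(strength_bins) - 1L
  bin_of <- function(x, edges, nbin, what) {
    i <- findInterval(x, edges, rightmost.closed = TRUE)
    if (any(i < 1 | i > nbin)) {
      warning(what, " values outside bin range clamped to edge bins")
      i <- pmin(pmax(i, 1L), nbin)
    }
    i
  }
  counts <- matrix(0L, nl, ns)
  if (nrow(table) > 0) {
    li <- bin_of(table$length_mm, length_bins, nl, "length")
    si <- bin_of(table$strength, strength_bins, ns, "strength")
    tab <- tabulate((si - 1L) * nl + li, nbins = nl * ns)
    counts <- matrix(tab, nl, ns)
  }
  structure(
    list(
      counts = counts, length_edges = length_bins, strength_edges = strength_bins,
      provenance = provenance
    ),
    class = "histogram2d"
  )
}

#' @export
print.histogram2d <- function(x, ...) {
  cat(
    "2-D length x strength histogram:", sum(x$counts), "connections in",
    nrow(x$counts), "x", ncol(x$counts), "bins\n"
  )
  invisible(x)
}

#' Difference of two 2-D histograms
#'
#' Entrywise `hA - hB` over identical bin edges; positive counts mark
#' (length, strength) cells where `hA` holds more connections.
#'
#' @param hA,hB [histogram2d] objects on identical bin edges.
#' @return A signed `histogram2d`.
#' @export
difference_histogram <- function(hA, hB) {
  stopifnot(inherits(hA, "histogram2d"), inherits(hB, "histogram2d"))
  if (!identical(hA$length_edges, hB$length_edges) ||
    !identical(hA$strength_edges, hB$strength_edges)) {
    stop_netcost("bin edges differ between histograms")
  }
  out <- hA
  out$counts <- hA$counts - hB$counts
  out$provenance <- list(difference = TRUE, a = hA$provenance, b = hB$provenance)
  out
}

#' Iso-cost contour
#'
#' All (length, strength) points with `length * strength == cost_level`:
#' `strength = cost_level / length`, keeping points with strength in
#' `(0, 1]` and skipping zero lengths. A level-24 contour passes through
#' (40 mm, 0.6) and (60 mm, 0.4).
#'
#' @param cost_level contour cost level (> 0).
#' @param length_grid lengths (mm) at which to evaluate the contour.
#' @return Data frame `length_mm`, `strength` of in-range contour points.
#' @export
iso_cost_contour <- function(cost_level, length_grid) {
  if (cost_level <= 0) stop_netcost("cost_level must be > 0")
  length_grid <- length_grid[length_grid > 0]
  s <- cost_level / length_grid
  keep <- s <= 1
  data.frame(length_mm = length_grid[keep], strength = s[keep])
}

#' Plot a 2-D histogram with iso-cost contours
#'
#' Heatmap of connection counts over length x strength, overlaid with
#' iso-cost contour lines (`length * strength = level`). For difference
#' histograms a diverging palette centres at zero.
#'
#' @param x a [histogram2d].
#' @param contour_levels cost levels to overlay (default quartiles of the
#'   observed cost range).
#' @param ... passed to [graphics::image].
#' @export
plot.histogram2d <- function(x, contour_levels = NULL, ...) {
  lmid <- (utils::head(x$length_edges, -1) + utils::tail(x$length_edges, -1)) / 2
  smid <- (utils::head(x$strength_edges, -1) + utils::tail(x$strength_edges, -1)) / 2
  signed <- any(x$counts < 0)
  if (signed) {
    mx <- max(abs(x$counts), 1)
    breaks <- seq(-mx, mx, length.out = 33)
    cols <- grDevices::hcl.colors(32, "Blue-Red 2")
  } else {
    breaks <- NULL
    cols <- grDevices::hcl.colors(32, "YlOrRd", rev = TRUE)
  }
  graphics::image(lmid, smid, x$counts,
    col = cols, breaks = breaks,
    xlab = "connection length (mm)", ylab = "connection strength", ...
  )
  if (is.null(contour_levels)) {
    top <- max(x$length_edges) * max(x$strength_edges)
    contour_levels <- round(top * c(0.1, 0.25, 0.5, 0.75))
  }
  lg <- seq(min(x$length_edges[x$length_edges > 0], 1), max(x$length_edges), length.out = 200)
  for (lev in contour_levels) {
    ctr <- iso_cost_contour(lev, lg)
    if (nrow(ctr) > 1) {
      graphics::lines(ctr$length_mm, ctr$strength, lty = 2, col = "grey30")
      graphics::text(ctr$length_mm[1], ctr$strength[1], labels = lev, cex = 0.7, pos = 4)
    }
  }
  invisible(x)
}

#' Write a 2-D histogram as TSV
#'
#' Matrix layout with bin-edge header rows (`# length_edges:` and
#' `# strength_edges:`).
#'
#' @param h a [histogram2d].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_histogram2d <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# length_edges:", paste(h$length_edges, collapse = " ")),
    paste("# strength_edges:", paste(h$strength_edges, collapse = " "))
  ), con)
  utils::write.table(h$counts, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
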