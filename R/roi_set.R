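#' Construct an ROI set
#'
#' An ROI set is the spatial frame for all cost computations: one row per
#' region of interest (ROI), holding its 3-D coordinate in millimetres and the
#' brain subsystem it belongs to (e.g. default mode network, executive
#' control). Coordinates must be finite and distinct; every ROI carries
#' exactly one subsystem label.
#'
#' @param coords numeric matrix or data frame with 3 columns (x, y, z), in mm.
#' @param subsystem character or factor vector of subsystem labels, one per ROI.
#' @param roi_id integer ROI identifiers; defaults to `1:n`.
#' @return A data frame of class `roi_set` with columns
#'   `roi_id`, `x`, `y`, `z`, `subsystem`.
#' @export
#' @examples
#' rs <- roi_set(matrix(rnorm(15), ncol = 3), subsystem = rep(c("A", "B"), c(3, 2)))
#' roi_distances(rs)[1, 2]
roi_set <- function(coords, subsystem, roi_id = seq_len(nrow(coords))) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop_netcost("coords must have 3 columns (x, y, z in mm)")
  if (!all(is.finite(coords))) stop_netcost("ROI coordinates must be finite")
  if (anyDuplicated(coords)) stop_netcost("two ROIs share an identical coordinate")
  subsystem <- as.character(subsystem)
  if (length(subsystem) != nrow(coords)) {
    stop_netcost("need exactly one subsystem label per ROI")
  }
  if (anyNA(subsystem)) stop_netcost("missing subsystem labels")
  out <- data.frame(
    roi_id = as.integer(roi_id),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    subsystem = subsystem,
    stringsAsFactors = FALSE
  )
  class(out) <- c("roi_set", "data.frame")
  out
}

#' Generate a synthetic ROI parcellation
#'
#' Draws `n_roi` ROI coordinates inside a brain-sized bounding box
#' (140 x 170 x 120 mm) grouped into `n_subsystems` spatially coherent
#' subsystems. Each subsystem is seeded at a random centre and its ROIs are
#' scattered around that centre, so within-subsystem distances are on average
#' shorter than between-subsystem distances -- the property that makes
#' connection-length analyses of subsystems meaningful. The default sizes
#' mirror the widely used 264-region functional parcellation collapsed into
#' 20 subsystems.
#'
#' @param n_roi number of ROIs (>= `n_subsystems`).
#' @param n_subsystems number of subsystems (>= 1).
#' @param seed RNG seed; fixing it fixes the output exactly.
#' @param cluster_sd spatial spread (mm) of ROIs around their subsystem centre.
#' @return A [roi_set] with subsystems labelled `"S01"`, `"S02"`, ...
#' @export
#' @examples
#' rs <- generate_roi_set(60, 4, seed = 7)
#' table(rs$subsystem)
generate_roi_set <- function(n_roi = 264, n_subsystems = 20, seed = 1,
                             cluster_sd = 12) {
  if (n_subsystems < 1L) stop_netcost("n_subsystems must be >= 1")
  if (n_roi < n_subsystems) {
    stop_netcost("invalid spec: n_roi (", n_roi, ") < n_subsystems (", n_subsystems, ")")
  }
  box <- rbind(x = c(-70, 70), y = c(-85, 85), z = c(-50, 70))
  with_seed(seed, {
    # Maximin-style seeding: sample candidate centres, greedily keep the one
    # farthest from those already chosen, so subsystems do not collapse on
    # top of each other.
    cand <- cbind(
      runif(25 * n_subsystems, box[1, 1], box[1, 2]),
      runif(25 * n_subsystems, box[2, 1], box[2, 2]),
      runif(25 * n_subsystems, box[3, 1], box[3, 2])
    )
    centers <- cand[sample(nrow(cand), 1), , drop = FALSE]
    while (nrow(centers) < n_subsystems) {
      d2 <- apply(cand, 1, function(p) min(colSums((t(centers) - p)^2)))
      centers <- rbind(centers, cand[which.max(d2), ])
    }
    # Balanced allocation: subsystem sizes differ by at most one ROI.
    sizes <- rep(n_roi %/% n_subsystems, n_subsystems)
    extra <- n_roi %% n_subsystems
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    label <- rep(seq_len(n_subsystems), times = sizes)
    coords <- centers[label, , drop = FALSE] +
      matrix(rnorm(3 * n_roi, sd = cluster_sd), ncol = 3)
    for (k in 1:3) coords[, k] <- pmin(pmax(coords[, k], box[k, 1]), box[k, 2])
    while (anyDuplicated(coords)) { # continuous draws; collisions essentially never
      dup <- which(duplicated(coords))
      coords[dup, ] <- coords[dup, ] + matrix(rnorm(3 * length(dup), sd = 0.01), ncol = 3)
    }
    roi_set(coords, subsystem = sprintf("S%02d", label))
  })
}

#' Pairwise Euclidean ROI distances
#'
#' @param rois a [roi_set].
#' @return Symmetric `n x n` matrix of distances in mm.
#' @export
roi_distances <- function(rois) {
  stopifnot(inherits(rois, "roi_set"))
  as.matrix(stats::dist(as.matrix(rois[, c("x", "y", "z")])))
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set:", nrow(x), "ROIs in", length(unique(x$subsystem)), "subsystems\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more ROIs)\n", sep = "")
  invisible(x)
}

#' Read / write an ROI set as TSV
#'
#' Plain-text interchange: columns `roi_id`, `x`, `y`, `z`, `subsystem`.
#' @param rois a [roi_set].
#' @param path file path.
#' @return `read_roi_set` returns a [roi_set]; `write_roi_set` returns
#'   `path` invisibly.
#' @export
write_roi_set <- function(rois, path) {
  utils::write.table(as.data.frame(rois), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  roi_set(df[, c("x", "y", "z")], subsystem = df$subsystem, roi_id = df$roi_id)
}
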