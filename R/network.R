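#' Construct a weighted functional connectivity network
#'
#' A weighted network is a symmetric `n x n` matrix of retained absolute
#' correlation weights (0 = no edge, zero diagonal, weights in `[0, 1]`)
#' together with the two-sided p-values of the retained edges and provenance
#' labels. Objects are usually produced by [correlation_network]; this
#' constructor validates a matrix built by other means.
#'
#' @param weights symmetric numeric matrix, zero diagonal, entries in `[0, 1]`.
#' @param pvals optional matrix of the retained edges' p-values (`NA`
#'   elsewhere); must be positive exactly where `weights > 0`.
#' @param provenance named list (subject, group, time point, scanner, ...).
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, pvals = NULL, provenance = list()) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop_netcost("weights must be square")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12))) {
    stop_netcost("weights must be symmetric")
  }
  if (any(diag(weights) != 0)) stop_netcost("diagonal must be zero")
  if (any(weights < 0 | weights > 1)) stop_netcost("weights must lie in [0, 1]")
  if (!is.null(pvals)) {
    pvals <- as.matrix(pvals)
    if (!all(dim(pvals) == n)) stop_netcost("pvals dimension mismatch")
    if (any(!is.na(pvals) & (weights == 0))) {
      stop_netcost("pvals present where no edge was retained")
    }
  }
  structure(
    list(weights = unname(weights), pvals = pvals, n_roi = n, provenance = provenance),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- sum(x$weights[upper_tri(x$n_roi)] > 0)
  cat(
    "Weighted connectivity network:", x$n_roi, "ROIs,", m, "retained edges",
    sprintf(
      "(density %.3f)\n",
      m / (x$n_roi * (x$n_roi - 1) / 2)
    )
  )
  if (length(x$provenance)) {
    cat(
      "  provenance:",
      paste(names(x$provenance), unlist(x$provenance), sep = "=", collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Benjamini-Hochberg edge retention
#'
#' Applies the Benjamini-Hochberg step-up procedure (via
#' [stats::p.adjust]) at level `alpha` and returns the retain mask.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level in `(0, 1)`.
#' @return Logical vector: `TRUE` for p-values surviving the step-up.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.011, 0.02, 0.8), alpha = 0.05)
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop_netcost("p-values must lie in [0, 1]")
  }
  if (!(alpha > 0 && alpha < 1)) stop_netcost("alpha must be in (0, 1)")
  stats::p.adjust(pvalues, method = "BH") <= alpha
}

#' Build an FDR-thresholded correlation network from a time-series panel
#'
#' Computes the Pearson correlation and its two-sided p-value (t-transform
#' with `n_volumes - 2` degrees of freedom) for every ROI pair, applies
#' Benjamini-Hochberg over exactly those `n(n-1)/2` tests at level `alpha`,
#' and stores the surviving edges as absolute correlation weights. Negative
#' correlations are therefore retained by magnitude, which is why the test is
#' two-sided.
#'
#' @param panel a [ts_panel] (or a plain `n_volumes x n_roi` matrix).
#' @param alpha FDR level (default 0.05).
#' @return A [weighted_network] with retained `|r|` weights and their p-values.
#' @export
correlation_network <- function(panel, alpha = 0.05) {
  if (inherits(panel, "ts_panel")) {
    X <- panel$data
    prov <- panel[c("subject_id", "group", "time_point", "scanner")]
  } else {
    X <- as.matrix(panel)
    prov <- list()
  }
  nv <- nrow(X)
  n <- ncol(X)
  if (nv < 3) stop_netcost("need at least 3 volumes")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    stop_netcost("zero-variance ROI column(s): ", paste(which(v == 0), collapse = ", "))
  }
  R <- stats::cor(X)
  df <- nv - 2
  r2 <- pmin(R^2, 1)
  tval <- abs(R) * sqrt(df / pmax(1 - r2, .Machine$double.eps))
  P <- 2 * stats::pt(tval, df, lower.tail = FALSE)
  P[r2 >= 1] <- 0
  ut <- upper_tri(n)
  keep_ut <- bh_fdr(P[ut], alpha)
  keep <- matrix(FALSE, n, n)
  keep[ut] <- keep_ut
  keep <- keep | t(keep)
  W <- abs(R) * keep
  diag(W) <- 0
  Pk <- ifelse(keep, P, NA_real_)
  diag(Pk) <- NA_real_
  weighted_network(W, pvals = Pk, provenance = prov)
}

#' Binarize a gray-matter probability mask
#'
#' A voxel enters the mask iff its gray-matter probability strictly exceeds
#' `threshold` (default 0.6).
#'
#' @param mask 3-D array of probabilities in `[0, 1]`.
#' @param threshold inclusion threshold in `[0, 1]`.
#' @return Logical array of the same dimension.
#' @export
binarize_mask <- function(mask, threshold = 0.6) {
  if (any(mask < 0 | mask > 1, na.rm = TRUE)) {
    stop_netcost("mask probabilities must lie in [0, 1]")
  }
  if (threshold < 0 || threshold > 1) stop_netcost("threshold must lie in [0, 1]")
  mask > threshold
}

#' Extract mean ROI time series from a 4-D image
#'
#' Averages, per ROI and time point, the signal of the in-mask voxels whose
#' centres fall within `sphere_radius_mm` of the ROI coordinate. Voxels
#' inside two spheres are assigned to the nearest ROI centre (ties to the
#' lower `roi_id`). An ROI with no eligible voxel is flagged and its column
#' filled with `NA`.
#'
#' @param image4d 4-D numeric array (x, y, z, time).
#' @param binary_mask logical 3-D array on the same grid (see [binarize_mask]).
#' @param rois a [roi_set]; coordinates in the image's mm frame.
#' @param sphere_radius_mm sphere radius in mm (default 7.5, i.e. a 15 mm
#'   diameter sphere).
#' @param voxel_size_mm length-3 voxel size; voxel centre of index `(i,j,k)`
#'   is `(i-1, j-1, k-1) * voxel_size_mm` unless `affine` is given.
#' @param affine optional 4x4 matrix mapping 0-based voxel indices to mm.
#' @return A [ts_panel] whose `flagged_rois` attribute lists ROIs with no
#'   eligible voxels.
#' @export
extract_roi_timeseries <- function(image4d, binary_mask, rois,
                                   sphere_radius_mm = 7.5,
                                   voxel_size_mm = c(1, 1, 1),
                                   affine = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  d <- dim(image4d)
  if (length(d) != 4) stop_netcost("image4d must be 4-D (x, y, z, time)")
  if (!all(dim(binary_mask) == d[1:3])) stop_netcost("image and mask grids differ")
  if (sphere_radius_mm <= 0) stop_netcost("sphere_radius_mm must be > 0")
  vox <- which(binary_mask, arr.ind = TRUE)
  centers <- as.matrix(rois[, c("x", "y", "z")])
  nt <- d[4]
  out <- matrix(NA_real_, nt, nrow(rois))
  colnames(out) <- rois$roi_id
  flagged <- integer(0)
  if (nrow(vox) > 0) {
    if (is.null(affine)) {
      mmpos <- sweep(vox - 1, 2, voxel_size_mm, "*")
    } else {
      mmpos <- t(affine %*% rbind(t(vox - 1), 1))[, 1:3, drop = FALSE]
    }
    # squared distance voxel x ROI; nearest-centre assignment resolves overlap
    D2 <- outer(rowSums(mmpos^2), rowSums(centers^2), "+") - 2 * mmpos %*% t(centers)
    nearest <- max.col(-D2, ties.method = "first")
    inside <- D2[cbind(seq_len(nrow(vox)), nearest)] <= sphere_radius_mm^2
    img_mat <- matrix(image4d, ncol = nt) # voxels (linear index) x time
    lin <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
    for (r in seq_len(nrow(rois))) {
      mine <- inside & nearest == r
      if (!any(mine)) next
      block <- img_mat[lin[mine], , drop = FALSE]
      out[, r] <- colMeans(block)
    }
  }
  flagged <- rois$roi_id[colSums(!is.na(out)) == 0]
  panel <- ts_panel_allow_na(out)
  attr(panel, "flagged_rois") <- flagged
  panel
}

# Internal: a ts_panel that tolerates all-NA columns (flagged ROIs).
ts_panel_allow_na <- function(data) {
  structure(
    list(
      data = as.matrix(data), subject_id = "extracted", group = NA_character_,
      time_point = NA_character_, scanner = NA_character_
    ),
    class = "ts_panel"
  )
}

#' Edge table of a weighted network
#'
#' @param net a [weighted_network].
#' @return Data frame with one row per retained edge: `roi_i`, `roi_j`
#'   (`i < j`), `weight`, `p`.
#' @export
edge_table <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  n <- net$n_roi
  idx <- which(upper_tri(n) & net$weights > 0, arr.ind = TRUE)
  data.frame(
    roi_i = idx[, 1], roi_j = idx[, 2],
    weight = net$weights[idx],
    p = if (is.null(net$pvals)) NA_real_ else net$pvals[idx]
  )
}

#' Read / write a network as edge-list TSV
#'
#' Columns `roi_i`, `roi_j`, `weight`, `p`; a `# n_roi=<n>` header line
#' preserves the node count so isolated ROIs survive the round trip.
#'
#' @param net a [weighted_network].
#' @param path file path.
#' @return `read_network` returns a [weighted_network]; `write_network`
#'   returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_roi=%d", net$n_roi), con)
  utils::write.table(edge_table(net), con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  first <- readLines(path, n = 1)
  n <- as.integer(sub("# n_roi=", "", first, fixed = TRUE))
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  W <- matrix(0, n, n)
  P <- matrix(NA_real_, n, n)
  ij <- cbind(df$roi_i, df$roi_j)
  W[ij] <- df$weight
  W[ij[, 2:1, drop = FALSE]] <- df$weight
  P[ij] <- df$p
  P[ij[, 2:1, drop = FALSE]] <- df$p
  weighted_network(W, pvals = P)
}
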