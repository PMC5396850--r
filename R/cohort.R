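#' Specify a synthetic longitudinal cohort
#'
#' Describes a multi-group, multi-timepoint resting-state cohort whose ROI
#' time series are drawn from a multivariate normal with a block-structured
#' correlation matrix: `base_correlation` within each subsystem,
#' `background_correlation` between subsystems, plus optional implanted
#' hyper-/hypoconnectivity increments on designated (group, time point,
#' subsystem) blocks. The defaults emulate a longitudinal brain-injury
#' design: 14 injured subjects scanned at three time points and 12 healthy
#' controls scanned at two, 145 volumes per scan, on three scanners assigned
#' round-robin.
#'
#' @param n_roi,n_subsystems parcellation size (passed to [generate_roi_set]
#'   when no `roi_set` is supplied downstream).
#' @param subjects_per_group named integer vector, subjects per group.
#' @param time_points named list, time-point labels per group.
#' @param n_volumes time-series length per scan (>= 30 so correlation
#'   significance is meaningful).
#' @param base_correlation within-subsystem target correlation in `[0, 1)`.
#' @param background_correlation between-subsystem target, `>= 0` and below
#'   `base_correlation`.
#' @param effect_map `NULL` or a data frame with columns
#'   `group`, `time_point`, `subsystem`, `increment`: each row adds
#'   `increment` to the within-subsystem correlations of that block for that
#'   group and time point (the implanted ground-truth effect).
#' @param noise_sd additive white observation noise (signal units; the latent
#'   signal has unit variance, so 0 leaves sample correlations centred on the
#'   targets).
#' @param n_scanners number of scanner labels assigned round-robin to subjects.
#' @param scanner_sd optional per-scanner additive noise SD (scalar or one
#'   value per scanner); 0 injects no scanner effect.
#' @param seed RNG seed for cohort generation.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_roi = 264, n_subsystems = 20,
                        subjects_per_group = c(TBI = 14, HC = 12),
                        time_points = list(TBI = c("T1", "T2", "T3"), HC = c("T1", "T2")),
                        n_volumes = 145,
                        base_correlation = 0.5,
                        background_correlation = 0.05,
                        effect_map = NULL,
                        noise_sd = 0,
                        n_scanners = 3,
                        scanner_sd = 0,
                        seed = 1) {
  if (is.null(names(subjects_per_group))) stop_netcost("subjects_per_group must be named")
  if (!setequal(names(time_points), names(subjects_per_group))) {
    stop_netcost("time_points must name the same groups as subjects_per_group")
  }
  if (n_volumes < 30) stop_netcost("n_volumes must be >= 30")
  if (background_correlation < 0 || base_correlation <= background_correlation) {
    stop_netcost("need base_correlation > background_correlation >= 0")
  }
  if (base_correlation >= 1) stop_netcost("base_correlation must be < 1")
  if (!is.null(effect_map)) {
    effect_map <- as.data.frame(effect_map)
    need <- c("group", "time_point", "subsystem", "increment")
    if (!all(need %in% names(effect_map))) {
      stop_netcost("effect_map needs columns ", paste(need, collapse = ", "))
    }
    bad <- !effect_map$group %in% names(subjects_per_group)
    if (any(bad)) stop_netcost("effect_map references unknown group: ", effect_map$group[bad][1])
    for (i in seq_len(nrow(effect_map))) {
      if (!effect_map$time_point[i] %in% time_points[[effect_map$group[i]]]) {
        stop_netcost(
          "effect_map references time point '", effect_map$time_point[i],
          "' absent for group '", effect_map$group[i], "'"
        )
      }
    }
  }
  structure(
    list(
      n_roi = as.integer(n_roi), n_subsystems = as.integer(n_subsystems),
      subjects_per_group = subjects_per_group, time_points = time_points,
      n_volumes = as.integer(n_volumes),
      base_correlation = base_correlation,
      background_correlation = background_correlation,
      effect_map = effect_map, noise_sd = noise_sd,
      n_scanners = as.integer(n_scanners), scanner_sd = scanner_sd,
      seed = seed
    ),
    class = "cohort_spec"
  )
}

# Target correlation matrix for one (group, time_point) cell: background
# everywhere, base on within-subsystem blocks, effect_map increments added,
# then repaired to the nearest valid correlation matrix by eigenvalue
# clipping (at 1e-6) and re-normalisation to unit diagonal.
target_correlation <- function(spec, rois, group, time_point) {
  n <- nrow(rois)
  sub <- rois$subsystem
  R <- matrix(spec$background_correlation, n, n)
  same <- outer(sub, sub, "==")
  R[same] <- spec$base_correlation
  em <- spec$effect_map
  if (!is.null(em)) {
    em <- em[em$group == group & em$time_point == time_point, , drop = FALSE]
    for (i in seq_len(nrow(em))) {
      s <- em$subsystem[i]
      if (!s %in% sub) stop_netcost("effect_map references unknown subsystem '", s, "'")
      idx <- sub == s
      R[idx, idx] <- R[idx, idx] + em$increment[i]
      if (any(R[idx, idx][upper_tri(sum(idx))] >= 1)) {
        stop_netcost(
          "target correlation >= 1 in block (", group, ", ", time_point, ", ", s,
          "): base + increment must stay below 1"
        )
      }
    }
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    R <- stats::cov2cor(R)
  }
  R
}

#' Generate a synthetic longitudinal cohort of ROI time series
#'
#' Draws one time-series panel per (subject, time point) from the
#' multivariate normal implied by the [cohort_spec] target correlation
#' matrices, and records those targets as recoverable ground truth. Fixing
#' the spec seed fixes every panel bit-for-bit.
#'
#' @param spec a [cohort_spec].
#' @param rois a [roi_set]; defaults to a generated parcellation of the size
#'   named in `spec` (seeded from the spec seed).
#' @return A list of class `cohort` with elements
#'   \describe{
#'     \item{panels}{list of `ts_panel` objects (`n_volumes x n_roi` matrix
#'       plus subject/group/time/scanner labels),}
#'     \item{ground_truth}{the spec, the ROI set, and the exact target
#'       correlation matrix per `"group:time"` cell,}
#'     \item{manifest}{data frame of subject, group, time point, scanner.}
#'   }
#' @export
#' @examples
#' sp <- cohort_spec(n_roi = 20, n_subsystems = 4, n_volumes = 60,
#'                   subjects_per_group = c(TBI = 2, HC = 2),
#'                   time_points = list(TBI = "T1", HC = "T1"), seed = 3)
#' co <- generate_cohort(sp)
#' length(co$panels)
generate_cohort <- function(spec, rois = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(rois)) {
    rois <- generate_roi_set(spec$n_roi, spec$n_subsystems, seed = child_seed(spec$seed, 1))
  }
  if (nrow(rois) != spec$n_roi) stop_netcost("rois size disagrees with spec$n_roi")
  groups <- names(spec$subjects_per_group)
  scanner_sd <- rep_len(spec$scanner_sd, spec$n_scanners)
  cells <- list() # chol factor cache per (group, time)
  targets <- list()
  for (g in groups) {
    for (tp in spec$time_points[[g]]) {
      R <- target_correlation(spec, rois, g, tp)
      key <- paste0(g, ":", tp)
      targets[[key]] <- R
      cells[[key]] <- chol(R)
    }
  }
  panels <- list()
  manifest <- NULL
  with_seed(child_seed(spec$seed, 2), {
    sid <- 0L
    for (g in groups) {
      for (s in seq_len(spec$subjects_per_group[[g]])) {
        sid <- sid + 1L
        subject <- sprintf("%s%02d", g, s)
        scanner <- sprintf("scanner%d", (s - 1L) %% spec$n_scanners + 1L)
        for (tp in spec$time_points[[g]]) {
          U <- cells[[paste0(g, ":", tp)]]
          X <- matrix(stats::rnorm(spec$n_volumes * spec$n_roi), spec$n_volumes) %*% U
          if (spec$noise_sd > 0) {
            X <- X + matrix(stats::rnorm(length(X), sd = spec$noise_sd), nrow(X))
          }
          sc_sd <- scanner_sd[(s - 1L) %% spec$n_scanners + 1L]
          if (sc_sd > 0) {
            X <- X + matrix(stats::rnorm(length(X), sd = sc_sd), nrow(X))
          }
          colnames(X) <- rois$roi_id
          panels[[length(panels) + 1L]] <- ts_panel(X,
            subject_id = subject, group = g, time_point = tp, scanner = scanner
          )
          manifest <- rbind(manifest, data.frame(
            subject_id = subject, group = g, time_point = tp,
            scanner = scanner, stringsAsFactors = FALSE
          ))
        }
      }
    }
  })
  structure(
    list(
      panels = panels,
      ground_truth = list(spec = spec, rois = rois, targets = targets),
      manifest = manifest
    ),
    class = "cohort"
  )
}

#' Construct a time-series panel
#'
#' @param data numeric matrix, `n_volumes x n_roi`; no missing values and
#'   every column must vary.
#' @param subject_id,group,time_point,scanner provenance labels.
#' @return An object of class `ts_panel`.
#' @export
ts_panel <- function(data, subject_id = "S01", group = NA_character_,
                     time_point = NA_character_, scanner = NA_character_) {
  data <- as.matrix(data)
  if (anyNA(data)) stop_netcost("panel contains missing values")
  structure(
    list(
      data = data, subject_id = subject_id, group = group,
      time_point = time_point, scanner = scanner
    ),
    class = "ts_panel"
  )
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(
    "Time-series panel:", x$subject_id,
    sprintf("(group %s, time %s, %s):", x$group, x$time_point, x$scanner),
    nrow(x$data), "volumes x", ncol(x$data), "ROIs\n"
  )
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(
    "Synthetic cohort:", length(x$panels), "panels,",
    nrow(x$ground_truth$rois), "ROIs,",
    x$ground_truth$spec$n_volumes, "volumes each\n"
  )
  print(table(group = x$manifest$group, time = x$manifest$time_point))
  invisible(x)
}

#' Generate behavioural scores correlated with subsystem cost
#'
#' Produces one score per panel as a linear function of that panel's
#' connection cost (the sum over ROI pairs incident on `subsystem` -- or all
#' pairs when `subsystem` is `NULL` -- of Euclidean distance times absolute
#' sample correlation) plus Gaussian noise calibrated so the population
#' correlation between cost and score equals `target_r`:
#' `score = target_r * z(cost) + sqrt(1 - target_r^2) * e`.
#'
#' @param cohort a [generate_cohort] result.
#' @param target_r population correlation in `(-1, 1)`.
#' @param seed RNG seed for the noise component.
#' @param subsystem optional subsystem label restricting the cost basis.
#' @param costs optional numeric vector (one per panel) overriding the
#'   computed cost basis.
#' @return Data frame: `subject_id`, `group`, `time_point`, `cost`, `score`.
#' @export
generate_behavior <- function(cohort, target_r, seed = 1, subsystem = NULL,
                              costs = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (!(target_r > -1 && target_r < 1)) stop_netcost("target_r must be in (-1, 1)")
  rois <- cohort$ground_truth$rois
  D <- roi_distances(rois)
  if (!is.null(subsystem)) {
    if (!subsystem %in% rois$subsystem) stop_netcost("unknown subsystem '", subsystem, "'")
    member <- rois$subsystem == subsystem
    incident <- outer(member, member, "|")
  } else {
    incident <- matrix(TRUE, nrow(rois), nrow(rois))
  }
  sel <- upper_tri(nrow(rois)) & incident
  if (is.null(costs)) {
    costs <- vapply(cohort$panels, function(p) {
      sum((abs(stats::cor(p$data)) * D)[sel])
    }, numeric(1))
  }
  if (length(costs) != length(cohort$panels)) {
    stop_netcost("costs must supply one value per panel")
  }
  z <- if (stats::sd(costs) > 0) as.numeric(scale(costs)) else {
    warning("cost basis has zero variance; scores are pure noise")
    rep(0, length(costs))
  }
  score <- with_seed(seed, {
    target_r * z + sqrt(1 - target_r^2) * stats::rnorm(length(z))
  })
  data.frame(
    subject_id = vapply(cohort$panels, `[[`, "", "subject_id"),
    group = vapply(cohort$panels, `[[`, "", "group"),
    time_point = vapply(cohort$panels, `[[`, "", "time_point"),
    cost = costs, score = score, stringsAsFactors = FALSE
  )
}

#' Write a cohort to plain-text files
#'
#' One TSV per panel (columns = ROI ids, rows = volumes), the ROI set as TSV,
#' ground-truth target correlations as JSON, and a manifest TSV listing
#' subject, group, time point and scanner.
#'
#' @param cohort a [generate_cohort] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_roi_set(cohort$ground_truth$rois, file.path(dir, "rois.tsv"))
  manifest <- cohort$manifest
  manifest$file <- sprintf("panel_%s_%s.tsv", manifest$subject_id, manifest$time_point)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  for (i in seq_along(cohort$panels)) {
    p <- cohort$panels[[i]]
    utils::write.table(as.data.frame(p$data),
      file.path(dir, sprintf("panel_%s_%s.tsv", p$subject_id, p$time_point)),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  jsonlite::write_json(
    lapply(cohort$ground_truth$targets, function(m) round(unname(m), 6)),
    file.path(dir, "ground_truth.json")
  )
  invisible(dir)
}

#' Read cohort panels written by [write_cohort]
#'
#' @param dir directory containing `manifest.tsv`, `rois.tsv` and panel TSVs.
#' @return A list with `panels` (list of [ts_panel]) and `rois` ([roi_set]).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
  rois <- read_roi_set(file.path(dir, "rois.tsv"))
  panels <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    ts_panel(as.matrix(utils::read.delim(file.path(dir, m$file))),
      subject_id = m$subject_id, group = m$group,
      time_point = m$time_point, scanner = m$scanner
    )
  })
  list(panels = panels, rois = rois, manifest = manifest)
}

#' Construct a matched network pair with extra medium-cost connections
#'
#' Builds two weighted networks over the same ROI set that differ only in a
#' set of extra connections incident on one subsystem, drawn at
#' medium connection length (default 40--100 mm) and medium strength
#' (default 0.2--0.5). The denser network is the analogue of an early
#' post-injury time point whose elevated cost is carried by medium-length,
#' medium-strength connections; subtracting the sparser network's
#' length-by-strength histogram isolates exactly that signature.
#'
#' @param rois a [roi_set].
#' @param subsystem subsystem receiving the extra connections.
#' @param n_base number of shared background edges.
#' @param n_extra number of extra incident edges in the denser network.
#' @param length_range,strength_range ranges (mm, unitless) for the extras.
#' @param seed RNG seed; the construction is deterministic given the seed.
#' @return list with elements `dense` and `sparse`, both [weighted_network].
#' @export
generate_cost_contrast_pair <- function(rois, subsystem,
                                        n_base = 400, n_extra = 250,
                                        length_range = c(40, 100),
                                        strength_range = c(0.2, 0.5),
                                        seed = 1) {
  stopifnot(inherits(rois, "roi_set"))
  if (!subsystem %in% rois$subsystem) stop_netcost("unknown subsystem '", subsystem, "'")
  n <- nrow(rois)
  D <- roi_distances(rois)
  ut <- which(upper_tri(n))
  member <- rois$subsystem == subsystem
  incident <- outer(member, member, "|")
  with_seed(seed, {
    base_idx <- sample(ut, min(n_base, length(ut)))
    cand <- setdiff(
      ut[incident[ut] & D[ut] >= length_range[1] & D[ut] <= length_range[2]],
      base_idx
    )
    if (length(cand) < n_extra) n_extra <- length(cand)
    extra_idx <- sample(cand, n_extra)
    W <- matrix(0, n, n)
    W[base_idx] <- stats::runif(length(base_idx), 0.15, 0.95)
    W_sparse <- W
    W_dense <- W
    W_dense[extra_idx] <- stats::runif(n_extra, strength_range[1], strength_range[2])
    sym <- function(M) {
      M[lower.tri(M)] <- t(M)[lower.tri(M)]
      M
    }
    list(
      dense = weighted_network(sym(W_dense), provenance = list(time_point = "T2")),
      sparse = weighted_network(sym(W_sparse), provenance = list(time_point = "T3"))
    )
  })
}
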