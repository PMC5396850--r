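#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with the
#' study-style defaults: FDR level 0.05 for edge retention, 50 repetitions
#' over deletion percentages 1..99 for the attack simulation, 50000-wide
#' cost bands, Cohen's d gate 0.70 and partial eta squared gate 0.06 for the
#' subsystem screen and its follow-up, and 10 mm x 0.05 histogram bins.
#'
#' @param cohort a [cohort_spec] describing the synthetic cohort to analyse
#'   (or `NULL` with `cohort_dir` pointing at panels written by
#'   [write_cohort]).
#' @param cohort_dir optional directory of a written cohort; overrides
#'   `cohort`.
#' @param alpha FDR level for edge retention and the screen.
#' @param reps,pct attack-simulation repetitions and deletion percentages.
#' @param band_width cost-band width for [band_compare].
#' @param d_gate,eta_sq_gate effect-size gates for screen and follow-up.
#' @param length_bins,strength_bins histogram bin edges.
#' @param patient_group,control_group group labels in the cohort.
#' @param screen_time patient time point screened against controls.
#' @param behavior_target_r population cost-behaviour correlation for the
#'   generated behavioural scores (`NULL` skips the behaviour stage).
#' @param sim_cells `"patient"` (default: simulate each patient time point)
#'   or `"all"` (also each control time point).
#' @param seed root seed; each stage derives its own child stream, so
#'   changing one stage's workload does not perturb another's draws.
#' @param out_dir optional output directory for TSV results and the run
#'   manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            cohort_dir = NULL,
                            alpha = 0.05,
                            reps = 50, pct = 1:99,
                            band_width = 50000,
                            d_gate = 0.70, eta_sq_gate = 0.06,
                            length_bins = seq(0, 180, by = 10),
                            strength_bins = (0:20) / 20,
                            patient_group = "TBI", control_group = "HC",
                            screen_time = "T2",
                            behavior_target_r = NULL,
                            sim_cells = c("patient", "all"),
                            seed = 1,
                            out_dir = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop_netcost("alpha must be in (0, 1)")
  if (d_gate < 0 || eta_sq_gate < 0) stop_netcost("effect-size gates must be >= 0")
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir)) {
    stop_netcost("cohort_dir does not exist: ", cohort_dir)
  }
  structure(
    list(
      cohort = cohort, cohort_dir = cohort_dir, alpha = alpha,
      reps = reps, pct = pct, band_width = band_width,
      d_gate = d_gate, eta_sq_gate = eta_sq_gate,
      length_bins = length_bins, strength_bins = strength_bins,
      patient_group = patient_group, control_group = control_group,
      screen_time = screen_time, behavior_target_r = behavior_target_r,
      sim_cells = match.arg(sim_cells), seed = seed, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys matching the [pipeline_config] arguments; nested `cohort:` keys
#' are passed to [cohort_spec].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_netcost("the 'yaml' package is required to read YAML configs")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort)) raw$cohort <- do.call(cohort_spec, raw$cohort)
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_netcost("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort synthesis (or loading), per-panel FDR network
#' construction, connectivity profiling, global ANCOVA contrasts (patient
#' time points vs the per-subject control mean, scanner as covariate),
#' the cost-efficiency attack simulation per simulated cell with cost-band
#' comparison between the screened and the final patient time point, the
#' subsystem hyper-/hypoconnectivity screen with eta-squared follow-up at
#' the other patient time points, length x strength histograms (screened vs
#' final time point, plus their difference) for each flagged subsystem, and
#' cost-behaviour correlations. Counts are logged per stage; any stage
#' failure aborts with the stage named.
#'
#' @param config a [pipeline_config].
#' @param quiet suppress stage logging.
#' @return List of class `netcost_run` bundling every stage's results.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[netcost] ", sprintf(...))
  seed <- config$seed

  # --- synth / load -----------------------------------------------------
  cohort <- stage("synth", {
    if (!is.null(config$cohort_dir)) {
      loaded <- read_cohort(config$cohort_dir)
      structure(
        list(
          panels = loaded$panels,
          ground_truth = list(spec = config$cohort, rois = loaded$rois),
          manifest = loaded$manifest
        ),
        class = "cohort"
      )
    } else {
      sp <- config$cohort
      sp$seed <- child_seed(seed, 11)
      generate_cohort(sp)
    }
  })
  rois <- cohort$ground_truth$rois
  say("cohort: %d panels, %d ROIs", length(cohort$panels), nrow(rois))

  # --- build ------------------------------------------------------------
  nets <- stage("build", lapply(cohort$panels, correlation_network, alpha = config$alpha))
  n_edges <- vapply(nets, function(n) sum(n$weights[upper_tri(n$n_roi)] > 0), numeric(1))
  if (any(n_edges == 0)) warning("empty network(s) after FDR for panel(s) ",
    paste(which(n_edges == 0), collapse = ", "))
  say("networks: mean %.0f retained edges (range %d-%d)",
    mean(n_edges), min(n_edges), max(n_edges))

  # --- profile ----------------------------------------------------------
  profiles <- stage("profile", profile_table(nets, rois))
  pg <- config$patient_group
  cg <- config$control_group
  meta <- profiles$scalars

  # --- global contrasts -------------------------------------------------
  global <- stage("global", {
    hc <- meta[meta$group == cg, ]
    hc_mean <- stats::aggregate(
      hc[, c("network_strength", "total_links", "network_cost",
             "avg_clustering_unweighted", "avg_shortest_path_unweighted")],
      by = list(subject_id = hc$subject_id, scanner = hc$scanner), FUN = mean
    )
    metrics <- c("network_strength", "total_links", "network_cost",
                 "avg_clustering_unweighted", "avg_shortest_path_unweighted")
    rows <- list()
    for (tp in unique(meta$time_point[meta$group == pg])) {
      tbi <- meta[meta$group == pg & meta$time_point == tp, ]
      for (mm in metrics) {
        a <- ancova_contrast(
          c(tbi[[mm]], hc_mean[[mm]]),
          rep(c(pg, cg), c(nrow(tbi), nrow(hc_mean))),
          c(tbi$scanner, hc_mean$scanner)
        )
        rows[[length(rows) + 1L]] <- data.frame(
          time_point = tp, metric = mm, F = a$F, p = a$p,
          partial_eta_sq = a$partial_eta_sq, stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
  say("global contrasts: %d tests", nrow(global))

  # --- cost-efficiency simulation --------------------------------------
  sim <- stage("simulate", {
    cells <- unique(meta[meta$group == pg, c("group", "time_point")])
    if (config$sim_cells == "all") {
      cells <- unique(meta[, c("group", "time_point")])
    }
    out <- list()
    for (i in seq_len(nrow(cells))) {
      sel <- meta$group == cells$group[i] & meta$time_point == cells$time_point[i]
      avg <- group_average_network(nets[sel])
      key <- paste0(cells$group[i], ":", cells$time_point[i])
      out[[key]] <- run_attack_simulation(avg, rois,
        reps = config$reps, pct = config$pct,
        seed = child_seed(seed, 13 + i)
      )
    }
    out
  })
  say("simulation: %d cells x %d records", length(sim), nrow(sim[[1]]))
  patient_times <- config$cohort$time_points[[pg]] %||%
    unique(meta$time_point[meta$group == pg])
  final_time <- utils::tail(patient_times, 1)
  bands <- stage("bands", {
    a <- sim[[paste0(pg, ":", config$screen_time)]]
    b <- sim[[paste0(pg, ":", final_time)]]
    if (!is.null(a) && !is.null(b) && config$screen_time != final_time) {
      band_compare(a, b, band_width = config$band_width)
    } else {
      NULL
    }
  })

  # --- subsystem screen -------------------------------------------------
  screen <- stage("screen", {
    submap <- rois$subsystem
    subsystems <- sort(unique(submap))
    per_roi_mat <- function(sel, fun) {
      t(vapply(which(sel), function(i) fun(nets[[i]]), numeric(nrow(rois))))
    }
    hc_mat_over_time <- function(fun) {
      # per-subject mean over control time points: the "mean control" profile
      hc_ids <- unique(meta$subject_id[meta$group == cg])
      t(vapply(hc_ids, function(id) {
        sel <- meta$group == cg & meta$subject_id == id
        colMeans(per_roi_mat(sel, fun))
      }, numeric(nrow(rois))))
    }
    pool <- function(mat) {
      vals <- lapply(subsystems, function(s) subsystem_distribution(mat, submap, s))
      names(vals) <- subsystems
      vals
    }
    tbi_sel <- meta$group == pg & meta$time_point == config$screen_time
    res <- list()
    for (mm in c("strength", "cost")) {
      fun <- if (mm == "strength") {
        function(net) unname(roi_strength(net))
      } else {
        function(net) unname(roi_cost(net, rois))
      }
      tbi_mat <- per_roi_mat(tbi_sel, fun)
      hc_mat <- hc_mat_over_time(fun)
      scr <- screen_subsystems(pool(tbi_mat), pool(hc_mat),
        alpha = config$alpha, d_gate = config$d_gate, metric = mm
      )
      flagged <- scr$subsystem[scr$direction != "none"]
      followups <- list()
      if (length(flagged)) {
        hc_scanner <- vapply(unique(meta$subject_id[meta$group == cg]), function(id) {
          meta$scanner[meta$group == cg & meta$subject_id == id][1]
        }, "")
        for (tp in setdiff(patient_times, config$screen_time)) {
          sel <- meta$group == pg & meta$time_point == tp
          tbi_mat_tp <- per_roi_mat(sel, fun)
          tv <- pool(tbi_mat_tp)[flagged]
          hv <- pool(hc_mat)[flagged]
          # pooled values are column-major (all subjects for ROI 1, then ROI
          # 2, ...), so recycling the per-subject scanner vector aligns it
          fu <- subsystem_followup(tv, hv,
            tbi_covariate = meta$scanner[sel],
            hc_covariate = hc_scanner,
            eta_sq_gate = config$eta_sq_gate
          )
          fu$time_point <- tp
          followups[[tp]] <- fu
        }
      }
      res[[mm]] <- list(screen = scr, followup = do.call(rbind, followups))
    }
    res
  })
  flagged <- unique(c(
    screen$strength$screen$subsystem[screen$strength$screen$direction != "none"],
    screen$cost$screen$subsystem[screen$cost$screen$direction != "none"]
  ))
  say("screen: %d subsystem(s) flagged (%s)", length(flagged),
    if (length(flagged)) paste(flagged, collapse = ", ") else "none")

  # --- histograms -------------------------------------------------------
  hist_subsystems <- if (length(flagged)) flagged else sort(unique(rois$subsystem))[1]
  hists <- stage("hist", {
    out <- list()
    for (s in hist_subsystems) {
      nets_a <- nets[meta$group == pg & meta$time_point == config$screen_time]
      nets_b <- nets[meta$group == pg & meta$time_point == final_time]
      ha <- histogram2d(incident_edge_table(nets_a, rois, s),
        config$length_bins, config$strength_bins,
        provenance = list(subsystem = s, time_point = config$screen_time)
      )
      hb <- histogram2d(incident_edge_table(nets_b, rois, s),
        config$length_bins, config$strength_bins,
        provenance = list(subsystem = s, time_point = final_time)
      )
      out[[s]] <- list(a = ha, b = hb, difference = difference_histogram(ha, hb))
    }
    out
  })

  # --- behaviour --------------------------------------------------------
  behavior <- NULL
  if (!is.null(config$behavior_target_r)) {
    behavior <- stage("behavior", {
      s <- hist_subsystems[1]
      beh <- generate_behavior(cohort, config$behavior_target_r,
        seed = child_seed(seed, 17), subsystem = s
      )
      member <- rois$subsystem == s
      sub_cost <- vapply(seq_along(nets), function(i) {
        sum(roi_cost(nets[[i]], rois)[member])
      }, numeric(1))
      rows <- list()
      for (tp in patient_times) {
        sel <- meta$group == pg & meta$time_point == tp
        if (sum(sel) >= 3 && stats::sd(sub_cost[sel]) > 0) {
          bc <- behavior_correlation(sub_cost[sel], beh$score[sel])
          rows[[length(rows) + 1L]] <- data.frame(
            subsystem = s, time_point = tp, r = bc$r, p = bc$p, n = bc$n
          )
        }
      }
      list(scores = beh, correlations = do.call(rbind, rows))
    })
  }

  bundle <- structure(
    list(
      config = config, cohort = cohort, networks = nets, profiles = profiles,
      global = global, simulation = sim, bands = bands, screen = screen,
      flagged_subsystems = flagged, histograms = hists, behavior = behavior
    ),
    class = "netcost_run"
  )
  if (!is.null(config$out_dir)) write_run(bundle, config$out_dir)
  bundle
}

#' @export
print.netcost_run <- function(x, ...) {
  cat("netcost pipeline run\n")
  cat("  panels:", length(x$cohort$panels), " networks:", length(x$networks), "\n")
  cat("  simulated cells:", paste(names(x$simulation), collapse = ", "), "\n")
  cat(
    "  flagged subsystems:",
    if (length(x$flagged_subsystems)) paste(x$flagged_subsystems, collapse = ", ") else "none",
    "\n"
  )
  invisible(x)
}

# Write all tabular results plus a machine-readable run manifest.
write_run <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  wt(bundle$profiles$scalars, "profiles.tsv")
  wt(bundle$profiles$per_roi, "roi_metrics.tsv")
  wt(bundle$global, "global_contrasts.tsv")
  for (key in names(bundle$simulation)) {
    wt(bundle$simulation[[key]], sprintf("simulation_%s.tsv", gsub(":", "_", key)))
  }
  if (!is.null(bundle$bands)) wt(bundle$bands, "cost_bands.tsv")
  for (mm in names(bundle$screen)) {
    wt(as.data.frame(bundle$screen[[mm]]$screen), sprintf("screen_%s.tsv", mm))
    if (!is.null(bundle$screen[[mm]]$followup)) {
      wt(bundle$screen[[mm]]$followup, sprintf("followup_%s.tsv", mm))
    }
  }
  for (s in names(bundle$histograms)) {
    write_histogram2d(
      bundle$histograms[[s]]$difference,
      file.path(dir, sprintf("difference_histogram_%s.tsv", s))
    )
  }
  if (!is.null(bundle$behavior)) {
    wt(bundle$behavior$scores, "behavior_scores.tsv")
    wt(bundle$behavior$correlations, "behavior_correlations.tsv")
  }
  cfg <- bundle$config
  manifest <- list(
    package = "netcost",
    version = as.character(utils::packageVersion("netcost")),
    seed = cfg$seed,
    config_hash = fnv1a(paste(deparse(cfg[setdiff(names(cfg), "cohort")]), collapse = "")),
    alpha = cfg$alpha, reps = cfg$reps, d_gate = cfg$d_gate,
    band_width = cfg$band_width,
    n_panels = length(bundle$cohort$panels),
    flagged_subsystems = bundle$flagged_subsystems
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
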