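#' Cohen's d (pooled standard deviation)
#'
#' Standardised mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled SD `sqrt(((nx-1) sx^2 + (ny-1) sy^2) / (nx + ny - 2))`.
#'
#' @param x,y numeric samples.
#' @return Cohen's d; `0` when both samples are degenerate with equal means.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) stop_netcost("need >= 2 values per group")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  diff <- mean(x) - mean(y)
  if (sp == 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / sp
}

#' Pooled per-subsystem distribution of a per-ROI metric
#'
#' Pools a per-ROI metric (ROI-strength or ROI-cost) across all subjects of
#' a group and all ROIs of one subsystem, yielding the distribution the
#' hyperconnectivity screen compares between groups. A subsystem of 13 ROIs
#' over 14 subjects yields 182 pooled values.
#'
#' @param per_roi_values numeric matrix, subjects x ROIs (one row per
#'   subject, columns in ROI order), or a single-subject numeric vector.
#' @param subsystem_map character vector of subsystem labels, one per ROI.
#' @param subsystem subsystem to pool.
#' @return Numeric vector of pooled values.
#' @export
subsystem_distribution <- function(per_roi_values, subsystem_map, subsystem) {
  if (is.vector(per_roi_values)) per_roi_values <- matrix(per_roi_values, nrow = 1)
  if (ncol(per_roi_values) != length(subsystem_map)) {
    stop_netcost("subsystem_map must label every ROI column")
  }
  if (!subsystem %in% subsystem_map) stop_netcost("unknown subsystem '", subsystem, "'")
  as.numeric(per_roi_values[, subsystem_map == subsystem, drop = FALSE])
}

#' Screen subsystems for hyper-/hypoconnectivity
#'
#' For each subsystem, compares the pooled patient and control distributions
#' of a per-ROI metric with an independent two-sample t-test (pooled
#' variance), adjusts p across the subsystem family by Benjamini-Hochberg,
#' and computes Cohen's d (pooled SD). The operative inclusion gate is the
#' effect size: a subsystem is labelled `hyper` (patient mean above control)
#' or `hypo` (below) only when `|d| > d_gate`; FDR-adjusted p-values are
#' reported alongside, and `require_fdr = TRUE` additionally demands
#' `p_fdr <= alpha` before labelling. Subsystems with degenerate variance
#' are reported with `p = NA` and excluded from the FDR family.
#'
#' @param tbi_values named list of numeric vectors, pooled patient values
#'   per subsystem (see [subsystem_distribution]).
#' @param hc_values named list with the same names, control values.
#' @param alpha FDR level for the reported adjusted p-values.
#' @param d_gate Cohen's d magnitude required to label a direction
#'   (default 0.70, sensitivity to medium effects).
#' @param metric label recorded in the output (e.g. `"strength"`, `"cost"`).
#' @param require_fdr also require FDR significance for a label.
#' @return Data frame of class `subsystem_screen`: `subsystem`, `metric`,
#'   `n_tbi`, `n_hc`, `t`, `p`, `p_fdr`, `cohens_d`, `direction`.
#' @export
screen_subsystems <- function(tbi_values, hc_values, alpha = 0.05,
                              d_gate = 0.70, metric = "strength",
                              require_fdr = FALSE) {
  subsystems <- names(tbi_values)
  if (is.null(subsystems) || !setequal(subsystems, names(hc_values))) {
    stop_netcost("tbi_values and hc_values must be named lists over the same subsystems")
  }
  rows <- lapply(subsystems, function(s) {
    x <- tbi_values[[s]]
    y <- hc_values[[s]]
    if (length(x) < 2 || length(y) < 2) stop_netcost("need >= 2 values per group in ", s)
    if (stats::sd(c(x, y)) == 0) {
      return(data.frame(
        subsystem = s, metric = metric, n_tbi = length(x), n_hc = length(y),
        t = NA_real_, p = NA_real_, cohens_d = cohens_d(x, y),
        stringsAsFactors = FALSE
      ))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(
      subsystem = s, metric = metric, n_tbi = length(x), n_hc = length(y),
      t = unname(tt$statistic), p = tt$p.value, cohens_d = cohens_d(x, y),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p)
  if (any(!ok)) {
    message(
      "degenerate variance in subsystem(s) ",
      paste(out$subsystem[!ok], collapse = ", "), "; excluded from FDR family"
    )
  }
  out$p_fdr[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  gate <- abs(out$cohens_d) > d_gate & is.finite(out$cohens_d)
  if (require_fdr) gate <- gate & !is.na(out$p_fdr) & out$p_fdr <= alpha
  out$direction <- ifelse(!gate, "none", ifelse(out$cohens_d > 0, "hyper", "hypo"))
  attr(out, "alpha") <- alpha
  attr(out, "d_gate") <- d_gate
  class(out) <- c("subsystem_screen", "data.frame")
  out
}

#' @export
print.subsystem_screen <- function(x, ...) {
  cat(
    "Subsystem screen (", x$metric[1], "): ", nrow(x), " subsystems, d-gate ",
    attr(x, "d_gate"), "\n",
    sep = ""
  )
  flagged <- x[x$direction != "none", , drop = FALSE]
  if (nrow(flagged) == 0) {
    cat("  no subsystem passes the effect-size gate\n")
  } else {
    print.data.frame(flagged[, c("subsystem", "p_fdr", "cohens_d", "direction")],
      row.names = FALSE, digits = 3
    )
  }
  invisible(x)
}

#' One-way ANCOVA with a categorical covariate
#'
#' Fits `values ~ covariate + group` by least squares and reports the group
#' effect adjusted for the covariate: its F statistic, p-value and partial
#' eta squared `SS_group / (SS_group + SS_error)`. A covariate with a single
#' level reduces exactly to one-way ANOVA. A design in which group is
#' confounded with (aliased by) the covariate is an error.
#'
#' @param values numeric response.
#' @param group_labels factor-like group membership (>= 2 groups).
#' @param covariate_labels factor-like categorical covariate (e.g. scanner).
#' @return List with `F`, `df`, `df_error`, `p`, `partial_eta_sq`.
#' @export
ancova_contrast <- function(values, group_labels, covariate_labels) {
  group <- factor(group_labels)
  covariate <- factor(covariate_labels)
  if (nlevels(group) < 2) stop_netcost("need >= 2 groups")
  if (length(values) != length(group) || length(values) != length(covariate)) {
    stop_netcost("values, group_labels and covariate_labels lengths disagree")
  }
  if (nlevels(covariate) < 2) {
    fit <- stats::lm(values ~ group)
  } else {
    fit <- stats::lm(values ~ covariate + group)
    cf <- stats::coef(fit)
    if (anyNA(cf[grep("^group", names(cf))])) {
      stop_netcost("confounded design: group is aliased with the covariate")
    }
  }
  tab <- stats::anova(fit)
  grow <- which(rownames(tab) == "group")
  erow <- which(rownames(tab) == "Residuals")
  ss_g <- tab$`Sum Sq`[grow]
  ss_e <- tab$`Sum Sq`[erow]
  list(
    F = tab$`F value`[grow],
    df = tab$Df[grow],
    df_error = tab$Df[erow],
    p = tab$`Pr(>F)`[grow],
    partial_eta_sq = ss_g / (ss_g + ss_e)
  )
}

#' Follow-up ANCOVA for screened subsystems
#'
#' Re-tests subsystems that survived the initial screen at another time
#' point against controls, adjusting for scanner, and reports those whose
#' partial eta squared meets `eta_sq_gate` (small-to-medium effects,
#' default 0.06).
#'
#' @param tbi_values,hc_values named lists of pooled per-subsystem values
#'   (as in [screen_subsystems]), restricted to the surviving subsystems.
#' @param tbi_covariate,hc_covariate covariate label per pooled value
#'   (vectors aligned with each subsystem's values, or a single vector
#'   recycled across subsystems).
#' @param eta_sq_gate minimum partial eta squared to report as elevated.
#' @return Data frame: `subsystem`, `F`, `p`, `partial_eta_sq`, `elevated`.
#' @export
subsystem_followup <- function(tbi_values, hc_values, tbi_covariate, hc_covariate,
                               eta_sq_gate = 0.06) {
  subsystems <- names(tbi_values)
  rows <- lapply(subsystems, function(s) {
    x <- tbi_values[[s]]
    y <- hc_values[[s]]
    cx <- rep_len(unlist(tbi_covariate), length(x))
    cy <- rep_len(unlist(hc_covariate), length(y))
    a <- ancova_contrast(
      c(x, y), rep(c("TBI", "HC"), c(length(x), length(y))), c(cx, cy)
    )
    data.frame(
      subsystem = s, F = a$F, p = a$p, partial_eta_sq = a$partial_eta_sq,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$elevated <- out$partial_eta_sq >= eta_sq_gate
  out
}

#' Correlate subsystem cost with behaviour
#'
#' Bivariate Pearson correlation between per-subject subsystem cost and a
#' behavioural score, with its two-sided p-value.
#'
#' @param subsystem_cost numeric vector, one cost per subject.
#' @param score numeric vector, paired behavioural scores.
#' @return List with `r`, `p`, `n`.
#' @export
behavior_correlation <- function(subsystem_cost, score) {
  if (length(subsystem_cost) != length(score)) stop_netcost("unpaired inputs")
  if (length(score) < 3) stop_netcost("need >= 3 subjects")
  if (stats::sd(subsystem_cost) == 0 || stats::sd(score) == 0) {
    stop_netcost("zero variance input")
  }
  ct <- stats::cor.test(subsystem_cost, score, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(score))
}
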