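test_that("subsystem pooling flattens subjects x ROIs", {
  submap <- rep(c("A", "B"), c(13, 7))
  vals <- matrix(seq_len(14 * 20), 14, 20) # 14 subjects x 20 ROIs
  pooled <- subsystem_distribution(vals, submap, "A")
  expect_length(pooled, 14 * 13)
  expect_length(subsystem_distribution(matrix(1, 1, 20), submap, "B"), 7)
  # balanced design: pooled mean equals mean of per-subject means
  expect_equal(mean(pooled), mean(rowMeans(vals[, submap == "A"])))
  expect_error(subsystem_distribution(vals, submap, "Z"), "unknown subsystem")
})

test_that("cohens_d matches its definition", {
  x <- c(0.5, 1, 1.5) # mean 1, sd 0.5
  y <- c(-0.5, 0, 0.5) # mean 0, sd 0.5
  expect_equal(cohens_d(x, y), 2)
  set.seed(2)
  a <- rnorm(500, 1, 1)
  b <- rnorm(500, 0, 1)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.15)
  expect_equal(cohens_d(a, a), 0)
})

test_that("the screen labels direction only past the effect-size gate", {
  set.seed(5)
  tbi <- list(A = rnorm(100, 1.0), B = rnorm(100), C = rnorm(100, -1.0))
  hc <- list(A = rnorm(100), B = rnorm(100), C = rnorm(100))
  scr <- screen_subsystems(tbi, hc, d_gate = 0.70)
  expect_s3_class(scr, "subsystem_screen")
  expect_equal(scr$direction[scr$subsystem == "A"], "hyper")
  expect_equal(scr$direction[scr$subsystem == "C"], "hypo")
  expect_equal(scr$direction[scr$subsystem == "B"], "none")
  expect_true(all(scr$p_fdr >= scr$p, na.rm = TRUE))

  # identical distributions: d = 0, no label
  same <- list(A = c(1, 2, 3, 4))
  scr0 <- screen_subsystems(same, same)
  expect_equal(scr0$cohens_d, 0)
  expect_equal(scr0$direction, "none")

  # invariant to subsystem ordering
  scr_rev <- screen_subsystems(rev(tbi), rev(hc), d_gate = 0.70)
  expect_equal(
    scr_rev[order(scr_rev$subsystem), ]$cohens_d,
    scr[order(scr$subsystem), ]$cohens_d
  )

  # degenerate variance excluded from the FDR family
  tbi$D <- rep(1, 10)
  hc$D <- rep(1, 10)
  expect_message(scr_d <- screen_subsystems(tbi, hc), "degenerate")
  expect_true(is.na(scr_d$p[scr_d$subsystem == "D"]))
})

test_that("an implanted hyperconnectivity effect is recovered by the screen", {
  em <- data.frame(group = "TBI", time_point = "T2", subsystem = "S02", increment = 0.25)
  sp <- cohort_spec(
    n_roi = 40, n_subsystems = 4, n_volumes = 145,
    subjects_per_group = c(TBI = 14, HC = 12),
    time_points = list(TBI = "T2", HC = "T1"),
    effect_map = em, seed = 21
  )
  co <- generate_cohort(sp)
  rois <- co$ground_truth$rois
  submap <- rois$subsystem
  strengths <- function(group) {
    sel <- vapply(co$panels, function(p) p$group == group, logical(1))
    t(vapply(
      co$panels[sel],
      function(p) unname(roi_strength(correlation_network(p))),
      numeric(nrow(rois))
    ))
  }
  pool <- function(mat) {
    out <- lapply(sort(unique(submap)), function(s) subsystem_distribution(mat, submap, s))
    names(out) <- sort(unique(submap))
    out
  }
  scr <- screen_subsystems(pool(strengths("TBI")), pool(strengths("HC")))
  expect_equal(scr$direction[scr$subsystem == "S02"], "hyper")
  expect_gt(scr$cohens_d[scr$subsystem == "S02"], 0.70)
  expect_true(all(scr$direction[scr$subsystem != "S02"] == "none"))
})

test_that("ANCOVA adjusts for a categorical covariate", {
  set.seed(8)
  # constant covariate reduces exactly to one-way ANOVA
  y <- rnorm(30)
  g <- rep(c("a", "b"), 15)
  a <- ancova_contrast(y, g, rep("s1", 30))
  f_anova <- anova(lm(y ~ factor(g)))$`F value`[1]
  expect_equal(a$F, f_anova, tolerance = 1e-10)

  # null group effect: F near 1, eta^2 small, on average
  Fs <- replicate(200, {
    yy <- rnorm(26)
    ancova_contrast(yy, rep(c("a", "b"), 13), rep(c("s1", "s2", "s3"), length.out = 26))$F
  })
  expect_equal(mean(Fs), 1, tolerance = 0.35)

  # planted 1 SD shift, n = 13/group: partial eta^2 near d^2/(d^2+4) = 0.2
  etas <- replicate(300, {
    yy <- c(rnorm(13, 1), rnorm(13, 0))
    ancova_contrast(yy, rep(c("a", "b"), each = 13),
      rep(c("s1", "s2", "s3"), length.out = 26))$partial_eta_sq
  })
  expect_lt(abs(mean(etas) - 0.2), 0.06) # eta^2 estimate is upward biased at small n

  # group aliased with the covariate is confounded
  expect_error(
    ancova_contrast(rnorm(20), rep(c("a", "b"), each = 10), rep(c("s1", "s2"), each = 10)),
    "confounded"
  )
})

test_that("follow-up contrasts gate on partial eta squared", {
  set.seed(12)
  tbi <- list(A = rnorm(60, 1), B = rnorm(60, 0.05))
  hc <- list(A = rnorm(60), B = rnorm(60))
  fu <- subsystem_followup(tbi, hc,
    tbi_covariate = rep(c("s1", "s2"), 30),
    hc_covariate = rep(c("s1", "s2"), 30),
    eta_sq_gate = 0.06
  )
  expect_true(fu$elevated[fu$subsystem == "A"])
  expect_false(fu$elevated[fu$subsystem == "B"])
})

test_that("behaviour correlations recover planted relationships", {
  expect_equal(behavior_correlation(1:10, 1:10)$r, 1)
  set.seed(3)
  cost <- rnorm(200)
  r_null <- behavior_correlation(cost, rnorm(200))
  expect_lt(abs(r_null$r), 0.15)
  expect_error(behavior_correlation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(behavior_correlation(1:2, 1:2), ">= 3")

  # round trip with the generator at target_r = 0.8
  sp <- cohort_spec(
    n_roi = 10, n_subsystems = 2, n_volumes = 60,
    subjects_per_group = c(G = 150), time_points = list(G = "T1"), seed = 19
  )
  co <- generate_cohort(sp)
  beh <- generate_behavior(co, target_r = 0.8, seed = 4)
  expect_equal(behavior_correlation(beh$cost, beh$score)$r, 0.8, tolerance = 0.1)
})
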