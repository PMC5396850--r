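test_that("generate_roi_set produces spatially coherent subsystems", {
  rs <- generate_roi_set(264, 20, seed = 1)
  expect_s3_class(rs, "roi_set")
  expect_equal(nrow(rs), 264)
  expect_equal(length(unique(rs$subsystem)), 20)

  # pigeonhole: n_roi == n_subsystems forces singletons
  rs5 <- generate_roi_set(5, 5, seed = 0)
  expect_true(all(table(rs5$subsystem) == 1))

  # within-subsystem pairwise distances shorter than between, on average
  rs60 <- generate_roi_set(60, 4, seed = 7)
  D <- roi_distances(rs60)
  same <- outer(rs60$subsystem, rs60$subsystem, "==") & upper.tri(D)
  diff <- (!outer(rs60$subsystem, rs60$subsystem, "==")) & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))

  expect_error(generate_roi_set(3, 5), "invalid spec")
})

test_that("roi sets round-trip through TSV and reject bad input", {
  rs <- generate_roi_set(20, 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roi_set(rs, path)
  back <- read_roi_set(path)
  expect_equal(as.data.frame(back), as.data.frame(rs), tolerance = 1e-9)

  expect_error(roi_set(matrix(1, 2, 3), c("A", "B")), "identical coordinate")
  expect_error(roi_set(matrix(c(1, 2, 3, Inf, 5, 6), 2, byrow = TRUE), c("A", "B")), "finite")
})

test_that("cohort generation is reproducible and shaped by the design", {
  sp <- cohort_spec(
    n_roi = 24, n_subsystems = 4, n_volumes = 40,
    subjects_per_group = c(TBI = 3, HC = 2),
    time_points = list(TBI = c("T1", "T2"), HC = "T1"), seed = 5
  )
  co1 <- generate_cohort(sp)
  co2 <- generate_cohort(sp)
  expect_equal(length(co1$panels), 3 * 2 + 2 * 1)
  expect_identical(co1$panels[[1]]$data, co2$panels[[1]]$data)
  expect_identical(co1$panels[[8]]$data, co2$panels[[8]]$data)
  # the study-sized design yields 14*3 + 12*2 = 66 panels
  sp_study <- cohort_spec(n_roi = 10, n_subsystems = 2, seed = 1)
  expect_equal(
    sum(sp_study$subjects_per_group * lengths(sp_study$time_points)),
    66
  )
})

test_that("sample correlations converge to the block ground truth", {
  sp <- cohort_spec(
    n_roi = 24, n_subsystems = 4, n_volumes = 2000,
    subjects_per_group = c(G = 1), time_points = list(G = "T1"),
    base_correlation = 0.5, background_correlation = 0.05, seed = 11
  )
  co <- generate_cohort(sp)
  R <- cor(co$panels[[1]]$data)
  target <- co$ground_truth$targets[["G:T1"]]
  expect_lt(max(abs(R - target)), 0.08) # single draw, elementwise
  sub <- co$ground_truth$rois$subsystem
  within <- outer(sub, sub, "==") & upper.tri(R)
  expect_lt(abs(mean(R[within]) - 0.5), 0.02)
  expect_lt(abs(mean(R[!outer(sub, sub, "==") & upper.tri(R)]) - 0.05), 0.02)
})

test_that("implanted correlation increments appear in the designated block", {
  em <- data.frame(group = "TBI", time_point = "T2", subsystem = "S03", increment = 0.2)
  sp <- cohort_spec(
    n_roi = 20, n_subsystems = 4, n_volumes = 500,
    subjects_per_group = c(TBI = 25, HC = 25),
    time_points = list(TBI = "T2", HC = "T2"),
    effect_map = em, seed = 13
  )
  co <- generate_cohort(sp)
  sub <- co$ground_truth$rois$subsystem
  blk <- outer(sub == "S03", sub == "S03", "&") & upper.tri(diag(20))
  mean_block <- function(group) {
    sel <- vapply(co$panels, function(p) p$group == group, logical(1))
    mean(vapply(co$panels[sel], function(p) mean(cor(p$data)[blk]), numeric(1)))
  }
  expect_lt(abs(mean_block("TBI") - mean_block("HC") - 0.2), 0.03)
})

test_that("cohort spec validation catches bad designs", {
  expect_error(cohort_spec(base_correlation = 0.1, background_correlation = 0.2))
  expect_error(cohort_spec(n_volumes = 10), "n_volumes")
  expect_error(
    cohort_spec(effect_map = data.frame(
      group = "TBI", time_point = "T9", subsystem = "S01", increment = 0.1
    )),
    "time point"
  )
  # increments pushing a block to r >= 1 must name the block
  em <- data.frame(group = "TBI", time_point = "T1", subsystem = "S01", increment = 0.6)
  sp <- cohort_spec(
    n_roi = 8, n_subsystems = 2, base_correlation = 0.5,
    subjects_per_group = c(TBI = 1), time_points = list(TBI = "T1"),
    effect_map = em, seed = 1
  )
  expect_error(generate_cohort(sp), "S01")
})

test_that("behavioural scores recover the target correlation", {
  sp <- cohort_spec(
    n_roi = 12, n_subsystems = 3, n_volumes = 60,
    subjects_per_group = c(G = 200), time_points = list(G = "T1"), seed = 17
  )
  co <- generate_cohort(sp)
  beh <- generate_behavior(co, target_r = 0.8, seed = 3)
  r_hat <- cor(beh$cost, beh$score)
  expect_gte(r_hat, 0.7)
  expect_lte(r_hat, 0.9)

  beh_neg <- generate_behavior(co, target_r = -0.5, seed = 3)
  expect_lt(cor(beh_neg$cost, beh_neg$score), 0)

  beh_null <- generate_behavior(co, target_r = 0, seed = 3)
  expect_lt(abs(cor(beh_null$cost, beh_null$score)), 0.15)

  expect_error(generate_behavior(co, target_r = 1.2), "target_r")
})

test_that("written cohorts round-trip through the TSV manifest", {
  sp <- cohort_spec(
    n_roi = 8, n_subsystems = 2, n_volumes = 30,
    subjects_per_group = c(TBI = 2, HC = 1),
    time_points = list(TBI = "T1", HC = "T1"), seed = 23
  )
  co <- generate_cohort(sp)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$panels), 3)
  expect_equal(back$panels[[1]]$data, unname(co$panels[[1]]$data),
    ignore_attr = TRUE, tolerance = 1e-6
  )
  expect_equal(back$panels[[2]]$group, co$panels[[2]]$group)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
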