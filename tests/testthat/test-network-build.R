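test_that("bh_fdr applies the step-up rule", {
  # hand-applied step-up on sorted p: 0.001 <= 1*0.05/4, 0.011 <= 2*0.05/4,
  # 0.02 <= 3*0.05/4, 0.8 > 0.05 -> first three retained
  expect_equal(bh_fdr(c(0.001, 0.011, 0.02, 0.8), 0.05), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(bh_fdr(rep(0, 5), 0.05), rep(TRUE, 5))
  expect_identical(bh_fdr(numeric(0)), logical(0))
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
})

test_that("correlation networks retain |r| for FDR-surviving pairs", {
  set.seed(42)
  n <- 12
  X <- matrix(rnorm(100 * n), 100, n)
  X[, 2] <- X[, 1] # perfect correlation
  X[, 4] <- -0.9 * X[, 3] + sqrt(1 - 0.81) * rnorm(100) # strong anti-correlation
  net <- correlation_network(ts_panel(X), alpha = 0.05)
  expect_equal(net$weights[1, 2], 1.0)
  expect_gt(net$weights[3, 4], 0.8) # stored as magnitude despite negative r
  expect_equal(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
  # retained <=> p recorded
  ut <- upper.tri(net$weights)
  expect_identical(net$weights[ut] > 0, !is.na(net$pvals[ut]))

  Xz <- X
  Xz[, 5] <- 0
  expect_error(correlation_network(ts_panel(matrix(Xz, 100))), "zero-variance")
})

test_that("retained edges are permutation equivariant and monotone in alpha", {
  set.seed(7)
  X <- matrix(rnorm(80 * 10), 80, 10)
  X[, 1:4] <- X[, 1:4] + rnorm(80) # correlated block
  net <- correlation_network(X, alpha = 0.05)
  perm <- sample(10)
  net_p <- correlation_network(X[, perm], alpha = 0.05)
  expect_equal(net_p$weights, net$weights[perm, perm])

  strict <- correlation_network(X, alpha = 0.01)
  expect_true(all(which(strict$weights > 0) %in% which(net$weights > 0)))
})

test_that("block structure is recovered at large n_volumes", {
  sp <- cohort_spec(
    n_roi = 16, n_subsystems = 2, n_volumes = 1000,
    subjects_per_group = c(G = 1), time_points = list(G = "T1"),
    base_correlation = 0.5, background_correlation = 0.02, seed = 9
  )
  co <- generate_cohort(sp)
  net <- correlation_network(co$panels[[1]], alpha = 0.05)
  sub <- co$ground_truth$rois$subsystem
  within <- outer(sub, sub, "==") & upper.tri(net$weights)
  between <- (!outer(sub, sub, "==")) & upper.tri(net$weights)
  expect_equal(mean(net$weights[within] > 0), 1)
  expect_lte(mean(net$weights[between] > 0), 0.10)
})

test_that("mask binarization is strict and extraction averages in-sphere voxels", {
  m <- array(0.6, c(2, 2, 2))
  expect_false(any(binarize_mask(m, 0.6))) # "greater than": 0.6 excluded at 0.6
  expect_true(all(binarize_mask(array(0.7, c(2, 2, 2)), 0.6)))
  expect_false(any(binarize_mask(array(0, c(2, 2, 2)), 0.6)))
  expect_error(binarize_mask(array(1.5, c(2, 2, 2))), "0, 1")

  # two voxels with constant signals 1 and 3 -> mean series constant 2
  img <- array(0, c(3, 1, 1, 4))
  img[1, 1, 1, ] <- 1
  img[2, 1, 1, ] <- 3
  mask <- array(TRUE, c(3, 1, 1))
  rois1 <- roi_set(matrix(c(0.5, 0, 0), 1), subsystem = "A")
  p <- extract_roi_timeseries(img, mask, rois1, sphere_radius_mm = 0.6)
  expect_equal(unname(p$data[, 1]), rep(2, 4)) # voxels at 0 and 1 mm, signals 1 and 3

  # masked-out ROI is flagged, column NA
  mask0 <- array(FALSE, c(3, 1, 1))
  p0 <- extract_roi_timeseries(img, mask0, rois1, sphere_radius_mm = 0.6)
  expect_equal(attr(p0, "flagged_rois"), 1L)
  expect_true(all(is.na(p0$data)))
})

test_that("extraction round-trips planted per-ROI signals on disjoint spheres", {
  set.seed(1)
  nt <- 10
  dims <- c(12, 4, 4)
  centers <- matrix(c(1, 1, 1, 9, 2, 2), 2, byrow = TRUE)
  sig <- matrix(rnorm(nt * 2), nt, 2)
  img <- array(0, c(dims, nt))
  vox <- as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3]))
  for (r in 1:2) {
    d2 <- colSums((t(vox - 1) - centers[r, ])^2)
    inside <- which(d2 <= 1.5^2)
    for (t in 1:nt) {
      img[vox[inside, , drop = FALSE] + 0][seq_along(inside)] <- 0 # no-op guard
      lin <- vox[inside, 1] + dims[1] * (vox[inside, 2] - 1) +
        dims[1] * dims[2] * (vox[inside, 3] - 1) + prod(dims) * (t - 1)
      img[lin] <- sig[t, r]
    }
  }
  rois2 <- roi_set(centers, subsystem = c("A", "B"))
  p <- extract_roi_timeseries(img, array(TRUE, dims), rois2, sphere_radius_mm = 1.5)
  expect_equal(unname(p$data), sig, tolerance = 1e-12)
})

test_that("networks round-trip through edge-list TSV", {
  net <- random_network(9, p = 0.4, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$weights, net$weights, tolerance = 1e-9)
  expect_equal(back$n_roi, 9)
})
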