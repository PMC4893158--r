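test_that("area_to_diameter reproduces the conventional size-bin diameters", {
  expect_equal(round(area_to_diameter(5000)), 80)
  expect_equal(round(area_to_diameter(15000)), 138)
  expect_equal(area_to_diameter(pi * 50^2), 100)
  expect_error(area_to_diameter(-1), "non-negative")
})

test_that("threshold calibration is deterministic, validates inputs and lies
           above r0 at study densities", {
  w <- roi(0, 0, 1000, 1000)
  t1 <- calibrate_threshold(200, w, n_sim = 20, seed = 5)
  t2 <- calibrate_threshold(200, w, n_sim = 20, seed = 5)
  expect_identical(t1, t2)
  expect_error(calibrate_threshold(-1, w), "positive")
  expect_error(calibrate_threshold(200, w, n_sim = 5), "at least 20")
  expect_error(calibrate_threshold(200, w, quantile = 0.4), "quantile")
  t_low <- calibrate_threshold(200, w, n_sim = 20, quantile = 0.9, seed = 6)
  expect_gte(t_low$threshold, 30)
  expect_gte(t1$threshold, t_low$threshold)
})

test_that("pixel-pooled calibration marks about 1 - quantile of CSR map
           pixels", {
  w <- roi(0, 0, 1500, 1500)
  th <- calibrate_threshold(200, w, n_sim = 30, quantile = 0.95, seed = 7,
                            pool = "pixels")
  marked <- withr::with_seed(8, {
    vapply(1:6, function(i) {
      m <- build_cluster_map(runif_points(450, w), w)
      mean(m$values > th$threshold)
    }, numeric(1))
  })
  expect_lt(mean(marked), 0.05 + 0.03)
})

test_that("event-pooled calibration keeps CSR event false-assignment near
           1 - quantile", {
  w <- roi(0, 0, 1500, 1500)
  th <- calibrate_threshold(200, w, n_sim = 30, quantile = 0.95, seed = 9)
  frac <- withr::with_seed(10, {
    vapply(1:6, function(i) {
      pts <- runif_points(450, w)
      mean(local_l(pts, w)$l_local > th$threshold)
    }, numeric(1))
  })
  expect_lt(mean(frac), 0.05 + 0.03)
})

test_that("cluster maps have the declared geometry and peak at a tight
           cluster's centre", {
  w <- roi(0, 0, 1000, 700)
  pts <- tight_cluster_points(center = c(400, 350), window = w, seed = 2)
  m <- build_cluster_map(pts, w, grid_step = 10)
  expect_equal(dim(m$values), c(ceiling(1000 / 10), ceiling(700 / 10)))
  peak <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  peak_nm <- (peak - 0.5) * 10
  expect_lt(sqrt(sum((peak_nm - c(400, 350))^2)), 60)
  expect_error(build_cluster_map(pts[1, ], w), "at least 2")
})

test_that("binarize_and_label follows the area definition and drops
           sub-minimum components", {
  w <- roi(0, 0, 200, 200)
  m <- structure(list(values = matrix(0, 20, 20), grid_step = 10,
                      window = w, r0 = 30,
                      points = tibble::tibble(x = c(35, 150), y = c(35, 150))),
                 class = "nc_cluster_map")
  expect_equal(nrow(binarize_and_label(m, 10, min_area = 0)), 0)
  m$values[3:5, 3:4] <- 50  # 6 pixels
  cl <- binarize_and_label(m, 10, min_area = 0)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$area, 6 * 10^2)
  expect_equal(cl$n_events, 1L)  # the event at (35, 35) sits on the footprint
  expect_equal(nrow(binarize_and_label(m, 10, min_area = 700)), 0)
})

test_that("component labeling equals brute-force flood fill", {
  for (seed in 1:5) {
    b <- withr::with_seed(seed, matrix(runif(40 * 30) < 0.4, 40, 30))
    expect_true(same_partition(label_components(b, 8), flood_fill_label(b, 8)))
    expect_true(same_partition(label_components(b, 4), flood_fill_label(b, 4)))
  }
  # diagonal neighbours merge under 8- but not 4-connectivity
  d <- matrix(FALSE, 3, 3); d[1, 1] <- d[2, 2] <- TRUE
  expect_equal(max(label_components(d, 8)), 1)
  expect_equal(max(label_components(d, 4)), 2)
})

test_that("cluster summaries satisfy their accounting identities", {
  w <- roi(0, 0, 200, 200)
  pts <- tibble::tibble(x = runif(20, 0, 200), y = runif(20, 0, 200))
  m <- structure(list(values = matrix(100, 20, 20), grid_step = 10,
                      window = w, r0 = 30, points = pts),
                 class = "nc_cluster_map")
  cl <- binarize_and_label(m, 10, min_area = 0)  # one cluster = whole ROI
  s <- summarize_clusters(cl, window = w)
  expect_equal(s$percent_in_clusters, 100)
  expect_equal(s$relative_density, 1)
  expect_equal(s$clusters_per_um2, 1 / (roi_area(w) / 1e6))
  expect_equal(s$frac_small + s$frac_mid + s$frac_large, 1)

  # a cluster of exactly 5000 nm^2 falls in the closed lower bin
  cl2 <- tibble::tibble(id = 1L, n_pixels = 50L, area = 5000,
                        centroid_x = 100, centroid_y = 100, n_events = 5L)
  attr(cl2, "events") <- pts
  s2 <- summarize_clusters(cl2, pts, w)
  expect_equal(s2$frac_small, 1)
  expect_equal(s2$frac_large, 0)
})

test_that("percent-in-clusters recomputed from memberships matches and never
           exceeds the event total", {
  args <- smlm_regime(6000, window = roi(0, 0, 2000, 2000),
                      total_density = 200)
  sim <- do.call(simulate_smlm, c(args, list(seed = 33)))
  w <- roi(0, 0, 2000, 2000)
  pts <- crop_region(sim$points, w)
  m <- build_cluster_map(pts, w)
  cl <- binarize_and_label(m, 80)
  ev <- attr(cl, "events")
  expect_lte(sum(cl$n_events), nrow(pts))
  expect_equal(sum(cl$n_events), sum(!is.na(ev$cluster)))
  s <- summarize_clusters(cl, window = w)
  expect_equal(s$percent_in_clusters, 100 * sum(!is.na(ev$cluster)) /
                 nrow(pts))
  if (nrow(cl) > 0) {
    expect_equal(s$frac_small + s$frac_mid + s$frac_large, 1)
  }
})

test_that("recovered median area does not decrease with the generator's
           cluster size", {
  w <- roi(0, 0, 2000, 2000)
  th <- calibrate_threshold(200, w, n_sim = 20, seed = 40,
                            mean_redetections = 2, sigma_loc = 20)
  med <- vapply(c(4000, 9000, 18000), function(a) {
    args <- smlm_regime(a, window = w, total_density = 200)
    sim <- do.call(simulate_smlm, c(args, list(seed = 41)))
    pts <- crop_region(sim$points, w)
    cl <- binarize_and_label(build_cluster_map(pts, w), th)
    stats::median(cl$area)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})
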