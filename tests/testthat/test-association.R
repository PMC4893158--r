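# build a cluster tibble + labels attribute from explicit pixel footprints
fake_clusters <- function(footprints, dim = c(64, 64), ps = 20) {
  labels <- matrix(0L, dim[1], dim[2])
  rows <- lapply(seq_along(footprints), function(i) {
    f <- footprints[[i]]
    labels[f] <<- i
    tibble::tibble(id = i, n_pixels = nrow(f), area = nrow(f) * ps^2,
                   centroid_x = mean((f[, 1] - 0.5) * ps),
                   centroid_y = mean((f[, 2] - 0.5) * ps))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "labels") <- labels
  attr(out, "pixel_size") <- ps
  out
}

square_foot <- function(ix, iy, w = 2) {
  as.matrix(expand.grid(ix:(ix + w - 1), iy:(iy + w - 1)))
}

test_that("tertile assignment splits exact thirds and follows the remainder
           rule", {
  cl <- tibble::tibble(id = 1:6, area = c(3, 1, 5, 2, 6, 4))
  t6 <- assign_tertiles(cl)
  expect_equal(as.character(t6$tertile[order(t6$area)]),
               rep(c("small", "medium", "large"), each = 2))
  cl7 <- tibble::tibble(id = 1:7, area = 7:1)
  t7 <- assign_tertiles(cl7)
  expect_equal(as.numeric(table(t7$tertile)), c(3, 2, 2))
  # permuting input order leaves labels attached to the same clusters
  perm <- withr::with_seed(1, sample.int(7))
  tp <- assign_tertiles(cl7[perm, ])
  merged <- dplyr::left_join(t7, tp, by = "id")
  expect_equal(merged$tertile.x, merged$tertile.y)
  expect_error(assign_tertiles(cl7[1:2, ]), "fewer than 3")
})

test_that("association flags respect the strict search radius", {
  ps <- 20
  rec <- fake_clusters(list(square_foot(10, 10)), ps = ps)
  # signaling cluster centred on the receptor centroid -> associated
  sig_on <- fake_clusters(list(square_foot(10, 10)), ps = ps)
  r_on <- screen_association(rec, sig_on, search_radius = 100)
  expect_true(all(r_on$associated))
  # nearest signaling pixel one pixel beyond the radius -> not associated
  centroid <- c(rec$centroid_x, rec$centroid_y)
  radius <- 100
  far_ix <- ceiling((centroid[1] + radius + ps) / ps) + 1
  sig_off <- fake_clusters(list(cbind(far_ix, 10)), ps = ps)
  r_off <- screen_association(rec, sig_off, search_radius = radius)
  expect_false(any(r_off$associated))
})

test_that("association flags equal exhaustive pixel-by-pixel checks", {
  ps <- 20
  withr::with_seed(31, {
    rec <- fake_clusters(lapply(1:8, function(i) {
      square_foot(sample(5:55, 1), sample(5:55, 1), w = sample(1:3, 1))
    }), ps = ps)
    sig <- fake_clusters(lapply(1:6, function(i) {
      square_foot(sample(5:55, 1), sample(5:55, 1), w = sample(1:2, 1))
    }), ps = ps)
  })
  for (radius in c(60, 150, 400)) {
    got <- screen_association(rec, sig, search_radius = radius)
    want <- brute_association(rec$centroid_x, rec$centroid_y,
                              attr(sig, "labels"), ps, radius)
    expect_equal(got$associated, want)
  }
})

test_that("enlarging the search radius never de-associates a cluster", {
  ps <- 20
  withr::with_seed(32, {
    rec <- fake_clusters(lapply(1:10, function(i) {
      square_foot(sample(5:55, 1), sample(5:55, 1))
    }), ps = ps)
    sig <- fake_clusters(lapply(1:5, function(i) {
      square_foot(sample(5:55, 1), sample(5:55, 1))
    }), ps = ps)
  })
  prev <- rep(FALSE, nrow(rec))
  for (radius in c(50, 100, 200, 400, 800)) {
    cur <- screen_association(rec, sig, search_radius = radius)$associated
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("nearby intensity sums the signaling image over the circle", {
  ps <- 20
  rec <- fake_clusters(list(square_foot(16, 16)), dim = c(32, 32), ps = ps)
  img <- pixel_image(matrix(2, 32, 32), ps)
  sig <- fake_clusters(list(square_foot(16, 16)), dim = c(32, 32), ps = ps)
  got <- screen_association(rec, sig, img, search_radius = 200)
  cx <- rec$centroid_x; cy <- rec$centroid_y
  px <- (row(matrix(0, 32, 32)) - 0.5) * ps
  py <- (col(matrix(0, 32, 32)) - 0.5) * ps
  want <- 2 * sum((px - cx)^2 + (py - cy)^2 <= 200^2)
  expect_equal(got$nearby_intensity, want)
})

test_that("the randomization null preserves footprints, stays in the mask and
           is seed-deterministic", {
  mask <- make_cell_mask(dim = 64, pixel_size = 20, seed = 7)
  tc <- simulate_two_channel(n_spots = 6, offset = 200, mask = mask,
                             seed = 8)
  cl_a <- assign_tertiles(binarize_image_clusters(tc$img_a, mask))
  cl_b <- binarize_image_clusters(tc$img_b, mask)
  n1 <- randomize_null(cl_a, cl_b, tc$img_b, mask, search_radius = 400,
                       n_reps = 10, seed = 99)
  n2 <- randomize_null(cl_a, cl_b, tc$img_b, mask, search_radius = 400,
                       n_reps = 10, seed = 99)
  expect_identical(n1, n2)
  expect_equal(nrow(n1), 10)
  # the cluster count and per-cluster areas are preserved by construction
  # (rigid translation); a footprint that cannot fit errors out
  big_sig <- fake_clusters(list(square_foot(2, 2, w = 60)),
                           dim = c(64, 64), ps = 20)
  expect_error(randomize_null(cl_a, big_sig, NULL, mask, n_reps = 2,
                              seed = 1),
               "cannot be placed")
})

test_that("null association probability matches the closed form for
           point-like signaling clusters in a full-window mask", {
  ps <- 20; n_px <- 64
  mask <- cell_mask(matrix(TRUE, n_px, n_px), ps)
  withr::with_seed(41, {
    rec <- fake_clusters(lapply(1:6, function(i) {
      square_foot(sample(15:50, 1), sample(15:50, 1))
    }), dim = c(n_px, n_px), ps = ps)
    sig <- fake_clusters(lapply(1:4, function(i) cbind(sample(n_px, 1),
                                                       sample(n_px, 1))),
                         dim = c(n_px, n_px), ps = ps)
  })
  rec <- assign_tertiles(rec)
  radius <- 180
  null <- randomize_null(rec, sig, NULL, mask, search_radius = radius,
                         n_reps = 400, seed = 42)
  p_mc <- mean(attr(null, "per_cluster"))
  # exact discrete expectation: an anchor pixel is uniform over the grid
  px <- (row(matrix(0, n_px, n_px)) - 0.5) * ps
  py <- (col(matrix(0, n_px, n_px)) - 0.5) * ps
  p_i <- vapply(seq_len(nrow(rec)), function(i) {
    k <- sum((px - rec$centroid_x[i])^2 + (py - rec$centroid_y[i])^2 <=
               radius^2)
    1 - (1 - k / n_px^2)^4
  }, numeric(1))
  se <- sqrt(mean(p_i) * (1 - mean(p_i)) / (400 * nrow(rec)))
  expect_lt(abs(p_mc - mean(p_i)), 4 * se + 0.01)
})

test_that("feeding a null replicate back as the observation zeroes the
           size-effect differences", {
  mask <- make_cell_mask(dim = 64, pixel_size = 20, seed = 17)
  tc <- simulate_two_channel(n_spots = 9, offset = 150, mask = mask,
                             seed = 18)
  cl_a <- assign_tertiles(binarize_image_clusters(tc$img_a, mask))
  cl_b <- binarize_image_clusters(tc$img_b, mask)
  obs <- screen_association(cl_a, cl_b, tc$img_b, search_radius = 400)
  # a "null" with the observed configuration: compare with itself
  null1 <- structure(
    tibble::tibble(rep = 1L,
                   frac_associated = attr(obs, "summary")$frac_associated,
                   frac_small = attr(obs, "summary")$frac_small,
                   frac_medium = attr(obs, "summary")$frac_medium,
                   frac_large = attr(obs, "summary")$frac_large,
                   p_small = tapply(obs$associated, obs$tertile, mean)[[1]],
                   p_medium = tapply(obs$associated, obs$tertile, mean)[[2]],
                   p_large = tapply(obs$associated, obs$tertile, mean)[[3]],
                   median_nearby = stats::median(obs$nearby_intensity)),
    class = c("null_distribution", class(tibble::tibble())))
  s <- size_effect_summary(obs, null1)
  expect_equal(s$frac_difference, rep(0, 3))
  expect_equal(s$observed_p, s$null_p)
})

test_that("signaling clusters seeded at large receptor clusters beat the
           null in the large tertile", {
  ps <- 20; n_px <- 96
  mask <- cell_mask(matrix(TRUE, n_px, n_px), ps)
  withr::with_seed(51, {
    sizes <- c(1, 1, 1, 2, 2, 2, 4, 4, 4)
    pos <- cbind(sample(seq(8, 88, by = 8), 9), sample(seq(8, 88, by = 8), 9))
    rec <- fake_clusters(lapply(seq_along(sizes), function(i) {
      square_foot(pos[i, 1], pos[i, 2], w = sizes[i])
    }), dim = c(n_px, n_px), ps = ps)
  })
  rec <- assign_tertiles(rec)
  # signaling clusters adjacent to the three largest receptor clusters
  large_idx <- which(rec$tertile == "large")
  sig <- fake_clusters(lapply(large_idx, function(i) {
    cbind(round(rec$centroid_x[i] / ps) + 3, round(rec$centroid_y[i] / ps))
  }), dim = c(n_px, n_px), ps = ps)
  obs <- screen_association(rec, sig, search_radius = 150)
  null <- randomize_null(rec, sig, NULL, mask, search_radius = 150,
                         n_reps = 100, seed = 52)
  s <- size_effect_summary(obs, null)
  expect_gt(s$observed_frac[3], s$null_frac[3])
  expect_gt(s$observed_p[3], mean(null$p_large))
})
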