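test_that("two points beyond r give K = 0 and L - r = -r", {
  w <- roi(0, 0, 1000, 1000)
  pts <- tibble::tibble(x = c(450, 550), y = c(500, 500))
  rc <- ripley_k(pts, radii = 50, window = w)
  expect_equal(rc$k, 0)
  expect_equal(rc$l_minus_r, -50)
})

test_that("K matches the brute-force pair count for interior points", {
  w <- roi(0, 0, 2000, 2000)
  pts <- tibble::tibble(x = c(900, 1000, 1100, 950, 1050),
                        y = c(1000, 1020, 980, 1100, 900))
  radii <- c(50, 120, 200)
  rc <- ripley_k(pts, radii, w)
  expect_equal(rc$k, brute_ripley_k(pts, radii, w))
  expect_equal(rc$l, sqrt(rc$k / pi))
})

test_that("K is invariant to translation and event relabeling", {
  w <- roi(0, 0, 1000, 1000)
  pts <- withr::with_seed(7, runif_points(40, roi(0, 0, 600, 600)))
  pts$x <- pts$x + 150; pts$y <- pts$y + 250
  radii <- c(40, 80)
  k1 <- ripley_k(pts, radii, w)$k
  shifted <- dplyr::mutate(pts, x = x - 100, y = y + 50)
  k2 <- ripley_k(shifted, radii, w)$k
  k3 <- ripley_k(pts[sample.int(nrow(pts)), ], radii, w)$k
  expect_equal(k2, k1)
  expect_equal(k3, k1)
})

test_that("edge correction is inactive for patterns far from the borders and
           agrees with the closed-form duplicate-pair count", {
  w <- roi(0, 0, 2000, 2000)
  pts <- withr::with_seed(3, {
    tibble::tibble(x = runif(25, 900, 1100), y = runif(25, 900, 1100))
  })
  radii <- c(30, 60, 100)
  expect_equal(ripley_k(pts, radii, w)$k,
               ripley_k(pts, radii, w, edge_correction = FALSE)$k)

  # doubling every point: each point gains its exact duplicate; at r -> 0 the
  # pair count is 2n (ordered duplicate pairs), K = A * 2n / (2n * (2n - 1))
  dup <- dplyr::bind_rows(pts, pts)
  n2 <- nrow(dup)
  k0 <- ripley_k(dup, radii = 1e-9, window = w)$k
  expect_equal(k0, roi_area(w) * 2 * nrow(pts) / (n2 * (n2 - 1)))
  # and the local-L ordering of distinct positions is unchanged
  l1 <- local_l(pts, w, r0 = 60)$l_local
  l2 <- local_l(dup, w, r0 = 60)$l_local[seq_len(nrow(pts))]
  expect_equal(order(l1), order(l2))
})

test_that("the isotropic correction matches an independent reference
           implementation on a boundary-heavy pattern", {
  skip_if_not_installed("spatstat.explore")
  w <- roi(0, 0, 1000, 1000)
  pts <- withr::with_seed(9, runif_points(40, w))
  radii <- c(50, 100, 200, 350, 500)
  rc <- ripley_k(pts, radii, w)
  pp <- spatstat.geom::ppp(pts$x, pts$y,
                           window = spatstat.geom::owin(c(0, 1000),
                                                        c(0, 1000)))
  ke <- spatstat.explore::Kest(pp, r = c(0, radii), correction = "isotropic")
  expect_equal(rc$k, ke$iso[-1], tolerance = 1e-10)
})

test_that("parameter validation rejects degenerate Ripley inputs", {
  w <- roi(0, 0, 1000, 1000)
  pts <- runif_points(10, w)
  expect_error(ripley_k(pts[1, ], 50, w), "at least 2")
  expect_error(ripley_k(pts, c(100, 50), w), "ascending")
  expect_error(ripley_k(pts, 600, w), "half the shorter window")
  expect_error(local_l(pts, w, r0 = -1), "positive")
  expect_error(csr_envelope(50, w, 50, n_sim = 99, alpha = 1.2), "alpha")
})

test_that("CSR envelopes are seed-deterministic, contain 0, shrink with n,
           and contain a CSR curve at most radii", {
  w <- roi(0, 0, 1000, 1000)
  radii <- seq(20, 100, by = 20)
  e1 <- csr_envelope(100, w, radii, n_sim = 99, seed = 11)
  e2 <- csr_envelope(100, w, radii, n_sim = 99, seed = 11)
  expect_identical(e1, e2)
  expect_true(all(e1$lower <= 0 & e1$upper >= 0))

  e_big <- csr_envelope(1000, w, radii, n_sim = 99, seed = 12)
  expect_lt(mean(e_big$upper - e_big$lower), mean(e1$upper - e1$lower))

  # a fresh CSR pattern escapes a pointwise alpha envelope at ~alpha of radii
  radii2 <- seq(10, 80, by = 10)
  env <- csr_envelope(100, w, radii2, n_sim = 199, alpha = 0.2, seed = 13)
  out_frac <- withr::with_seed(14, {
    mean(replicate(30, {
      cur <- ripley_k(runif_points(100, w), radii2, w)$l_minus_r
      mean(cur < env$lower | cur > env$upper)
    }))
  })
  expect_gt(out_frac, 0.08)
  expect_lt(out_frac, 0.35)
})

test_that("a CSR pattern's mean L - r stays within its 99% envelope", {
  w <- roi()
  radii <- seq(10, 200, by = 10)
  pts <- withr::with_seed(21, runif_points(2000, w))
  rc <- ripley_k(pts, radii, w)
  env <- csr_envelope(2000, w, radii, n_sim = 99, alpha = 0.01, seed = 22)
  expect_true(mean(rc$l_minus_r) > min(env$lower) &&
              mean(rc$l_minus_r) < max(env$upper))
})

test_that("local L matches the closed form for hand-counted neighbours and is
           0 for isolated events", {
  w <- roi(0, 0, 1000, 1000)
  # interior event with exactly 3 neighbours within 50 nm
  pts <- tibble::tibble(
    x = c(500, 520, 480, 500, 100, 900),
    y = c(500, 500, 510, 540, 100, 900))
  ll <- local_l(pts, w, r0 = 50)$l_local
  a <- roi_area(w); n <- nrow(pts)
  k <- brute_neighbor_counts(pts, 50)
  expect_equal(ll, sqrt(a * k / (pi * (n - 1))))
  expect_equal(ll[5], 0)  # no neighbour within r0
})

test_that("local L on dense CSR has median near r0 and rms near r0", {
  w <- roi(0, 0, 1000, 1000)
  pts <- withr::with_seed(31, runif_points(2000, w))
  ll <- local_l(pts, w, r0 = 30)$l_local
  expect_lt(abs(stats::median(ll) - 30) / 30, 0.15)
  expect_lt(abs(sqrt(mean(ll^2)) - 30) / 30, 0.15)
})

test_that("circle_in_window_fraction is exact against numeric integration", {
  w <- roi(0, 0, 1000, 800)
  cases <- expand.grid(x = c(5, 30, 120, 500, 990),
                       y = c(5, 50, 400, 795), r = c(10, 60, 150))
  th <- seq(0, 2 * pi, length.out = 20001)[-1]
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; y <- cases$y[i]; r <- cases$r[i]
    px <- x + r * cos(th); py <- y + r * sin(th)
    num <- mean(px >= 0 & px <= 1000 & py >= 0 & py <= 800)
    expect_equal(circle_in_window_fraction(x, y, r, w), num,
                 tolerance = 1e-3)
  }
})
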