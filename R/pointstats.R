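#' Ripley's K, L(r) - r and the CSR envelope
#'
#' `ripley_k()` estimates Ripley's K function of a planar point pattern in a
#' rectangular window with isotropic (Ripley) edge correction:
#' \deqn{\hat K(r) = \frac{A}{n(n-1)} \sum_i \sum_{j \ne i} e_{ij}
#'   \, 1(d_{ij} \le r)}
#' where `A` is the window area and `e_ij` is the reciprocal of the fraction
#' of the circle of radius `d_ij` centred at point `i` that lies inside the
#' window. The variance-stabilised transform `L(r) = sqrt(K(r)/pi)` is
#' returned alongside; under complete spatial randomness (CSR)
#' `L(r) - r` is approximately 0, positive values indicate clustering at
#' scale `r`.
#'
#' @param points Localization tibble with `x`, `y` in nm, expressed relative
#'   to the window origin (see [crop_region()]).
#' @param radii Ascending positive radii (nm); the largest must not exceed
#'   half the shorter window side.
#' @param window An [roi()] describing the observation window.
#' @param edge_correction Apply isotropic edge correction (default) or use
#'   raw pair counts.
#' @return A tibble of class `ripley_curve` with columns `r`, `k`, `l`,
#'   `l_minus_r`, and attributes `n_events` and `window_area`.
#' @seealso [csr_envelope()], [local_l()]
#' @export
ripley_k <- function(points, radii, window, edge_correction = TRUE) {
  n <- nrow(points)
  if (n < 2) stop("ripley_k needs at least 2 events", call. = FALSE)
  if (any(radii <= 0) || is.unsorted(radii)) {
    stop("radii must be positive and ascending", call. = FALSE)
  }
  if (max(radii) > min(window$width, window$height) / 2) {
    stop("max radius exceeds half the shorter window side", call. = FALSE)
  }
  a <- roi_area(window)
  pw <- .pairs_within(points$x, points$y, max(radii))
  if (nrow(pw) == 0) {
    k <- rep(0, length(radii))
  } else {
    w <- if (edge_correction) {
      1 / circle_in_window_fraction(points$x[pw$i], points$y[pw$i], pw$d,
                                    window)
    } else {
      rep(1, nrow(pw))
    }
    ord <- order(pw$d)
    cum_w <- cumsum(w[ord])
    idx <- findInterval(radii, pw$d[ord])
    k <- a / (n * (n - 1)) * ifelse(idx == 0, 0, cum_w[pmax(idx, 1)])
  }
  l <- sqrt(k / pi)
  out <- tibble::tibble(r = radii, k = k, l = l, l_minus_r = l - radii)
  attr(out, "n_events") <- n
  attr(out, "window_area") <- a
  class(out) <- c("ripley_curve", class(out))
  out
}

# All ordered pairs (i, j), i != j, with d_ij <= rmax. Chunked O(n^2) with
# C-level vectorised distance evaluation; fine up to ~10^4 events.
.pairs_within <- function(x, y, rmax, chunk = 512L) {
  n <- length(x)
  r2 <- rmax^2
  res_i <- list(); res_j <- list(); res_d <- list(); k <- 0L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(x[s:e], x, "-")
    dy <- outer(y[s:e], y, "-")
    d2 <- dx * dx + dy * dy
    hit <- which(d2 <= r2, arr.ind = TRUE)
    hit <- hit[hit[, 1] + s - 1L != hit[, 2], , drop = FALSE]
    if (nrow(hit)) {
      k <- k + 1L
      res_i[[k]] <- hit[, 1] + s - 1L
      res_j[[k]] <- hit[, 2]
      res_d[[k]] <- sqrt(d2[hit])
    }
  }
  if (k == 0L) {
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  }
  data.frame(i = unlist(res_i), j = unlist(res_j), d = unlist(res_d))
}

#' Fraction of a circle lying inside a rectangular window
#'
#' For a circle of radius `r` centred at `(x, y)` inside the window, returns
#' the fraction of its circumference inside the window — the reciprocal of
#' the isotropic edge-correction weight. Exact closed form: the exterior arc
#' is the union of up to four arcs (one per window edge), each centred on the
#' outward edge normal with half-width `acos(distance/r)`; arcs of adjacent
#' edges may overlap at corners, arcs of opposite edges cannot overlap for
#' points inside the window.
#'
#' @param x,y Circle centres, nm (inside the window).
#' @param r Radii, nm.
#' @param window An [roi()].
#' @return Numeric vector of fractions in (0, 1].
#' @keywords internal
#' @export
circle_in_window_fraction <- function(x, y, r, window) {
  w <- window$width; h <- window$height
  x <- x - window$x0; y <- y - window$y0
  hw <- function(dist) ifelse(dist < r, acos(pmax(pmin(dist / r, 1), -1)), 0)
  h_r <- hw(w - x); h_l <- hw(x); h_t <- hw(h - y); h_b <- hw(y)
  overlap <- function(a, b) pmax(0, a + b - pi / 2)
  outside <- 2 * (h_r + h_l + h_t + h_b) -
    overlap(h_r, h_t) - overlap(h_t, h_l) -
    overlap(h_l, h_b) - overlap(h_b, h_r)
  pmax(1 - outside / (2 * pi), .Machine$double.eps)
}

#' Monte-Carlo CSR envelope of L(r) - r
#'
#' Simulates `n_sim` patterns of exactly `n_events` uniform points in the
#' window, computes `L(r) - r` for each, and returns the pointwise central
#' `(1 - alpha)` quantile envelope. An observed curve escaping the envelope
#' indicates departure from complete spatial randomness at that scale.
#'
#' @param n_events Number of events per simulated pattern.
#' @param window An [roi()].
#' @param radii Radii at which to evaluate, nm.
#' @param n_sim Number of CSR simulations (>= 99 recommended for
#'   `alpha = 0.01`).
#' @param alpha Two-sided tail mass outside the envelope.
#' @param seed Integer seed; the envelope is reproducible given the seed.
#' @return A tibble of class `csr_envelope` with columns `r`, `lower`,
#'   `upper` and attributes `n_sim`, `alpha`, `n_events`.
#' @export
csr_envelope <- function(n_events, window, radii, n_sim = 199, alpha = 0.01,
                         seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_sim < 2) stop("n_sim must be at least 2", call. = FALSE)
  sims <- withr::with_seed(seed %||% sample.int(2^31 - 1, 1), {
    vapply(seq_len(n_sim), function(i) {
      pts <- runif_points(n_events, window)
      ripley_k(pts, radii, window)$l_minus_r
    }, numeric(length(radii)))
  })
  sims <- matrix(sims, nrow = length(radii))
  out <- tibble::tibble(
    r = radii,
    lower = apply(sims, 1, stats::quantile, probs = alpha / 2, names = FALSE),
    upper = apply(sims, 1, stats::quantile, probs = 1 - alpha / 2,
                  names = FALSE)
  )
  attr(out, "n_sim") <- n_sim
  attr(out, "alpha") <- alpha
  attr(out, "n_events") <- n_events
  class(out) <- c("csr_envelope", class(out))
  out
}

#' Uniform (CSR) point pattern in a window
#'
#' @param n Number of points.
#' @param window An [roi()].
#' @return A localization tibble with `x`, `y` relative to the window origin
#'   plus a sequential `frame` column.
#' @export
runif_points <- function(n, window) {
  tibble::tibble(
    x = stats::runif(n, 0, window$width),
    y = stats::runif(n, 0, window$height),
    frame = seq_len(n)
  )
}

#' Getis-Franklin local L values
#'
#' Computes the per-event local clustering statistic
#' \deqn{L_i(r_0) = \sqrt{\frac{A \sum_{j \ne i} e_{ij} 1(d_{ij} \le r_0)}
#'   {\pi (n - 1)}}}
#' with the same isotropic edge correction as [ripley_k()]. Under CSR the
#' expected value of `L_i` is approximately `r0`; events in clusters score
#' much higher, events with no neighbour within `r0` score 0. The `(n - 1)`
#' divisor excludes the self-pair.
#'
#' @param points Localization tibble with `x`, `y` relative to the window
#'   origin.
#' @param window An [roi()].
#' @param r0 Search radius, nm (default 30, the conventional scale for
#'   receptor nanocluster maps).
#' @return `points` with an added `l_local` column (nm).
#' @export
local_l <- function(points, window, r0 = 30) {
  if (r0 <= 0) stop("r0 must be positive", call. = FALSE)
  n <- nrow(points)
  if (n < 2) stop("local_l needs at least 2 events", call. = FALSE)
  a <- roi_area(window)
  pw <- .pairs_within(points$x, points$y, r0)
  s <- numeric(n)
  if (nrow(pw)) {
    w <- 1 / circle_in_window_fraction(points$x[pw$i], points$y[pw$i], pw$d,
                                       window)
    agg <- rowsum(w, pw$i)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  dplyr::mutate(points, l_local = sqrt(a * s / (pi * (n - 1))))
}
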