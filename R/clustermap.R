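#' Calibrate the cluster-map binarization threshold on randomized data
#'
#' Simulates `n_sim` spatially random patterns density-matched to the data,
#' computes local L for each, and returns the given quantile of the pooled
#' null values as the cluster threshold, so clusters called on real data
#' exceed what matched-density randomness produces.
#'
#' Two null models are available. The default (`mean_redetections = 1`,
#' `sigma_loc = 0`) is complete spatial randomness of the events themselves.
#' When the data carry per-molecule re-detections (blinking), a CSR null is
#' too permissive — every multiply-detected background molecule is a genuine
#' event clump — so the null should randomize *molecule* positions while
#' preserving the re-detection statistics: set `mean_redetections` and
#' `sigma_loc` to the values that describe the data and the null places
#' `event_density / mean_redetections` molecules uniformly, re-detects each a
#' geometric number of times and jitters every detection.
#'
#' Two pooling conventions are available. The default pools the per-event L
#' values of the null patterns, which calibrates the fraction of *events*
#' falsely assigned to clusters (about `1 - quantile`). `pool = "pixels"`
#' pools the interpolated map pixels instead, which calibrates the fraction
#' of map *pixels* marked: because events concentrate exactly where chance
#' clumps drive L up, the pixel convention admits several-fold more false
#' event assignments than `1 - quantile`.
#'
#' @param event_density Events per square micrometre (> 0).
#' @param window An [roi()]; the calibration window (the threshold depends on
#'   density, radius and window geometry, not on the data).
#' @param r0 Local-L search radius, nm.
#' @param grid_step Map grid spacing, nm (used for `pool = "pixels"`).
#' @param n_sim Number of null simulations pooled (>= 20).
#' @param quantile Null quantile used as threshold, in (0.5, 1).
#' @param seed Integer seed; the calibration is deterministic given the seed.
#' @param mean_redetections Mean detections per molecule in the null
#'   (1 = plain CSR events).
#' @param sigma_loc Localization noise sd applied to null detections, nm.
#' @param pool Pool `"events"` (per-event L values, default) or `"pixels"`
#'   (interpolated map pixels).
#' @return A list of class `nc_threshold` with the threshold and every
#'   calibration parameter.
#' @export
calibrate_threshold <- function(event_density, window = roi(), r0 = 30,
                                grid_step = 10, n_sim = 50, quantile = 0.99,
                                seed = NULL, mean_redetections = 1,
                                sigma_loc = 0, pool = c("events", "pixels")) {
  pool <- match.arg(pool)
  if (event_density <= 0) stop("event_density must be positive", call. = FALSE)
  if (n_sim < 20) stop("n_sim must be at least 20", call. = FALSE)
  if (quantile <= 0.5 || quantile >= 1) {
    stop("quantile must be in (0.5, 1)", call. = FALSE)
  }
  n <- max(2L, round(event_density * roi_area(window) / 1e6))
  seed <- seed %||% sample.int(2^31 - 1, 1)
  pooled <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_sim), function(i) {
      pts <- .null_pattern(n, window, mean_redetections, sigma_loc)
      if (pool == "events") {
        local_l(pts, window, r0 = r0)$l_local
      } else {
        as.numeric(build_cluster_map(pts, window, r0 = r0,
                                     grid_step = grid_step)$values)
      }
    }))
  })
  structure(
    list(threshold = stats::quantile(pooled, quantile, names = FALSE),
         event_density = event_density, r0 = r0, grid_step = grid_step,
         n_sim = n_sim, quantile = quantile, seed = seed,
         mean_redetections = mean_redetections, sigma_loc = sigma_loc,
         pool = pool),
    class = "nc_threshold"
  )
}

# density-matched null pattern: CSR events, or CSR molecules with geometric
# re-detections and Gaussian localization jitter
.null_pattern <- function(n_events, window, mean_redetections, sigma_loc) {
  if (mean_redetections <= 1 && sigma_loc <= 0) {
    return(runif_points(n_events, window))
  }
  n_mol <- max(2L, round(n_events / mean_redetections))
  mx <- stats::runif(n_mol, 0, window$width)
  my <- stats::runif(n_mol, 0, window$height)
  blinks <- 1L + stats::rgeom(n_mol, prob = 1 / max(mean_redetections, 1))
  em <- rep(seq_len(n_mol), blinks)
  pts <- tibble::tibble(
    x = mx[em] + stats::rnorm(length(em), 0, sigma_loc),
    y = my[em] + stats::rnorm(length(em), 0, sigma_loc),
    frame = seq_along(em)
  )
  dplyr::filter(pts, .data$x >= 0, .data$x < window$width,
                .data$y >= 0, .data$y < window$height)
}

#' @export
print.nc_threshold <- function(x, ...) {
  cat(sprintf(
    "<threshold> L(%g) > %.1f nm (q%.3g of %d CSR maps at %.3g events/um^2)\n",
    x$r0, x$threshold, x$quantile, x$n_sim, x$event_density))
  invisible(x)
}

#' Build an interpolated local-L cluster map
#'
#' Computes per-event Getis-Franklin `L(r0)` values ([local_l()]) and
#' interpolates them onto a regular pixel grid covering the window (linear
#' interpolation on the Delaunay triangulation of event positions; pixels
#' outside the convex hull of the events are 0). Pixel `(i, j)` is centred at
#' `((i - 1/2) * grid_step, (j - 1/2) * grid_step)` relative to the window
#' origin; the grid has `ceiling(width / grid_step)` columns along x.
#'
#' @param points Localization tibble with `x`, `y` relative to the window
#'   origin (>= 2 events).
#' @param window An [roi()].
#' @param r0 Local-L search radius, nm.
#' @param grid_step Grid spacing, nm (default 10, well below the default
#'   `r0 = 30` so interpolation does not limit resolution).
#' @return An object of class `nc_cluster_map`: list with `values` (matrix
#'   `[ix, iy]` of interpolated L values), `grid_step`, `window`, `r0`, and
#'   `points` (the input with its `l_local` column).
#' @export
build_cluster_map <- function(points, window, r0 = 30, grid_step = 10) {
  if (nrow(points) < 2) {
    stop("build_cluster_map needs at least 2 events", call. = FALSE)
  }
  pts <- local_l(points, window, r0 = r0)
  nx <- ceiling(window$width / grid_step)
  ny <- ceiling(window$height / grid_step)
  xo <- (seq_len(nx) - 0.5) * grid_step
  yo <- (seq_len(ny) - 0.5) * grid_step
  values <- matrix(0, nx, ny)
  if (nrow(pts) >= 3 && .non_collinear(pts$x, pts$y)) {
    g <- interp::interp(pts$x, pts$y, pts$l_local, xo = xo, yo = yo,
                        method = "linear", duplicate = "mean")
    z <- g$z
    z[is.na(z)] <- 0
    values <- z
  }
  structure(list(values = values, grid_step = grid_step, window = window,
                 r0 = r0, points = pts),
            class = "nc_cluster_map")
}

.non_collinear <- function(x, y) {
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(FALSE)
  dx <- x - x[1]; dy <- y - y[1]
  any(abs(dx * dy[2] - dy * dx[2]) > 1e-9 * max(abs(c(dx, dy)), 1))
}

#' @export
print.nc_cluster_map <- function(x, ...) {
  cat(sprintf(
    "<cluster_map> L(%g) on %d x %d grid (%g nm/px), %d events, max %.1f\n",
    x$r0, nrow(x$values), ncol(x$values), x$grid_step, nrow(x$points),
    max(x$values)))
  invisible(x)
}

#' Binarize a cluster map and label nanoclusters
#'
#' Pixels with map value above the threshold form the binary map; its
#' 8-connected components become clusters. Components smaller than `min_area`
#' are discarded. Each event is assigned to the cluster whose pixel footprint
#' contains it (events on sub-threshold pixels stay unclustered).
#'
#' @param map An `nc_cluster_map` from [build_cluster_map()].
#' @param threshold Numeric threshold or an `nc_threshold` from
#'   [calibrate_threshold()].
#' @param min_area Minimum cluster area in nm^2 (default 300, i.e. 3 pixels
#'   at the default 10 nm grid, suppressing single-pixel speckle).
#' @return A tibble with one row per cluster (`id`, `n_pixels`, `area` nm^2,
#'   `centroid_x`, `centroid_y` nm, `n_events`) and attributes `labels`
#'   (integer matrix of pixel labels) and `events` (the map's events with a
#'   `cluster` column, `NA` for unclustered). An empty tibble is valid.
#' @export
binarize_and_label <- function(map, threshold, min_area = 300) {
  stopifnot(inherits(map, "nc_cluster_map"))
  if (inherits(threshold, "nc_threshold")) threshold <- threshold$threshold
  gs <- map$grid_step
  labels <- label_components(map$values > threshold, connectivity = 8)
  px_per_cluster <- tabulate(labels)
  keep <- which(px_per_cluster * gs^2 >= min_area)
  relab <- integer(length(px_per_cluster))
  relab[keep] <- seq_along(keep)
  labels[labels > 0] <- relab[labels[labels > 0]]

  pts <- map$points
  ix <- pmin(pmax(floor(pts$x / gs) + 1L, 1L), nrow(labels))
  iy <- pmin(pmax(floor(pts$y / gs) + 1L, 1L), ncol(labels))
  ev_lab <- labels[cbind(ix, iy)]
  pts$cluster <- ifelse(ev_lab > 0, ev_lab, NA_integer_)

  n_cl <- length(keep)
  if (n_cl == 0) {
    out <- tibble::tibble(id = integer(), n_pixels = integer(),
                          area = numeric(), centroid_x = numeric(),
                          centroid_y = numeric(), n_events = integer())
  } else {
    pix <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[pix]
    cx <- (pix[, 1] - 0.5) * gs
    cy <- (pix[, 2] - 0.5) * gs
    out <- tibble::tibble(
      id = seq_len(n_cl),
      n_pixels = as.integer(tabulate(lab, n_cl)),
      centroid_x = as.numeric(rowsum(cx, lab)) / tabulate(lab, n_cl),
      centroid_y = as.numeric(rowsum(cy, lab)) / tabulate(lab, n_cl),
      n_events = as.integer(tabulate(pts$cluster[!is.na(pts$cluster)], n_cl))
    ) |>
      dplyr::mutate(area = .data$n_pixels * gs^2, .after = "n_pixels")
  }
  attr(out, "labels") <- labels
  attr(out, "events") <- pts
  attr(out, "grid_step") <- gs
  out
}

#' 8- or 4-connected component labeling of a binary grid
#'
#' Two-pass union-find labeling. Foreground pixels sharing an edge (and, for
#' 8-connectivity, a corner) receive the same positive label; background is 0.
#' Labels are renumbered 1..k in first-encounter (column-major) order.
#'
#' @param binary Logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape.
#' @export
label_components <- function(binary, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  b <- binary > 0
  nr <- nrow(b); nc <- ncol(b)
  idx <- which(b)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(lab)
  # union-find over foreground pixels
  parent <- seq_along(idx)
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  r <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(-1L, 0L), c(0L, -1L))
  if (connectivity == 8) offs <- c(offs, list(c(-1L, -1L), c(1L, -1L)))
  for (o in offs) {
    rr <- r + o[1]; cc <- cl + o[2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nb <- (cc[ok] - 1L) * nr + rr[ok]
    ok2 <- which(ok)[pos[nb] > 0]
    nb <- nb[pos[nb] > 0]
    for (t in seq_along(ok2)) union(ok2[t], pos[nb[t]])
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Summarize nanoclusters over an ROI
#'
#' Computes the per-ROI cluster statistics used throughout membrane
#' nanocluster quantification: median and mean cluster area, cluster density,
#' the percentage of events lying in clusters, the relative in-cluster event
#' density (events/nm^2 inside cluster footprints over the overall ROI
#' density), the overall event density, and the fractions of clusters in the
#' size bins `[0, 5000]`, `(5000, 15000]` and `(15000, Inf)` nm^2 (a
#' 5000 nm^2 cluster corresponds to an 80 nm equivalent-circle diameter, a
#' 15000 nm^2 one to 138 nm).
#'
#' @param clusters Cluster tibble from [binarize_and_label()] (same ROI and
#'   events).
#' @param points Localization tibble of the ROI (defaults to the events
#'   attached to `clusters`).
#' @param window The [roi()] the clusters were derived from.
#' @param size_bins Two ascending area cut points, nm^2.
#' @return A one-row tibble: `n_clusters`, `median_area`, `mean_area`,
#'   `clusters_per_um2`, `percent_in_clusters`, `relative_density`,
#'   `event_density`, `frac_small`, `frac_mid`, `frac_large`.
#' @export
summarize_clusters <- function(clusters, points = NULL, window,
                               size_bins = c(5000, 15000)) {
  if (is.null(points)) points <- attr(clusters, "events")
  a_um2 <- roi_area(window) / 1e6
  n_ev <- nrow(points)
  n_cl <- nrow(clusters)
  in_cl <- sum(clusters$n_events)
  cl_area <- sum(clusters$area)
  pct <- if (n_ev > 0) 100 * in_cl / n_ev else NA_real_
  rel <- if (n_ev > 0 && cl_area > 0) {
    (in_cl / cl_area) / (n_ev / roi_area(window))
  } else {
    NA_real_
  }
  fr <- if (n_cl > 0) {
    c(mean(clusters$area <= size_bins[1]),
      mean(clusters$area > size_bins[1] & clusters$area <= size_bins[2]),
      mean(clusters$area > size_bins[2]))
  } else {
    rep(NA_real_, 3)
  }
  tibble::tibble(
    n_clusters = n_cl,
    median_area = if (n_cl) stats::median(clusters$area) else NA_real_,
    mean_area = if (n_cl) mean(clusters$area) else NA_real_,
    clusters_per_um2 = n_cl / a_um2,
    percent_in_clusters = pct,
    relative_density = rel,
    event_density = n_ev / a_um2,
    frac_small = fr[1], frac_mid = fr[2], frac_large = fr[3]
  )
}

#' Equivalent-circle diameter of a cluster area
#'
#' Diameter of the circle with the given area, `d = 2 * sqrt(area / pi)`.
#' The conventional size-bin edges translate as 5000 nm^2 -> 80 nm and
#' 15000 nm^2 -> 138 nm (nearest integer).
#'
#' @param area Area(s), nm^2 (>= 0).
#' @return Diameter(s), nm.
#' @export
#' @examples
#' round(area_to_diameter(c(5000, 15000)))
area_to_diameter <- function(area) {
  if (any(area < 0)) stop("area must be non-negative", call. = FALSE)
  2 * sqrt(area / pi)
}
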