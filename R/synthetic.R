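#' Simulate a clustered SMLM localization table with known truth
#'
#' Generates molecule positions as tight clusters over a uniform (CSR)
#' background, then emulates single-molecule blinking: each molecule is
#' detected `1 + Geometric` times (memoryless re-detection, mean
#' `mean_redetections`), and every detection is jittered independently by
#' isotropic Gaussian localization noise of standard deviation `sigma_loc`.
#' Frames are assigned sequentially. Events are not clipped to the window;
#' crop with [crop_region()] before analysis.
#'
#' Clusters are uniform discs of radius `cluster_radius` by default, so each
#' cluster has the unambiguous true area `pi * cluster_radius^2`;
#' `cluster_shape = "gaussian"` instead draws molecules from an isotropic
#' Gaussian of sd `sigma_c`, whose conventional equivalent area is the
#' 2-sigma footprint `pi * (2 * sigma_c)^2` (the disc holding ~86% of its
#' molecules). The defaults produce the nanocluster regime of receptor SMLM
#' data: ~200 events/um^2 overall in a 3 x 3 um window, ~30% of events in
#' dense clusters, the rest a blinking background. Use [smlm_regime()] to
#' translate target summary statistics into generator arguments.
#'
#' @param n_clusters Number of clusters.
#' @param molecules_per_cluster Mean molecules per cluster (Poisson).
#' @param cluster_radius Disc radius, nm (`cluster_shape = "disc"`). Scalar
#'   or one value per cluster.
#' @param sigma_c Gaussian spread, nm (`cluster_shape = "gaussian"`).
#' @param cluster_shape `"disc"` (default) or `"gaussian"`.
#' @param n_background Number of background molecules (uniform in window).
#' @param mean_redetections Mean detections per molecule (>= 1).
#' @param sigma_loc Localization noise sd, nm.
#' @param window An [roi()]; cluster centres are kept one cluster extent
#'   plus 80 nm from the borders.
#' @param cluster_centers Optional matrix/data frame of cluster centres (nm);
#'   generated uniformly when `NULL`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list with `points` (localization tibble: `x`, `y`, `frame`,
#'   `molecule`, `cluster`; `cluster` is `NA` for background) and `truth`
#'   (generator parameters, per-cluster centres, molecule counts and true
#'   areas).
#' @export
simulate_smlm <- function(n_clusters = 12, molecules_per_cluster = 23.4,
                          cluster_radius = 43.7, sigma_c = 22,
                          cluster_shape = c("disc", "gaussian"),
                          n_background = 630, mean_redetections = 2,
                          sigma_loc = 20, window = roi(),
                          cluster_centers = NULL, seed = NULL) {
  cluster_shape <- match.arg(cluster_shape)
  stopifnot(n_clusters >= 0, molecules_per_cluster >= 0,
            all(cluster_radius > 0), all(sigma_c > 0), n_background >= 0,
            mean_redetections >= 1, sigma_loc >= 0)
  extent <- if (cluster_shape == "disc") {
    rep_len(cluster_radius, max(n_clusters, 1))
  } else {
    3 * rep_len(sigma_c, max(n_clusters, 1))
  }
  margin <- max(extent) + 80
  if (n_clusters > 0 &&
      (window$width <= 2 * margin || window$height <= 2 * margin)) {
    stop("window too small for clusters of extent ", max(extent), " nm",
         call. = FALSE)
  }
  seed <- seed %||% sample.int(2^31 - 1, 1)
  withr::with_seed(seed, {
    if (n_clusters > 0) {
      if (is.null(cluster_centers)) {
        cluster_centers <- cbind(
          stats::runif(n_clusters, margin, window$width - margin),
          stats::runif(n_clusters, margin, window$height - margin))
      } else {
        cluster_centers <- as.matrix(cluster_centers)
        stopifnot(nrow(cluster_centers) == n_clusters)
      }
      n_mol_cl <- stats::rpois(n_clusters, molecules_per_cluster)
    } else {
      cluster_centers <- matrix(numeric(0), 0, 2)
      n_mol_cl <- integer(0)
    }
    cl_id <- rep(seq_len(n_clusters), n_mol_cl)
    if (cluster_shape == "disc") {
      rad <- rep_len(cluster_radius, max(n_clusters, 1))
      rr <- rad[cl_id] * sqrt(stats::runif(length(cl_id)))
      th <- stats::runif(length(cl_id), 0, 2 * pi)
      off_x <- rr * cos(th); off_y <- rr * sin(th)
      true_area <- pi * rad^2
    } else {
      sc <- rep_len(sigma_c, max(n_clusters, 1))
      off_x <- stats::rnorm(length(cl_id), 0, sc[cl_id])
      off_y <- stats::rnorm(length(cl_id), 0, sc[cl_id])
      true_area <- pi * (2 * sc)^2
    }
    mol_x <- c(cluster_centers[cl_id, 1] + off_x,
               stats::runif(n_background, 0, window$width))
    mol_y <- c(cluster_centers[cl_id, 2] + off_y,
               stats::runif(n_background, 0, window$height))
    mol_cl <- c(cl_id, rep(NA_integer_, n_background))
    n_mol <- length(mol_x)

    blinks <- 1L + stats::rgeom(n_mol, prob = 1 / mean_redetections)
    ev_mol <- rep(seq_len(n_mol), blinks)
    n_ev <- length(ev_mol)
    points <- tibble::tibble(
      x = mol_x[ev_mol] + stats::rnorm(n_ev, 0, sigma_loc),
      y = mol_y[ev_mol] + stats::rnorm(n_ev, 0, sigma_loc),
      frame = seq_len(n_ev),
      molecule = ev_mol,
      cluster = mol_cl[ev_mol]
    )
    truth <- list(
      cluster_centers = cluster_centers,
      molecules_per_cluster_realized = n_mol_cl,
      true_area = if (n_clusters > 0) true_area else numeric(0),
      n_clusters = n_clusters,
      molecules_per_cluster = molecules_per_cluster,
      cluster_shape = cluster_shape,
      cluster_radius = cluster_radius, sigma_c = sigma_c,
      n_background = n_background,
      mean_redetections = mean_redetections, sigma_loc = sigma_loc,
      window = window, seed = seed
    )
    list(points = points, truth = truth)
  })
}

#' Translate target summary statistics into SMLM generator arguments
#'
#' Computes [simulate_smlm()] arguments from the summary statistics in which
#' membrane nanocluster data are usually described: the target median cluster
#' area, the overall event density, the fraction of events in clusters, and
#' the in-cluster event density. Defaults emulate receptor nanocluster
#' fields: 200 events/um^2 overall, 30% of events in clusters, and an
#' in-cluster density of 7.8e-3 events/nm^2 — the dense packing produced by
#' antibody labeling and blinking pile-up, which keeps cluster interiors well
#' above any density-matched randomization threshold so that detection is a
#' property of the geometry rather than of shot noise.
#'
#' @param median_area Target true cluster area, nm^2.
#' @param window An [roi()].
#' @param total_density Overall event density, events/um^2.
#' @param frac_clustered Fraction of events belonging to clusters.
#' @param cluster_event_density In-cluster event density, events/nm^2.
#' @param mean_redetections,sigma_loc As in [simulate_smlm()].
#' @return A named list of [simulate_smlm()] arguments.
#' @export
#' @examples
#' args <- smlm_regime(6000)
#' sim <- do.call(simulate_smlm, c(args, seed = 1))
smlm_regime <- function(median_area, window = roi(), total_density = 200,
                        frac_clustered = 0.3,
                        cluster_event_density = 7.8e-3,
                        mean_redetections = 2, sigma_loc = 20) {
  n_events <- total_density * roi_area(window) / 1e6
  events_per_cluster <- cluster_event_density * median_area
  list(
    n_clusters = max(3L, round(frac_clustered * n_events /
                                 events_per_cluster)),
    molecules_per_cluster = events_per_cluster / mean_redetections,
    cluster_radius = sqrt(median_area / pi),
    cluster_shape = "disc",
    n_background = round((1 - frac_clustered) * n_events /
                           mean_redetections),
    mean_redetections = mean_redetections,
    sigma_loc = sigma_loc,
    window = window
  )
}

#' Simulate a two-channel STED-style image pair with known truth
#'
#' Renders `n_spots` uniform discs per channel inside a cell mask, convolves
#' each channel with a Gaussian point-spread function of the stated FWHM, and
#' optionally applies Poisson noise over a constant background. Channel-B
#' discs are displaced from their channel-A partners by `offset` nm in a
#' random direction per pair; `offset = 0` emulates a same-protein positive
#' control, offsets of 150-250 nm emulate juxtaposed (segregated)
#' nanoclusters.
#'
#' @param n_spots Discs per channel.
#' @param spot_radius Disc radius, nm. Scalar or one per spot.
#' @param amplitude Disc intensity (photon-scale). Scalar or one per spot;
#'   channel B uses `amplitude_b` (defaults to `amplitude`).
#' @param amplitude_b Channel-B disc intensity.
#' @param offset Inter-channel centroid offset, nm.
#' @param psf_fwhm Gaussian PSF full width at half maximum, nm.
#' @param pixel_size Pixel size, nm.
#' @param background Constant background level added before noise.
#' @param noise `"poisson"` or `"none"`.
#' @param mask A [cell_mask()]; an inscribed ellipse is generated when
#'   `NULL`.
#' @param dim Image size in pixels (square) when `mask` is `NULL`.
#' @param seed Integer seed.
#' @return A list with `img_a`, `img_b` ([pixel_image()]), `mask`
#'   ([cell_mask()]) and `truth` (disc centres per channel, offsets and all
#'   parameters).
#' @export
simulate_two_channel <- function(n_spots = 12, spot_radius = 60,
                                 amplitude = 100, amplitude_b = amplitude,
                                 offset = 0, psf_fwhm = 80, pixel_size = 20,
                                 background = 2,
                                 noise = c("poisson", "none"),
                                 mask = NULL, dim = 192, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(n_spots >= 1, all(spot_radius > 0), psf_fwhm > 0, pixel_size > 0)
  seed <- seed %||% sample.int(2^31 - 1, 1)
  spot_radius <- rep_len(spot_radius, n_spots)
  amplitude <- rep_len(amplitude, n_spots)
  amplitude_b <- rep_len(amplitude_b, n_spots)
  withr::with_seed(seed, {
    if (is.null(mask)) {
      mask <- make_cell_mask(dim = c(dim, dim), pixel_size = pixel_size,
                             seed = sample.int(2^31 - 1, 1))
    }
    ps <- mask$pixel_size
    stopifnot(ps == pixel_size)
    nx <- nrow(mask$values); ny <- ncol(mask$values)
    # place A centres so that both the A disc and its offset B partner fit
    # fully inside the mask
    centers_a <- matrix(NA_real_, n_spots, 2)
    centers_b <- matrix(NA_real_, n_spots, 2)
    for (s in seq_len(n_spots)) {
      ok <- FALSE
      for (try in seq_len(5000)) {
        ca <- c(stats::runif(1, 0, nx * ps), stats::runif(1, 0, ny * ps))
        th <- stats::runif(1, 0, 2 * pi)
        cb <- ca + offset * c(cos(th), sin(th))
        if (.disc_in_mask(ca, spot_radius[s], mask) &&
            .disc_in_mask(cb, spot_radius[s], mask)) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        stop("could not place disc ", s, " (radius ", spot_radius[s],
             " nm, offset ", offset, " nm) inside the mask", call. = FALSE)
      }
      centers_a[s, ] <- ca
      centers_b[s, ] <- cb
    }
    render <- function(centers, amp) {
      v <- matrix(0, nx, ny)
      px <- (row(v) - 0.5) * ps
      py <- (col(v) - 0.5) * ps
      for (s in seq_len(n_spots)) {
        inside <- (px - centers[s, 1])^2 + (py - centers[s, 2])^2 <=
          spot_radius[s]^2
        v <- v + amp[s] * inside
      }
      v
    }
    sigma_px <- psf_fwhm / (2 * sqrt(2 * log(2))) / ps
    finish <- function(v) {
      v <- gaussian_blur(v, sigma_px) + background
      if (noise == "poisson") {
        v <- matrix(stats::rpois(length(v), v), nrow(v), ncol(v))
      }
      pixel_image(v, ps)
    }
    img_a <- finish(render(centers_a, amplitude))
    img_b <- finish(render(centers_b, amplitude_b))
    truth <- list(centers_a = centers_a, centers_b = centers_b,
                  offset = offset, spot_radius = spot_radius,
                  amplitude = amplitude, amplitude_b = amplitude_b,
                  psf_fwhm = psf_fwhm, pixel_size = pixel_size,
                  background = background, noise = noise, seed = seed)
    list(img_a = img_a, img_b = img_b, mask = mask, truth = truth)
  })
}

.disc_in_mask <- function(center, radius, mask) {
  ps <- mask$pixel_size
  nx <- nrow(mask$values); ny <- ncol(mask$values)
  ix <- floor((center[1] + c(-radius, 0, radius, 0)) / ps) + 1L
  iy <- floor((center[2] + c(0, -radius, 0, radius)) / ps) + 1L
  if (any(ix < 1 | ix > nx | iy < 1 | iy > ny)) return(FALSE)
  all(mask$values[cbind(ix, iy)])
}

#' Separable Gaussian blur of a matrix
#'
#' Direct separable convolution with a truncated (4 sigma) Gaussian kernel
#' and replicated edges.
#'
#' @param values Numeric matrix.
#' @param sigma_px Gaussian sd in pixels; returned unchanged when 0.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(values, sigma_px) {
  if (sigma_px <= 0) return(values)
  k <- ceiling(4 * sigma_px)
  w <- stats::dnorm(-k:k, sd = sigma_px)
  w <- w / sum(w)
  pass <- function(m) { # blur along rows (dim 1)
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m))
    for (o in -k:k) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      acc <- acc + w[o + k + 1] * m[idx, , drop = FALSE]
    }
    acc
  }
  t(pass(t(pass(values))))
}

#' Generate an elliptical cell mask
#'
#' Filled ellipse centred in the image, with optional smooth boundary
#' roughness (low-order harmonic modulation of the radius).
#'
#' @param dim Image size, pixels (`c(nx, ny)` or scalar).
#' @param pixel_size Pixel size, nm.
#' @param semi_axes Ellipse semi-axes, nm; default 80% of the half-image.
#' @param roughness Relative amplitude of the boundary perturbation
#'   (0 = smooth ellipse; keep below ~0.15 to preserve a single component).
#' @param seed Integer seed (used for the roughness harmonics).
#' @return A [cell_mask()].
#' @export
make_cell_mask <- function(dim = 192, pixel_size = 20, semi_axes = NULL,
                           roughness = 0, seed = NULL) {
  dim <- rep_len(dim, 2)
  nx <- dim[1]; ny <- dim[2]
  cx <- nx * pixel_size / 2; cy <- ny * pixel_size / 2
  if (is.null(semi_axes)) semi_axes <- 0.8 * c(cx, cy)
  if (any(semi_axes <= 0)) stop("ellipse axes must be positive", call. = FALSE)
  seed <- seed %||% sample.int(2^31 - 1, 1)
  withr::with_seed(seed, {
    px <- (row(matrix(0, nx, ny)) - 0.5) * pixel_size
    py <- (col(matrix(0, nx, ny)) - 0.5) * pixel_size
    u <- (px - cx) / semi_axes[1]
    v <- (py - cy) / semi_axes[2]
    rr <- sqrt(u^2 + v^2)
    lim <- 1
    if (roughness > 0) {
      th <- atan2(v, u)
      ab <- stats::rnorm(6, 0, 1)
      lim <- 1 + roughness * (
        ab[1] * cos(th) + ab[2] * sin(th) +
        ab[3] * cos(2 * th) + ab[4] * sin(2 * th) +
        ab[5] * cos(3 * th) + ab[6] * sin(3 * th)) / sqrt(6)
    }
    cell_mask(rr <= lim, pixel_size)
  })
}
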