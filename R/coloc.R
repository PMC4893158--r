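#' Pearson co-localization with Costes auto-thresholds
#'
#' Quantifies two-channel co-localization as a Pearson correlation
#' coefficient, ranging from 1 (complete co-localization) to -1 (complete
#' segregation). Thresholds are chosen automatically by the Costes procedure:
#' channel B is regressed on channel A by orthogonal regression of the
#' standardized channels (reduced major axis) over the mask pixels, and the
#' threshold pair is moved down the regression
#' line (bisection on the A threshold) until the Pearson coefficient of the
#' pixels *below* both thresholds is at most zero. The reported coefficient
#' is then computed over mask pixels above threshold in either channel
#' (Coloc 2 convention) or, optionally, over all mask pixels.
#'
#' @param img_a,img_b [pixel_image()]s of identical geometry.
#' @param mask A [cell_mask()] of the same shape.
#' @param use_costes Apply Costes auto-thresholding (default). When `FALSE`
#'   the plain Pearson coefficient over all mask pixels is returned and both
#'   thresholds are reported at the channel minima.
#' @param pixels Pixels entering the final coefficient when thresholding:
#'   `"either_above"` (default) or `"all"`.
#' @return A one-row tibble of class `coloc_result`: `pearson_r`,
#'   `threshold_a`, `threshold_b`, `n_pixels_used`, `n_pixels_mask`.
#' @export
pearson_costes <- function(img_a, img_b, mask, use_costes = TRUE,
                           pixels = c("either_above", "all")) {
  pixels <- match.arg(pixels)
  .check_geometry(img_a, img_b, mask)
  a <- img_a$values[mask$values]
  b <- img_b$values[mask$values]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant channel within the mask: correlation undefined",
         call. = FALSE)
  }
  if (!use_costes) {
    res <- tibble::tibble(pearson_r = stats::cor(a, b),
                          threshold_a = min(a), threshold_b = min(b),
                          n_pixels_used = length(a),
                          n_pixels_mask = length(a))
    class(res) <- c("coloc_result", class(res))
    return(res)
  }
  fit <- .major_axis(a, b)
  th_a <- .costes_search(a, b, fit)
  th_b <- fit$intercept + fit$slope * th_a
  use <- if (pixels == "either_above") a > th_a | b > th_b else rep(TRUE,
                                                                    length(a))
  if (sum(use) < 3 || stats::sd(a[use]) == 0 || stats::sd(b[use]) == 0) {
    stop("too few variable pixels above the Costes thresholds", call. = FALSE)
  }
  res <- tibble::tibble(pearson_r = stats::cor(a[use], b[use]),
                        threshold_a = th_a, threshold_b = th_b,
                        n_pixels_used = sum(use),
                        n_pixels_mask = length(a))
  class(res) <- c("coloc_result", class(res))
  res
}

# orthogonal regression of b on a in standardized coordinates (reduced major
# axis): slope = sign(cov) * sd(b)/sd(a). Unlike the unstandardized major
# axis this is equivariant under affine rescaling of either channel, so the
# Costes threshold pair — and hence the coefficient — is scale-free.
.major_axis <- function(a, b) {
  sab <- stats::cov(a, b)
  slope <- (if (sab < 0) -1 else 1) * stats::sd(b) / stats::sd(a)
  list(slope = slope, intercept = mean(b) - slope * mean(a))
}

# bisection on the A threshold: find the highest threshold whose
# below-threshold pixel set has Pearson <= 0; returns the channel minimum
# when even the full range never reaches a non-positive correlation
.costes_search <- function(a, b, fit, iters = 40) {
  r_below <- function(th_a) {
    th_b <- fit$intercept + fit$slope * th_a
    sel <- a < th_a & b < th_b
    if (sum(sel) < 3) return(NA_real_)
    if (stats::sd(a[sel]) == 0 || stats::sd(b[sel]) == 0) return(0)
    stats::cor(a[sel], b[sel])
  }
  lo <- min(a); hi <- max(a)
  r_lo <- r_below(lo)
  if (!is.na(r_lo) && r_lo > 0) return(lo)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    r <- r_below(mid)
    if (is.na(r) || r <= 0) lo <- mid else hi <- mid
  }
  lo
}

.check_geometry <- function(...) {
  objs <- list(...)
  dims <- lapply(objs, function(o) dim(o$values))
  ps <- vapply(objs, function(o) o$pixel_size, numeric(1))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1 ||
      length(unique(ps)) > 1) {
    stop("images and mask must share shape and pixel size", call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean intensity over the cell mask
#'
#' Arithmetic mean of the pixel intensities inside the mask — the
#' per-pixel fluorescence summary used on raw images to compare, e.g.,
#' membrane recruitment of a signaling protein between conditions.
#'
#' @param img A [pixel_image()].
#' @param mask A [cell_mask()] of the same geometry.
#' @return Mean intensity (scalar).
#' @export
mean_intensity <- function(img, mask) {
  .check_geometry(img, mask)
  mean(img$values[mask$values])
}

#' Binarize an image into clusters within a cell mask
#'
#' Thresholds the (deconvolved) image inside the mask — Otsu's method on the
#' mask-pixel histogram by default, or an absolute threshold — and labels the
#' 8-connected foreground components as clusters with intensity-weighted (or
#' geometric) centroids. Components smaller than `min_area` are discarded.
#'
#' @param img A [pixel_image()].
#' @param mask A [cell_mask()] of the same geometry.
#' @param method `"otsu"` or `"absolute"`.
#' @param threshold Absolute threshold (required for `method = "absolute"`).
#' @param min_area Minimum cluster area, nm^2.
#' @param weighted_centroids Intensity-weighted centroids (default) or
#'   geometric.
#' @return A tibble with one row per cluster (`id`, `n_pixels`, `area` nm^2,
#'   `centroid_x`, `centroid_y` nm, `intensity` summed over the footprint)
#'   and attributes `labels` (pixel label matrix), `threshold` and
#'   `pixel_size`. Empty foreground gives an empty tibble.
#' @export
binarize_image_clusters <- function(img, mask, method = c("otsu", "absolute"),
                                    threshold = NULL, min_area = 0,
                                    weighted_centroids = TRUE) {
  method <- match.arg(method)
  .check_geometry(img, mask)
  ps <- img$pixel_size
  if (method == "otsu") {
    threshold <- otsu_threshold(img$values[mask$values])
  } else if (is.null(threshold)) {
    stop("method = 'absolute' needs a threshold", call. = FALSE)
  }
  fg <- img$values > threshold & mask$values
  labels <- label_components(fg, connectivity = 8)
  n0 <- max(labels)
  keep <- which(tabulate(labels, n0) * ps^2 >= min_area)
  relab <- integer(n0)
  relab[keep] <- seq_along(keep)
  labels[labels > 0] <- relab[labels[labels > 0]]
  n_cl <- length(keep)
  if (n_cl == 0) {
    out <- tibble::tibble(id = integer(), n_pixels = integer(),
                          area = numeric(), centroid_x = numeric(),
                          centroid_y = numeric(), intensity = numeric())
  } else {
    pix <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[pix]
    w <- if (weighted_centroids) img$values[pix] else rep(1, nrow(pix))
    cx <- (pix[, 1] - 0.5) * ps
    cy <- (pix[, 2] - 0.5) * ps
    wsum <- as.numeric(rowsum(w, lab))
    out <- tibble::tibble(
      id = seq_len(n_cl),
      n_pixels = as.integer(tabulate(lab, n_cl)),
      centroid_x = as.numeric(rowsum(w * cx, lab)) / wsum,
      centroid_y = as.numeric(rowsum(w * cy, lab)) / wsum,
      intensity = as.numeric(rowsum(img$values[pix], lab))
    ) |>
      dplyr::mutate(area = .data$n_pixels * ps^2, .after = "n_pixels")
  }
  attr(out, "labels") <- labels
  attr(out, "threshold") <- threshold
  attr(out, "pixel_size") <- ps
  out
}

#' Otsu threshold of an intensity sample
#'
#' Classic between-class-variance maximisation on a 256-bin histogram,
#' applicable to an arbitrary subset of pixels (e.g. the cell-mask pixels
#' only). Returns a threshold on the intensity scale of the input; pixels
#' strictly above it are foreground.
#'
#' @param values Numeric vector of intensities.
#' @param n_bins Histogram bins.
#' @return Threshold (scalar).
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  valid <- w0 > 0 & w0 < 1
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!valid] <- -Inf
  best <- which(bcv == max(bcv))  # flat maxima (empty valley): take middle
  br[round(mean(best)) + 1]
}

#' Nearest-neighbour distances between two sets of cluster centroids
#'
#' For each cluster in `clusters_a`, the Euclidean distance to the nearest
#' centroid in `clusters_b`, plus the per-cell median — the standard summary
#' of how closely two nanocluster populations approach each other.
#'
#' @param clusters_a,clusters_b Cluster tibbles with `centroid_x`,
#'   `centroid_y` (nm); both non-empty.
#' @return A tibble (one row per cluster of A: `id`, `distance`, `nearest_b`)
#'   with attribute `median_distance`.
#' @export
centroid_distances <- function(clusters_a, clusters_b) {
  if (nrow(clusters_a) == 0) stop("no clusters in set A", call. = FALSE)
  if (nrow(clusters_b) == 0) {
    stop("no partner clusters in set B: nearest-centroid distance undefined",
         call. = FALSE)
  }
  d2 <- outer(clusters_a$centroid_x, clusters_b$centroid_x, "-")^2 +
    outer(clusters_a$centroid_y, clusters_b$centroid_y, "-")^2
  nn <- apply(d2, 1, which.min)
  out <- tibble::tibble(
    id = clusters_a$id,
    distance = sqrt(d2[cbind(seq_len(nrow(d2)), nn)]),
    nearest_b = clusters_b$id[nn]
  )
  attr(out, "median_distance") <- stats::median(out$distance)
  out
}
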