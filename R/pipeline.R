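#' Analysis configuration
#'
#' Bundles every tunable parameter of the localization and image pipelines so
#' that results can be reproduced from their serialized configuration alone.
#'
#' @param r0 Local-L search radius, nm.
#' @param grid_step Cluster-map grid spacing, nm.
#' @param threshold_quantile,threshold_n_sim Calibration quantile and number
#'   of null simulations ([calibrate_threshold()]).
#' @param null_redetections,null_sigma_loc Blinking statistics of the
#'   calibration null; the defaults (1, 0) give plain CSR events. Match these
#'   to the acquisition's re-detection behaviour when analyzing SMLM data
#'   with multiple detections per fluorophore.
#' @param min_area Minimum cluster area, nm^2.
#' @param size_bins Cluster-size bin edges, nm^2.
#' @param roi_size Side of the square analysis ROI, nm.
#' @param search_radius Association search radius, nm.
#' @param n_null_reps Replicates of the association randomization null.
#' @param sted_min_area Minimum image-cluster area, nm^2.
#' @param seed Integer seed governing calibration and null randomness.
#' @return A list of class `nc_config`.
#' @export
analysis_config <- function(r0 = 30, grid_step = 10,
                            threshold_quantile = 0.99, threshold_n_sim = 50,
                            null_redetections = 1, null_sigma_loc = 0,
                            min_area = 300, size_bins = c(5000, 15000),
                            roi_size = 3000, search_radius = 500,
                            n_null_reps = 100, sted_min_area = 0,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "nc_config")
}

#' @export
print.nc_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (n in names(x)) cat(sprintf("  %-18s %s\n", n,
                                  paste(x[[n]], collapse = ", ")))
  invisible(x)
}

#' Analyze one SMLM cell: ROIs to cluster statistics
#'
#' Runs the localization pipeline for each ROI of a cell: crop, calibrate the
#' local-L threshold at the ROI's event density, build the interpolated
#' cluster map, binarize and label nanoclusters, and summarize them. Per-cell
#' values are the means over ROIs; ROIs with fewer than 2 events are skipped
#' with a warning.
#'
#' @param points Localization tibble of the whole cell (nm coordinates).
#' @param rois A list of [roi()]s (or a single one).
#' @param config An [analysis_config()].
#' @return An object of class `gsd_analysis`: list with `per_roi` (one row
#'   per ROI of [summarize_clusters()] output plus the calibrated threshold),
#'   `clusters` (all clusters, with an `roi` column), `per_cell` (one-row
#'   tibble of means over ROIs), and `config`. `tidy()` returns `per_roi`,
#'   `glance()` returns `per_cell`.
#' @export
analyze_gsd_cell <- function(points, rois, config = analysis_config()) {
  if (inherits(rois, "nc_roi")) rois <- list(rois)
  stopifnot(length(rois) >= 1)
  per_roi <- list(); clusters <- list()
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    pts <- crop_region(points, r)
    if (nrow(pts) < 2) {
      warning("ROI ", i, " has fewer than 2 events; skipped", call. = FALSE)
      next
    }
    win <- roi(0, 0, r$width, r$height)
    dens <- nrow(pts) / (roi_area(win) / 1e6)
    th <- calibrate_threshold(
      dens, win, r0 = config$r0, grid_step = config$grid_step,
      n_sim = config$threshold_n_sim, quantile = config$threshold_quantile,
      seed = config$seed + i,
      mean_redetections = config$null_redetections,
      sigma_loc = config$null_sigma_loc)
    map <- build_cluster_map(pts, win, r0 = config$r0,
                             grid_step = config$grid_step)
    cl <- binarize_and_label(map, th, min_area = config$min_area)
    stats_row <- summarize_clusters(cl, window = win,
                                    size_bins = config$size_bins)
    per_roi[[length(per_roi) + 1]] <-
      dplyr::mutate(stats_row, roi = i, threshold = th$threshold,
                    .before = 1)
    if (nrow(cl)) {
      clusters[[length(clusters) + 1]] <- dplyr::mutate(
        tibble::as_tibble(cl), roi = i, .before = 1)
    }
  }
  if (!length(per_roi)) stop("no ROI with at least 2 events", call. = FALSE)
  per_roi <- dplyr::bind_rows(per_roi)
  per_cell <- per_roi |>
    dplyr::summarise(dplyr::across(!dplyr::any_of(c("roi", "threshold")),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_rois = dplyr::n())
  structure(list(per_roi = per_roi,
                 clusters = dplyr::bind_rows(clusters),
                 per_cell = per_cell, config = config),
            class = "gsd_analysis")
}

#' Analyze one STED cell: co-localization, geometry and association
#'
#' Runs the two-channel image pipeline: binarize both channels inside the
#' cell mask (Otsu), compute the Costes-thresholded Pearson coefficient and
#' nearest-centroid distances, split channel-A (receptor) clusters into size
#' tertiles, screen for nearby channel-B (signaling) clusters, and estimate
#' the chance-association null by randomizing the signaling footprints
#' within the mask.
#'
#' @param img_a Receptor-channel [pixel_image()].
#' @param img_b Signaling-channel [pixel_image()].
#' @param mask A [cell_mask()].
#' @param config An [analysis_config()].
#' @return An object of class `sted_analysis`: list with `coloc`,
#'   `clusters_a`, `clusters_b`, `distances`, `association`, `null`,
#'   `size_effect`, `config`. `tidy()` returns the per-cluster association
#'   table, `glance()` a one-row cell summary.
#' @export
analyze_sted_cell <- function(img_a, img_b, mask,
                              config = analysis_config()) {
  step <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(what, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  coloc <- step("pearson_costes", pearson_costes(img_a, img_b, mask))
  cl_a <- step("binarize channel A",
               binarize_image_clusters(img_a, mask,
                                       min_area = config$sted_min_area))
  cl_b <- step("binarize channel B",
               binarize_image_clusters(img_b, mask,
                                       min_area = config$sted_min_area))
  distances <- if (nrow(cl_a) && nrow(cl_b)) {
    centroid_distances(cl_a, cl_b)
  }
  cl_a <- step("assign_tertiles", assign_tertiles(cl_a))
  assoc <- step("screen_association",
                screen_association(cl_a, cl_b, img_b,
                                   search_radius = config$search_radius))
  null <- step("randomize_null",
               randomize_null(cl_a, cl_b, img_b, mask,
                              search_radius = config$search_radius,
                              n_reps = config$n_null_reps,
                              seed = config$seed))
  structure(list(coloc = coloc, clusters_a = cl_a, clusters_b = cl_b,
                 distances = distances, association = assoc, null = null,
                 size_effect = size_effect_summary(assoc, null),
                 config = config),
            class = "sted_analysis")
}

#' @export
print.gsd_analysis <- function(x, ...) {
  cat(sprintf("<gsd_analysis> %d ROI(s), %d clusters\n",
              nrow(x$per_roi), nrow(x$clusters)))
  print(x$per_cell)
  invisible(x)
}

#' @export
print.sted_analysis <- function(x, ...) {
  cat(sprintf(
    "<sted_analysis> pearson_r = %.3f; %d receptor / %d signaling clusters; %.0f%% associated\n",
    x$coloc$pearson_r, nrow(x$clusters_a), nrow(x$clusters_b),
    100 * mean(x$association$associated)))
  print(x$size_effect)
  invisible(x)
}

#' @rdname tidy.group_comparison
#' @method tidy gsd_analysis
#' @export
tidy.gsd_analysis <- function(x, ...) x$per_roi

#' @rdname tidy.group_comparison
#' @method glance gsd_analysis
#' @export
glance.gsd_analysis <- function(x, ...) x$per_cell

#' @rdname tidy.group_comparison
#' @method tidy sted_analysis
#' @export
tidy.sted_analysis <- function(x, ...) tibble::as_tibble(x$association)

#' @rdname tidy.group_comparison
#' @method glance sted_analysis
#' @export
glance.sted_analysis <- function(x, ...) {
  tibble::tibble(
    pearson_r = x$coloc$pearson_r,
    median_centroid_distance =
      if (!is.null(x$distances)) attr(x$distances, "median_distance")
      else NA_real_,
    n_receptor = nrow(x$clusters_a),
    n_signaling = nrow(x$clusters_b),
    frac_associated = mean(x$association$associated)
  )
}

#' Serialize an analysis to JSON with full provenance
#'
#' Writes the analysis results together with the complete configuration and
#' the package version, so that two runs with identical configuration and
#' seeds produce byte-identical files.
#'
#' @param x A `gsd_analysis` or `sted_analysis`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  payload <- if (inherits(x, "gsd_analysis")) {
    list(kind = "gsd", per_roi = x$per_roi, per_cell = x$per_cell,
         clusters = x$clusters)
  } else if (inherits(x, "sted_analysis")) {
    list(kind = "sted", coloc = x$coloc,
         association = tibble::as_tibble(x$association),
         size_effect = x$size_effect,
         null = tibble::as_tibble(x$null))
  } else {
    stop("unsupported analysis object", call. = FALSE)
  }
  payload$config <- unclass(x$config)
  payload$package_version <- as.character(utils::packageVersion("nanoclustr"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
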