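#' Split receptor clusters into size tertiles
#'
#' Ranks clusters by area and labels the lowest third `small`, the middle
#' third `medium`, and the top third `large`. When the cluster count is not
#' divisible by three the remainder goes to the smallest bins first (7
#' clusters give bin sizes 3/2/2); ties in area are broken by input order.
#' Tertiles are computed over *all* clusters of a cell, and association
#' fractions are reported among associated clusters afterwards.
#'
#' @param clusters Cluster tibble with an `area` column (>= 3 rows).
#' @return The tibble with an added ordered-factor `tertile` column
#'   (`small < medium < large`) and attribute `tertile_boundaries` (the two
#'   area cut points, nm^2).
#' @export
assign_tertiles <- function(clusters) {
  n <- nrow(clusters)
  if (n < 3) {
    stop("tertiles undefined for fewer than 3 clusters", call. = FALSE)
  }
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1, rem >= 2, 0)
  lab <- rep(c("small", "medium", "large"), times = sizes)
  ord <- order(clusters$area)  # stable: ties keep input order
  tert <- character(n)
  tert[ord] <- lab
  out <- dplyr::mutate(
    clusters,
    tertile = factor(tert, levels = c("small", "medium", "large"),
                     ordered = TRUE))
  bnd <- c(max(clusters$area[ord][seq_len(sizes[1])]),
           max(clusters$area[ord][seq_len(sizes[1] + sizes[2])]))
  attr(out, "tertile_boundaries") <- bnd
  for (a in c("labels", "pixel_size"))
    attr(out, a) <- attr(clusters, a)
  out
}

#' Screen receptor clusters for nearby signaling clusters
#'
#' For each receptor cluster, screens a circular area of radius
#' `search_radius` around its centroid for the presence of signaling-cluster
#' pixels: the cluster is *associated* when any pixel of any signaling
#' cluster lies within the circle. The nearby signal intensity is the sum of
#' the signaling image over the circle (or over every whole signaling cluster
#' touching it, with `intensity = "whole_cluster"`). `mode = "edge"` measures
#' the search radius from the receptor cluster footprint instead of its
#' centroid, which makes chance association explicitly size-dependent.
#'
#' @param receptor_clusters Cluster tibble (from [binarize_and_label()] or
#'   [binarize_image_clusters()], ideally after [assign_tertiles()]).
#' @param signaling_clusters Cluster tibble carrying its `labels` attribute.
#' @param signaling_img [pixel_image()] of the signaling channel (same
#'   geometry as the cluster maps); `NULL` skips intensity quantification.
#' @param search_radius Search radius, nm. The value is a free analysis
#'   parameter; it is recorded in the output and should be reported alongside
#'   any result.
#' @param mode `"centroid"` (default) or `"edge"`.
#' @param intensity `"in_circle"` (default) or `"whole_cluster"`.
#' @return An object of class `association_result`: the receptor tibble with
#'   added `associated` and `nearby_intensity` columns, plus attributes
#'   `search_radius`, `mode` and `summary` (a one-row tibble: `n_receptor`,
#'   `n_signaling`, `frac_associated`, and `frac_small`, `frac_medium`,
#'   `frac_large` — the shares of associated clusters falling in each
#'   tertile, summing to 1 when any cluster is associated).
#' @export
screen_association <- function(receptor_clusters, signaling_clusters,
                               signaling_img = NULL, search_radius = 500,
                               mode = c("centroid", "edge"),
                               intensity = c("in_circle", "whole_cluster")) {
  mode <- match.arg(mode)
  intensity <- match.arg(intensity)
  if (nrow(receptor_clusters) == 0) {
    stop("no receptor clusters to screen", call. = FALSE)
  }
  if (search_radius <= 0) stop("search_radius must be positive",
                               call. = FALSE)
  sig_px <- .cluster_pixel_coords(signaling_clusters)
  if (!"tertile" %in% names(receptor_clusters) &&
      nrow(receptor_clusters) >= 3) {
    receptor_clusters <- assign_tertiles(receptor_clusters)
  }
  out <- .screen_core(receptor_clusters, sig_px, signaling_img,
                      search_radius, mode, intensity,
                      rec_labels = attr(receptor_clusters, "labels"),
                      grid_step = .cluster_grid_step(receptor_clusters))
  attr(out, "search_radius") <- search_radius
  attr(out, "mode") <- mode
  attr(out, "summary") <- .association_summary(out, sig_px)
  class(out) <- c("association_result", class(out))
  out
}

# signaling pixels as a data frame: cluster id, centre coordinates (nm),
# pixel intensity slot filled by callers that carry an image
.cluster_pixel_coords <- function(clusters) {
  labels <- attr(clusters, "labels")
  if (is.null(labels)) {
    stop("cluster tibble lacks its 'labels' attribute; pass the object ",
         "returned by binarize_and_label()/binarize_image_clusters()",
         call. = FALSE)
  }
  ps <- .cluster_grid_step(clusters)
  pix <- which(labels > 0, arr.ind = TRUE)
  data.frame(id = labels[pix], ix = pix[, 1], iy = pix[, 2],
             x = (pix[, 1] - 0.5) * ps, y = (pix[, 2] - 0.5) * ps)
}

.cluster_grid_step <- function(clusters) {
  attr(clusters, "pixel_size") %||% attr(clusters, "grid_step")
}

.screen_core <- function(rec, sig_px, signaling_img, search_radius, mode,
                         intensity, rec_labels = NULL, grid_step = NULL) {
  n <- nrow(rec)
  associated <- rep(FALSE, n)
  nearby <- rep(NA_real_, n)
  if (nrow(sig_px)) {
    if (mode == "centroid") {
      d2 <- outer(rec$centroid_x, sig_px$x, "-")^2 +
        outer(rec$centroid_y, sig_px$y, "-")^2
      associated <- apply(d2 <= search_radius^2, 1, any)
    } else {
      if (is.null(rec_labels)) {
        stop("mode = 'edge' needs receptor pixel footprints", call. = FALSE)
      }
      rpx <- which(rec_labels > 0, arr.ind = TRUE)
      rid <- rec_labels[rpx]
      rx <- (rpx[, 1] - 0.5) * grid_step
      ry <- (rpx[, 2] - 0.5) * grid_step
      d2 <- outer(rx, sig_px$x, "-")^2 + outer(ry, sig_px$y, "-")^2
      hit <- apply(d2 <= search_radius^2, 1, any)
      associated <- vapply(rec$id, function(i) any(hit[rid == i]),
                           logical(1))
    }
  }
  if (!is.null(signaling_img)) {
    nearby <- .nearby_intensity(rec, sig_px, signaling_img, search_radius,
                                intensity)
  }
  dplyr::mutate(rec, associated = associated, nearby_intensity = nearby)
}

.nearby_intensity <- function(rec, sig_px, img, search_radius, intensity) {
  ps <- img$pixel_size
  nx <- nrow(img$values); ny <- ncol(img$values)
  vapply(seq_len(nrow(rec)), function(i) {
    cx <- rec$centroid_x[i]; cy <- rec$centroid_y[i]
    if (intensity == "whole_cluster") {
      if (!nrow(sig_px)) return(0)
      d2 <- (sig_px$x - cx)^2 + (sig_px$y - cy)^2
      ids <- unique(sig_px$id[d2 <= search_radius^2])
      sel <- sig_px$id %in% ids
      return(sum(img$values[cbind(sig_px$ix[sel], sig_px$iy[sel])]))
    }
    ix <- max(1, floor((cx - search_radius) / ps)):
      min(nx, ceiling((cx + search_radius) / ps))
    iy <- max(1, floor((cy - search_radius) / ps)):
      min(ny, ceiling((cy + search_radius) / ps))
    px <- (rep(ix, times = length(iy)) - 0.5) * ps
    py <- (rep(iy, each = length(ix)) - 0.5) * ps
    inside <- (px - cx)^2 + (py - cy)^2 <= search_radius^2
    sum(img$values[ix, iy][inside])
  }, numeric(1))
}

.association_summary <- function(res, sig_px) {
  n_assoc <- sum(res$associated)
  fr <- if ("tertile" %in% names(res) && n_assoc > 0) {
    as.numeric(table(res$tertile[res$associated]) / n_assoc)
  } else {
    rep(NA_real_, 3)
  }
  tibble::tibble(
    n_receptor = nrow(res),
    n_signaling = length(unique(sig_px$id)),
    frac_associated = n_assoc / nrow(res),
    frac_small = fr[1], frac_medium = fr[2], frac_large = fr[3]
  )
}

#' Randomization null for cluster association
#'
#' Estimates chance association by rigidly translating every
#' signaling-cluster pixel footprint (with its intensity patch) to a uniform
#' random position fully inside the cell mask, re-screening against the fixed
#' receptor clusters, and repeating `n_reps` times. Each replicate preserves
#' the number, shapes and areas of the signaling clusters exactly; randomized
#' clusters may overlap one another. Under this null the per-cluster nearby
#' intensity counts translated cluster pixels only (the diffuse background
#' has no randomized position).
#'
#' @inheritParams screen_association
#' @param mask A [cell_mask()] delimiting the cell area.
#' @param n_reps Number of null replicates.
#' @param seed Integer seed; the null is bit-reproducible given the seed.
#' @return An object of class `null_distribution`: a tibble with one row per
#'   replicate (`rep`, `frac_associated`, `frac_small/medium/large` — shares
#'   of associated clusters per tertile — and `p_small/p_medium/p_large` —
#'   per-tertile association probabilities), with attributes `search_radius`,
#'   `mode` and `per_cluster` (matrix of association indicators, replicates
#'   in rows).
#' @export
randomize_null <- function(receptor_clusters, signaling_clusters,
                           signaling_img = NULL, mask, search_radius = 500,
                           n_reps = 100, mode = c("centroid", "edge"),
                           seed = NULL) {
  mode <- match.arg(mode)
  if (!"tertile" %in% names(receptor_clusters) &&
      nrow(receptor_clusters) >= 3) {
    receptor_clusters <- assign_tertiles(receptor_clusters)
  }
  sig_px <- .cluster_pixel_coords(signaling_clusters)
  if (!is.null(signaling_img)) {
    sig_px$value <- signaling_img$values[cbind(sig_px$ix, sig_px$iy)]
  }
  ps <- .cluster_grid_step(signaling_clusters)
  nx <- nrow(mask$values); ny <- ncol(mask$values)
  mask_idx <- which(mask$values, arr.ind = TRUE)
  ids <- unique(sig_px$id)
  foot <- lapply(ids, function(i) {
    p <- sig_px[sig_px$id == i, ]
    list(dx = p$ix - p$ix[1], dy = p$iy - p$iy[1],
         value = p$value %||% rep(0, nrow(p)))
  })
  grid_step <- .cluster_grid_step(receptor_clusters)
  seed <- seed %||% sample.int(2^31 - 1, 1)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      placed <- lapply(seq_along(foot), function(fi) {
        f <- foot[[fi]]
        for (try in seq_len(10000)) {
          anchor <- mask_idx[sample.int(nrow(mask_idx), 1), ]
          ix <- anchor[1] + f$dx; iy <- anchor[2] + f$dy
          if (all(ix >= 1 & ix <= nx & iy >= 1 & iy <= ny) &&
              all(mask$values[cbind(ix, iy)])) {
            return(data.frame(id = ids[fi], ix = ix, iy = iy,
                              x = (ix - 0.5) * ps, y = (iy - 0.5) * ps,
                              value = f$value))
          }
        }
        stop("signaling cluster ", ids[fi],
             " cannot be placed inside the mask", call. = FALSE)
      })
      do.call(rbind, placed)
    })
  })
  per_cluster <- matrix(NA, n_reps, nrow(receptor_clusters))
  rows <- lapply(seq_len(n_reps), function(r) {
    px <- reps[[r]]
    res <- .screen_core(receptor_clusters, px, signaling_img = NULL,
                        search_radius, mode, "in_circle",
                        rec_labels = attr(receptor_clusters, "labels"),
                        grid_step = grid_step)
    if (!is.null(signaling_img)) {
      res$nearby_intensity <- .null_nearby_intensity(res, px, search_radius)
    }
    per_cluster[r, ] <<- res$associated
    s <- .association_summary(res, px)
    pt <- if ("tertile" %in% names(res)) {
      tapply(res$associated, res$tertile, mean)
    } else {
      c(small = NA, medium = NA, large = NA)
    }
    tibble::tibble(rep = r, frac_associated = s$frac_associated,
                   frac_small = s$frac_small, frac_medium = s$frac_medium,
                   frac_large = s$frac_large,
                   p_small = pt[["small"]], p_medium = pt[["medium"]],
                   p_large = pt[["large"]],
                   median_nearby = stats::median(res$nearby_intensity))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "search_radius") <- search_radius
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "per_cluster") <- per_cluster
  class(out) <- c("null_distribution", class(out))
  out
}

.null_nearby_intensity <- function(rec, px, search_radius) {
  vapply(seq_len(nrow(rec)), function(i) {
    d2 <- (px$x - rec$centroid_x[i])^2 + (px$y - rec$centroid_y[i])^2
    sum(px$value[d2 <= search_radius^2])
  }, numeric(1))
}

#' Observed-versus-null association summary by size tertile
#'
#' Per tertile: the observed share of associated receptor clusters, the mean
#' share under the randomization null, their difference, the observed and
#' null per-tertile association probabilities, and the observed median
#' nearby signal intensity. A positive difference concentrated in one
#' tertile indicates association beyond what cluster geometry alone
#' produces.
#'
#' @param observed An `association_result` from [screen_association()].
#' @param null A `null_distribution` from [randomize_null()] computed on the
#'   same cell.
#' @return A tibble with one row per tertile.
#' @export
size_effect_summary <- function(observed, null) {
  stopifnot(inherits(observed, "association_result"),
            inherits(null, "null_distribution"))
  s <- attr(observed, "summary")
  obs_fr <- c(s$frac_small, s$frac_medium, s$frac_large)
  null_fr <- c(mean(null$frac_small, na.rm = TRUE),
               mean(null$frac_medium, na.rm = TRUE),
               mean(null$frac_large, na.rm = TRUE))
  obs_p <- tapply(observed$associated, observed$tertile, mean)
  null_p <- c(mean(null$p_small), mean(null$p_medium), mean(null$p_large))
  med_int <- tapply(observed$nearby_intensity, observed$tertile,
                    stats::median)
  tibble::tibble(
    tertile = factor(c("small", "medium", "large"),
                     levels = c("small", "medium", "large"), ordered = TRUE),
    observed_frac = obs_fr,
    null_frac = null_fr,
    frac_difference = obs_fr - null_fr,
    observed_p = as.numeric(obs_p),
    null_p = null_p,
    median_nearby_intensity = as.numeric(med_int)
  )
}
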