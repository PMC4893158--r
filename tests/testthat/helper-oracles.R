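# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain double loops and breadth-first search.

# Ripley K by direct double loop; weights = 1 (for interior configurations)
brute_ripley_k <- function(points, radii, window) {
  n <- nrow(points)
  a <- window$width * window$height
  vapply(radii, function(r) {
    s <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) {
          d <- sqrt((points$x[i] - points$x[j])^2 +
                    (points$y[i] - points$y[j])^2)
          if (d <= r) s <- s + 1
        }
      }
    }
    a * s / (n * (n - 1))
  }, numeric(1))
}

# per-event neighbour counts within r0, double loop
brute_neighbor_counts <- function(points, r0) {
  n <- nrow(points)
  k <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        d <- sqrt((points$x[i] - points$x[j])^2 +
                  (points$y[i] - points$y[j])^2)
        if (d <= r0) k[i] <- k[i] + 1L
      }
    }
  }
  k
}

# BFS flood fill labeling
flood_fill_label <- function(binary, connectivity = 8) {
  b <- binary > 0
  nr <- nrow(b); nc <- ncol(b)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (b[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        queue <- list(c(i, j))
        lab[i, j] <- cur
        while (length(queue)) {
          p <- queue[[1]]; queue <- queue[-1]
          for (o in seq_len(nrow(offs))) {
            ii <- p[1] + offs[o, 1]; jj <- p[2] + offs[o, 2]
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                b[ii, jj] && lab[ii, jj] == 0L) {
              lab[ii, jj] <- cur
              queue[[length(queue) + 1]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  lab
}

# labels equal up to renumbering?
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  !anyDuplicated(unique(cbind(a[fg], b[fg]))[, 1]) &&
    !anyDuplicated(unique(cbind(a[fg], b[fg]))[, 2])
}

# exhaustive nearest-centroid distances
brute_nn_distances <- function(ax, ay, bx, by) {
  vapply(seq_along(ax), function(i) {
    min(sqrt((ax[i] - bx)^2 + (ay[i] - by)^2))
  }, numeric(1))
}

# association flags by pixel-by-pixel distance checks
brute_association <- function(centroids_x, centroids_y, labels, pixel_size,
                              radius) {
  pix <- which(labels > 0, arr.ind = TRUE)
  px <- (pix[, 1] - 0.5) * pixel_size
  py <- (pix[, 2] - 0.5) * pixel_size
  vapply(seq_along(centroids_x), function(i) {
    any(sqrt((px - centroids_x[i])^2 + (py - centroids_y[i])^2) <= radius)
  }, logical(1))
}

# tiny deterministic clustered pattern for map tests
tight_cluster_points <- function(center = c(500, 500), n = 40, spread = 25,
                                 n_bg = 30, window = roi(0, 0, 1000, 1000),
                                 seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      x = c(stats::rnorm(n, center[1], spread),
            stats::runif(n_bg, 0, window$width)),
      y = c(stats::rnorm(n, center[2], spread),
            stats::runif(n_bg, 0, window$height)),
      frame = seq_len(n + n_bg)
    )
  })
}
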