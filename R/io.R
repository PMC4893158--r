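#' Column dialect for localization tables
#'
#' A dialect maps the package's canonical localization columns (`x`, `y`,
#' `frame`, `intensity`, `uncertainty`) to the column headers used by a
#' particular localization software export. The default is the ThunderSTORM
#' CSV export ("x \[nm\]", "y \[nm\]", ...). `x` and `y` are mandatory; the
#' remaining columns are optional and silently skipped when absent from the
#' file.
#'
#' @param x,y,frame,intensity,uncertainty Column headers in the file.
#' @return A named list usable as the `dialect` argument of
#'   [read_localizations()].
#' @export
#' @examples
#' thunderstorm_dialect()
#' # a minimal x/y export:
#' dialect(x = "x", y = "y")
thunderstorm_dialect <- function() {
  dialect(
    x = "x [nm]", y = "y [nm]", frame = "frame",
    intensity = "intensity [photon]", uncertainty = "uncertainty [nm]"
  )
}

#' @rdname thunderstorm_dialect
#' @export
dialect <- function(x = "x", y = "y", frame = NULL, intensity = NULL,
                    uncertainty = NULL) {
  d <- list(x = x, y = y, frame = frame, intensity = intensity,
            uncertainty = uncertainty)
  d[!vapply(d, is.null, logical(1))]
}

#' Read a localization table
#'
#' Reads a CSV table of single-molecule localization events (one row per
#' detected blink) and returns a tibble in the package's canonical form:
#' columns `x` and `y` in nanometres plus whichever of `frame`, `intensity`
#' and `uncertainty` the file provides. Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param dialect Named column mapping, see [thunderstorm_dialect()].
#' @param unit Unit of the coordinate columns in the file; `"um"` coordinates
#'   are converted to nm on loading.
#' @return A tibble of localization events with coordinates in nm.
#' @export
read_localizations <- function(path, dialect = thunderstorm_dialect(),
                               unit = c("nm", "um")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) {
    stop("localization file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("x", "y")) {
    if (!dialect[[col]] %in% names(raw)) {
      stop("mandatory column '", dialect[[col]], "' (", col,
           ") missing from ", path, call. = FALSE)
    }
  }
  present <- dialect[vapply(dialect, function(h) h %in% names(raw), logical(1))]
  out <- tibble::as_tibble(stats::setNames(raw[unlist(present)], names(present)))
  for (col in c("x", "y")) {
    v <- out[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric ", col, " coordinate at row ",
           if (length(bad)) bad[1] else NA, call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop("non-finite ", col, " coordinate at row ",
           which(!is.finite(v))[1], call. = FALSE)
    }
  }
  scale <- if (unit == "um") 1000 else 1
  dplyr::mutate(out, x = .data$x * scale, y = .data$y * scale)
}

#' Write a localization table
#'
#' Inverse of [read_localizations()]: writes the canonical tibble back to CSV
#' using the given dialect's column headers, always in nm.
#'
#' @param points Localization tibble with nm coordinates.
#' @param path Output CSV path.
#' @inheritParams read_localizations
#' @return `path`, invisibly.
#' @export
write_localizations <- function(points, path,
                                dialect = thunderstorm_dialect()) {
  keep <- intersect(names(dialect), names(points))
  out <- stats::setNames(points[keep], unlist(dialect[keep]))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Rectangular region of interest
#'
#' An ROI is an axis-aligned rectangle in nm, anchored at its lower-left
#' corner. The default 3000 x 3000 nm matches the 3 x 3 um analysis tiles
#' conventionally used for membrane nanocluster quantification.
#'
#' @param x0,y0 Lower-left corner, nm.
#' @param width,height Side lengths, nm (must be positive).
#' @return An object of class `nc_roi`.
#' @export
roi <- function(x0 = 0, y0 = 0, width = 3000, height = 3000) {
  stopifnot(is.numeric(x0), is.numeric(y0), width > 0, height > 0)
  structure(list(x0 = x0, y0 = y0, width = width, height = height),
            class = "nc_roi")
}

#' @export
print.nc_roi <- function(x, ...) {
  cat(sprintf("<roi> [%g, %g) x [%g, %g) nm (%g x %g nm)\n",
              x$x0, x$x0 + x$width, x$y0, x$y0 + x$height,
              x$width, x$height))
  invisible(x)
}

#' @rdname roi
#' @param roi An `nc_roi`.
#' @return `roi_area()`: the ROI area in nm^2.
#' @export
roi_area <- function(roi) roi$width * roi$height

#' Read and write ROIs as JSON
#'
#' A single ROI is stored as a JSON object; a list of ROIs as a JSON array.
#'
#' @param path JSON file path.
#' @return `read_rois()` returns a list of `nc_roi` objects.
#' @export
read_rois <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$x0)) x <- list(x)
  lapply(x, function(r) roi(r$x0, r$y0, r$width, r$height))
}

#' @rdname read_rois
#' @param rois A single `nc_roi` or a list of them.
#' @export
write_rois <- function(rois, path) {
  if (inherits(rois, "nc_roi")) rois <- list(rois)
  jsonlite::write_json(lapply(rois, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Crop a localization table to an ROI
#'
#' Retains events with `x0 <= x < x0 + width` and `y0 <= y < y0 + height`
#' (half-open, consistent with grid binning) and re-expresses coordinates
#' relative to the ROI origin. An empty result is valid.
#'
#' @param points Localization tibble (nm coordinates).
#' @param roi An [roi()].
#' @return The cropped tibble, coordinates relative to the ROI lower-left
#'   corner.
#' @export
crop_region <- function(points, roi) {
  stopifnot(inherits(roi, "nc_roi"))
  points |>
    dplyr::filter(.data$x >= roi$x0, .data$x < roi$x0 + roi$width,
                  .data$y >= roi$y0, .data$y < roi$y0 + roi$height) |>
    dplyr::mutate(x = .data$x - roi$x0, y = .data$y - roi$y0)
}

#' Pixel images and cell masks
#'
#' A `pixel_image` is a 2-D non-negative intensity grid with a square pixel
#' size in nm; a `cell_mask` is a logical grid of the same form. The package
#' stores grids as matrices indexed `[ix, iy]`, with pixel `(1, 1)` covering
#' `[0, pixel_size)` in both axes and the origin at the lower-left of the
#' field, so image pixels, ROI coordinates and localization coordinates share
#' one convention.
#'
#' @param values Numeric matrix (non-negative) or logical matrix for masks.
#' @param pixel_size Pixel side length, nm (> 0; pixels are square).
#' @return An object of class `nc_image` or `nc_mask`.
#' @export
pixel_image <- function(values, pixel_size) {
  stopifnot(is.matrix(values), pixel_size > 0)
  if (any(values < 0)) stop("pixel intensities must be non-negative",
                            call. = FALSE)
  structure(list(values = values, pixel_size = pixel_size),
            class = "nc_image")
}

#' @rdname pixel_image
#' @export
cell_mask <- function(values, pixel_size) {
  stopifnot(is.matrix(values), pixel_size > 0)
  values <- values > 0
  if (!any(values)) stop("cell mask has no foreground pixels", call. = FALSE)
  structure(list(values = values, pixel_size = pixel_size),
            class = "nc_mask")
}

#' @export
print.nc_image <- function(x, ...) {
  cat(sprintf("<pixel_image> %d x %d px, %g nm/px, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.nc_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d px, %g nm/px, %d foreground px\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              sum(x$values)))
  invisible(x)
}

# TIFF stores top-left-origin [row, col] grids in [0, 1]; the package stores
# lower-left-origin [ix, iy] grids in physical units. The conversion and the
# intensity scale live here and in the JSON sidecar written next to the file.
.to_tiff <- function(values) t(values)[rev(seq_len(ncol(values))), , drop = FALSE]
.from_tiff <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

#' Read and write grayscale TIFF images and masks
#'
#' Images are written as single-channel TIFFs with intensities scaled into
#' `[0, 1]`; the scale factor and the pixel size are recorded in a JSON
#' sidecar (`<path>.json`) so that `read_image()` restores physical values.
#' Integer-valued images round-trip exactly (16-bit storage). Masks are
#' written as 8-bit binary TIFFs.
#'
#' @param path TIFF file path.
#' @param pixel_size Pixel size in nm; taken from the sidecar when `NULL`.
#' @return `read_image()`: a [pixel_image()]; `read_mask()`: a [cell_mask()].
#' @export
read_image <- function(path, pixel_size = NULL) {
  m <- tiff::readTIFF(path, all = TRUE)
  if (length(m) > 1) {
    stop("multi-image TIFF; supply a single-channel file", call. = FALSE)
  }
  m <- m[[1]]
  if (length(dim(m)) == 3) {
    if (dim(m)[3] > 1) {
      stop("multi-channel TIFF without a channel selector; ",
           "supply a grayscale file", call. = FALSE)
    }
    m <- m[, , 1]
  }
  meta <- .read_sidecar(path)
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size
  if (is.null(pixel_size)) {
    stop("pixel_size not given and no sidecar found for ", path,
         call. = FALSE)
  }
  scale <- meta$scale %||% 1
  values <- .from_tiff(m) * scale
  if (isTRUE(meta$integer)) values <- round(values)
  pixel_image(values, pixel_size)
}

#' @rdname read_image
#' @param img A [pixel_image()].
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "nc_image"))
  v <- img$values
  int <- all(v == round(v)) && max(v) < 2^16
  scale <- if (int) 2^16 - 1 else max(v, 1)
  tiff::writeTIFF(.to_tiff(v / scale), path,
                  bits.per.sample = if (int) 16L else 32L)
  .write_sidecar(path, list(pixel_size = img$pixel_size, scale = scale,
                            integer = int))
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path, pixel_size = NULL) {
  img <- read_image(path, pixel_size)
  cell_mask(img$values > 0.5, img$pixel_size)
}

#' @rdname read_image
#' @param mask A [cell_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "nc_mask"))
  tiff::writeTIFF(.to_tiff(mask$values * 1), path, bits.per.sample = 8L)
  .write_sidecar(path, list(pixel_size = mask$pixel_size, scale = 1,
                            integer = TRUE))
  invisible(path)
}

.sidecar_path <- function(path) paste0(path, ".json")

.read_sidecar <- function(path) {
  sc <- .sidecar_path(path)
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else list()
}

.write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
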