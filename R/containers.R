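#' ramanem: epigenetic-modification mapping from Raman hyperspectral data
#'
#' The package chains spectral preprocessing, convolutional classification of
#' pixel spectra into nucleus/cytoplasm/stroma, reference-spectrum correlation
#' scoring, quartile-based modification calling, volcano-plot spectral peak
#' analysis, group-level semi-quantification and low-dimensional embeddings
#' into one reproducible pipeline, and ships a synthetic-data generator with
#' known ground truth against which every stage is validated.
#'
#' @keywords internal
"_PACKAGE"

## ---- wavenumber grids -------------------------------------------------------

#' Validate a wavenumber grid
#'
#' A grid is a strictly ascending vector of finite, positive wavenumbers
#' (cm^-1). Spectra loaded from files whose grid is stored descending are
#' reordered before they reach this check.
#'
#' @param values numeric vector of wavenumbers.
#' @return the validated grid, invisibly.
#' @export
validate_grid <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("wavenumber grid must be a numeric vector with at least 2 points")
  if (anyNA(values) || any(!is.finite(values)))
    stop("wavenumber grid contains non-finite values")
  if (any(values <= 0))
    stop("wavenumber grid contains non-positive values")
  if (any(diff(values) <= 0))
    stop("wavenumber grid must be strictly ascending")
  invisible(values)
}

## ---- hyperspectral map ------------------------------------------------------

#' Construct a hyperspectral map
#'
#' The central container: per-pixel Raman spectra on one shared wavenumber
#' grid, with integer pixel coordinates. Coordinates are 0-based, `x` is the
#' column and `y` the row, origin top-left; the physical pixel pitch
#' (`step_size`, in micrometres) is carried as metadata only.
#'
#' @param wavenumber shared grid (cm^-1); reordered ascending if needed.
#' @param intensity numeric matrix, one row per pixel, one column per grid
#'   point.
#' @param x,y integer pixel coordinates, one per row of `intensity`.
#' @param width,height map dimensions in pixels; inferred as `max(x) + 1` /
#'   `max(y) + 1` when omitted.
#' @param step_size physical pixel pitch in micrometres.
#' @param metadata free-form named list.
#' @return an object of class `hypermap`.
#' @export
hypermap <- function(wavenumber, intensity, x, y,
                     width = NULL, height = NULL,
                     step_size = 1, metadata = list()) {
  intensity <- as.matrix(intensity)
  if (is.unsorted(wavenumber, strictly = TRUE)) {
    ord <- order(wavenumber)
    wavenumber <- wavenumber[ord]
    intensity <- intensity[, ord, drop = FALSE]
  }
  validate_grid(wavenumber)
  if (ncol(intensity) != length(wavenumber))
    stop("intensity matrix has ", ncol(intensity),
         " columns but grid has ", length(wavenumber), " points")
  if (length(x) != nrow(intensity) || length(y) != nrow(intensity))
    stop("x/y coordinate length does not match the number of spectra")
  if (any(x != floor(x)) || any(y != floor(y)) || any(x < 0) || any(y < 0))
    stop("pixel coordinates must be non-negative integers")
  x <- as.integer(x); y <- as.integer(y)
  if (anyDuplicated(paste(x, y)))
    stop("duplicate pixel coordinates in map")
  if (is.null(width)) width <- max(x) + 1L
  if (is.null(height)) height <- max(y) + 1L
  if (any(x >= width) || any(y >= height))
    stop("pixel coordinates exceed the declared map dimensions")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("map intensities contain non-finite values")
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 x = x, y = y,
                 width = as.integer(width), height = as.integer(height),
                 step_size = step_size, metadata = metadata),
            class = "hypermap")
}

#' @export
print.hypermap <- function(x, ...) {
  cat(sprintf("<hypermap> %d spectra (%d x %d px), %d wavenumbers [%.1f, %.1f] cm^-1\n",
              nrow(x$intensity), x$width, x$height, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Number of pixel spectra in a map
#' @param map a `hypermap`.
#' @return integer count.
#' @export
n_pixels <- function(map) nrow(map$intensity)

#' Restrict a map to a wavenumber window
#'
#' @param map a `hypermap`.
#' @param lo,hi window bounds in cm^-1 (inclusive).
#' @return a `hypermap` on the clipped grid.
#' @export
restrict_window <- function(map, lo = 600, hi = 1900) {
  keep <- map$wavenumber >= lo & map$wavenumber <= hi
  if (sum(keep) < 2L) stop("window [", lo, ", ", hi, "] overlaps fewer than 2 grid points")
  hypermap(map$wavenumber[keep], map$intensity[, keep, drop = FALSE],
           map$x, map$y, map$width, map$height, map$step_size, map$metadata)
}

## ---- reference spectrum -----------------------------------------------------

#' Construct a labelled reference spectrum
#'
#' One wavenumber/intensity curve for one molecular species or DNA
#' conformation. Canonical labels used throughout the pipeline are
#' `DNA`, `DNA-m`, `Lys`, `Lys-m`, `Lys-a`, `Arg`, `Arg-m`, `B-DNA`,
#' `Z-DNA`; user-defined labels are allowed.
#'
#' @param label nonempty species identifier.
#' @param wavenumber grid (cm^-1); reordered ascending if needed.
#' @param intensity numeric vector, one value per grid point.
#' @return an object of class `ref_spectrum`.
#' @export
ref_spectrum <- function(label, wavenumber, intensity) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("reference label must be a nonempty string")
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity lengths differ")
  dup <- duplicated(wavenumber)
  if (any(dup))
    stop("duplicated wavenumber in reference: ", wavenumber[dup][1L])
  if (is.unsorted(wavenumber, strictly = TRUE)) {
    ord <- order(wavenumber)
    wavenumber <- wavenumber[ord]
    intensity <- intensity[ord]
  }
  validate_grid(wavenumber)
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("reference intensities contain non-finite values")
  structure(list(label = label, wavenumber = wavenumber,
                 intensity = as.numeric(intensity)),
            class = "ref_spectrum")
}

#' @export
print.ref_spectrum <- function(x, ...) {
  cat(sprintf("<ref_spectrum> '%s', %d points [%.1f, %.1f] cm^-1\n",
              x$label, length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

## ---- class map --------------------------------------------------------------

#' Construct a per-pixel tissue-class map
#'
#' Labels follow the classifier's convention: 0 = stroma/empty, 1 = nucleus,
#' 2 = cytoplasm.
#'
#' @param labels integer vector in `{0, 1, 2}`, one per pixel.
#' @param x,y pixel coordinates matching the parent map.
#' @param width,height parent map dimensions.
#' @return an object of class `class_map`.
#' @export
class_map <- function(labels, x, y, width = max(x) + 1L, height = max(y) + 1L) {
  labels <- as.integer(labels)
  if (length(labels) != length(x) || length(x) != length(y))
    stop("labels and coordinates must have equal length")
  if (anyNA(labels) || !all(labels %in% 0:2))
    stop("class labels must all lie in {0, 1, 2}")
  if (anyDuplicated(paste(x, y)))
    stop("duplicate pixel coordinates in class map")
  structure(list(labels = labels, x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height)),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2,
                      labels = c("stroma/empty", "nucleus", "cytoplasm")))
  cat(sprintf("<class_map> %d x %d px: %s\n", x$width, x$height,
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

## internal: check a class map is aligned with a hypermap pixel-for-pixel
check_alignment <- function(map, classmap) {
  if (!identical(map$x, classmap$x) || !identical(map$y, classmap$y))
    stop("class map pixels are not aligned with the hyperspectral map")
  invisible(TRUE)
}
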