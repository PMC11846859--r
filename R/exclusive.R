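## Binary modification-status calling via the 3rd-quartile cutoff, exclusive
## spectra selection, and multiplexed overlay rendering.

MOD_LABELS <- c("DNA-m", "Lys-m", "Lys-a", "Arg-m")
ALL_STATUS_LABELS <- c("DNA", "DNA-m", "Lys", "Lys-m", "Lys-a", "Arg", "Arg-m")

#' Call binary modification status over nucleus pixels
#'
#' For each reference label, the cutoff is the 3rd quartile (by default) of
#' that label's correlation scores computed over nucleus pixels only
#' (linear-interpolation quantile); a nucleus pixel is called positive for
#' the label iff its score is at or above the cutoff (ties positive). The
#' 0.75 default is the value that performed best among cutoffs from 0.50 to
#' 0.95.
#'
#' @param corr_maps named list of [correlation_map()] results, one per
#'   reference label (names default to each map's `reference_label`).
#' @param classmap a [class_map()] aligned with the correlation maps.
#' @param quantile cutoff quantile in `(0, 1)`, default 0.75.
#' @return an object of class `status_table`: a data frame with `x`, `y` and
#'   one 0/1 column per label, rows = nucleus pixels; cutoffs in
#'   `attr(, "cutoffs")`.
#' @export
call_status <- function(corr_maps, classmap, quantile = 0.75) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  if (is.null(names(corr_maps)) || any(!nzchar(names(corr_maps))))
    names(corr_maps) <- vapply(corr_maps, `[[`, "", "reference_label")
  for (cm in corr_maps) {
    if (!identical(cm$x, classmap$x) || !identical(cm$y, classmap$y))
      stop("correlation maps and class map do not share one pixel set")
  }
  nuc <- which(classmap$labels == 1L)
  if (!length(nuc)) stop("empty domain: class map contains no nucleus pixels")
  out <- data.frame(x = classmap$x[nuc], y = classmap$y[nuc])
  cutoffs <- numeric(length(corr_maps))
  names(cutoffs) <- names(corr_maps)
  for (lab in names(corr_maps)) {
    sc <- corr_maps[[lab]]$raw[nuc]
    cutoffs[lab] <- stats::quantile(sc, quantile, type = 7, names = FALSE)
    out[[lab]] <- as.integer(sc >= cutoffs[lab])
  }
  structure(out, cutoffs = cutoffs, quantile = quantile,
            class = c("status_table", "data.frame"))
}

#' Extract the exclusive spectra of one modification
#'
#' An exclusive pixel for a modification is positive for the modification
#' AND its base species (DNA for DNA-m, Lys for Lys-m/Lys-a, Arg for Arg-m)
#' and negative for every other modification; multi-positive spectra are
#' deliberately discarded. An empty result is valid.
#'
#' @param status a [call_status()] table covering all seven labels.
#' @param modification one of `DNA-m`, `Lys-m`, `Lys-a`, `Arg-m`.
#' @param map optional preprocessed [hypermap()]; if given, the member
#'   spectra are attached.
#' @return an object of class `exclusive_set` with `modification`, `pixels`
#'   (x/y data frame) and optionally `spectra`.
#' @export
extract_exclusive <- function(status, modification, map = NULL) {
  if (!modification %in% MOD_LABELS)
    stop("unknown modification label: ", modification)
  need <- setdiff(ALL_STATUS_LABELS, names(status))
  if (length(need))
    stop("status table is missing labels: ", paste(need, collapse = ", "))
  base <- base_species(modification)
  others <- setdiff(MOD_LABELS, modification)
  member <- status[[modification]] == 1L & status[[base]] == 1L
  for (o in others) member <- member & status[[o]] == 0L
  pixels <- status[member, c("x", "y"), drop = FALSE]
  rownames(pixels) <- NULL
  spectra <- NULL
  if (!is.null(map) && nrow(pixels)) {
    idx <- match(paste(pixels$x, pixels$y), paste(map$x, map$y))
    if (anyNA(idx)) stop("exclusive pixels missing from the supplied map")
    spectra <- map$intensity[idx, , drop = FALSE]
  }
  structure(list(modification = modification, pixels = pixels,
                 spectra = spectra, n = nrow(pixels)),
            class = "exclusive_set")
}

#' Extract base-only spectra (unmodified counterpart of an exclusive set)
#'
#' Pixels positive for a base species (DNA, Lys or Arg) and negative for all
#' four modifications; the comparison group for volcano-plot peak analysis.
#'
#' @param status a [call_status()] table covering all seven labels.
#' @param base one of `DNA`, `Lys`, `Arg`.
#' @param map optional map to attach spectra.
#' @return an `exclusive_set` whose `modification` field is `<base>-only`.
#' @export
extract_base_only <- function(status, base, map = NULL) {
  if (!base %in% c("DNA", "Lys", "Arg")) stop("unknown base species: ", base)
  need <- setdiff(ALL_STATUS_LABELS, names(status))
  if (length(need))
    stop("status table is missing labels: ", paste(need, collapse = ", "))
  member <- status[[base]] == 1L
  for (o in MOD_LABELS) member <- member & status[[o]] == 0L
  pixels <- status[member, c("x", "y"), drop = FALSE]
  rownames(pixels) <- NULL
  spectra <- NULL
  if (!is.null(map) && nrow(pixels)) {
    idx <- match(paste(pixels$x, pixels$y), paste(map$x, map$y))
    spectra <- map$intensity[idx, , drop = FALSE]
  }
  structure(list(modification = paste0(base, "-only"), pixels = pixels,
                 spectra = spectra, n = nrow(pixels)),
            class = "exclusive_set")
}

#' @export
print.exclusive_set <- function(x, ...) {
  cat(sprintf("<exclusive_set> %s: %d pixel(s)%s\n", x$modification, x$n,
              if (is.null(x$spectra)) "" else " (spectra attached)"))
  invisible(x)
}

#' Default overlay colours per modification
#' @return named colour vector.
#' @export
modification_palette <- function() {
  c("DNA-m" = "blue", "Lys-m" = "magenta", "Lys-a" = "green", "Arg-m" = "cyan")
}

#' Compose a multiplexed overlay of modification levels on a base heatmap
#'
#' The base DNA correlation heatmap is rendered in greyscale; each
#' modification contributes a coloured layer whose per-pixel opacity scales
#' with the modification's normalised score, drawn only on pixels that are
#' positive for the modification and its base species (levels are only
#' determined where the base is present).
#'
#' @param base_corr the base [correlation_map()] (typically DNA, Pearson).
#' @param status a [call_status()] table.
#' @param em_levels named list of [correlation_map()]s, one per modification
#'   to overlay.
#' @param palette overlay colours.
#' @return list with `image` (height x width x 3 RGB array) and `alpha`
#'   (named list of height x width opacity matrices, 0 = transparent).
#' @export
overlay_multiplex <- function(base_corr, status, em_levels,
                              palette = modification_palette()) {
  h <- base_corr$height; w <- base_corr$width
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3)
    img[cbind(base_corr$y + 1L, base_corr$x + 1L, ch)] <- base_corr$norm
  alphas <- list()
  key_corr <- paste(base_corr$x, base_corr$y)
  for (mod in names(em_levels)) {
    if (!mod %in% MOD_LABELS) stop("unknown modification label: ", mod)
    lv <- em_levels[[mod]]
    a <- matrix(0, h, w)
    pos <- status[[mod]] == 1L & status[[base_species(mod)]] == 1L
    if (any(pos)) {
      idx <- match(paste(status$x[pos], status$y[pos]), key_corr)
      a[cbind(status$y[pos] + 1L, status$x[pos] + 1L)] <- lv$norm[idx]
    }
    rgb <- grDevices::col2rgb(palette[[mod]]) / 255
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer <- (1 - a) * layer + a * rgb[ch]
      img[, , ch] <- layer
    }
    alphas[[mod]] <- a
  }
  list(image = img, alpha = alphas)
}
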