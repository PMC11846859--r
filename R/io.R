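## Reading and writing the delimited interchange formats.
##
## Wide table:  row 1 = "x,y,<w1>,<w2>,..."; rows 2+ = one pixel each.
## Long table:  header "x,y,wavenumber,intensity"; one row per (pixel, point).
## Reference:   "# label: <name>" comment line, then "wavenumber,intensity".
## All comma-delimited UTF-8; text is the normative on-disk format.

#' Read a hyperspectral map from a delimited spectral table
#'
#' @param path file path.
#' @param format `"wide"` (row 1 wavenumbers, one pixel per subsequent row) or
#'   `"long"` (rows of x, y, wavenumber, intensity).
#' @return a validated [hypermap()]; the grid is ascending after load and
#'   intensities are reordered to match, regardless of file order.
#' @export
read_map <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "wide") read_map_wide(path) else read_map_long(path)
}

read_map_wide <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("wide-table map needs a header and >= 1 pixel row: ", path)
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (length(header) < 4L || trimws(header[1L]) != "x" || trimws(header[2L]) != "y")
    stop("wide-table header must start with 'x,y' followed by wavenumbers (line 1)")
  wn <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(wn)) stop("non-numeric wavenumber in wide-table header (line 1)")
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  nf <- lengths(body)
  bad <- which(nf != length(header))
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, ": expected ",
         length(header), " fields, found ", nf[bad[1L]])
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(length(header))))
  nav <- which(colSums(is.na(vals)) > 0)
  if (length(nav)) stop("non-numeric value at line ", nav[1L] + 1L)
  vals <- t(vals)
  hypermap(wn, vals[, -(1:2), drop = FALSE], vals[, 1L], vals[, 2L])
}

read_map_long <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric", fileEncoding = "UTF-8"),
    warning = function(w) stop("malformed long-table map: ", conditionMessage(w)),
    error = function(e) stop("malformed long-table map: ", conditionMessage(e)))
  need <- c("x", "y", "wavenumber", "intensity")
  if (!all(need %in% names(df)))
    stop("long-table map must have columns ", paste(need, collapse = ", "))
  if (anyNA(df)) stop("non-numeric value at line ",
                      which(rowSums(is.na(df)) > 0)[1L] + 1L)
  wn <- sort(unique(df$wavenumber))
  key <- paste(df$x, df$y)
  pix <- unique(key)
  per <- table(key)
  if (any(per != length(wn)))
    stop("inconsistent wavenumber grids across pixels in ", path)
  xy <- do.call(rbind, strsplit(pix, " ", fixed = TRUE))
  mat <- matrix(NA_real_, length(pix), length(wn))
  row_i <- match(key, pix)
  col_i <- match(df$wavenumber, wn)
  if (anyDuplicated(cbind(row_i, col_i)))
    stop("duplicate (pixel, wavenumber) records in ", path)
  mat[cbind(row_i, col_i)] <- df$intensity
  hypermap(wn, mat, as.numeric(xy[, 1L]), as.numeric(xy[, 2L]))
}

#' Write a hyperspectral map to a delimited spectral table
#'
#' @param map a [hypermap()].
#' @param path output path.
#' @param format `"wide"` or `"long"`; see [read_map()].
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    header <- paste(c("x", "y", format(map$wavenumber, digits = 10, trim = TRUE,
                                       scientific = FALSE)), collapse = ",")
    rows <- apply(cbind(map$x, map$y, map$intensity), 1L, function(r)
      paste(format(r, digits = 10, trim = TRUE, scientific = FALSE), collapse = ","))
    writeLines(c(header, rows), path, useBytes = TRUE)
  } else {
    n <- n_pixels(map); m <- length(map$wavenumber)
    df <- data.frame(x = rep(map$x, each = m), y = rep(map$y, each = m),
                     wavenumber = rep(map$wavenumber, times = n),
                     intensity = as.vector(t(map$intensity)))
    utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a labelled reference spectrum
#'
#' Expects a `# label: <name>` header line followed by a
#' `wavenumber,intensity` table.
#'
#' @param path file path.
#' @return a validated [ref_spectrum()] on an ascending grid.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lab_line <- grep("^#\\s*label\\s*:", lines)
  if (!length(lab_line)) stop("reference file lacks a '# label: <name>' header: ", path)
  label <- trimws(sub("^#\\s*label\\s*:", "", lines[lab_line[1L]]))
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  body <- body[!grepl("^\\s*wavenumber\\s*,", body)]  # optional column header
  if (length(body) < 8L)
    stop("degenerate reference (", length(body), " points, need >= 8): ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed row at line ", which(lengths(parts) != 2L)[1L], " of ", path)
  wn <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  iv <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(wn) || anyNA(iv))
    stop("non-numeric cell in reference file ", path)
  ref_spectrum(label, wn, iv)
}

#' Write a labelled reference spectrum
#'
#' @param ref a [ref_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  writeLines(c(paste0("# label: ", ref$label), "wavenumber,intensity",
               paste(format(ref$wavenumber, digits = 10, trim = TRUE, scientific = FALSE),
                     format(ref$intensity, digits = 10, trim = TRUE, scientific = FALSE),
                     sep = ",")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Resample a spectrum onto a target wavenumber grid
#'
#' Linear interpolation; no extrapolation is performed, so the target range
#' must lie inside the source range. Reference spectra acquired on a
#' different instrument grid are brought onto the map grid with this before
#' any correlation scoring.
#'
#' @param wavenumber,intensity source curve (ascending grid).
#' @param target ascending target grid (cm^-1).
#' @return intensity vector of `length(target)`.
#' @export
resample_spectrum <- function(wavenumber, intensity, target) {
  validate_grid(target)
  if (min(target) < min(wavenumber) || max(target) > max(wavenumber))
    stop(sprintf("target range [%.2f, %.2f] extends beyond source range [%.2f, %.2f]",
                 min(target), max(target), min(wavenumber), max(wavenumber)))
  stats::approx(wavenumber, intensity, xout = target, method = "linear")$y
}

#' Resample a reference spectrum onto a map's grid window
#'
#' Clips to the intersection of the map grid, the reference range and the
#' fingerprint window, then interpolates.
#'
#' @param ref a [ref_spectrum()].
#' @param map a [hypermap()].
#' @param window fingerprint analysis window, cm^-1.
#' @return list with `wavenumber` (the common grid) and `intensity`.
#' @export
align_reference <- function(ref, map, window = c(600, 1900)) {
  keep <- map$wavenumber >= max(window[1L], min(ref$wavenumber)) &
    map$wavenumber <= min(window[2L], max(ref$wavenumber))
  if (sum(keep) < 8L)
    stop("empty or degenerate overlap between reference '", ref$label,
         "' and map grid within the analysis window")
  wn <- map$wavenumber[keep]
  list(wavenumber = wn,
       intensity = resample_spectrum(ref$wavenumber, ref$intensity, wn),
       keep = keep)
}
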