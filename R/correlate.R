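## Reference-spectrum similarity scoring: five metrics, per-pixel correlation
## heatmaps with per-map 0-1 normalisation, and the quantitative
## metric-comparison study.

#' The five supported similarity metrics
#' @return character vector of metric names.
#' @export
similarity_metrics <- function() {
  c("pearson", "spearman", "euclidean-unit-norm",
    "cosine-squared", "first-difference-cosine-squared")
}

cosine_sq <- function(a, b) {
  den <- sum(a^2) * sum(b^2)
  if (den <= 0) stop("zero-norm input under cosine similarity")
  sum(a * b)^2 / den
}

#' Score the similarity of two spectra
#'
#' Pearson and Spearman are correlations in `[-1, 1]`; the squared cosine
#' similarities lie in `[0, 1]`; the unit-normalised Euclidean metric is a
#' distance (lower = more similar, >= 0). Pearson is the pipeline default
#' for tissue work.
#'
#' @param a,b numeric vectors on the same grid (resample first).
#' @param metric one of [similarity_metrics()].
#' @return a single numeric score.
#' @export
similarity <- function(a, b, metric = "pearson") {
  metric <- match.arg(metric, similarity_metrics())
  if (length(a) != length(b)) stop("spectra must share one grid")
  if (metric %in% c("pearson", "spearman")) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("undefined correlation: constant input spectrum")
  }
  switch(metric,
         "pearson" = stats::cor(a, b),
         "spearman" = stats::cor(a, b, method = "spearman"),
         "euclidean-unit-norm" = sqrt(sum((a / sqrt(sum(a^2)) -
                                             b / sqrt(sum(b^2)))^2)),
         "cosine-squared" = cosine_sq(a, b),
         "first-difference-cosine-squared" = cosine_sq(diff(a), diff(b)))
}

## vectorised per-pixel raw scores of every map row against one reference
raw_scores <- function(X, r, metric) {
  switch(metric,
         "pearson" = drop(stats::cor(t(X), r)),
         "spearman" = drop(stats::cor(t(X), r, method = "spearman")),
         "euclidean-unit-norm" = {
           U <- X / sqrt(rowSums(X^2))
           v <- r / sqrt(sum(r^2))
           sqrt(rowSums(sweep(U, 2L, v)^2))
         },
         "cosine-squared" = drop(X %*% r)^2 / (rowSums(X^2) * sum(r^2)),
         "first-difference-cosine-squared" = {
           D <- t(diff(t(X)))
           dr <- diff(r)
           drop(D %*% dr)^2 / (rowSums(D^2) * sum(dr^2))
         })
}

#' Correlate every pixel of a map with a reference spectrum
#'
#' The reference is resampled onto the map grid restricted to the common
#' fingerprint window, each pixel is scored, and the scores are min-max
#' normalised over the map to `[0, 1]`. Distance-type metrics are
#' sign-flipped before normalisation so a higher normalised score always
#' means more similar. If every pixel scores identically the normalisation
#' is degenerate: normalised scores are set to 0.5 and the map is flagged.
#'
#' @param map a preprocessed [hypermap()].
#' @param reference a [ref_spectrum()].
#' @param metric one of [similarity_metrics()].
#' @param window fingerprint analysis window (cm^-1).
#' @return an object of class `corr_map` with per-pixel `raw` and `norm`
#'   scores.
#' @export
correlation_map <- function(map, reference, metric = "pearson",
                            window = c(600, 1900)) {
  metric <- match.arg(metric, similarity_metrics())
  al <- align_reference(reference, map, window)
  X <- map$intensity[, al$keep, drop = FALSE]
  raw <- raw_scores(X, al$intensity, metric)
  if (anyNA(raw))
    stop("undefined scores for ", sum(is.na(raw)), " pixel(s) (constant spectra?)")
  oriented <- if (metric == "euclidean-unit-norm") -raw else raw
  rng <- range(oriented)
  degenerate <- diff(rng) <= 0
  norm <- if (degenerate) rep(0.5, length(raw))
          else (oriented - rng[1L]) / diff(rng)
  structure(list(reference_label = reference$label, metric = metric,
                 raw = raw, norm = norm, x = map$x, y = map$y,
                 width = map$width, height = map$height,
                 grid_range = range(al$wavenumber),
                 higher_is_similar = metric != "euclidean-unit-norm",
                 degenerate = degenerate),
            class = "corr_map")
}

#' @export
print.corr_map <- function(x, ...) {
  cat(sprintf("<corr_map> ref '%s', metric %s, %d pixels, raw [%.3f, %.3f]%s\n",
              x$reference_label, x$metric, length(x$raw), min(x$raw), max(x$raw),
              if (x$degenerate) " (degenerate normalisation)" else ""))
  invisible(x)
}

#' Compare the five similarity metrics on a ground-truthed map
#'
#' Operationalises metric choice as a contrast statistic: for each metric,
#' the difference between the mean normalised score over nucleus pixels and
#' over non-nucleus pixels, for a DNA-type reference. A larger separation
#' means a crisper nucleus heatmap.
#'
#' @param map a preprocessed [hypermap()].
#' @param reference a [ref_spectrum()] (typically DNA).
#' @param truth ground-truth [class_map()] (synthetic).
#' @param window analysis window.
#' @return data frame with one row per metric: `metric`, `separation`.
#' @export
compare_metrics <- function(map, reference, truth, window = c(600, 1900)) {
  if (missing(truth) || !inherits(truth, "class_map"))
    stop("compare_metrics requires a ground-truth class_map")
  check_alignment(map, truth)
  nuc <- truth$labels == 1L
  if (!any(nuc) || all(nuc)) stop("ground truth must contain nucleus and non-nucleus pixels")
  sep <- vapply(similarity_metrics(), function(m) {
    cm <- correlation_map(map, reference, m, window)
    mean(cm$norm[nuc]) - mean(cm$norm[!nuc])
  }, numeric(1L))
  data.frame(metric = similarity_metrics(), separation = unname(sep),
             row.names = NULL)
}
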