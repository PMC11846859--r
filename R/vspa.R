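## Volcano-plot-based spectral peak analysis (VSPA): per-peak log2 fold
## change between two spectrum groups with two-sided Mann-Whitney
## significance, and the significant-peaks plot data.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test with midranks. For group sizes both <= `exact_max` the
#' p-value is computed by exhaustive enumeration of the rank-sum
#' distribution over all group assignments (a dynamic-programming count,
#' equivalent to brute-force enumeration and exact under ties); otherwise
#' the normal approximation with tie correction is used. No continuity
#' correction is applied. No multiple-testing correction happens here.
#'
#' @param x,y numeric samples.
#' @param exact_max largest group size for the exact path (default 12).
#' @return list with `U` (the U statistic of `x`), `p` (two-sided) and
#'   `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  r <- rank(c(x, y))                       # midranks
  w <- sum(r[seq_len(n1)])                 # rank sum of x
  U <- w - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= exact_max) {
    p <- exact_ranksum_p(r, n1, w)
    list(U = U, p = p, method = "exact")
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
  }
}

## exact two-sided p for the rank sum of a group of size n1, given all
## midranks r; DP over the distribution of subset rank sums (midranks
## doubled to integers)
exact_ranksum_p <- function(r, n1, w_obs) {
  r2 <- as.integer(round(2 * r))
  n <- length(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  ## dp[k+1, s+1] = number of k-subsets with doubled rank sum s
  dp <- matrix(0, n1 + 1L, smax + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1) {
      src <- dp[k, ]
      if (any(src > 0)) {
        shifted <- c(rep(0, v), src)[seq_len(smax + 1L)]
        dp[k + 1L, ] <- dp[k + 1L, ] + shifted
      }
    }
  }
  counts <- dp[n1 + 1L, ]
  total <- sum(counts)
  w2 <- as.integer(round(2 * w_obs))
  p_le <- sum(counts[seq_len(min(w2 + 1L, smax + 1L))]) / total
  p_ge <- sum(counts[(w2 + 1L):(smax + 1L)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Find the spectral positions to test
#'
#' In `"peaks"` mode (the default), positions are the local maxima of the
#' pooled mean spectrum whose prominence (height above the higher of the two
#' flanking minima) is at least `prominence` times the mean spectrum's
#' range. In `"exhaustive"` mode every grid point is tested.
#'
#' @param group_a,group_b spectrum matrices (rows = spectra), >= 3 rows each.
#' @param wavenumber shared grid.
#' @param mode `"peaks"` or `"exhaustive"`.
#' @param prominence relative prominence floor (default 0.05).
#' @return numeric vector of wavenumber positions (ascending; possibly
#'   empty in peak mode).
#' @export
detect_test_positions <- function(group_a, group_b, wavenumber,
                                  mode = c("peaks", "exhaustive"),
                                  prominence = 0.05) {
  mode <- match.arg(mode)
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (nrow(A) < 3L || nrow(B) < 3L)
    stop("each group needs at least 3 spectra")
  if (ncol(A) != length(wavenumber) || ncol(B) != length(wavenumber))
    stop("groups and grid do not share one length")
  if (mode == "exhaustive") return(wavenumber)
  y <- colMeans(rbind(A, B))
  m <- length(y)
  rng <- diff(range(y))
  if (rng <= 0) return(numeric(0))
  is_max <- which(y[2:(m - 1L)] > y[1:(m - 2L)] & y[2:(m - 1L)] >= y[3:m]) + 1L
  is_min <- c(1L, which(y[2:(m - 1L)] <= y[1:(m - 2L)] &
                          y[2:(m - 1L)] < y[3:m]) + 1L, m)
  keep <- vapply(is_max, function(i) {
    left <- max(is_min[is_min < i])
    right <- min(is_min[is_min > i])
    y[i] - max(y[left], y[right]) >= prominence * rng
  }, logical(1L))
  wavenumber[is_max[keep]]
}

#' Volcano analysis of two spectrum groups
#'
#' At each tested position, the fold change is the mean intensity of group A
#' over the mean intensity of group B (log2-transformed; A is conventionally
#' the modified set) and the p-value is a two-sided Mann-Whitney test on the
#' per-spectrum intensities at that position. Positions with a zero group-B
#' mean (or otherwise undefined log2 fold change) are excluded and logged in
#' `attr(, "excluded")`. Raw p-values are compared with `alpha`; an optional
#' Benjamini-Hochberg adjustment is available but off by default.
#'
#' @param group_a,group_b spectrum matrices on one grid.
#' @param wavenumber shared grid.
#' @param positions wavenumbers to test (see [detect_test_positions()]).
#' @param alpha significance level (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return object of class `volcano_result`: data frame with `wavenumber`,
#'   `log2_fold_change`, `p_value`, `significant`.
#' @export
volcano <- function(group_a, group_b, wavenumber, positions = NULL,
                    alpha = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (ncol(A) != ncol(B) || ncol(A) != length(wavenumber))
    stop("groups must share the wavenumber grid")
  if (is.null(positions))
    positions <- detect_test_positions(A, B, wavenumber)
  step <- if (length(wavenumber) > 1) stats::median(diff(wavenumber)) else 1
  idx <- vapply(positions, function(p) {
    j <- which.min(abs(wavenumber - p))
    if (abs(wavenumber[j] - p) > step / 2 + 1e-9)
      stop("position ", p, " lies outside the grid")
    j
  }, integer(1L))
  lfc <- p <- rep(NA_real_, length(idx))
  excluded <- character(0)
  for (k in seq_along(idx)) {
    j <- idx[k]
    mb <- mean(B[, j])
    if (mb == 0) {
      excluded <- c(excluded, sprintf("%g: zero group-B mean", wavenumber[j]))
      next
    }
    fc <- mean(A[, j]) / mb
    l <- log2(fc)
    if (!is.finite(l)) {
      excluded <- c(excluded, sprintf("%g: undefined log2 fold change", wavenumber[j]))
      next
    }
    lfc[k] <- l
    p[k] <- mann_whitney(A[, j], B[, j])$p
  }
  ok <- !is.na(lfc)
  pv <- p[ok]
  if (adjust == "BH") pv <- stats::p.adjust(pv, "BH")
  res <- data.frame(wavenumber = wavenumber[idx[ok]],
                    log2_fold_change = lfc[ok],
                    p_value = pv,
                    significant = pv < alpha)
  res <- res[order(res$wavenumber), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, alpha = alpha, group_sizes = c(n1 = nrow(A), n2 = nrow(B)),
            excluded = excluded, direction = "group_a / group_b",
            class = c("volcano_result", "data.frame"))
}

#' Significant-peaks plot data
#'
#' Translates the volcano result back onto the spectral axis: Raman shift on
#' x, log2 fold change on y, significant positions flagged (the red dots).
#'
#' @param result a [volcano()] result.
#' @return data frame with `wavenumber` (ascending), `log2_fold_change`,
#'   `significant`.
#' @export
significant_peaks_plot <- function(result) {
  if (!inherits(result, "volcano_result")) stop("result must be a volcano_result")
  out <- data.frame(wavenumber = result$wavenumber,
                    log2_fold_change = result$log2_fold_change,
                    significant = result$significant)
  out[order(out$wavenumber), , drop = FALSE]
}

#' @export
plot.volcano_result <- function(x, ...) {
  graphics::plot(x$log2_fold_change, -log10(x$p_value),
                 xlab = "log2 fold change", ylab = "-log10 p",
                 pch = 19, col = ifelse(x$significant, "red", "grey40"), ...)
  graphics::abline(h = -log10(attr(x, "alpha")), lty = 2)
  invisible(x)
}
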