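## Group-structure analyses of nucleus spectra: principal component
## decomposition with loadings and per-group score medians, and a t-SNE
## embedding. PCA operates on mean-centred, unscaled 0-1-normalised spectra
## (intensities share units); t-SNE is the exact (quadratic) algorithm with
## PCA initialisation, deterministic given its seed.

#' Principal component embedding of labelled spectra
#'
#' @param spectra numeric matrix (rows = spectra) on one grid.
#' @param groups group label per row.
#' @param k number of components to report.
#' @param wavenumber optional grid for labelling loadings.
#' @return an `embedding_result` with `coordinates` (n x k scores),
#'   `loadings` (grid x k), `explained` (variance fractions),
#'   `group_medians` (median score per group per component) and
#'   `center` (the mean spectrum).
#' @export
pca_embed <- function(spectra, groups, k = 2L, wavenumber = NULL) {
  X <- as.matrix(spectra)
  if (length(groups) != nrow(X)) stop("one group label per spectrum required")
  if (nrow(X) < k + 1L)
    stop("rank error: k = ", k, " requires at least k + 1 spectra")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (k > ncol(pr$x))
    stop("rank error: k = ", k, " exceeds the data rank ", ncol(pr$x))
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  med <- do.call(rbind, lapply(split(seq_len(nrow(X)), groups), function(i)
    apply(pr$x[i, seq_len(k), drop = FALSE], 2L, stats::median)))
  structure(list(method = "pca",
                 coordinates = pr$x[, seq_len(k), drop = FALSE],
                 groups = groups,
                 loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 all_loadings = pr$rotation, all_scores = pr$x,
                 explained = expl[seq_len(k)],
                 group_medians = med,
                 center = pr$center,
                 wavenumber = wavenumber),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %s, %d spectra, %d dims", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  if (x$method == "pca")
    cat(sprintf(", explained %s", paste(sprintf("%.1f%%", 100 * x$explained),
                                        collapse = " + ")))
  cat("\n")
  invisible(x)
}

#' Top-loading wavenumbers of a PCA embedding
#'
#' @param result a [pca_embed()] result.
#' @param top_n rows per component (clipped to the grid length, with a
#'   warning, if larger).
#' @return data frame `component`, `wavenumber` (or grid index when no grid
#'   was supplied), `weight`, sorted by `|weight|` descending within each
#'   component.
#' @export
loading_interpretation <- function(result, top_n = 10L) {
  if (!inherits(result, "embedding_result") || result$method != "pca")
    stop("loading interpretation requires a PCA embedding result")
  m <- nrow(result$loadings)
  if (top_n > m) {
    warning("top_n clipped from ", top_n, " to grid length ", m)
    top_n <- m
  }
  if (top_n == 0L)
    return(data.frame(component = integer(0), wavenumber = numeric(0),
                      weight = numeric(0)))
  wn <- if (is.null(result$wavenumber)) seq_len(m) else result$wavenumber
  do.call(rbind, lapply(seq_len(ncol(result$loadings)), function(cc) {
    w <- result$loadings[, cc]
    ord <- order(abs(w), decreasing = TRUE)[seq_len(top_n)]
    data.frame(component = cc, wavenumber = wn[ord], weight = w[ord],
               row.names = NULL)
  }))
}

## perplexity -> conditional probabilities via per-point binary search
tsne_p <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) { H <- 0; Pi[] <- 0 }
      else {
        H <- log(sumP) + beta * sum(Di * Pi) / sumP
        Pi <- Pi / sumP
      }
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- Pi
  }
  P
}

#' t-SNE embedding of labelled spectra
#'
#' Exact t-SNE (no tree approximation): input distances are taken after a
#' 50-component PCA reduction, affinities use a per-point
#' perplexity-calibrated Gaussian kernel, the 2-D map is initialised from
#' the first two principal components, and optimisation runs gradient
#' descent with momentum and early exaggeration. Deterministic given
#' `seed`.
#'
#' @param spectra numeric matrix (rows = spectra).
#' @param groups group label per row.
#' @param perplexity effective neighbour count; requires
#'   `nrow(spectra) > 3 * perplexity`.
#' @param seed integer seed.
#' @param n_iter gradient-descent iterations (default 1000).
#' @return an `embedding_result` with 2-D `coordinates`.
#' @export
tsne_embed <- function(spectra, groups, perplexity = 30, seed = 1L,
                       n_iter = 1000L) {
  X <- as.matrix(spectra)
  n <- nrow(X)
  if (length(groups) != n) stop("one group label per spectrum required")
  if (n <= 3 * perplexity)
    stop("perplexity ", perplexity, " too large for ", n,
         " spectra (need n > 3 * perplexity)")
  set.seed(seed)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (ncol(Xc) > 50L) {
    pr <- stats::prcomp(Xc, center = FALSE, rank. = 50L)
    Xc <- pr$x
  }
  D2 <- as.matrix(stats::dist(Xc))^2
  P <- tsne_p(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  pr2 <- stats::prcomp(Xc, center = FALSE, rank. = 2L)
  Y <- pr2$x[, 1:2, drop = FALSE]
  Y <- Y / stats::sd(Y[, 1L]) * 1e-4
  dY <- Y * 0; gains <- Y * 0 + 1
  momentum <- 0.5; eta <- 200
  exag <- 12
  Pe <- P * exag
  for (it in seq_len(n_iter)) {
    if (it == 251L) { Pe <- P; momentum <- 0.8 }
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  colnames(Y) <- c("dim1", "dim2")
  med <- do.call(rbind, lapply(split(seq_len(n), groups), function(i)
    apply(Y[i, , drop = FALSE], 2L, stats::median)))
  structure(list(method = "tsne", coordinates = Y, groups = groups,
                 perplexity = perplexity, seed = seed,
                 group_medians = med),
            class = "embedding_result")
}
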