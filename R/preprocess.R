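## Spectral preprocessing chain: cosmic-spike removal, 3rd-order polynomial
## baseline removal, optional convolutional-autoencoder denoising, and 0-1
## normalisation. Pipeline order is fixed: despike -> baseline -> (optional)
## denoise -> normalize01.

#' Remove a polynomial baseline from a spectrum
#'
#' Iterative polynomial fitting with point rejection above the fit (modified
#' polyfit): after each least-squares fit, intensities above the fitted curve
#' are clipped down to it and the fit is repeated, so the polynomial settles
#' onto the signal floor instead of tracking peaks. A plain least-squares fit
#' is recovered when the input has no peaks.
#'
#' @param intensity numeric vector (>= 8 points).
#' @param degree polynomial degree (default 3, a cubic).
#' @param max_iter,tol iteration controls; convergence is declared when the
#'   fitted curve moves less than `tol` times the intensity scale.
#' @return list with `corrected` (intensity minus baseline) and `baseline`.
#' @export
remove_baseline <- function(intensity, degree = 3L, max_iter = 25L, tol = 1e-7) {
  m <- length(intensity)
  if (m < max(8L, degree + 1L))
    stop("too few points (", m, ") for degree-", degree, " baseline removal")
  t <- seq(0, 1, length.out = m)
  basis <- stats::poly(t, degree = degree, raw = TRUE)
  basis <- cbind(1, basis)
  y <- intensity
  scale <- max(abs(intensity), 1e-12)
  fit <- drop(basis %*% qr.coef(qr(basis), y))
  for (i in seq_len(max_iter)) {
    y <- pmin(y, fit)
    new_fit <- drop(basis %*% qr.coef(qr(basis), y))
    if (max(abs(new_fit - fit)) < tol * scale) { fit <- new_fit; break }
    fit <- new_fit
  }
  ## the clipped iteration carries a small downward bias near peaks; refit
  ## on the points that sit at the estimated floor to remove it
  floor_pts <- which(intensity - fit < 0.02 * max(scale, diff(range(intensity))))
  if (length(floor_pts) > 2L * (degree + 1L)) {
    refit <- drop(basis %*% qr.coef(qr(basis[floor_pts, , drop = FALSE]),
                                    intensity[floor_pts]))
    if (all(is.finite(refit))) fit <- refit
  }
  list(corrected = intensity - fit, baseline = fit)
}

#' Remove single-bin cosmic-ray spikes
#'
#' Flags single-bin outliers with a modified z-score (median/MAD) on the
#' first-difference signal: a spike is an extreme up-step immediately
#' followed by an extreme down-step (or the mirror image), which genuine
#' Raman bands several bins wide never produce. Flagged bins are replaced by
#' linear interpolation between their nearest unflagged neighbours.
#'
#' @param intensity numeric vector.
#' @param threshold modified z-score threshold (default 8).
#' @return list with `intensity` (despiked), `n_removed` and `positions`.
#' @export
remove_spikes <- function(intensity, threshold = 8) {
  m <- length(intensity)
  if (m < 4L) return(list(intensity = intensity, n_removed = 0L, positions = integer(0)))
  d <- diff(intensity)
  med <- stats::median(d)
  mad <- stats::median(abs(d - med))
  if (mad < 1e-12) mad <- max(stats::sd(d), 1e-12) / 1.4826
  mz <- 0.6745 * (d - med) / mad
  mid <- 2:(m - 1L)
  up_down <- mz[mid - 1L] > threshold & mz[mid] < -threshold
  down_up <- mz[mid - 1L] < -threshold & mz[mid] > threshold
  pos <- mid[up_down | down_up]
  ## width discrimination: a cosmic spike is a one-bin excursion, so the
  ## steps into and out of it must dwarf the adjacent (background) steps;
  ## the apex of a genuine band a few bins wide fails this because its
  ## flanking steps are at least as large as the apex steps
  if (length(pos)) {
    eps <- 1e-12
    flank_ok <- vapply(pos, function(i) {
      left <- if (i > 2L) abs(d[i - 2L]) else 0
      right <- if (i < m - 1L) abs(d[i + 1L]) else 0
      abs(d[i - 1L]) > 3 * (left + eps) && abs(d[i]) > 3 * (right + eps)
    }, logical(1L))
    pos <- pos[flank_ok]
  }
  if (mz[1L] < -threshold || mz[1L] > threshold) {
    ## end bins have one-sided evidence; require a very large step
    if (abs(mz[1L]) > 2 * threshold) pos <- c(1L, pos)
  }
  if (abs(mz[m - 1L]) > 2 * threshold) pos <- c(pos, m)
  pos <- sort(unique(pos))
  if (!length(pos)) return(list(intensity = intensity, n_removed = 0L,
                                positions = integer(0)))
  good <- setdiff(seq_len(m), pos)
  intensity[pos] <- stats::approx(good, intensity[good], xout = pos,
                                  method = "linear", rule = 2)$y
  list(intensity = intensity, n_removed = length(pos), positions = pos)
}

#' Min-max normalise a spectrum to the 0-1 range
#'
#' @param intensity numeric, non-constant.
#' @return normalised vector with `min = 0`, `max = 1`.
#' @export
normalize01 <- function(intensity) {
  rng <- range(intensity)
  if (diff(rng) <= 0)
    stop("degenerate input: constant spectrum cannot be 0-1 normalised")
  (intensity - rng[1L]) / diff(rng)
}

#' Preprocess every spectrum of a hyperspectral map
#'
#' Applies the fixed chain despike -> polynomial baseline removal ->
#' optional autoencoder denoising -> 0-1 normalisation, and returns an audit
#' report per pixel. Denoising operates on per-spectrum 0-1 scaled input
#' (the autoencoder's contract) and its sigmoidal output feeds the final
#' normalisation directly.
#'
#' @param map a [hypermap()].
#' @param denoiser optional trained [train_autoencoder()] model.
#' @param despike,baseline logical switches for the two artefact removers.
#' @param despike_threshold modified z-score threshold.
#' @param baseline_degree baseline polynomial degree.
#' @return list with `map` (processed) and `report` (data frame with
#'   `n_spikes_removed`, `baseline_rms`, `denoise_applied` per pixel).
#' @export
preprocess_map <- function(map, denoiser = NULL, despike = TRUE,
                           baseline = TRUE, despike_threshold = 8,
                           baseline_degree = 3L) {
  X <- map$intensity
  n <- nrow(X)
  n_spikes <- integer(n)
  base_rms <- numeric(n)
  if (despike) {
    for (i in seq_len(n)) {
      r <- remove_spikes(X[i, ], despike_threshold)
      X[i, ] <- r$intensity
      n_spikes[i] <- r$n_removed
    }
  }
  if (baseline) {
    for (i in seq_len(n)) {
      r <- remove_baseline(X[i, ], degree = baseline_degree)
      X[i, ] <- r$corrected
      base_rms[i] <- sqrt(mean(r$baseline^2))
    }
  }
  ## scale each spectrum to [0, 1]; constant spectra are degenerate
  rng <- cbind(apply(X, 1L, min), apply(X, 1L, max))
  flat <- rng[, 2L] - rng[, 1L] <= 0
  if (any(flat))
    stop("degenerate constant spectrum at pixel(s) ",
         paste(utils::head(which(flat), 3L), collapse = ", "))
  X <- (X - rng[, 1L]) / (rng[, 2L] - rng[, 1L])
  if (!is.null(denoiser)) {
    X <- denoise(denoiser, X)
    rng <- cbind(apply(X, 1L, min), apply(X, 1L, max))
    X <- (X - rng[, 1L]) / pmax(rng[, 2L] - rng[, 1L], 1e-12)
  }
  out <- hypermap(map$wavenumber, X, map$x, map$y, map$width, map$height,
                  map$step_size, map$metadata)
  list(map = out,
       report = data.frame(n_spikes_removed = n_spikes,
                           baseline_rms = base_rms,
                           denoise_applied = !is.null(denoiser)))
}

## ---- autoencoder ------------------------------------------------------------

#' Specify the denoising autoencoder
#'
#' A 1-D convolutional autoencoder: an encoder of 9 convolutional layers
#' that compresses the spectrum, a decoder of 9 convolutional layers
#' (interleaved with nearest-neighbour upsampling), and a flat sigmoidal
#' output layer mapping back to the input length. Trained with Adam,
#' Glorot-uniform initialisation, batch size 105 and 42 epochs by default,
#' under an elementwise cross-entropy loss on 0-1 intensities
#' (`"crossentropy"`), with mean-squared error available as an alternative.
#'
#' @param epochs training epochs (default 42).
#' @param batch_size minibatch size (default 105).
#' @param loss `"crossentropy"` or `"mse"`.
#' @param lr Adam learning rate.
#' @param seed integer seed; training is deterministic given it.
#' @return an object of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(epochs = 42L, batch_size = 105L,
                             loss = c("crossentropy", "mse"),
                             lr = 2e-3, seed = 1L) {
  loss <- match.arg(loss)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 loss = loss, lr = lr, seed = as.integer(seed)),
            class = "autoencoder_spec")
}

ae_layers <- function() {
  ## hidden activations are tanh: Glorot-uniform init preserves signal
  ## variance through the 18 conv layers for tanh, where relu would let the
  ## encoder output collapse towards zero at this depth
  cv <- function(k, f, s) nn_conv(k, f, s, activation = "tanh")
  c(list(cv(7, 8, 2), cv(5, 8, 2), cv(5, 16, 2),
         cv(3, 16, 1), cv(3, 16, 1), cv(3, 16, 1),
         cv(3, 16, 1), cv(3, 16, 1), cv(3, 8, 1)),                  # encoder: 9 conv
    list(nn_upsample(2), cv(3, 16, 1), nn_upsample(2), cv(5, 16, 1),
         nn_upsample(2), cv(5, 8, 1), cv(5, 8, 1), cv(5, 8, 1),
         cv(7, 8, 1), cv(7, 4, 1), cv(7, 4, 1),
         cv(7, 2, 1)))                                               # decoder: 9 conv
}

#' Train the convolutional denoising autoencoder
#'
#' @param spectra numeric matrix of training spectra (rows), all on one grid
#'   and scaled to `[0, 1]`; at least `batch_size` rows.
#' @param spec an [autoencoder_spec()].
#' @return a `denoiser_model` usable with [denoise()].
#' @export
train_autoencoder <- function(spectra, spec = autoencoder_spec()) {
  X <- as.matrix(spectra)
  if (anyNA(X)) stop("training spectra contain missing values")
  if (nrow(X) < spec$batch_size)
    stop("need at least batch_size (", spec$batch_size, ") spectra, got ", nrow(X))
  if (min(X) < -1e-9 || max(X) > 1 + 1e-9)
    stop("autoencoder input must be scaled to [0, 1]")
  layers <- c(ae_layers(), list(nn_flatten(),
                                nn_dense(ncol(X), activation = "sigmoid")))
  model <- nn_init(layers, input_len = ncol(X), seed = spec$seed)
  loss <- if (spec$loss == "crossentropy") "bce" else "mse"
  tr <- nn_train(model, X, X, epochs = spec$epochs,
                 batch_size = spec$batch_size, loss = loss, lr = spec$lr,
                 seed = spec$seed)
  structure(list(net = tr$model, input_len = ncol(X), spec = spec,
                 history = tr$history),
            class = "denoiser_model")
}

#' Denoise spectra with a trained autoencoder
#'
#' The sigmoidal output layer guarantees values in `[0, 1]`; length and grid
#' are preserved.
#'
#' @param model a `denoiser_model` from [train_autoencoder()].
#' @param spectra numeric vector or matrix of spectra on the training grid.
#' @return denoised spectra, same shape as the input.
#' @export
denoise <- function(model, spectra) {
  if (!inherits(model, "denoiser_model")) stop("model is not a denoiser_model")
  vec <- is.null(dim(spectra))
  X <- if (vec) matrix(spectra, 1L) else as.matrix(spectra)
  if (ncol(X) != model$input_len)
    stop("spectrum length ", ncol(X), " does not match training length ",
         model$input_len)
  out <- nn_predict(model$net, X)
  if (vec) drop(out) else out
}
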