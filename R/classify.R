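## Convolutional classifier of pixel spectra into stroma/empty (0),
## nucleus (1) and cytoplasm (2), with prediction-map rendering.

#' Specify the spectral classifier
#'
#' A 1-D convolutional network of 10 convolutional layers for feature
#' identification followed by 4 fully connected layers for classification
#' into three classes, trained with Adam, categorical cross-entropy,
#' Glorot-uniform initialisation, batch size 105 and a 70/30 train/test
#' split. Training runs for 10 to 38 epochs with early stopping on the
#' held-out loss (patience 5); labels are shuffled and one-hot encoded
#' internally.
#'
#' @param epochs maximum epochs (default 38).
#' @param min_epochs minimum epochs before early stopping may trigger
#'   (default 10).
#' @param batch_size minibatch size (default 105).
#' @param split training fraction of the 70/30 split.
#' @param patience early-stopping patience on held-out loss.
#' @param lr Adam learning rate.
#' @param seed integer seed; training is deterministic given it.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(epochs = 38L, min_epochs = 10L, batch_size = 105L,
                            split = 0.7, patience = 5L, lr = 1e-3, seed = 1L) {
  if (split <= 0 || split >= 1) stop("split must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs), min_epochs = as.integer(min_epochs),
                 batch_size = as.integer(batch_size), split = split,
                 patience = as.integer(patience), lr = lr,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

cnn_layers <- function() {
  list(nn_conv(7, 8, 1),  nn_conv(5, 8, 2),  nn_conv(5, 16, 2),
       nn_conv(5, 16, 2), nn_conv(5, 24, 2), nn_conv(3, 24, 2),
       nn_conv(3, 32, 2), nn_conv(3, 32, 2), nn_conv(3, 32, 1),
       nn_conv(3, 32, 1),                                   # 10 conv layers
       nn_flatten(),
       nn_dense(256), nn_dense(64), nn_dense(16),
       nn_dense(3, activation = "softmax"))                 # 4 dense layers
}

#' Train the nucleus/cytoplasm/stroma spectral classifier
#'
#' @param spectra numeric matrix of preprocessed spectra (rows), one grid.
#' @param labels integer class per row, in `{0, 1, 2}` (0 stroma/empty,
#'   1 nucleus, 2 cytoplasm); all three classes must be present.
#' @param spec a [classifier_spec()].
#' @return list with `model` (a `classifier_model`) and `report` (held-out
#'   validation accuracy, epochs run, per-class precision/recall).
#' @export
train_classifier <- function(spectra, labels, spec = classifier_spec()) {
  X <- as.matrix(spectra)
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop("one label per spectrum required")
  missing_cls <- setdiff(0:2, unique(labels))
  if (length(missing_cls))
    stop("class ", paste(missing_cls, collapse = ", "),
         " absent from the training labels")
  if (nrow(X) < spec$batch_size)
    stop("need at least batch_size (", spec$batch_size, ") samples, got ", nrow(X))
  set.seed(spec$seed)
  ord <- sample.int(nrow(X))                    # combined and shuffled
  n_train <- floor(spec$split * nrow(X))
  tr_i <- ord[seq_len(n_train)]
  te_i <- ord[-seq_len(n_train)]
  onehot <- function(l) {
    Y <- matrix(0, length(l), 3L)
    Y[cbind(seq_along(l), l + 1L)] <- 1
    Y
  }
  model <- nn_init(cnn_layers(), input_len = ncol(X), seed = spec$seed)
  tr <- nn_train(model, X[tr_i, , drop = FALSE], onehot(labels[tr_i]),
                 epochs = spec$epochs, batch_size = spec$batch_size,
                 loss = "cce", lr = spec$lr, seed = spec$seed,
                 validation = list(X = X[te_i, , drop = FALSE],
                                   Y = onehot(labels[te_i])),
                 min_epochs = spec$min_epochs, patience = spec$patience)
  cm <- structure(list(net = tr$model, input_len = ncol(X), spec = spec),
                  class = "classifier_model")
  pred <- predict_classes(cm, X[te_i, , drop = FALSE])
  truth <- labels[te_i]
  acc <- mean(pred == truth)
  prec <- rec <- numeric(3L)
  for (k in 0:2) {
    prec[k + 1L] <- if (sum(pred == k)) mean(truth[pred == k] == k) else NA_real_
    rec[k + 1L] <- if (sum(truth == k)) mean(pred[truth == k] == k) else NA_real_
  }
  list(model = cm,
       report = list(validation_accuracy = acc,
                     epochs_run = tr$epochs_run,
                     best_epoch = tr$best_epoch,
                     n_train = n_train, n_test = length(te_i),
                     precision = stats::setNames(prec, 0:2),
                     recall = stats::setNames(rec, 0:2)))
}

#' Predict class labels for a matrix of spectra
#'
#' Softmax ties resolve to the lowest class index.
#'
#' @param model a `classifier_model`.
#' @param spectra numeric matrix on the training grid.
#' @return integer labels in `{0, 1, 2}`.
#' @export
predict_classes <- function(model, spectra) {
  X <- as.matrix(spectra)
  if (ncol(X) != model$input_len)
    stop("spectrum length ", ncol(X), " does not match training length ",
         model$input_len)
  p <- nn_predict(model$net, X)
  max.col(p, ties.method = "first") - 1L
}

#' Classify every pixel of a hyperspectral map
#'
#' @param model a `classifier_model`.
#' @param map a preprocessed [hypermap()] on the training grid.
#' @return a [class_map()] aligned with the map's pixels.
#' @export
predict_map <- function(model, map) {
  labels <- predict_classes(model, map$intensity)
  class_map(labels, map$x, map$y, map$width, map$height)
}

#' Default prediction-map palette
#'
#' Nucleus green, cytoplasm red, stroma/other yellow.
#' @return named vector of colours indexed by class label.
#' @export
class_palette <- function() c("0" = "yellow", "1" = "green", "2" = "red")

#' Render a class map as an RGB raster
#'
#' @param classmap a [class_map()].
#' @param palette named colour vector indexed `"0"`, `"1"`, `"2"`.
#' @return height x width x 3 array of RGB values in `[0, 1]`; pixels absent
#'   from the map are white.
#' @export
render_class_image <- function(classmap, palette = class_palette()) {
  img <- array(1, c(classmap$height, classmap$width, 3L))
  rgb <- grDevices::col2rgb(palette[as.character(classmap$labels)]) / 255
  for (ch in 1:3)
    img[cbind(classmap$y + 1L, classmap$x + 1L, ch)] <- rgb[ch, ]
  attr(img, "palette") <- palette
  img
}

#' Recover class labels from a rendered class image
#'
#' Exact palette inversion; the round trip
#' `image_to_labels(render_class_image(cm))` reproduces `cm` wherever pixels
#' exist.
#'
#' @param img output of [render_class_image()].
#' @param palette the palette used to render.
#' @return integer label matrix (height x width), `NA` off-map.
#' @export
image_to_labels <- function(img, palette = attr(img, "palette")) {
  rgb <- grDevices::col2rgb(palette) / 255
  lab <- matrix(NA_integer_, dim(img)[1L], dim(img)[2L])
  for (k in seq_along(palette)) {
    hit <- abs(img[, , 1L] - rgb[1L, k]) < 1e-9 &
      abs(img[, , 2L] - rgb[2L, k]) < 1e-9 &
      abs(img[, , 3L] - rgb[3L, k]) < 1e-9
    lab[hit] <- as.integer(names(palette)[k])
  }
  lab
}
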