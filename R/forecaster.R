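#' CNN forecaster configuration
#'
#' Architecture of the 1D-kernel convolutional forecaster: two valid
#' convolutions along the time axis (shared across the three feature rows)
#' each followed by ReLU and a pairwise max-pooling that halves the time
#' axis, then a ReLU dense layer and a single linear output neuron.
#'
#' @param filters1 feature maps in the first convolutional layer (default 26).
#' @param filters2 feature maps in the second convolutional layer (default 20).
#' @param kernel_time time width of the 1 x k kernels (odd, default 5).
#' @param dense_units width of the dense head (default 64).
#' @return object of class `"cnn_config"`.
#' @export
cnn_config <- function(filters1 = 26L, filters2 = 20L, kernel_time = 5L,
                       dense_units = 64L) {
  if (filters1 < 1 || filters2 < 1 || dense_units < 1)
    stop("filters and dense_units must be >= 1")
  if (kernel_time %% 2 == 0) stop("kernel_time must be odd")
  structure(list(filters1 = as.integer(filters1),
                 filters2 = as.integer(filters2),
                 kernel_time = as.integer(kernel_time),
                 dense_units = as.integer(dense_units),
                 pool = 2L),
            class = "cnn_config")
}

#' LSTM forecaster configuration
#'
#' Architecture of the recurrent forecaster: one LSTM layer consuming the
#' 30-step, 3-feature sequence, a ReLU dense layer, and a single linear
#' output neuron.
#'
#' @param lstm_units LSTM state size (default 64).
#' @param dense_units width of the dense head (default 64).
#' @return object of class `"lstm_config"`.
#' @export
lstm_config <- function(lstm_units = 64L, dense_units = 64L) {
  if (lstm_units < 1 || dense_units < 1) stop("units must be >= 1")
  structure(list(lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units)),
            class = "lstm_config")
}

#' Training recipe
#'
#' Optimizer and schedule for [fit_forecaster()]: stochastic gradient descent
#' with momentum and element-wise gradient value clipping, mean-squared-error
#' loss, mini-batches of about one day of data, and early stopping on the
#' validation loss with best-weight restoration. The defaults are the
#' reference recipe (learning rate 1e-4, momentum 0.9, clip value 0.5, batch
#' 1400, up to 200 epochs); smaller studies typically rescale the learning
#' rate and epoch budget.
#'
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param clip_value element-wise gradient clipping bound.
#' @param batch_size mini-batch size in samples.
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience, in epochs without validation
#'   improvement (must be < `max_epochs`).
#' @param seed integer seed for weight initialization and batch shuffling.
#' @param standardize standardize features and target with training-set
#'   statistics inside the model (predictions are always returned on the
#'   original scale).
#' @param shuffle reshuffle mini-batches every epoch.
#' @param verbose print per-epoch losses.
#' @return object of class `"train_control"`.
#' @export
train_control <- function(learning_rate = 1e-4, momentum = 0.9,
                          clip_value = 0.5, batch_size = 1400L,
                          max_epochs = 200L, patience = 10L, seed = 1L,
                          standardize = FALSE, shuffle = TRUE,
                          verbose = FALSE) {
  if (learning_rate <= 0 || momentum < 0 || clip_value <= 0 ||
      batch_size < 1 || max_epochs < 1 || patience < 1)
    stop("invalid training control values")
  if (patience >= max_epochs + 1)
    stop("patience must not exceed max_epochs")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 clip_value = clip_value, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 standardize = isTRUE(standardize), shuffle = isTRUE(shuffle),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

# windows -> (N, 3, wl) batch array, optionally standardized
.batch_array <- function(windows, scaling = NULL) {
  X <- aperm(windows$x, c(3, 1, 2))
  if (!is.null(scaling))
    for (r in 1:3)
      X[, r, ] <- (X[, r, ] - scaling$feat_mean[r]) / scaling$feat_sd[r]
  X
}

#' Fit a glucose forecaster
#'
#' Trains a CNN or LSTM 30-min-ahead CGM forecaster on the chronological
#' train/validation blocks of a [split_dataset()], with SGD + momentum,
#' gradient value clipping, MSE loss, and early stopping that restores the
#' weights of the best validation epoch. Training is deterministic for a
#' fixed `control$seed`.
#'
#' @param split a `"dataset_split"`.
#' @param arch `"cnn"` or `"lstm"`.
#' @param config a [cnn_config()] or [lstm_config()]; defaults to the
#'   architecture's reference configuration.
#' @param control a [train_control()].
#' @return object of class `c("<arch>_forecaster", "glucose_forecaster")`
#'   with elements `arch`, `config`, `control`, `weights` (named tensors),
#'   `history` (per-epoch train/validation loss), `scaling` (or `NULL`),
#'   `best_val_loss`, `best_epoch`, `patient_id`.
#' @examples
#' \donttest{
#' pats <- draw_patients(1, seed = 7)
#' cfg <- scenario_config("realistic", n_days = 2, seed = 7)
#' sim <- simulate_patient(pats[[1]], cfg)
#' sp <- split_dataset(build_windows(feature_series(sim)))
#' fit <- fit_forecaster(sp, "cnn",
#'                       control = train_control(max_epochs = 2, seed = 1))
#' print(fit)
#' }
#' @export
fit_forecaster <- function(split, arch = c("cnn", "lstm"), config = NULL,
                           control = train_control()) {
  stopifnot(inherits(split, "dataset_split"), inherits(control, "train_control"))
  arch <- match.arg(arch)
  if (is.null(config))
    config <- if (arch == "cnn") cnn_config() else lstm_config()
  if (arch == "cnn") stopifnot(inherits(config, "cnn_config"))
  else stopifnot(inherits(config, "lstm_config"))
  if (length(split$train) == 0 || length(split$validation) == 0)
    stop("split must have non-empty train and validation blocks")
  wl <- split$train$window_len
  if (arch == "cnn") .cnn_shapes(wl, config)  # validate shapes early
  scaling <- NULL
  if (control$standardize) {
    X <- aperm(split$train$x, c(3, 1, 2))
    fm <- vapply(1:3, function(r) mean(X[, r, ]), numeric(1))
    fs <- vapply(1:3, function(r) stats::sd(X[, r, ]), numeric(1))
    fs[fs < 1e-12] <- 1
    ys <- stats::sd(split$train$y)
    scaling <- list(feat_mean = fm, feat_sd = fs,
                    y_mean = mean(split$train$y),
                    y_sd = if (is.finite(ys) && ys > 1e-12) ys else 1)
  }
  sc_y <- function(y) if (is.null(scaling)) y
                      else (y - scaling$y_mean) / scaling$y_sd
  Xtr <- .batch_array(split$train, scaling)
  Xval <- .batch_array(split$validation, scaling)
  fit <- .net_train(arch, config, Xtr, sc_y(split$train$y),
                    Xval, sc_y(split$validation$y), control)
  structure(list(arch = arch, config = config, control = control,
                 weights = fit$weights, history = fit$history,
                 scaling = scaling, best_val_loss = fit$best_val,
                 best_epoch = fit$best_epoch,
                 window_len = wl, ph = split$train$ph,
                 patient_id = split$train$patient_id),
            class = c(paste0(arch, "_forecaster"), "glucose_forecaster"))
}

#' Number of trainable parameters
#' @param object a fitted or quantized forecaster.
#' @return integer parameter count.
#' @export
n_params <- function(object) {
  if (inherits(object, "quantized_forecaster")) object <- object$base
  sum(vapply(object$weights, length, integer(1)))
}

#' @export
print.glucose_forecaster <- function(x, ...) {
  cat(sprintf("%s glucose forecaster (%d parameters), %d-min horizon\n",
              toupper(x$arch), n_params(x), x$ph))
  if (!is.null(x$patient_id) && !is.na(x$patient_id))
    cat("  patient:", x$patient_id, "\n")
  cat(sprintf("  trained %d epochs (best epoch %d, val MSE %.4g)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.glucose_forecaster <- function(object, ...) {
  print(object)
  cat("  config:", paste(names(unclass(object$config)),
                         unlist(object$config), sep = "=", collapse = ", "), "\n")
  cat("  weights:", paste(sprintf("%s[%s]", names(object$weights),
        vapply(object$weights, function(w)
          paste(if (is.matrix(w)) dim(w) else length(w), collapse = "x"),
          character(1))), collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.glucose_forecaster <- function(object, ...) object$weights

#' Predict future CGM values
#'
#' Applies the trained forecaster to a window collection without any weight
#' update. Each prediction targets the window's anchor + `ph` minutes.
#'
#' @param object a fitted `"glucose_forecaster"`.
#' @param newdata a `"cgm_windows"` collection (or `(N, 3, wl)` array).
#' @param ... unused.
#' @return numeric predictions on the training-data scale (mg/dL, or levels
#'   when the model was trained on normalized levels).
#' @export
predict.glucose_forecaster <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "cgm_windows")) {
    if (newdata$window_len != object$window_len)
      stop("window length ", newdata$window_len, " does not match model (",
           object$window_len, ")")
    .batch_array(newdata, object$scaling)
  } else {
    if (length(dim(newdata)) != 3 || dim(newdata)[2] != 3 ||
        dim(newdata)[3] != object$window_len)
      stop("newdata must be an (N, 3, ", object$window_len, ") array")
    .batch_array(list(x = aperm(newdata, c(2, 3, 1))), object$scaling)
  }
  p <- .net_predict(object$arch, object$weights, X, object$config)
  if (!is.null(object$scaling)) p <- p * object$scaling$y_sd + object$scaling$y_mean
  p
}

#' @export
residuals.glucose_forecaster <- function(object, newdata, ...) {
  if (missing(newdata) || !inherits(newdata, "cgm_windows"))
    stop("supply the cgm_windows collection to compute residuals on")
  newdata$y - predict(object, newdata)
}

#' @export
plot.glucose_forecaster <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE loss",
                    main = sprintf("%s training history", toupper(x$arch)), ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Default hyper-parameter grids
#'
#' Grid-search ranges covering the reference optima: CNN kernels 3/5/7 with
#' 16/26/32 and 10/20/26 feature maps; LSTM state and dense widths 32/64/128.
#'
#' @param arch `"cnn"` or `"lstm"`.
#' @return list of configuration objects, in grid order.
#' @export
default_grid <- function(arch = c("cnn", "lstm")) {
  arch <- match.arg(arch)
  if (arch == "cnn") {
    g <- expand.grid(kernel_time = c(3L, 5L, 7L), filters1 = c(16L, 26L, 32L),
                     filters2 = c(10L, 20L, 26L))
    lapply(seq_len(nrow(g)), function(i)
      cnn_config(filters1 = g$filters1[i], filters2 = g$filters2[i],
                 kernel_time = g$kernel_time[i]))
  } else {
    g <- expand.grid(lstm_units = c(32L, 64L, 128L),
                     dense_units = c(32L, 64L, 128L))
    lapply(seq_len(nrow(g)), function(i)
      lstm_config(lstm_units = g$lstm_units[i], dense_units = g$dense_units[i]))
  }
}

#' Per-patient hyper-parameter grid search
#'
#' Trains one model per grid configuration and selects the one with the
#' lowest validation RMSE; ties are broken by fewer parameters, then by grid
#' order. Deterministic for a fixed `control$seed`.
#'
#' @param split a `"dataset_split"`.
#' @param arch `"cnn"` or `"lstm"`.
#' @param grid list of configuration objects (default [default_grid()]).
#' @param control a [train_control()].
#' @return list with `best_config`, `model` (the refitted winner), and
#'   `results` (data.frame of configuration, validation RMSE, parameters).
#' @export
grid_search <- function(split, arch = c("cnn", "lstm"),
                        grid = default_grid(arch), control = train_control()) {
  arch <- match.arg(arch)
  if (length(grid) == 0) stop("grid must be non-empty")
  best <- NULL
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    m <- fit_forecaster(split, arch, config = grid[[i]], control = control)
    vr <- sqrt(m$best_val_loss)
    np <- n_params(m)
    rows[[i]] <- data.frame(grid_index = i, val_rmse = vr, n_params = np,
                            t(unlist(unclass(grid[[i]]))))
    if (is.null(best) || vr < best$vr ||
        (vr == best$vr && np < best$np)) {
      best <- list(i = i, vr = vr, np = np, model = m)
    }
  }
  list(best_config = grid[[best$i]], model = best$model,
       results = do.call(rbind, rows))
}

#' Save / load forecaster weights as a portable text archive
#'
#' Serializes the named weight tensors, configuration, scaling and seed to a
#' YAML file (full double precision via 17-digit formatting), so a model can
#' be archived and restored without binary formats.
#'
#' @param object a fitted `"glucose_forecaster"`.
#' @param path file path.
#' @return `save_forecaster` returns `path` invisibly; `load_forecaster`
#'   returns the restored model.
#' @export
save_forecaster <- function(object, path) {
  stopifnot(inherits(object, "glucose_forecaster"))
  ser <- list(
    arch = object$arch,
    config = unclass(object$config),
    control = unclass(object$control),
    window_len = object$window_len, ph = object$ph,
    patient_id = object$patient_id,
    best_val_loss = object$best_val_loss, best_epoch = object$best_epoch,
    scaling = if (is.null(object$scaling)) NULL else lapply(object$scaling,
      function(v) sprintf("%.17g", v)),
    weights = lapply(object$weights, function(w) list(
      dim = if (is.matrix(w)) dim(w) else length(w),
      data = sprintf("%.17g", as.numeric(w))))
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname save_forecaster
#' @export
load_forecaster <- function(path) {
  ser <- yaml::read_yaml(path)
  weights <- lapply(ser$weights, function(w) {
    v <- as.numeric(w$data)
    if (length(w$dim) == 2) matrix(v, w$dim[[1]], w$dim[[2]]) else v
  })
  config <- ser$config
  class(config) <- paste0(ser$arch, "_config")
  control <- ser$control
  class(control) <- "train_control"
  scaling <- if (is.null(ser$scaling)) NULL else lapply(ser$scaling,
    function(v) as.numeric(v))
  structure(list(arch = ser$arch, config = config, control = control,
                 weights = weights, history = NULL, scaling = scaling,
                 best_val_loss = ser$best_val_loss,
                 best_epoch = ser$best_epoch, window_len = ser$window_len,
                 ph = ser$ph, patient_id = ser$patient_id),
            class = c(paste0(ser$arch, "_forecaster"), "glucose_forecaster"))
}
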