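# 8-bit post-training quantization emulation: dynamic-range (int8 weights,
# float activations) and full-integer (uint8 activations calibrated on a
# representative set), plus the 0-255 level normalization and the uint8
# overflow-reconstruction post-processing.

# per-tensor affine int8 parameters; the represented range always includes 0
.qparams_int8 <- function(w) {
  rmin <- min(0, min(w))
  rmax <- max(0, max(w))
  if (rmax == rmin) return(list(scale = 1, zp = 0L))
  scale <- (rmax - rmin) / 255
  zp <- as.integer(round(-128 - rmin / scale))
  list(scale = scale, zp = max(-128L, min(127L, zp)))
}

.quantize_tensor <- function(w, qp) {
  q <- round(w / qp$scale) + qp$zp
  pmin(pmax(q, -128), 127)
}

.dequantize_tensor <- function(q, qp) qp$scale * (q - qp$zp)

# quantize every weight matrix of a model; bias vectors stay float (they are
# accumulated at higher precision in integer runtimes)
.quantize_weights <- function(weights) {
  lapply(weights, function(w) {
    if (!is.matrix(w)) return(list(float = w))
    qp <- .qparams_int8(w)
    q <- .quantize_tensor(w, qp)
    attr(q, "dim") <- dim(w)
    list(q = q, scale = qp$scale, zp = qp$zp)
  })
}

.dequantize_weights <- function(qw) {
  lapply(qw, function(t) {
    if (!is.null(t$float)) return(t$float)
    .dequantize_tensor(t$q, list(scale = t$scale, zp = t$zp))
  })
}

#' Dynamic-range quantization
#'
#' Stores every weight matrix of a trained forecaster as signed 8-bit values
#' with per-tensor affine scale/zero-point; inference dequantizes the weights
#' and computes activations in floating point, so outputs remain
#' floating-point glucose values. Each dequantized weight is within one
#' quantization step of the original.
#'
#' @param model a fitted `"glucose_forecaster"`.
#' @return object of class `"quantized_forecaster"` with `mode =
#'   "dynamic_range"`.
#' @export
quantize_dynamic <- function(model) {
  stopifnot(inherits(model, "glucose_forecaster"))
  structure(list(base = model, mode = "dynamic_range",
                 qweights = .quantize_weights(model$weights),
                 act = NULL),
            class = "quantized_forecaster")
}

#' Representative calibration set
#'
#' Returns the last `n` windows of the combined train + validation blocks in
#' chronological order. Ordered (rather than randomly sampled) data are
#' required because of the time-series nature of the task: the calibration
#' set must cover the activation ranges the model actually visits on recent,
#' contiguous data.
#'
#' @param split a `"dataset_split"`.
#' @param n number of calibration windows, between 100 and 500.
#' @return a `"cgm_windows"` collection of `n` chronologically ordered
#'   windows.
#' @export
select_calibration <- function(split, n = 300L) {
  stopifnot(inherits(split, "dataset_split"))
  if (n < 100 || n > 500)
    stop("calibration size must lie in [100, 500]")
  n_tv <- length(split$train) + length(split$validation)
  if (n_tv < n)
    stop("insufficient windows: train+validation has ", n_tv, ", need ", n)
  n_from_val <- min(n, length(split$validation))
  n_from_tr <- n - n_from_val
  pieces <- list()
  if (n_from_tr > 0) {
    ntr <- length(split$train)
    pieces$train <- split$train[(ntr - n_from_tr + 1):ntr]
  }
  nv <- length(split$validation)
  pieces$val <- split$validation[(nv - n_from_val + 1):nv]
  x <- do.call(abind3, lapply(pieces, function(p) p$x))
  structure(list(x = x,
                 y = unname(unlist(lapply(pieces, function(p) p$y))),
                 anchor = unname(unlist(lapply(pieces, function(p) p$anchor))),
                 feature_names = split$train$feature_names,
                 window_len = split$train$window_len, ph = split$train$ph,
                 patient_id = split$train$patient_id),
            class = "cgm_windows")
}

# bind 3-d arrays along the third axis
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n3 <- sum(vapply(xs, function(a) dim(a)[3], numeric(1)))
  out <- array(NA_real_, c(d[1], d[2], n3), dimnames = dimnames(xs[[1]]))
  at <- 0L
  for (a in xs) {
    k <- dim(a)[3]
    out[, , at + seq_len(k)] <- a
    at <- at + k
  }
  out
}

# tensor names fake-quantized between layers, per architecture
.act_tensor_names <- function(arch) {
  if (arch == "cnn") c("input", "conv1", "pool1", "conv2", "pool2",
                       "dense", "output")
  else c("input", "lstm_c", "lstm_h", "dense", "output")
}

# record per-tensor activation min/max over a forward pass
.calibrate_activations <- function(model, calib) {
  env <- new.env()
  for (nm in .act_tensor_names(model$arch))
    assign(nm, c(Inf, -Inf), envir = env)
  rec <- function(nm) {
    force(nm)
    function(x) {
      r <- get(nm, envir = env)
      assign(nm, c(min(r[1], min(x)), max(r[2], max(x))), envir = env)
      x
    }
  }
  fq <- stats::setNames(lapply(.act_tensor_names(model$arch), rec),
                        .act_tensor_names(model$arch))
  X <- .batch_array(calib, model$scaling)
  invisible(.net_predict(model$arch, model$weights, X, model$config, fq = fq))
  ranges <- lapply(.act_tensor_names(model$arch),
                   function(nm) get(nm, envir = env))
  names(ranges) <- .act_tensor_names(model$arch)
  lapply(ranges, function(r) {
    if (r[1] == r[2]) {
      warning("calibration range collapsed; widening by one step")
      r[2] <- r[1] + 1e-3
    }
    scale <- (r[2] - r[1]) / 255
    list(min = r[1], max = r[2], scale = scale,
         zp = as.integer(round(-r[1] / scale)))
  })
}

# uint8 fake-quantization closure for one calibrated tensor
.fq_uint8 <- function(ar, overflow = "saturate", dequant = TRUE) {
  function(x) {
    q <- round(x / ar$scale) + ar$zp
    q <- if (overflow == "wrap") q %% 256 else pmin(pmax(q, 0), 255)
    if (dequant) ar$scale * (q - ar$zp) else q
  }
}

#' Full-integer quantization
#'
#' Emulates end-to-end 8-bit inference: weights are stored as signed 8-bit
#' tensors and every inter-layer activation (including model input and
#' output) is re-quantized onto an unsigned 8-bit affine grid whose range is
#' calibrated from a representative set of ordered windows. Out-of-range
#' activations saturate at 0/255 by default; a wraparound switch on the
#' output tensor exists to exercise the overflow-reconstruction
#' post-processing.
#'
#' @param model a fitted `"glucose_forecaster"`.
#' @param calib a [select_calibration()] window collection from the model's
#'   own patient.
#' @return object of class `"quantized_forecaster"` with `mode =
#'   "full_integer"` and per-tensor activation scales/zero-points.
#' @export
quantize_full_int <- function(model, calib) {
  stopifnot(inherits(model, "glucose_forecaster"),
            inherits(calib, "cgm_windows"))
  structure(list(base = model, mode = "full_integer",
                 qweights = .quantize_weights(model$weights),
                 act = .calibrate_activations(model, calib)),
            class = "quantized_forecaster")
}

#' @export
print.quantized_forecaster <- function(x, ...) {
  cat(sprintf("%s forecaster, %s quantization (8-bit weights%s)\n",
              toupper(x$base$arch),
              if (x$mode == "dynamic_range") "dynamic-range" else "full-integer",
              if (x$mode == "full_integer") ", uint8 activations" else ""))
  invisible(x)
}

#' Predict with a quantized forecaster
#'
#' Dynamic-range mode dequantizes the 8-bit weights and computes in floating
#' point. Full-integer mode additionally re-quantizes every inter-layer
#' activation onto its calibrated uint8 grid; `type = "level"` returns the
#' raw unsigned 8-bit output levels, `type = "dequantized"` (default) maps
#' them back to the training-data scale.
#'
#' @param object a `"quantized_forecaster"`.
#' @param newdata a `"cgm_windows"` collection.
#' @param type `"dequantized"` or `"level"` (full-integer only).
#' @param overflow `"saturate"` (default: out-of-range output clamps to
#'   0/255) or `"wrap"` (modulo-256 wraparound on the output tensor, for
#'   exercising [reconstruct_overflow()]).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.quantized_forecaster <- function(object, newdata,
                                         type = c("dequantized", "level"),
                                         overflow = c("saturate", "wrap"),
                                         ...) {
  type <- match.arg(type)
  overflow <- match.arg(overflow)
  base <- object$base
  W <- .dequantize_weights(object$qweights)
  X <- if (inherits(newdata, "cgm_windows")) .batch_array(newdata, base$scaling)
       else stop("newdata must be a cgm_windows collection")
  if (object$mode == "dynamic_range") {
    p <- .net_predict(base$arch, W, X, base$config)
    if (!is.null(base$scaling))
      p <- p * base$scaling$y_sd + base$scaling$y_mean
    if (type == "level") stop("level output only exists for full_integer mode")
    return(p)
  }
  nms <- .act_tensor_names(base$arch)
  fq <- stats::setNames(lapply(nms, function(nm) {
    if (nm == "output")
      .fq_uint8(object$act[[nm]], overflow = overflow,
                dequant = (type == "dequantized"))
    else .fq_uint8(object$act[[nm]])
  }), nms)
  p <- .net_predict(base$arch, W, X, base$config, fq = fq)
  if (type == "dequantized" && !is.null(base$scaling))
    p <- p * base$scaling$y_sd + base$scaling$y_mean
  p
}

#' 0-255 level normalization of glucose values
#'
#' Affine remap of the CGM reporting range (10-600 mg/dL by default) onto the
#' 256 unsigned 8-bit levels, used as the pre-processing that avoids uint8
#' output overflow at the cost of a coarser prediction granularity of
#' `(600 - 10) / 255 = 2.31` mg/dL per level.
#'
#' @param glucose_min,glucose_max mapped range, mg/dL.
#' @param levels number of representable levels (256).
#' @return object of class `"normalization_spec"` with the derived `step`
#'   (mg/dL per level).
#' @export
normalization_spec <- function(glucose_min = 10, glucose_max = 600,
                               levels = 256L) {
  stopifnot(glucose_max > glucose_min, levels >= 2)
  structure(list(glucose_min = glucose_min, glucose_max = glucose_max,
                 levels = as.integer(levels),
                 step = (glucose_max - glucose_min) / (levels - 1)),
            class = "normalization_spec")
}

#' @rdname normalization_spec
#' @param values glucose values, mg/dL (clipped to the mapped range).
#' @param spec a `normalization_spec`.
#' @return `normalize_levels`: integer levels in 0..(levels-1);
#'   `denormalize_levels`: glucose values, mg/dL.
#' @export
normalize_levels <- function(values, spec = normalization_spec()) {
  v <- .clip(values, spec$glucose_min, spec$glucose_max)
  round((v - spec$glucose_min) / spec$step)
}

#' @rdname normalization_spec
#' @param level_values level values (integer or fractional).
#' @export
denormalize_levels <- function(level_values, spec = normalization_spec()) {
  spec$glucose_min + level_values * spec$step
}

#' Remap a window collection onto 0-255 levels
#'
#' Applies the level normalization to the CGM feature row and the target;
#' IOB and carbohydrate rows are remapped with fixed physiological ranges
#' (0-20 U and 0-200 g) onto the same 0-255 grid. The returned collection
#' carries the spec in its `"normalized"` attribute; predictions made on it
#' are decoded with [denormalize_levels()].
#'
#' @param windows a `"cgm_windows"` collection.
#' @param spec a [normalization_spec()].
#' @param iob_max,carbs_max upper bounds of the IOB and carb remaps.
#' @return a `"cgm_windows"` collection in level units.
#' @export
normalize_windows <- function(windows, spec = normalization_spec(),
                              iob_max = 20, carbs_max = 200) {
  stopifnot(inherits(windows, "cgm_windows"))
  x <- windows$x
  x["cgm", , ] <- normalize_levels(x["cgm", , ], spec)
  x["iob", , ] <- round(.clip(x["iob", , ], 0, iob_max) / iob_max *
                          (spec$levels - 1))
  x["carbs", , ] <- round(.clip(x["carbs", , ], 0, carbs_max) / carbs_max *
                            (spec$levels - 1))
  out <- windows
  out$x <- x
  out$y <- normalize_levels(windows$y, spec)
  attr(out, "normalized") <- spec
  out
}

#' Parameters of the uint8 overflow reconstruction
#'
#' @param high_threshold level at or above which the overflow state machine
#'   examines an element (default 240).
#' @param deltaY level drop per minute treated as physically impossible
#'   (default 50: glucose cannot fall by 50 mg/dL in one minute).
#' @param wrap_delta levels added back when the overflow state applies
#'   (default 255).
#' @return object of class `"reconstruction_params"`.
#' @export
reconstruction_params <- function(high_threshold = 240, deltaY = 50,
                                  wrap_delta = 255) {
  if (high_threshold >= 256) stop("high_threshold must be < 256")
  if (deltaY <= 0) stop("deltaY must be > 0")
  structure(list(high_threshold = high_threshold, deltaY = deltaY,
                 wrap_delta = wrap_delta),
            class = "reconstruction_params")
}

#' Reconstruct uint8 overflow in a predicted level series
#'
#' Undoes the modulo wraparound that an unsigned 8-bit output suffers when
#' the underlying value exceeds 255, exploiting that a glucose drop of
#' `deltaY` (50) levels in a single minute is physically impossible. A
#' boolean overflow state (initially off) is maintained: an element at or
#' above `high_threshold` turns the state off when it sits `deltaY` above
#' its predecessor (overflow exit) and on when it sits `deltaY` above its
#' successor (overflow entry); the toggling elements themselves are emitted
#' unshifted, and every other element is emitted shifted by `wrap_delta`
#' while the state is on. Boundary elements lacking the examined neighbour
#' skip that check. On series whose true values stay within \[10, 510\],
#' change by less than `deltaY` per minute and cross the 255 boundary
#' through a sample in \[`high_threshold`, 255\], this is the exact inverse
#' of the wrap operator (see [wrap_encode()]).
#'
#' @param levels predicted levels in \[0, 255\].
#' @param params a [reconstruction_params()].
#' @return reconstructed series (levels, possibly above 255).
#' @export
reconstruct_overflow <- function(levels, params = reconstruction_params()) {
  if (length(levels) == 0) return(numeric(0))
  if (any(levels < 0 | levels > 255)) stop("levels must lie in [0, 255]")
  thr <- params$high_threshold
  dy <- params$deltaY
  wd <- params$wrap_delta
  n <- length(levels)
  out <- numeric(n)
  ov <- FALSE
  for (i in seq_len(n)) {
    x <- levels[i]
    toggled <- FALSE
    if (x >= thr) {
      if (ov && i > 1 && (x - levels[i - 1]) >= dy) {
        ov <- FALSE; toggled <- TRUE
      } else if (!ov && i < n && (x - levels[i + 1]) >= dy) {
        ov <- TRUE; toggled <- TRUE
      }
    }
    out[i] <- if (toggled) x else x + if (ov) wd else 0
  }
  out
}

#' Wrap a level series into unsigned 8-bit range
#'
#' The forward operator that [reconstruct_overflow()] inverts: values above
#' 255 lose `wrap_delta` levels (single-wrap assumption: inputs must stay at
#' or below `255 + wrap_delta`).
#'
#' @param values level series in \[0, 255 + wrap_delta\].
#' @param wrap_delta levels subtracted on overflow (default 255).
#' @return wrapped series in \[0, 255\].
#' @export
wrap_encode <- function(values, wrap_delta = 255) {
  if (any(values > 255 + wrap_delta))
    stop("single-wrap assumption violated: values above ", 255 + wrap_delta)
  ifelse(values > 255, values - wrap_delta, values)
}

#' Random admissible glucose-level series for overflow testing
#'
#' Generates an integer level series that satisfies the reconstruction
#' admissibility conditions: values in \[10, 510\], per-minute changes below
#' 50 levels, and every crossing of the 255 boundary passing through a
#' sample in \[240, 255\]. The series alternates monotone excursions between
#' low (euglycemic-like) and high (overflow) waypoints, emulating the
#' hyperglycemic peaks that push a uint8 output past its range.
#'
#' @param len approximate series length (the last excursion completes).
#' @param seed integer seed.
#' @return integer vector of levels in \[10, 510\].
#' @export
random_admissible_series <- function(len = 300L, seed = 1L) {
  with_seed(seed, {
    out <- round(stats::runif(1, 60, 200))
    high <- FALSE
    while (length(out) < len) {
      target <- if (high) round(stats::runif(1, 280, 510))
                else round(stats::runif(1, 20, 200))
      cur <- out[length(out)]
      dir <- sign(target - cur)
      if (dir == 0) dir <- 1
      while ((target - cur) * dir > 0) {
        step <- round(stats::runif(1, 8, 49)) * dir
        nxt <- cur + step
        if ((nxt - target) * dir > 0) nxt <- target
        # force boundary crossings through the [240, 255] band
        if (cur <= 255 && nxt > 255 && cur < 240) nxt <- round(stats::runif(1, 240, 255))
        if (cur > 255 && nxt <= 255 && nxt < 240) nxt <- round(stats::runif(1, 240, 255))
        cur <- nxt
        out <- c(out, cur)
      }
      high <- !high
    }
    as.integer(out)
  })
}

#' Inference-timing harness
#'
#' Measures wall-clock single-window prediction latency. The application
#' bound is the CGM sampling period (one minute): a forecaster is viable
#' when its worst-case single-prediction time stays below 60 s. No
#' hardware-specific latency is asserted.
#'
#' @param model a `"glucose_forecaster"` or `"quantized_forecaster"`.
#' @param windows a `"cgm_windows"` collection.
#' @param repeats repetitions over the window set (0 gives an empty summary).
#' @return list with `per_window_ms`, `mean_ms`, `max_ms`, `n`.
#' @export
measure_inference <- function(model, windows, repeats = 1L) {
  stopifnot(length(windows) >= 1)
  times <- numeric(0)
  if (repeats >= 1) {
    for (r in seq_len(repeats)) {
      for (k in seq_len(length(windows))) {
        w1 <- windows[k]
        t0 <- proc.time()[["elapsed"]]
        invisible(predict(model, w1))
        times <- c(times, (proc.time()[["elapsed"]] - t0) * 1000)
      }
    }
  }
  list(per_window_ms = times,
       mean_ms = if (length(times)) mean(times) else NA_real_,
       max_ms = if (length(times)) max(times) else NA_real_,
       n = length(times))
}
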