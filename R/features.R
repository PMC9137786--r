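# Feature engineering: insulin-on-board, sliding windows, chronological split.

# linear 3-h insulin decay weights: alpha(i) = 1 - i/180, i = 0..179
.iob_alpha <- 1 - (0:179) / 180

# Dot-product kernel shared by the batch and streaming IOB paths so both
# produce bit-identical results. u_recent[1] is u(t), u_recent[2] is u(t-1), ...
.iob_dot <- function(u_recent) sum(.iob_alpha * u_recent)

#' Insulin-on-board from a per-minute insulin series
#'
#' Computes the amount of rapid-acting insulin still active at each minute as
#' a linearly decaying weighted sum of the last 3 hours of delivered insulin:
#' `IOB(t) = sum_{i=0..179} (1 - i/180) * u(t - i)`, using only past values.
#' Insulin delivered before the start of the series is taken as zero, so the
#' first 179 positions are warm-up values and are excluded downstream (the
#' first 3 h of each simulated patient are never used for modelling).
#'
#' @param insulin per-minute insulin delivery, units (>= 0), 1-min sampling.
#' @return numeric vector of IOB values (units), same length as `insulin`.
#' @export
compute_iob <- function(insulin) {
  if (any(insulin < 0)) stop("insulin must be non-negative")
  n <- length(insulin)
  pad <- c(numeric(179), insulin)
  vapply(seq_len(n), function(t) .iob_dot(pad[(t + 179):t]), numeric(1))
}

#' Aligned per-minute feature series for one patient
#'
#' Builds the model-ready feature table (CGM, IOB, carbohydrates) from a
#' simulated series. The IOB warm-up region (first 180 minutes) is retained
#' in the table but flagged, and is excluded when windows are built.
#'
#' @param sim a `"sim_output"` from [simulate_patient()] (or any list with
#'   `minute`, `cgm`, `insulin`, `carbs` per-minute vectors).
#' @return data.frame of class `"feature_series"` with columns `minute`,
#'   `cgm`, `iob`, `carbs`; attribute `warmup` gives the number of leading
#'   warm-up minutes (180).
#' @export
feature_series <- function(sim) {
  df <- data.frame(minute = sim$minute, cgm = sim$cgm,
                   iob = compute_iob(sim$insulin), carbs = sim$carbs)
  attr(df, "warmup") <- 180L
  attr(df, "patient_id") <- if (!is.null(sim$patient)) sim$patient$patient_id
                            else NA_character_
  class(df) <- c("feature_series", "data.frame")
  df
}

#' Sliding 3 x 30 input windows with 30-min-ahead targets
#'
#' Builds one sample per eligible minute (stride 1). Each sample is a
#' 3 x `window_len` matrix whose rows are the (cgm, iob, carbs) features over
#' the `window_len` most recent minutes (oldest first) and whose target is
#' the CGM reading `ph` minutes after the window's anchor (its last minute).
#' Anchors start after the 180-min IOB warm-up, so a series of length `L`
#' yields `L - 180 - window_len - ph + 1` windows.
#'
#' @param series a [feature_series()] (or data.frame with `cgm`, `iob`,
#'   `carbs` columns covering the full series including warm-up).
#' @param window_len window length in minutes (default 30).
#' @param ph prediction horizon in minutes (default 30).
#' @return object of class `"cgm_windows"`: list with `x` (array
#'   3 x window_len x n), `y` (targets, mg/dL), `anchor` (1-based anchor
#'   minutes), `feature_names`, `window_len`, `ph`, `patient_id`.
#' @export
build_windows <- function(series, window_len = 30L, ph = 30L) {
  L <- nrow(series)
  warmup <- 180L
  min_len <- warmup + window_len + ph
  if (L < min_len)
    stop("series too short: need at least ", min_len, " minutes, got ", L)
  anchors <- seq.int(warmup + window_len, L - ph)
  n <- length(anchors)
  idx <- outer(seq_len(window_len), anchors - window_len, "+")  # wl x n
  x <- array(NA_real_, dim = c(3L, window_len, n),
             dimnames = list(c("cgm", "iob", "carbs"), NULL, NULL))
  x["cgm", , ] <- series$cgm[idx]
  x["iob", , ] <- series$iob[idx]
  x["carbs", , ] <- series$carbs[idx]
  structure(list(x = x, y = series$cgm[anchors + ph],
                 anchor = as.integer(anchors),
                 feature_names = c("cgm", "iob", "carbs"),
                 window_len = as.integer(window_len), ph = as.integer(ph),
                 patient_id = attr(series, "patient_id")),
            class = "cgm_windows")
}

#' @export
length.cgm_windows <- function(x) length(x$y)

#' @export
`[.cgm_windows` <- function(x, i) {
  structure(list(x = x$x[, , i, drop = FALSE], y = x$y[i],
                 anchor = x$anchor[i], feature_names = x$feature_names,
                 window_len = x$window_len, ph = x$ph,
                 patient_id = x$patient_id),
            class = "cgm_windows")
}

#' @export
print.cgm_windows <- function(x, ...) {
  cat(sprintf("%d windows of %d x %d (features: %s), %d-min horizon\n",
              length(x), dim(x$x)[1], x$window_len,
              paste(x$feature_names, collapse = ", "), x$ph))
  invisible(x)
}

#' Chronological train / validation / test split
#'
#' Splits an ordered window collection into contiguous chronological blocks
#' in the order train, validation, test. Validation and test sizes are
#' floor-rounded; the remainder goes to the training block, so every training
#' anchor precedes every validation anchor, which precedes every test anchor.
#'
#' @param windows a [build_windows()] collection (ordered by anchor).
#' @param fractions numeric triple summing to 1 (default `c(0.7, 0.2, 0.1)`).
#' @return object of class `"dataset_split"`: list with `train`,
#'   `validation`, `test` (each a `"cgm_windows"`) and `fractions`.
#' @export
split_dataset <- function(windows, fractions = c(0.7, 0.2, 0.1)) {
  stopifnot(inherits(windows, "cgm_windows"))
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  n <- length(windows)
  if (n < 10) stop("need at least 10 windows to split, got ", n)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  structure(list(train = windows[seq_len(n_train)],
                 validation = windows[n_train + seq_len(n_val)],
                 test = windows[n_train + n_val + seq_len(n_test)],
                 fractions = fractions),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("Chronological split: %d train / %d validation / %d test windows\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Persistence (zero-order-hold) baseline forecast
#'
#' Predicts the current CGM value for the future timestamp: the skill floor
#' any trained forecaster must beat.
#'
#' @param windows a `"cgm_windows"` collection.
#' @return numeric vector of predictions (mg/dL), one per window.
#' @export
persistence_forecast <- function(windows) {
  stopifnot(inherits(windows, "cgm_windows"))
  as.numeric(windows$x["cgm", windows$window_len, ])
}

#' Write / read a window dataset as CSV with sidecar metadata
#'
#' Each row holds one sample: `anchor`, `target`, then the flattened
#' 3 x window_len feature matrix (feature rows in order, oldest minute
#' first). Values use 17 significant digits so the round trip is bit-exact.
#' A `<path>.meta.yaml` sidecar records window length, horizon and feature
#' order.
#'
#' @param windows a `"cgm_windows"` collection.
#' @param path CSV file path.
#' @return `write_windows_csv` returns `path` invisibly; `read_windows_csv`
#'   returns the reconstructed `"cgm_windows"` object.
#' @export
write_windows_csv <- function(windows, path) {
  n <- length(windows)
  wl <- windows$window_len
  feat <- windows$feature_names
  cols <- as.vector(t(outer(feat, seq_len(wl), paste, sep = "_t")))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("anchor", "target", cols), collapse = ","), con)
  flat <- matrix(aperm(windows$x, c(2, 1, 3)), nrow = wl * 3)  # (wl*3) x n
  lines <- vapply(seq_len(n), function(k) {
    paste(c(sprintf("%d", windows$anchor[k]), sprintf("%.17g", windows$y[k]),
            sprintf("%.17g", flat[, k])), collapse = ",")
  }, character(1))
  writeLines(lines, con)
  meta <- list(window_len = wl, ph = windows$ph, feature_order = feat,
               n_windows = n,
               patient_id = if (is.null(windows$patient_id)) NA
                            else windows$patient_id)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  df <- utils::read.csv(path)
  n <- nrow(df)
  wl <- meta$window_len
  flat <- t(as.matrix(df[, -(1:2), drop = FALSE]))  # (wl*3) x n
  x <- aperm(array(flat, dim = c(wl, 3, n)), c(2, 1, 3))
  dimnames(x) <- list(meta$feature_order, NULL, NULL)
  structure(list(x = x, y = df$target, anchor = as.integer(df$anchor),
                 feature_names = meta$feature_order,
                 window_len = as.integer(wl), ph = as.integer(meta$ph),
                 patient_id = if (is.null(meta$patient_id) ||
                                  all(is.na(meta$patient_id))) NA_character_
                              else meta$patient_id),
            class = "cgm_windows")
}
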