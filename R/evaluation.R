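# Evaluation: prediction-horizon RMSE and Clarke Error Grid analysis.

#' Bundle predictions with their references
#'
#' @param reference reference CGM values at anchor + ph, mg/dL (> 0).
#' @param predicted predicted CGM values at anchor + ph, mg/dL.
#' @param anchor optional anchor minutes.
#' @param ph prediction horizon, minutes.
#' @param patient_id,model,quantization optional tags used in reports.
#' @return data.frame of class `"prediction_series"`.
#' @export
prediction_series <- function(reference, predicted, anchor = NULL, ph = 30L,
                              patient_id = NA_character_,
                              model = NA_character_,
                              quantization = "float") {
  if (length(reference) != length(predicted))
    stop("reference and predicted must have equal length")
  if (any(reference <= 0)) stop("reference values must be positive")
  df <- data.frame(anchor = if (is.null(anchor)) seq_along(reference)
                            else anchor,
                   reference = reference, predicted = predicted)
  attr(df, "ph") <- as.integer(ph)
  attr(df, "patient_id") <- patient_id
  attr(df, "model") <- model
  attr(df, "quantization") <- quantization
  class(df) <- c("prediction_series", "data.frame")
  df
}

#' Root-mean-square prediction error
#'
#' The square root of the mean squared difference between the predicted and
#' the reference CGM values over all predicted timestamps, in mg/dL.
#'
#' @param series a [prediction_series()], or a numeric vector of references.
#' @param predicted predicted values (when `series` is a plain vector).
#' @return RMSE in mg/dL.
#' @export
rmse <- function(series, predicted = NULL) {
  if (inherits(series, "prediction_series")) {
    r <- series$reference
    p <- series$predicted
  } else {
    r <- series
    p <- predicted
  }
  if (length(r) == 0) stop("cannot compute RMSE of an empty series")
  if (length(r) != length(p)) stop("reference/prediction length mismatch")
  sqrt(mean((r - p)^2))
}

#' Clarke Error Grid zone of one or more prediction pairs
#'
#' Assigns each (reference, predicted) glucose pair to one of the five
#' clinical-accuracy zones of the Clarke Error Grid using the canonical
#' piecewise boundaries, evaluated in the order A, E, C, D, with B as the
#' remainder:
#' \itemize{
#'   \item A - clinically accurate: within 20\% of the reference, or both
#'     values below 70 mg/dL.
#'   \item E - erroneous treatment: reference >= 180 with prediction <= 70,
#'     or reference <= 70 with prediction >= 180.
#'   \item C - overcorrection: reference in \[70, 290\] with prediction >=
#'     reference + 110, or reference in \[130, 180\] with prediction <=
#'     (7/5) reference - 182.
#'   \item D - failure to detect: reference >= 240 with prediction in
#'     \[70, 180\], or reference <= 70 with prediction in \[70, 180\].
#'   \item B - benign error: everything else.
#' }
#'
#' @param reference reference glucose, mg/dL, in (0, 600].
#' @param predicted predicted glucose, mg/dL, in (0, 600].
#' @return character vector of zone labels (`"A"`..`"E"`).
#' @export
ceg_zone <- function(reference, predicted) {
  if (any(reference <= 0) || any(predicted <= 0))
    stop("glucose values must be positive")
  n <- max(length(reference), length(predicted))
  r <- rep_len(reference, n)
  p <- rep_len(predicted, n)
  zone <- rep("B", n)
  a <- (abs(p - r) <= 0.2 * r) | (r < 70 & p < 70)
  e <- (r >= 180 & p <= 70) | (r <= 70 & p >= 180)
  c_ <- (r >= 70 & r <= 290 & p >= r + 110) |
        (r >= 130 & r <= 180 & p <= (7 / 5) * r - 182)
  d <- (r >= 240 & p >= 70 & p <= 180) | (r <= 70 & p >= 70 & p <= 180)
  zone[d] <- "D"
  zone[c_ & !d] <- "C"
  zone[e] <- "E"
  zone[a] <- "A"
  zone
}

#' Clarke Error Grid zone summary
#'
#' Counts and percentages of predictions per zone; the zones partition the
#' predictions, so percentages sum to 100.
#'
#' @param series a [prediction_series()] (or reference vector).
#' @param predicted predicted values (when `series` is a plain vector).
#' @return object of class `"ceg_summary"`: list with `counts`, `percent`
#'   (both named A-E) and `n`.
#' @export
ceg_summary <- function(series, predicted = NULL) {
  if (inherits(series, "prediction_series")) {
    r <- series$reference
    p <- series$predicted
  } else {
    r <- series
    p <- predicted
  }
  if (length(r) == 0) stop("cannot summarize an empty series")
  z <- factor(ceg_zone(r, p), levels = c("A", "B", "C", "D", "E"))
  counts <- table(z)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 percent = stats::setNames(100 * as.numeric(counts) / length(r),
                                           names(counts)),
                 n = length(r)),
            class = "ceg_summary")
}

#' @export
print.ceg_summary <- function(x, ...) {
  cat("Clarke Error Grid zones (% of", x$n, "predictions):\n")
  cat(paste(sprintf("%s %.1f", names(x$percent), x$percent),
            collapse = "; "), "\n")
  invisible(x)
}

#' Clarke Error Grid plot
#'
#' Scatter of predicted versus reference glucose with the canonical zone
#' boundaries overlaid.
#'
#' @param x a [prediction_series()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.prediction_series <- function(x, ...) {
  zone <- ceg_zone(x$reference, x$predicted)
  cols <- c(A = "forestgreen", B = "olivedrab3", C = "gold",
            D = "darkorange", E = "firebrick")
  graphics::plot(x$reference, x$predicted, col = cols[zone], pch = 20,
                 cex = 0.5, xlim = c(0, 400), ylim = c(0, 400),
                 xlab = "reference glucose (mg/dL)",
                 ylab = "predicted glucose (mg/dL)", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::abline(0, 1.2, col = "grey60")
  graphics::abline(0, 0.8, col = "grey60")
  graphics::segments(c(70, 0, 240, 0, 180, 70), c(0, 70, 70, 180, 70, 180),
                     c(70, 70, 400, 70, 400, 70), c(56, 70, 70, 180, 70, 400),
                     col = "grey60")
  graphics::legend("topleft", names(cols), col = cols, pch = 20, bty = "n")
  invisible(x)
}

#' Study metrics report
#'
#' Aggregates prediction series into one row per (model, quantization)
#' configuration: population mean and sample standard deviation (n - 1) of
#' the per-patient RMSE, pooled Clarke Error Grid percentages over all test
#' predictions of the cell, and the best/worst patients by RMSE and by
#' zone-A percentage.
#'
#' @param series_list list of [prediction_series()] objects (one per
#'   patient, model and quantization combination).
#' @return object of class `"metrics_report"`: list with `table`
#'   (data.frame), `per_patient` (data.frame of per-patient RMSE and zone-A
#'   percentage) and `best_worst`.
#' @export
build_report <- function(series_list) {
  if (length(series_list) == 0) stop("need at least one prediction series")
  per <- do.call(rbind, lapply(series_list, function(s) {
    cs <- ceg_summary(s)
    data.frame(patient_id = attr(s, "patient_id"), model = attr(s, "model"),
               quantization = attr(s, "quantization"), rmse = rmse(s),
               zone_a_pct = cs$percent[["A"]], n = nrow(s))
  }))
  cells <- unique(per[, c("model", "quantization")])
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- per$model == cells$model[i] & per$quantization == cells$quantization[i]
    ss <- series_list[sel]
    pooled <- ceg_summary(
      do.call(rbind, lapply(ss, function(s) s[, c("reference", "predicted")])) |>
        (\(df) prediction_series(df$reference, df$predicted))()
    )
    data.frame(model = cells$model[i], quantization = cells$quantization[i],
               n_patients = sum(sel),
               rmse_mean = mean(per$rmse[sel]),
               rmse_sd = if (sum(sel) > 1) stats::sd(per$rmse[sel]) else 0,
               ceg_a = pooled$percent[["A"]], ceg_b = pooled$percent[["B"]],
               ceg_c = pooled$percent[["C"]], ceg_d = pooled$percent[["D"]],
               ceg_e = pooled$percent[["E"]])
  }))
  rownames(tab) <- NULL
  bw <- list(
    best_rmse = per$patient_id[which.min(per$rmse)],
    worst_rmse = per$patient_id[which.max(per$rmse)],
    best_zone_a = per$patient_id[which.max(per$zone_a_pct)],
    worst_zone_a = per$patient_id[which.min(per$zone_a_pct)]
  )
  structure(list(table = tab, per_patient = per, best_worst = bw),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-configuration results (RMSE mg/dL, mean +/- sd over patients;",
      "CEG % pooled):\n")
  t <- x$table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-5s %-13s  RMSE %5.1f +/- %4.1f   CEG A %5.1f; B %5.1f; C %4.1f; D %4.1f; E %4.1f\n",
                t$model[i], t$quantization[i], t$rmse_mean[i], t$rmse_sd[i],
                t$ceg_a[i], t$ceg_b[i], t$ceg_c[i], t$ceg_d[i], t$ceg_e[i]))
  invisible(x)
}

#' Write a metrics report as CSV
#' @param report a `"metrics_report"`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
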