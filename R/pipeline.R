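# End-to-end study orchestration: simulate -> featurize -> train -> quantize
# -> evaluate, with per-stage seeds derived from one global seed, persisted
# intermediates and a run manifest.

#' Experiment configuration
#'
#' One configuration object drives [run_pipeline()]. Every stochastic stage
#' derives its seed from the global `seed`, so a configuration reproduces a
#' study exactly. The object round-trips losslessly through YAML via
#' [write_experiment_config()] / [read_experiment_config()].
#'
#' @param n_patients number of virtual patients.
#' @param n_days simulated days per patient.
#' @param scenarios character subset of `c("realistic", "ideal")`.
#' @param window_len,ph input window and prediction horizon, minutes.
#' @param fractions chronological train/validation/test fractions.
#' @param archs architectures to train, subset of `c("cnn", "lstm")`.
#' @param grid `"none"` (reference configurations) or `"default"`
#'   (per-patient grid search).
#' @param train named list overriding [train_control()] fields (e.g.
#'   `list(max_epochs = 30, learning_rate = 0.05, standardize = TRUE)`).
#' @param normalize remap features and targets onto 0-255 levels before
#'   training (the coarse-granularity pre-processing that keeps a uint8
#'   output in range).
#' @param quantization modes to emulate, subset of
#'   `c("dynamic_range", "full_integer")`.
#' @param calib_n representative-set size for full-integer calibration.
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @return object of class `"experiment_config"`.
#' @export
experiment_config <- function(n_patients = 10L, n_days = 30L,
                              scenarios = "realistic",
                              window_len = 30L, ph = 30L,
                              fractions = c(0.7, 0.2, 0.1),
                              archs = c("cnn", "lstm"), grid = "none",
                              train = list(), normalize = FALSE,
                              quantization = c("dynamic_range", "full_integer"),
                              calib_n = 300L, out_dir = tempfile("cgmcast_run_"),
                              seed = 1L) {
  cfg <- structure(list(n_patients = as.integer(n_patients),
                        n_days = as.integer(n_days),
                        scenarios = scenarios, window_len = as.integer(window_len),
                        ph = as.integer(ph), fractions = fractions,
                        archs = archs, grid = grid, train = train,
                        normalize = isTRUE(normalize),
                        quantization = quantization,
                        calib_n = as.integer(calib_n),
                        out_dir = out_dir, seed = as.integer(seed)),
                   class = "experiment_config")
  validate_config(cfg)
  cfg
}

#' @rdname experiment_config
#' @param config an `"experiment_config"`.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$n_patients < 1 || config$n_days < 1)
    stop("n_patients and n_days must be >= 1")
  if (!all(config$scenarios %in% c("realistic", "ideal")) ||
      length(config$scenarios) < 1)
    stop("scenarios must be a subset of c('realistic', 'ideal')")
  if (length(config$fractions) != 3 || abs(sum(config$fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  if (!all(config$archs %in% c("cnn", "lstm")))
    stop("archs must be a subset of c('cnn', 'lstm')")
  if (!config$grid %in% c("none", "default"))
    stop("grid must be 'none' or 'default'")
  if (!all(config$quantization %in% c("dynamic_range", "full_integer")))
    stop("unknown quantization mode")
  invisible(config)
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  out$fractions <- sprintf("%.17g", out$fractions)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$fractions <- as.numeric(raw$fractions)
  do.call(experiment_config, raw)
}

# train_control derived from the config for one (patient, arch) pair
.control_for <- function(config, pat_idx, arch) {
  args <- config$train
  args$seed <- derive_seed(config$seed, 5L,
                           pat_idx * 10L + match(arch, c("cnn", "lstm")))
  do.call(train_control, args)
}

#' Run the full forecasting study
#'
#' Executes all stages in order for every requested scenario, patient and
#' architecture: simulation, feature engineering (IOB, windows,
#' chronological split, optional 0-255 normalization), training (reference
#' configurations or per-patient grid search), quantization emulation, and
#' evaluation. Intermediates (per-patient simulation CSVs, model weight
#' archives, the report CSV) are persisted under `config$out_dir`; a rerun
#' with `resume = TRUE` reuses any stage output already on disk. A manifest
#' with the configuration hash and per-file checksums is written alongside.
#'
#' @param config an [experiment_config()].
#' @param resume reuse existing stage outputs in `out_dir`.
#' @param quiet suppress progress messages.
#' @return list with `report` (a `"metrics_report"`), `series` (all
#'   prediction series), `models`, `manifest`.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  write_experiment_config(config, file.path(config$out_dir, "config.yaml"))
  patients <- draw_patients(config$n_patients, seed = config$seed)
  norm_spec <- if (config$normalize) normalization_spec() else NULL
  series_out <- list()
  models_out <- list()
  files <- character(0)

  # RMSE is reported per scenario; CEG only makes clinical sense on the
  # realistic (hypo/hyper) scenario and is computed there by build_report.
  for (scen in config$scenarios) {
    scfg <- scenario_config(scen, n_days = config$n_days, seed = config$seed)
    for (pi in seq_along(patients)) {
      pat <- patients[[pi]]
      sim_path <- file.path(config$out_dir,
                            sprintf("sim_%s_%s.csv", scen, pat$patient_id))
      if (resume && file.exists(sim_path)) {
        say("  [simulate] reusing ", sim_path)
        simdf <- read_sim_csv(sim_path)
        sim <- list(minute = simdf$minute, true_glucose = simdf$true_glucose,
                    cgm = simdf$cgm, insulin = simdf$insulin,
                    carbs = simdf$carbs, patient = pat)
      } else {
        say("  [simulate] ", scen, " ", pat$patient_id)
        sim <- simulate_patient(pat, scfg)
        write_sim_csv(sim, sim_path)
      }
      files <- c(files, sim_path)
      windows <- build_windows(feature_series(sim), config$window_len,
                               config$ph)
      if (config$normalize) windows <- normalize_windows(windows, norm_spec)
      split <- split_dataset(windows, config$fractions)
      decode <- function(v) if (config$normalize)
        denormalize_levels(v, norm_spec) else v
      ref <- decode(split$test$y)

      for (arch in config$archs) {
        ctl <- .control_for(config, pi, arch)
        model_path <- file.path(config$out_dir,
                                sprintf("model_%s_%s_%s.yaml", scen,
                                        pat$patient_id, arch))
        if (resume && file.exists(model_path)) {
          say("  [train] reusing ", model_path)
          fit <- load_forecaster(model_path)
        } else {
          say("  [train] ", arch, " for ", pat$patient_id, " (", scen, ")")
          fit <- if (config$grid == "default")
            grid_search(split, arch, control = ctl)$model
          else fit_forecaster(split, arch, control = ctl)
          save_forecaster(fit, model_path)
        }
        files <- c(files, model_path)
        models_out[[paste(scen, pat$patient_id, arch, sep = "_")]] <- fit
        tag <- function(q) paste(scen, pat$patient_id, arch, q, sep = "_")
        series_out[[tag("float")]] <- prediction_series(
          ref, decode(predict(fit, split$test)), anchor = split$test$anchor,
          ph = config$ph, patient_id = pat$patient_id,
          model = paste0(arch, "_", scen), quantization = "float")
        if ("dynamic_range" %in% config$quantization) {
          qd <- quantize_dynamic(fit)
          series_out[[tag("dynamic_range")]] <- prediction_series(
            ref, decode(predict(qd, split$test)), anchor = split$test$anchor,
            ph = config$ph, patient_id = pat$patient_id,
            model = paste0(arch, "_", scen), quantization = "dynamic_range")
        }
        if ("full_integer" %in% config$quantization) {
          qf <- quantize_full_int(fit, select_calibration(split, config$calib_n))
          series_out[[tag("full_integer")]] <- prediction_series(
            ref, decode(predict(qf, split$test)), anchor = split$test$anchor,
            ph = config$ph, patient_id = pat$patient_id,
            model = paste0(arch, "_", scen), quantization = "full_integer")
        }
      }
    }
  }
  report <- build_report(series_out)
  report_path <- file.path(config$out_dir, "report.csv")
  write_report_csv(report, report_path)
  files <- c(files, report_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(file.path(config$out_dir, "config.yaml"))),
    files = as.list(tools::md5sum(unique(files))),
    version = as.character(utils::packageVersion("cgmcast")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  list(report = report, series = series_out, models = models_out,
       manifest = manifest)
}

#' Streaming per-minute prediction
#'
#' Wraps a trained (or quantized) forecaster as an online predictor: each
#' new minute of (cgm, insulin, carbs) updates the insulin-on-board
#' incrementally with the same kernel as the batch path, forms the current
#' 3 x window matrix, and emits the 30-min-ahead prediction. The first
#' prediction appears once 210 minutes of history have accumulated (180 for
#' the IOB warm-up plus the 30-min window); a gap in the minute sequence
#' pauses the stream, reports a missing-data state, and restarts the warm-up.
#'
#' @param model a `"glucose_forecaster"` or `"quantized_forecaster"`.
#' @param normalize optional [normalization_spec()] when the model was
#'   trained on 0-255 levels; the stream then encodes inputs and decodes the
#'   prediction.
#' @param iob_max,carbs_max remap bounds used when `normalize` is set (must
#'   match [normalize_windows()]).
#' @return object of class `"glucose_stream"` with methods
#'   `$push(minute, cgm, insulin, carbs)` (returns a list with `prediction`
#'   - `NA` during warm-up - and `status` among `"warmup"`, `"ok"`,
#'   `"gap"`) and `$state()`.
#' @export
glucose_stream <- function(model, normalize = NULL, iob_max = 20,
                           carbs_max = 200) {
  wl <- if (inherits(model, "quantized_forecaster")) model$base$window_len
        else model$window_len
  env <- new.env()
  env$insulin_buf <- numeric(180)   # oldest .. newest, zero-padded cold start
  env$cgm_buf <- numeric(0)
  env$iob_buf <- numeric(0)
  env$carbs_buf <- numeric(0)
  env$seen <- 0L
  env$last_minute <- NA_integer_
  push <- function(minute, cgm, insulin, carbs) {
    gapped <- FALSE
    if (!is.na(env$last_minute) && minute != env$last_minute + 1L) {
      # missing minutes: pause, restart the warm-up from this sample
      env$insulin_buf <- numeric(180)
      env$cgm_buf <- env$iob_buf <- env$carbs_buf <- numeric(0)
      env$seen <- 0L
      gapped <- TRUE
    }
    env$last_minute <- as.integer(minute)
    env$insulin_buf <- c(env$insulin_buf[-1], insulin)
    iob <- .iob_dot(rev(env$insulin_buf))
    keep <- function(b, v) { b <- c(b, v); if (length(b) > wl) b[-1] else b }
    env$cgm_buf <- keep(env$cgm_buf, cgm)
    env$iob_buf <- keep(env$iob_buf, iob)
    env$carbs_buf <- keep(env$carbs_buf, carbs)
    env$seen <- env$seen + 1L
    if (env$seen < 180L + wl)
      return(list(prediction = NA_real_,
                  status = if (gapped) "gap" else "warmup"))
    x <- rbind(cgm = env$cgm_buf, iob = env$iob_buf, carbs = env$carbs_buf)
    if (!is.null(normalize)) {
      x["cgm", ] <- normalize_levels(x["cgm", ], normalize)
      x["iob", ] <- round(.clip(x["iob", ], 0, iob_max) / iob_max *
                            (normalize$levels - 1))
      x["carbs", ] <- round(.clip(x["carbs", ], 0, carbs_max) / carbs_max *
                              (normalize$levels - 1))
    }
    w1 <- structure(list(x = array(x, c(3L, wl, 1L),
                                   dimnames = list(rownames(x), NULL, NULL)),
                         y = NA_real_, anchor = as.integer(minute),
                         feature_names = rownames(x), window_len = wl,
                         ph = if (inherits(model, "quantized_forecaster"))
                           model$base$ph else model$ph,
                         patient_id = NA_character_),
                    class = "cgm_windows")
    p <- predict(model, w1)
    if (!is.null(normalize)) p <- denormalize_levels(p, normalize)
    list(prediction = unname(p), status = "ok")
  }
  structure(list(push = push,
                 state = function() list(seen = env$seen,
                                         last_minute = env$last_minute)),
            class = "glucose_stream")
}

#' @export
print.glucose_stream <- function(x, ...) {
  s <- x$state()
  cat(sprintf("Streaming glucose predictor: %d minutes seen (last minute %s)\n",
              s$seen, s$last_minute))
  invisible(x)
}
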