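#' Virtual pediatric T1D patient parameters
#'
#' Constructs the physiological and therapy parameter set for one virtual
#' pediatric patient of the stand-in glucose-insulin simulator. The core is a
#' minimal-model ODE (plasma glucose, remote insulin action, two-compartment
#' meal absorption, two-compartment subcutaneous insulin kinetics); all rate
#' constants are per minute.
#'
#' The carbohydrate glycemic impact is calibrated to the patient's own therapy
#' settings (`correction_factor / carb_ratio` mg/dL per gram) so that the
#' bolus calculator of [compute_bolus()] is near-optimal: under unperturbed
#' boluses the simulated glucose stays close to target, mirroring ideal
#' insulin management.
#'
#' @param patient_id character label.
#' @param carb_ratio grams of carbohydrate covered by one insulin unit (> 0).
#' @param correction_factor glucose drop (mg/dL) per insulin unit (> 0).
#' @param basal_rate basal insulin infusion, units/hour (>= 0).
#' @param glucose_target therapy target and basal equilibrium glucose, mg/dL.
#' @param body_mass body mass, kg.
#' @param ode_params named list of strictly positive rate constants:
#'   `sg` glucose effectiveness (1/min), `p2` insulin-action decay (1/min),
#'   `ka` subcutaneous insulin absorption (1/min), `ke` plasma insulin
#'   elimination (1/min), `kgut` gastric emptying (1/min), `kabs` gut
#'   absorption (1/min). Insulin sensitivity and carb impact are derived from
#'   the therapy settings (see Details).
#' @return object of class `"virtual_patient"`.
#' @seealso [draw_patients()], [simulate_patient()]
#' @export
virtual_patient <- function(patient_id,
                            carb_ratio = 15,
                            correction_factor = 50,
                            basal_rate = 0.8,
                            glucose_target = 120,
                            body_mass = 40,
                            ode_params = list(sg = 0.006, p2 = 0.02,
                                              ka = 0.02, ke = 0.07,
                                              kgut = 0.035, kabs = 0.017)) {
  if (carb_ratio <= 0) stop("carb_ratio must be > 0")
  if (correction_factor <= 0) stop("correction_factor must be > 0")
  if (basal_rate < 0) stop("basal_rate must be >= 0")
  needed <- c("sg", "p2", "ka", "ke", "kgut", "kabs")
  if (!all(needed %in% names(ode_params)))
    stop("ode_params must contain: ", paste(needed, collapse = ", "))
  if (any(unlist(ode_params[needed]) <= 0))
    stop("all ODE rate constants must be strictly positive")
  p <- list(
    patient_id = as.character(patient_id),
    carb_ratio = carb_ratio,
    correction_factor = correction_factor,
    basal_rate = basal_rate,
    glucose_target = glucose_target,
    body_mass = body_mass,
    ode_params = ode_params[needed]
  )
  # derived: insulin sensitivity si (1/min per U of plasma insulin above
  # basal) calibrated so one bolus unit lowers glucose by ~correction_factor
  # at a reference glycemia of 140 mg/dL; carb impact kcarb calibrated so
  # carb_ratio grams are countered by one unit.
  p$si <- correction_factor * ode_params$ke / 140
  p$kcarb <- correction_factor / carb_ratio
  class(p) <- "virtual_patient"
  p
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat("Virtual pediatric T1D patient:", x$patient_id, "\n")
  cat(sprintf("  carb ratio %.1f g/U, correction factor %.1f mg/dL/U, basal %.2f U/h\n",
              x$carb_ratio, x$correction_factor, x$basal_rate))
  cat(sprintf("  target %.0f mg/dL, body mass %.0f kg\n",
              x$glucose_target, x$body_mass))
  invisible(x)
}

#' Draw a virtual patient population
#'
#' Draws `n` virtual pediatric patients with parameters sampled uniformly from
#' pediatric-plausible ranges (carb ratio 10-20 g/U, correction factor 35-65
#' mg/dL/U, body mass 25-55 kg, basal 0.5-1.2 U/h and rate constants in
#' physiological bands). Distinct patients receive distinct draws under a
#' fixed population seed.
#'
#' @param n number of patients.
#' @param seed integer population seed.
#' @return list of [virtual_patient] objects named `child#001`, ...
#' @export
draw_patients <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  with_seed(derive_seed(seed, 4L, 0L), {
    lapply(seq_len(n), function(i) {
      virtual_patient(
        patient_id = sprintf("child#%03d", i),
        carb_ratio = stats::runif(1, 10, 20),
        correction_factor = stats::runif(1, 35, 65),
        basal_rate = stats::runif(1, 0.5, 1.2),
        glucose_target = stats::runif(1, 110, 130),
        body_mass = stats::runif(1, 25, 55),
        ode_params = list(
          sg = stats::runif(1, 0.0015, 0.0025),
          p2 = stats::runif(1, 0.010, 0.016),
          ka = stats::runif(1, 0.015, 0.025),
          ke = stats::runif(1, 0.06, 0.08),
          kgut = stats::runif(1, 0.025, 0.045),
          kabs = stats::runif(1, 0.012, 0.022)
        )
      )
    })
  })
}

#' Scenario configuration for the meal/bolus protocol
#'
#' Defines the simulation scenario: a 5-meal daily baseline schedule
#' (45, 20, 70, 20 and 80 g at 08:00, 10:30, 13:00, 17:00 and 20:00), random
#' per-meal time shifts of up to +/-60 min and carbohydrate shifts of up to
#' +/-20 g, and either ideal management (optimal boluses, error-free sensor)
#' or realistic management (bolus noise of up to +/-3 U and CGM sensor error).
#'
#' @param scenario `"ideal"` or `"realistic"`; presets for
#'   `bolus_noise_halfwidth` (0 vs 3 U) and `sensor_error` (off vs on). The
#'   meal-schedule randomization is common to both.
#' @param n_days number of simulated days.
#' @param baseline_meals data.frame with columns `carbs` (g) and `minute`
#'   (minutes since midnight) describing the daily baseline schedule.
#' @param time_shift_halfwidth halfwidth (min) of the uniform mealtime shift.
#' @param carb_shift_halfwidth halfwidth (g) of the uniform carb shift.
#' @param bolus_noise_halfwidth halfwidth (U) of the uniform bolus noise;
#'   overrides the preset when supplied.
#' @param sensor_error logical, add CGM sensor error; overrides the preset.
#' @param seed integer scenario seed.
#' @return object of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("realistic", "ideal"),
                            n_days = 30L,
                            baseline_meals = data.frame(
                              carbs = c(45, 20, 70, 20, 80),
                              minute = c(480, 630, 780, 1020, 1200)),
                            time_shift_halfwidth = 60,
                            carb_shift_halfwidth = 20,
                            bolus_noise_halfwidth = NULL,
                            sensor_error = NULL,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(bolus_noise_halfwidth))
    bolus_noise_halfwidth <- if (scenario == "realistic") 3 else 0
  if (is.null(sensor_error))
    sensor_error <- scenario == "realistic"
  if (n_days < 1) stop("n_days must be >= 1")
  if (!all(c("carbs", "minute") %in% names(baseline_meals)))
    stop("baseline_meals needs columns 'carbs' and 'minute'")
  if (any(baseline_meals$minute < 0 | baseline_meals$minute > 1439))
    stop("baseline meal minutes must lie in [0, 1439]")
  if (time_shift_halfwidth < 0 || carb_shift_halfwidth < 0 ||
      bolus_noise_halfwidth < 0)
    stop("halfwidths must be >= 0")
  structure(list(scenario = scenario,
                 n_days = as.integer(n_days),
                 baseline_meals = baseline_meals,
                 time_shift_halfwidth = time_shift_halfwidth,
                 carb_shift_halfwidth = carb_shift_halfwidth,
                 bolus_noise_halfwidth = bolus_noise_halfwidth,
                 sensor_error = sensor_error,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d days, %d meals/day\n", x$scenario, x$n_days,
              nrow(x$baseline_meals)))
  cat(sprintf("  meal shifts +/-%g min, +/-%g g; bolus noise +/-%g U; sensor error %s\n",
              x$time_shift_halfwidth, x$carb_shift_halfwidth,
              x$bolus_noise_halfwidth, if (x$sensor_error) "on" else "off"))
  invisible(x)
}

#' Generate a randomized meal schedule
#'
#' Perturbs the baseline daily meal schedule: each mealtime is shifted by an
#' amount drawn uniformly from +/-`time_shift_halfwidth` minutes and each
#' carbohydrate amount by a uniform draw of +/-`carb_shift_halfwidth` grams
#' (clipped at 0 g). Two meals landing on the same minute of the same day
#' trigger a re-draw of the later meal's shift (error after 100 attempts).
#'
#' @param config a [scenario_config()].
#' @param seed integer seed; defaults to the config's schedule stream.
#' @return data.frame with one row per meal event: `day` (0-based),
#'   `time_of_day` (minute in 0..1439), `minute` (1-based absolute simulation
#'   minute) and `carbs` (g), ordered chronologically.
#' @export
generate_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(seed)) seed <- derive_seed(config$seed, 1L, 0L)
  base <- config$baseline_meals[order(config$baseline_meals$minute), ]
  with_seed(seed, {
    out <- vector("list", config$n_days)
    for (d in seq_len(config$n_days)) {
      used <- integer(0)
      times <- numeric(nrow(base))
      carbs <- numeric(nrow(base))
      for (m in seq_len(nrow(base))) {
        ok <- FALSE
        for (attempt in 1:100) {
          shift <- round(stats::runif(1, -config$time_shift_halfwidth,
                                      config$time_shift_halfwidth))
          t <- base$minute[m] + shift
          t <- min(max(t, 0), 1439)
          if (!(t %in% used)) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place meal ", m, " on day ", d,
                      " after 100 re-draws")
        used <- c(used, t)
        times[m] <- t
        carbs[m] <- max(0, base$carbs[m] +
                          stats::runif(1, -config$carb_shift_halfwidth,
                                       config$carb_shift_halfwidth))
      }
      out[[d]] <- data.frame(day = rep(d - 1L, length(times)),
                             time_of_day = times, carbs = carbs)
    }
    sched <- do.call(rbind, out)
    sched <- sched[order(sched$day, sched$time_of_day), ]
    sched$minute <- sched$day * 1440L + as.integer(sched$time_of_day) + 1L
    rownames(sched) <- NULL
    sched[, c("day", "time_of_day", "minute", "carbs")]
  })
}

#' Standard meal bolus calculator
#'
#' Computes the insulin bolus for a meal from the patient's therapy settings:
#' a carbohydrate term `carbs / carb_ratio` plus a correction term
#' `(glucose - target) / correction_factor`, clipped at zero units.
#'
#' @param patient a [virtual_patient].
#' @param meal_carbs grams of carbohydrate about to be ingested (>= 0).
#' @param current_glucose current glucose, mg/dL (> 0).
#' @return bolus size in insulin units (>= 0).
#' @export
compute_bolus <- function(patient, meal_carbs, current_glucose) {
  stopifnot(inherits(patient, "virtual_patient"))
  if (meal_carbs < 0) stop("meal_carbs must be >= 0")
  if (current_glucose <= 0) stop("current_glucose must be > 0")
  max(0, meal_carbs / patient$carb_ratio +
        (current_glucose - patient$glucose_target) / patient$correction_factor)
}

#' Perturb an optimal bolus with uniform noise
#'
#' Emulates human dosing error: the delivered bolus is the optimal bolus plus
#' a uniform draw from +/-`halfwidth` units, clipped at zero (insulin cannot
#' be withdrawn).
#'
#' @param units_optimal optimal bolus, units (>= 0).
#' @param halfwidth noise halfwidth, units (>= 0); 0 reproduces the optimal
#'   bolus exactly.
#' @return list with `noise` (z, units) and `delivered` (units).
#' @export
perturb_bolus <- function(units_optimal, halfwidth) {
  if (halfwidth < 0) stop("halfwidth must be >= 0")
  z <- if (halfwidth == 0) 0 else stats::runif(1, -halfwidth, halfwidth)
  list(noise = z, delivered = max(0, units_optimal + z))
}

#' Additive AR(1) CGM sensor error
#'
#' Adds first-order autoregressive Gaussian noise to the true glucose trace
#' and clips the reading to the CGM reporting range of 10-600 mg/dL. `sd` is
#' the stationary (marginal) standard deviation of the noise process; the
#' innovation sd is `sd * sqrt(1 - coef^2)`.
#'
#' @param true_glucose true glucose series, mg/dL (> 0).
#' @param enabled logical; `FALSE` returns the input unchanged (still clipped
#'   to the reporting range).
#' @param coef AR(1) coefficient (default 0.7).
#' @param sd stationary noise standard deviation, mg/dL (default 2).
#' @param seed optional integer seed.
#' @return CGM series, mg/dL, clipped to \[10, 600\].
#' @export
apply_cgm_error <- function(true_glucose, enabled = TRUE, coef = 0.7, sd = 2,
                            seed = NULL) {
  if (any(true_glucose <= 0)) stop("true_glucose must be positive")
  if (!enabled) return(pmin(pmax(true_glucose, 10), 600))
  n <- length(true_glucose)
  run <- function() {
    innov_sd <- sd * sqrt(1 - coef^2)
    e <- numeric(n)
    e[1] <- stats::rnorm(1, 0, sd)
    if (n > 1) {
      eta <- stats::rnorm(n - 1, 0, innov_sd)
      for (t in 2:n) e[t] <- coef * e[t - 1] + eta[t - 1]
    }
    pmin(pmax(true_glucose + e, 10), 600)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ODE right-hand side of the minimal-model core.
# state: G (mg/dL), X (1/min), Isc (U), Ip (U), Q1 (g), Q2 (g)
# forcing: u basal infusion (U/min); impulses are applied outside.
.glucose_rhs <- function(state, patient, u_basal) {
  op <- patient$ode_params
  ipb <- patient$basal_rate / 60 / op$ke
  G <- state[1]; X <- state[2]; Isc <- state[3]
  Ip <- state[4]; Q1 <- state[5]; Q2 <- state[6]
  c(
    -op$sg * (G - patient$glucose_target) - X * G +
      patient$kcarb * op$kabs * Q2,
    -op$p2 * X + op$p2 * patient$si * (Ip - ipb),
    u_basal - op$ka * Isc,
    op$ka * Isc - op$ke * Ip,
    -op$kgut * Q1,
    op$kgut * Q1 - op$kabs * Q2
  )
}

# One RK4 step of length dt minutes.
.rk4_step <- function(state, patient, u_basal, dt) {
  k1 <- .glucose_rhs(state, patient, u_basal)
  k2 <- .glucose_rhs(state + dt / 2 * k1, patient, u_basal)
  k3 <- .glucose_rhs(state + dt / 2 * k2, patient, u_basal)
  k4 <- .glucose_rhs(state + dt * k3, patient, u_basal)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate one virtual patient
#'
#' Runs the stand-in glucose-insulin simulator minute by minute for the
#' scenario's duration: generates the randomized meal schedule, computes the
#' optimal bolus for each meal from the pre-meal glucose, perturbs it by the
#' scenario's bolus noise, integrates the ODE core with fixed-step RK4 at
#' 1-minute resolution, and applies the CGM sensor-error model. Basal
#' insulin, boluses and corrections are summed into a single insulin channel;
#' each meal's grams are recorded entirely at its event minute.
#'
#' @param patient a [virtual_patient].
#' @param config a [scenario_config()].
#' @return object of class `"sim_output"`: list with per-minute vectors
#'   `minute` (1..n), `true_glucose`, `cgm` (mg/dL), `insulin` (U delivered
#'   during the minute), `carbs` (g), plus the realized `meals` and `boluses`
#'   tables and the `patient` / `config` used.
#' @export
simulate_patient <- function(patient, config) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(config, "scenario_config"))
  pat_idx <- suppressWarnings(as.integer(gsub("\\D", "", patient$patient_id)))
  if (is.na(pat_idx)) pat_idx <- 0L
  sched <- generate_schedule(config,
                             seed = derive_seed(config$seed, 1L, pat_idx))
  n <- config$n_days * 1440L
  op <- patient$ode_params
  u_basal <- patient$basal_rate / 60
  # basal equilibrium initial state
  state <- c(G = patient$glucose_target, X = 0,
             Isc = u_basal / op$ka, Ip = u_basal / op$ke, Q1 = 0, Q2 = 0)
  true_g <- numeric(n)
  insulin <- rep(u_basal, n)
  carbs <- numeric(n)
  meal_at <- integer(n)
  meal_at[sched$minute] <- seq_len(nrow(sched))
  boluses <- data.frame(minute = sched$minute,
                        units_optimal = rep(NA_real_, nrow(sched)),
                        noise = rep(NA_real_, nrow(sched)),
                        units_delivered = rep(NA_real_, nrow(sched)))
  bolus_seed <- derive_seed(config$seed, 2L, pat_idx)
  with_seed(bolus_seed, {
    for (t in seq_len(n)) {
      if (meal_at[t] > 0L) {
        i <- meal_at[t]
        g_now <- state["G"]
        opt <- compute_bolus(patient, sched$carbs[i], g_now)
        pb <- perturb_bolus(opt, config$bolus_noise_halfwidth)
        boluses$units_optimal[i] <- opt
        boluses$noise[i] <- pb$noise
        boluses$units_delivered[i] <- pb$delivered
        insulin[t] <- insulin[t] + pb$delivered
        carbs[t] <- sched$carbs[i]
        state["Isc"] <- state["Isc"] + pb$delivered
        state["Q1"] <- state["Q1"] + sched$carbs[i]
      }
      state <- .rk4_step(state, patient, u_basal, 1)
      g <- state[["G"]]
      if (!is.finite(g) || g > 1000 || g < 1)
        stop(sprintf("glucose ODE diverged for patient %s at minute %d (G = %.1f)",
                     patient$patient_id, t, g))
      true_g[t] <- g
    }
  })
  cgm <- apply_cgm_error(true_g, enabled = config$sensor_error,
                         seed = derive_seed(config$seed, 3L, pat_idx))
  structure(list(minute = seq_len(n), true_glucose = true_g, cgm = cgm,
                 insulin = insulin, carbs = carbs, meals = sched,
                 boluses = boluses, patient = patient, config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  n <- length(x$minute)
  cat(sprintf("Simulated series for %s: %d minutes (%.1f days), scenario '%s'\n",
              x$patient$patient_id, n, n / 1440, x$config$scenario))
  cat(sprintf("  CGM mean %.1f mg/dL; %.1f%% < 70, %.1f%% > 180\n",
              mean(x$cgm), 100 * mean(x$cgm < 70), 100 * mean(x$cgm > 180)))
  invisible(x)
}

#' Simulate a virtual patient population
#'
#' @param patients list of [virtual_patient] objects (e.g. [draw_patients()]).
#' @param config a [scenario_config()].
#' @return named list of [simulate_patient()] outputs.
#' @export
simulate_population <- function(patients, config) {
  out <- lapply(patients, simulate_patient, config = config)
  names(out) <- vapply(patients, function(p) p$patient_id, character(1))
  out
}

#' Write / read a simulated series as CSV
#'
#' The per-minute table is written with header
#' `minute,true_glucose,cgm,insulin,carbs`, UTF-8, '.' decimal separator.
#' Values are formatted with 17 significant digits so that a write/read
#' round trip reproduces the doubles bit-exactly.
#'
#' @param sim a `"sim_output"` (or any list with the five per-minute vectors).
#' @param path file path.
#' @return `write_sim_csv` returns `path` invisibly; `read_sim_csv` returns a
#'   data.frame with the five columns.
#' @export
write_sim_csv <- function(sim, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("minute,true_glucose,cgm,insulin,carbs", con)
  writeLines(sprintf("%d,%.17g,%.17g,%.17g,%.17g", sim$minute,
                     sim$true_glucose, sim$cgm, sim$insulin, sim$carbs), con)
  invisible(path)
}

#' @rdname write_sim_csv
#' @export
read_sim_csv <- function(path) {
  utils::read.csv(path, colClasses = c(minute = "integer",
                                       true_glucose = "numeric",
                                       cgm = "numeric",
                                       insulin = "numeric",
                                       carbs = "numeric"))
}
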