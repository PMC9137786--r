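# Shared fixtures and independent oracles. Expensive fixtures are built
# lazily and cached for the whole test run.

.fixtures <- new.env()

# small fixed-parameter patient used when population variation is irrelevant
tiny_patient <- function(id = "child#001") {
  virtual_patient(id, carb_ratio = 14, correction_factor = 50,
                  basal_rate = 0.8, glucose_target = 120, body_mass = 40,
                  ode_params = list(sg = 0.002, p2 = 0.014, ka = 0.02,
                                    ke = 0.07, kgut = 0.035, kabs = 0.017))
}

# 2-day realistic simulation + split, cached
tiny_split <- function() {
  if (is.null(.fixtures$tiny_split)) {
    sim <- simulate_patient(tiny_patient(),
                            scenario_config("realistic", n_days = 2, seed = 5))
    .fixtures$tiny_sim <- sim
    .fixtures$tiny_split <- split_dataset(build_windows(feature_series(sim)))
  }
  .fixtures$tiny_split
}

tiny_sim <- function() {
  invisible(tiny_split())
  .fixtures$tiny_sim
}

# quickly trained CNN on the tiny split, cached (used by quantization and
# streaming tests; skill is irrelevant there)
tiny_cnn <- function() {
  if (is.null(.fixtures$tiny_cnn))
    .fixtures$tiny_cnn <- fit_forecaster(
      tiny_split(), "cnn",
      control = train_control(learning_rate = 0.05, max_epochs = 4,
                              patience = 3, seed = 2, standardize = TRUE))
  .fixtures$tiny_cnn
}

# brute-force term-by-term evaluation of the 3-h linear-decay IOB sum:
# the independent oracle for compute_iob
iob_oracle <- function(insulin) {
  n <- length(insulin)
  out <- numeric(n)
  for (t in seq_len(n)) {
    s <- 0
    for (i in 0:179) {
      if (t - i >= 1) s <- s + (1 - i / 180) * insulin[t - i]
    }
    out[t] <- s
  }
  out
}

# independent wrap operator for the overflow-reconstruction property
wrap_oracle <- function(v) ifelse(v > 255, v - 255, v)
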