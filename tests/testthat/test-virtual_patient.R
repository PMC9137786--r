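test_that("schedule with zero halfwidths reproduces the baseline protocol", {
  cfg <- scenario_config("ideal", n_days = 1, time_shift_halfwidth = 0,
                         carb_shift_halfwidth = 0, seed = 3)
  sched <- generate_schedule(cfg)
  expect_equal(sched$time_of_day, c(480, 630, 780, 1020, 1200))
  expect_equal(sched$carbs, c(45, 20, 70, 20, 80))
  expect_equal(sched$minute, c(481, 631, 781, 1021, 1201))
})

test_that("meal perturbations respect the +/-60 min / +/-20 g bounds", {
  cfg <- scenario_config("realistic", n_days = 400, seed = 11)  # 2000 events
  sched <- generate_schedule(cfg)
  expect_equal(nrow(sched), 5 * 400)
  base <- cfg$baseline_meals
  for (m in seq_len(nrow(base))) {
    ev <- sched[seq(m, nrow(sched), by = 5), ]
    expect_true(all(abs(ev$time_of_day - base$minute[m]) <= 60))
    expect_true(all(abs(ev$carbs - base$carbs[m]) <= 20))
  }
  expect_true(all(sched$carbs >= 0))
  # no two meals of a day on the same minute
  expect_false(any(duplicated(sched[, c("day", "time_of_day")])))
})

test_that("schedule generation is deterministic for a fixed seed", {
  cfg <- scenario_config("realistic", n_days = 5, seed = 21)
  expect_identical(generate_schedule(cfg), generate_schedule(cfg))
})

test_that("bolus calculator follows the carb + correction formula with a zero clip", {
  pat <- virtual_patient("p", carb_ratio = 15, correction_factor = 50,
                         glucose_target = 120)
  expect_equal(compute_bolus(pat, 45, 170), 45 / 15 + 50 / 50)  # 4.0 U
  expect_equal(compute_bolus(pat, 0, 120), 0)
  expect_equal(compute_bolus(pat, 0, 40), 0)   # clipped, not negative
  expect_error(compute_bolus(pat, -1, 120), "meal_carbs")
  expect_error(virtual_patient("p", carb_ratio = 0), "carb_ratio")
})

test_that("bolus noise is bounded and delivered insulin never negative", {
  expect_equal(perturb_bolus(5, 0)$delivered, 5)
  deliv <- cgmcast:::with_seed(2, replicate(500, perturb_bolus(5, 3)$delivered))
  expect_true(all(deliv >= 2 & deliv <= 8))
  zs <- cgmcast:::with_seed(3, replicate(500, perturb_bolus(1, 3)$noise))
  expect_true(all(abs(zs) <= 3))
  expect_true(all(pmax(0, 1 + zs) ==
                    cgmcast:::with_seed(3, replicate(500, perturb_bolus(1, 3)$delivered))))
})

test_that("basal-only simulation stays at the model's equilibrium glucose", {
  cfg <- scenario_config("ideal", n_days = 1,
                         baseline_meals = data.frame(carbs = numeric(0),
                                                     minute = numeric(0)),
                         seed = 1)
  sim <- simulate_patient(tiny_patient(), cfg)
  expect_true(all(abs(sim$true_glucose - 120) < 1e-6))
})

test_that("a meal raises glucose and an insulin bolus lowers it", {
  # meal impulse with (effectively) no bolus: huge therapy factors
  pat <- virtual_patient("p", carb_ratio = 1e9, correction_factor = 1e9,
                         basal_rate = 0.8, glucose_target = 120)
  cfg <- scenario_config("ideal", n_days = 1,
                         baseline_meals = data.frame(carbs = 70, minute = 100),
                         time_shift_halfwidth = 0, carb_shift_halfwidth = 0,
                         seed = 1)
  sim <- simulate_patient(pat, cfg)
  pre <- sim$true_glucose[100]
  post <- sim$true_glucose[101:300]
  expect_true(all(diff(sim$true_glucose[101:160]) > 0))  # rising after meal
  expect_gt(max(post), pre)
  # bolus without meal: inject 2 U into the subcutaneous depot directly
  pat2 <- tiny_patient()
  state <- c(G = 120, X = 0, Isc = pat2$basal_rate / 60 / 0.02,
             Ip = pat2$basal_rate / 60 / 0.07, Q1 = 0, Q2 = 0)
  s_b <- state; s_b["Isc"] <- s_b["Isc"] + 2
  g_ref <- g_bol <- numeric(300)
  for (t in 1:300) {
    state <- cgmcast:::.rk4_step(state, pat2, pat2$basal_rate / 60, 1)
    s_b <- cgmcast:::.rk4_step(s_b, pat2, pat2$basal_rate / 60, 1)
    g_ref[t] <- state[["G"]]; g_bol[t] <- s_b[["G"]]
  }
  expect_true(all(g_bol[20:300] < g_ref[20:300]))
})

test_that("simulation is deterministic and satisfies the output contract", {
  cfg <- scenario_config("realistic", n_days = 2, seed = 9)
  s1 <- simulate_patient(tiny_patient(), cfg)
  s2 <- simulate_patient(tiny_patient(), cfg)
  expect_identical(s1[c("true_glucose", "cgm", "insulin", "carbs")],
                   s2[c("true_glucose", "cgm", "insulin", "carbs")])
  n <- 2 * 1440
  expect_length(s1$true_glucose, n)
  expect_length(s1$cgm, n)
  expect_true(all(s1$true_glucose > 0))
  expect_true(all(s1$insulin >= 0) && all(s1$carbs >= 0))
  # boluses folded into the single insulin channel on meal minutes
  expect_true(all(s1$insulin[s1$meals$minute] >
                    s1$patient$basal_rate / 60))
})

test_that("realistic scenario produces hyperglycemia for every patient and more excursions than ideal", {
  pats <- draw_patients(4, seed = 1)
  out_real <- out_ideal <- 0
  for (p in pats) {
    sr <- simulate_patient(p, scenario_config("realistic", n_days = 7, seed = 1))
    si <- simulate_patient(p, scenario_config("ideal", n_days = 7, seed = 1))
    expect_gt(sum(sr$cgm > 180), 0)
    out_real <- out_real + sum(sr$cgm < 70 | sr$cgm > 180)
    out_ideal <- out_ideal + sum(si$cgm < 70 | si$cgm > 180)
  }
  expect_gt(out_real, out_ideal)
  # both tails present over the population
  all_cgm <- unlist(lapply(pats, function(p)
    simulate_patient(p, scenario_config("realistic", n_days = 7, seed = 1))$cgm))
  expect_gt(sum(all_cgm < 70), 0)
  expect_gt(sum(all_cgm > 180), 0)
})

test_that("population draws are distinct and reproducible under one seed", {
  p1 <- draw_patients(5, seed = 4)
  p2 <- draw_patients(5, seed = 4)
  expect_identical(p1, p2)
  crs <- vapply(p1, function(p) p$carb_ratio, numeric(1))
  expect_equal(length(unique(crs)), 5)
  expect_true(all(vapply(p1, function(p)
    all(unlist(p$ode_params) > 0), logical(1))))
})

test_that("CGM sensor error is AR(1) with the stated marginal sd and reporting-range clip", {
  g <- rep(100, 43200)
  cgm <- apply_cgm_error(g, enabled = TRUE, coef = 0.7, sd = 2, seed = 8)
  e <- cgm - g
  expect_lt(abs(sd(e) - 2) / 2, 0.2)          # within 20% of the nominal sd
  expect_gt(cor(e[-1], e[-length(e)]), 0.5)   # strong lag-1 correlation
  expect_identical(apply_cgm_error(g, enabled = FALSE), g)
  expect_equal(apply_cgm_error(c(650, 700), enabled = FALSE), c(600, 600))
  expect_true(all(apply_cgm_error(rep(599, 1000), seed = 1) <= 600))
})

test_that("simulation CSV writer/reader round-trips bit-exactly", {
  sim <- tiny_sim()
  path <- withr::local_tempfile(fileext = ".csv")
  write_sim_csv(sim, path)
  back <- read_sim_csv(path)
  expect_identical(back$true_glucose, sim$true_glucose)
  expect_identical(back$cgm, sim$cgm)
  expect_identical(back$insulin, sim$insulin)
  expect_identical(back$carbs, sim$carbs)
  expect_identical(back$minute, sim$minute)
})
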