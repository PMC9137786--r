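test_that("RMSE matches an independent recomputation and detects offsets", {
  r <- cgmcast:::with_seed(1, runif(1000, 40, 400))
  p <- r + cgmcast:::with_seed(2, rnorm(1000, 0, 15))
  direct <- sqrt(sum((r - p)^2) / length(r))     # two-line recomputation
  expect_lt(abs(rmse(r, p) - direct), 1e-9)
  expect_equal(rmse(r, r), 0)
  expect_equal(rmse(r, r + 5), 5)
  expect_equal(rmse(prediction_series(r, r + 5)), 5)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(r, p[-1]), "mismatch")
})

test_that("Clarke zones classify the pinned boundary cases", {
  cases <- list(
    # reference, prediction, zone  (hand-evaluated from the documented
    # piecewise inequalities)
    list(100, 100, "A"), list(30, 30, "A"), list(400, 400, "A"),
    list(100, 119, "A"), list(100, 120, "A"), list(50, 60, "A"),
    list(50, 69, "A"),                        # both hypoglycemic
    list(70, 84, "A"),                        # exactly 20% above
    list(100, 121, "B"), list(100, 79, "B"), list(90, 180, "B"),
    list(150, 29, "B"),                       # just above lower C bound
    list(291, 405, "B"),                      # just outside upper C region
    list(200, 150, "B"),
    list(100, 220, "C"), list(75, 190, "C"),
    list(150, 28, "C"),                       # exactly (7/5)*150 - 182
    list(170, 50, "C"), list(290, 400, "C"),
    list(240, 120, "D"), list(300, 100, "D"), list(240, 180, "D"),
    list(240, 71, "D"), list(50, 70, "D"), list(70, 85, "D"),
    list(65, 179, "D"),
    list(50, 200, "E"), list(250, 60, "E"), list(180, 70, "E"),
    list(70, 181, "E"), list(600, 10, "E")
  )
  for (cs in cases)
    expect_equal(ceg_zone(cs[[1]], cs[[2]]), cs[[3]],
                 label = sprintf("zone of (%g, %g)", cs[[1]], cs[[2]]))
})

test_that("zone assignment is a total single-valued function on the glucose grid", {
  g <- seq(10, 600, by = 1)
  ref <- rep(g, times = length(g))
  prd <- rep(g, each = length(g))
  z <- ceg_zone(ref, prd)
  expect_length(z, length(g)^2)
  expect_true(all(z %in% c("A", "B", "C", "D", "E")))
  expect_false(anyNA(z))
  # the diagonal is always A
  expect_true(all(ceg_zone(g, g) == "A"))
  expect_error(ceg_zone(0, 100), "positive")
})

test_that("zone summary is a partition consistent with the point classifier", {
  r <- cgmcast:::with_seed(3, runif(500, 20, 450))
  p <- pmax(10, r + cgmcast:::with_seed(4, rnorm(500, 0, 60)))
  s <- ceg_summary(r, p)
  expect_equal(sum(s$percent), 100, tolerance = 1e-9)
  expect_equal(sum(s$counts), 500)
  z <- ceg_zone(r, p)
  for (zz in c("A", "B", "C", "D", "E"))
    expect_equal(s$counts[[zz]], sum(z == zz))
  perfect <- ceg_summary(r, r)
  expect_equal(perfect$percent[["A"]], 100)
  ten_r <- c(100, 50, 240, 100, 290, 150, 50, 250, 70, 120)
  ten_p <- c(100, 200, 120, 220, 400, 28, 70, 60, 85, 110)
  s10 <- ceg_summary(ten_r, ten_p)
  expect_equal(unname(s10$counts),
               unname(table(factor(ceg_zone(ten_r, ten_p),
                                   levels = c("A", "B", "C", "D", "E")))) |>
                 as.integer())
})

test_that("report aggregates per-patient RMSE with sample sd and pooled CEG", {
  mk <- function(id, off) prediction_series(rep(100, 50), rep(100 + off, 50),
                                            patient_id = id, model = "cnn",
                                            quantization = "float")
  rep1 <- build_report(list(mk("p1", 10)))
  expect_equal(rep1$table$rmse_mean, 10)
  expect_equal(rep1$table$rmse_sd, 0)
  rep2 <- build_report(list(mk("p1", 10), mk("p2", 20)))
  expect_equal(rep2$table$rmse_mean, 15)
  expect_equal(rep2$table$rmse_sd, sd(c(10, 20)))   # sample sd, 7.0710678
  expect_equal(rep2$best_worst$best_rmse, "p1")
  expect_equal(rep2$best_worst$worst_rmse, "p2")
  two <- list(mk("p1", 10),
              prediction_series(rep(100, 50), rep(90, 50), patient_id = "p1",
                                model = "cnn", quantization = "dynamic_range"))
  expect_equal(nrow(build_report(two)$table), 2)
  expect_error(build_report(list()), "at least one")
})

test_that("plot methods draw without error", {
  pdf(NULL)
  on.exit(dev.off())
  s <- prediction_series(c(100, 200, 50), c(110, 180, 150))
  expect_invisible(plot(s))
  expect_invisible(plot(tiny_cnn()))
})
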