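test_that("IOB matches the brute-force decay-sum oracle", {
  u <- cgmcast:::with_seed(1, runif(2000, 0, 0.3))
  expect_lt(max(abs(compute_iob(u) - iob_oracle(u))), 1e-9)
})

test_that("IOB impulse response follows the linear 3-h decay exactly", {
  u <- numeric(600)
  u[200] <- 1
  iob <- compute_iob(u)
  expect_identical(iob[200], 1.0)          # alpha(0) = 1
  expect_identical(iob[290], 0.5)          # alpha(90) = 1 - 90/180
  expect_identical(iob[380], 0.0)          # support ends at 179 min
  expect_identical(compute_iob(numeric(100)), numeric(100))
  expect_error(compute_iob(c(1, -0.1)), "non-negative")
})

test_that("IOB is linear and bounded by the 180-min insulin sum", {
  u <- cgmcast:::with_seed(2, runif(800, 0, 0.2))
  v <- cgmcast:::with_seed(3, runif(800, 0, 0.5))
  expect_equal(compute_iob(2 * u + 3 * v),
               2 * compute_iob(u) + 3 * compute_iob(v), tolerance = 1e-12)
  run_sum <- vapply(seq_along(u), function(t)
    sum(u[max(1, t - 179):t]), numeric(1))
  iob <- compute_iob(u)
  expect_true(all(iob >= 0))
  expect_true(all(iob <= run_sum + 1e-12))
})

test_that("window construction yields the boundary and per-day counts", {
  mk <- function(L) {
    df <- data.frame(minute = 1:L, cgm = rnorm(L, 120, 10),
                     iob = runif(L), carbs = numeric(L))
    attr(df, "warmup") <- 180L
    class(df) <- c("feature_series", "data.frame")
    df
  }
  expect_equal(length(build_windows(mk(240))), 1)           # 180 + 30 + 30
  expect_equal(length(build_windows(mk(1440))), 1201)       # one day
  expect_error(build_windows(mk(239)), "at least 240")
})

test_that("windows align features and targets to their anchors", {
  s <- feature_series(tiny_sim())
  w <- build_windows(s)
  k <- c(1, 57, length(w))
  for (i in k) {
    a <- w$anchor[i]
    expect_identical(unname(w$x["cgm", 30, i]), s$cgm[a])
    expect_identical(unname(w$x["cgm", 1, i]), s$cgm[a - 29])
    expect_identical(unname(w$x["iob", 30, i]), s$iob[a])
    expect_identical(unname(w$x["carbs", 15, i]), s$carbs[a - 15])
    expect_identical(w$y[i], s$cgm[a + 30])
  }
  expect_equal(w$anchor[1], 210)
  expect_true(all(diff(w$anchor) == 1))
  # persistence baseline is the anchor-minute CGM
  expect_identical(persistence_forecast(w), as.numeric(s$cgm[w$anchor]))
})

test_that("chronological split floor-rounds with remainder to train", {
  w <- build_windows(feature_series(tiny_sim()))
  sz <- function(n) {
    sp <- split_dataset(w[seq_len(n)])
    c(length(sp$train), length(sp$validation), length(sp$test))
  }
  expect_equal(sz(100), c(70, 20, 10))
  expect_equal(sz(101), c(71, 20, 10))
  sp <- split_dataset(w)
  expect_lt(max(sp$train$anchor), min(sp$validation$anchor))
  expect_lt(max(sp$validation$anchor), min(sp$test$anchor))
  expect_error(split_dataset(w, fractions = c(0.6, 0.3, 0.2)), "summing to 1")
  expect_error(split_dataset(w[1:5]), "at least 10")
})

test_that("window CSV dump round-trips bit-exactly with its sidecar", {
  w <- build_windows(feature_series(tiny_sim()))[1:25]
  path <- withr::local_tempfile(fileext = ".csv")
  write_windows_csv(w, path)
  back <- read_windows_csv(path)
  expect_identical(back$x, w$x)
  expect_identical(back$y, w$y)
  expect_identical(back$anchor, w$anchor)
  expect_identical(back$feature_names, w$feature_names)
  expect_identical(back$window_len, w$window_len)
  expect_identical(back$ph, w$ph)
})
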