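test_that("int8 weight quantization is within one step, with safe degenerate cases", {
  set.seed(1)
  w <- matrix(rnorm(200, 0, 0.4), 20, 10)
  qp <- cgmcast:::.qparams_int8(w)
  wq <- cgmcast:::.dequantize_tensor(cgmcast:::.quantize_tensor(w, qp), qp)
  expect_true(all(abs(wq - w) <= qp$scale))
  z <- cgmcast:::.qparams_int8(matrix(0, 3, 3))
  expect_equal(z$scale, 1)
  expect_equal(z$zp, 0L)
})

test_that("weights exactly on the quantization grid survive dynamic range losslessly", {
  fit <- tiny_cnn()
  # rebuild every weight matrix on the affine grid 0.5 * [-128, 127]
  snap <- fit
  for (nm in names(snap$weights)) {
    w <- snap$weights[[nm]]
    if (is.matrix(w)) {
      w[] <- 0.5 * pmin(pmax(round(w / 0.5), -128), 127)
      w[1] <- -64           # pin the range so scale is exactly 0.5
      w[2] <- 63.5
      snap$weights[[nm]] <- w
    }
  }
  qd <- quantize_dynamic(snap)
  sp <- tiny_split()
  expect_identical(predict(qd, sp$test), predict(snap, sp$test))
})

test_that("dynamic-range quantization degrades a trained model only marginally", {
  fit <- tiny_cnn()
  sp <- tiny_split()
  pf <- predict(fit, sp$test)
  pq <- predict(quantize_dynamic(fit), sp$test)
  expect_lt(abs(rmse(sp$test$y, pq) - rmse(sp$test$y, pf)), 1.0)
  expect_gt(cor(pf, pq), 0.99)
})

test_that("calibration set is the ordered tail of train+validation", {
  sp <- tiny_split()
  cal <- select_calibration(sp, 100)
  expect_length(cal, 100)
  expect_true(all(diff(cal$anchor) > 0))
  tv_anchors <- c(sp$train$anchor, sp$validation$anchor)
  expect_identical(cal$anchor, utils::tail(tv_anchors, 100))
  expect_error(select_calibration(sp, 99), "\\[100, 500\\]")
  expect_error(select_calibration(sp, 501), "\\[100, 500\\]")
  small <- split_dataset(sp$train[1:80])
  expect_error(select_calibration(small, 100), "insufficient")
})

test_that("calibrated ranges cover the activations seen on the calibration set", {
  fit <- tiny_cnn()
  sp <- tiny_split()
  cal <- select_calibration(sp, 150)
  qf <- quantize_full_int(fit, cal)
  X <- cgmcast:::.batch_array(cal, fit$scaling)
  expect_equal(qf$act$input$min, min(X))
  expect_equal(qf$act$input$max, max(X))
  p <- cgmcast:::.net_predict(fit$arch, fit$weights, X, fit$config)
  expect_equal(qf$act$output$min, min(p))
  expect_equal(qf$act$output$max, max(p))
})

test_that("full-integer outputs are uint8 levels that saturate, never wrap, by default", {
  fit <- tiny_cnn()
  sp <- tiny_split()
  qf <- quantize_full_int(fit, select_calibration(sp, 150))
  lev <- predict(qf, sp$test, type = "level")
  expect_true(all(lev >= 0 & lev <= 255))
  expect_true(all(lev == round(lev)))
  # data far outside the calibrated ranges still yields in-range levels
  extreme <- sp$test[1:20]
  extreme$x[] <- extreme$x * 50
  lev_ex <- predict(qf, extreme, type = "level")
  expect_true(all(lev_ex >= 0 & lev_ex <= 255))
  # the uint8 quantizer itself saturates at the endpoints, never wraps
  out_fq <- cgmcast:::.fq_uint8(qf$act$output, dequant = FALSE)
  expect_equal(out_fq(qf$act$output$max + 1e6), 255)
  expect_equal(out_fq(qf$act$output$min - 1e6), 0)
  expect_error(predict(quantize_dynamic(fit), sp$test, type = "level"),
               "full_integer")
})

test_that("a linear map quantized with its known range stays within one step", {
  x <- seq(-1, 1, length.out = 201)
  y <- 2.5 * x + 1
  ar <- list(min = min(y), max = max(y), scale = (max(y) - min(y)) / 255)
  ar$zp <- as.integer(round(-ar$min / ar$scale))
  fq <- cgmcast:::.fq_uint8(ar)
  expect_true(all(abs(fq(y) - y) <= ar$scale))
})

test_that("level normalization maps the reporting range onto 0..255 and back", {
  spec <- normalization_spec()
  expect_equal(spec$step, (600 - 10) / 255)
  expect_equal(normalize_levels(10), 0)
  expect_equal(normalize_levels(600), 255)
  expect_equal(normalize_levels(650), 255)        # clipped
  expect_equal(denormalize_levels(0), 10)
  expect_equal(denormalize_levels(255), 600)
  k <- 0:255
  expect_identical(normalize_levels(denormalize_levels(k)), as.numeric(k))
  v <- cgmcast:::with_seed(4, runif(10000, 10, 600))
  err <- abs(v - denormalize_levels(normalize_levels(v)))
  expect_true(all(err <= spec$step / 2 + 1e-12))
})

test_that("overflow reconstruction leaves sub-threshold series untouched and inverts the worked wrap", {
  below <- c(100, 239, 10, 235, 120)
  expect_equal(reconstruct_overflow(below), below)
  true_series <- c(230, 250, 270, 290, 260, 240, 230)
  wrapped <- c(230, 250, 15, 35, 5, 240, 230)
  expect_equal(wrap_oracle(true_series), wrapped)
  expect_equal(reconstruct_overflow(wrapped), true_series)
  expect_error(reconstruct_overflow(c(10, 300)), "\\[0, 255\\]")
})

test_that("reconstruction exactly inverts the wrap on random admissible series", {
  ok <- 0L
  for (s in 1:200) {
    tr <- random_admissible_series(len = 240, seed = s)
    expect_true(all(tr >= 10 & tr <= 510))
    expect_true(all(diff(tr) > -50 & diff(tr) < 50))
    rec <- reconstruct_overflow(wrap_encode(tr))
    ok <- ok + as.integer(identical(as.numeric(rec), as.numeric(tr)))
  }
  expect_equal(ok, 200L)
})

test_that("admissible generator actually exercises the overflow regime", {
  crossed <- vapply(1:50, function(s)
    any(random_admissible_series(240, s) > 255), logical(1))
  expect_true(all(crossed))
})

test_that("timing harness reports sane order statistics under the 60-s bound", {
  fit <- tiny_cnn()
  sp <- tiny_split()
  tm <- measure_inference(fit, sp$test[1:5], repeats = 2)
  expect_equal(tm$n, 10)
  expect_gte(tm$max_ms, tm$mean_ms)
  expect_lt(tm$max_ms, 60000)
  empty <- measure_inference(fit, sp$test[1:5], repeats = 0)
  expect_equal(empty$n, 0)
  expect_length(empty$per_window_ms, 0)
})
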