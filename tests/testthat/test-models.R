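test_that("CNN shape arithmetic matches the valid-convolution/pooling chain", {
  s <- cgmcast:::.cnn_shapes(30, cnn_config())
  expect_equal(c(s$t1, s$p1, s$t2, s$p2), c(26, 13, 9, 4))
  expect_equal(s$flat, 3 * 4 * 20)  # 240 flattened features
  expect_error(cgmcast:::.cnn_shapes(30, cnn_config(kernel_time = 15)),
               "too large")
  expect_error(cnn_config(kernel_time = 4), "odd")
})

test_that("parameter counts match the closed-form architecture counts", {
  sp <- tiny_split()
  ctl <- train_control(max_epochs = 1, patience = 1, seed = 1)
  cnn <- fit_forecaster(sp, "cnn", control = ctl)
  # conv1: 5*26+26; conv2: (5*26)*20+20; dense: 240*64+64; out: 64+1
  expect_equal(n_params(cnn), 130 + 26 + 2600 + 20 + 15360 + 64 + 64 + 1)
  lstm <- fit_forecaster(sp, "lstm", control = ctl)
  # gates: 4H(F+H+1) with F=3, H=64; dense: 64*64+64; out: 64+1
  expect_equal(n_params(lstm), 4 * 64 * (3 + 64 + 1) + 4096 + 64 + 64 + 1)
  expect_equal(dim(coef(lstm)$Wx), c(3, 256))
  expect_equal(lstm$config$lstm_units, 64)
  expect_equal(lstm$config$dense_units, 64)
})

test_that("compiled kernels agree with the reference engine and finite differences", {
  set.seed(31)
  N <- 6
  X <- array(runif(N * 3 * 30, 0, 2), c(N, 3, 30))
  y <- runif(N, -1, 1)
  for (arch in c("cnn", "lstm")) {
    cfg <- if (arch == "cnn") cnn_config(filters1 = 4, filters2 = 3)
           else lstm_config(8, 6)
    W <- cgmcast:::with_seed(1, cgmcast:::.net_init(arch, cfg, 30))
    pR <- cgmcast:::.net_predict(arch, W, X, cfg, use_cpp = FALSE)
    pC <- cgmcast:::.net_predict(arch, W, X, cfg, use_cpp = TRUE)
    expect_equal(pC, pR, tolerance = 1e-12)
    G <- cgmcast:::.net_grad(arch, W, X, y, cfg)
    loss_at <- function(W) mean((cgmcast:::.net_predict(arch, W, X, cfg) - y)^2)
    eps <- 1e-6
    for (nm in names(W)) {
      i <- cgmcast:::with_seed(7, sample(length(W[[nm]]), 1))
      Wp <- W; Wp[[nm]][i] <- Wp[[nm]][i] + eps
      Wm <- W; Wm[[nm]][i] <- Wm[[nm]][i] - eps
      fd <- (loss_at(Wp) - loss_at(Wm)) / (2 * eps)
      expect_equal(as.numeric(G[[nm]])[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("a 50-window probe is overfit to near-zero training loss", {
  sp <- tiny_split()
  probe <- structure(list(train = sp$train[1:50], validation = sp$train[1:50],
                          test = sp$train[51:60], fractions = c(.7, .2, .1)),
                     class = "dataset_split")
  fit <- fit_forecaster(probe, "cnn",
                        control = train_control(learning_rate = 0.05,
                                                batch_size = 50,
                                                max_epochs = 200,
                                                patience = 200, seed = 3,
                                                standardize = TRUE))
  expect_lt(min(fit$history$train_loss), 0.01)  # standardized units
})

test_that("training is deterministic and early stopping restores the best epoch", {
  sp <- tiny_split()
  ctl <- train_control(learning_rate = 0.05, max_epochs = 6, patience = 3,
                       seed = 17, standardize = TRUE)
  f1 <- fit_forecaster(sp, "cnn", control = ctl)
  f2 <- fit_forecaster(sp, "cnn", control = ctl)
  expect_identical(f1$weights, f2$weights)
  expect_identical(predict(f1, sp$test), predict(f2, sp$test))
  expect_equal(f1$best_val_loss, min(f1$history$val_loss))
  expect_equal(f1$best_epoch, which.min(f1$history$val_loss))
  # validation loss improved over the initial epoch
  expect_lt(f1$best_val_loss, f1$history$val_loss[1])
})

test_that("a constant-target dataset is fit to the constant", {
  sp <- tiny_split()
  const <- sp
  const$train$y <- rep(140, length(const$train))
  const$validation$y <- rep(140, length(const$validation))
  fit <- fit_forecaster(const, "cnn",
                        control = train_control(learning_rate = 0.05,
                                                max_epochs = 8, patience = 8,
                                                seed = 5, standardize = TRUE))
  p <- predict(fit, const$validation)
  expect_lt(sqrt(mean((p - 140)^2)), 2)
})

test_that("predictions are pure, shape-checked and sane", {
  fit <- tiny_cnn()
  sp <- tiny_split()
  p1 <- predict(fit, sp$test)
  p2 <- predict(fit, sp$test)
  expect_identical(p1, p2)
  expect_length(p1, length(sp$test))
  expect_true(all(is.finite(p1)) && all(p1 >= 0) && all(p1 <= 650))
  expect_length(predict(fit, sp$test[integer(0)]), 0)
  bad <- array(0, c(2, 3, 31))
  expect_error(predict(fit, bad), "array")
})

test_that("grid search selects by validation RMSE with deterministic outcome", {
  sp <- tiny_split()
  ctl <- train_control(learning_rate = 0.05, max_epochs = 5, patience = 5,
                       seed = 9, standardize = TRUE)
  single <- grid_search(sp, "cnn", grid = list(cnn_config(filters1 = 8)),
                        control = ctl)
  expect_equal(single$best_config$filters1, 8)
  g <- list(cnn_config(filters1 = 1, filters2 = 1, kernel_time = 3),
            cnn_config())
  gs1 <- grid_search(sp, "cnn", grid = g, control = ctl)
  gs2 <- grid_search(sp, "cnn", grid = g, control = ctl)
  expect_identical(gs1$best_config, gs2$best_config)
  expect_identical(gs1$results$val_rmse, gs2$results$val_rmse)
  # the crippled 1-filter net loses to the reference configuration
  expect_equal(gs1$results$val_rmse[2], min(gs1$results$val_rmse))
  expect_identical(gs1$best_config, cnn_config())
  expect_error(grid_search(sp, "cnn", grid = list(), control = ctl),
               "non-empty")
})

test_that("default grids include the reference optima", {
  gc <- default_grid("cnn")
  expect_true(any(vapply(gc, function(g)
    g$filters1 == 26 && g$filters2 == 20 && g$kernel_time == 5, logical(1))))
  gl <- default_grid("lstm")
  expect_true(any(vapply(gl, function(g)
    g$lstm_units == 64 && g$dense_units == 64, logical(1))))
})

test_that("forecaster archive round-trips weights and predictions exactly", {
  fit <- tiny_cnn()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_forecaster(fit, path)
  back <- load_forecaster(path)
  expect_identical(back$weights, fit$weights)
  sp <- tiny_split()
  expect_identical(predict(back, sp$test), predict(fit, sp$test))
})
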