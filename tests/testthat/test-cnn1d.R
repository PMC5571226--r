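# The personal 1D CNN: topology arithmetic, forward/backward correctness,
# shallow-training contracts.

test_that("layer arithmetic matches the reference topology 128->40->11->1", {
  dims <- cnn_layer_dims(cnn_config())
  expect_equal(dims$conv_out, c(122L, 34L, 5L))
  expect_equal(dims$pooled_out, c(40L, 11L, 1L))
  expect_equal(dims$fc_input, 16L)
  # changing kernel/subsample recomputes and re-asserts
  dims2 <- cnn_layer_dims(cnn_config(kernel_size = 5, subsample = 2))
  expect_equal(dims2$conv_out[1], 124L)
  expect_error(cnn_layer_dims(cnn_config(kernel_size = 7), input_length = 5),
               "shorter than kernel")
})

test_that("an all-zero network outputs exactly zero", {
  m <- cnn_init(cnn_config(seed = 1))
  for (i in seq_along(m$conv)) {
    m$conv[[i]]$W[] <- 0; m$conv[[i]]$b[] <- 0
  }
  m$fc1$W[] <- 0; m$fc1$b[] <- 0
  m$fc2$W[] <- 0; m$fc2$b[] <- 0
  out <- cnn_forward(m, single = rnorm(128), trio = rnorm(128))
  expect_identical(out, rep(0, 5))
})

test_that("the batched forward pass matches the straight-loop oracle", {
  withr::with_seed(55, {
    for (i in 1:10) {
      m <- cnn_init(cnn_config(seed = 1000 + i))
      s <- rnorm(128); tr <- rnorm(128)
      expect_lt(max(abs(cnn_forward(m, single = s, trio = tr) -
                        cnn_forward_loop(m, s, tr))), 1e-10)
    }
    # and batching is consistent with single-item evaluation
    m <- cnn_init(cnn_config(seed = 7))
    X <- array(rnorm(4 * 2 * 128), c(4, 2, 128))
    out <- cnn_forward(m, X)
    for (b in 1:4)
      expect_equal(out[b, ], cnn_forward(m, single = X[b, 1, ],
                                         trio = X[b, 2, ]),
                   tolerance = 1e-12)
  })
})

test_that("forward pass rejects malformed shapes with a layer message", {
  m <- cnn_init(cnn_config(seed = 1))
  expect_error(cnn_forward(m, single = rnorm(100), trio = rnorm(128)),
               "input layer")
  expect_error(cnn_forward(m, X = array(0, c(2, 3, 128))), "input layer")
})

test_that("outputs equal to targets give zero loss and zero gradients", {
  m <- cnn_init(cnn_config(seed = 2))
  X <- array(rnorm(3 * 2 * 128), c(3, 2, 128))
  fw <- cnn_forward(m, X)
  lg <- loss_and_gradients(m, X, fw)  # targets := current outputs
  expect_equal(lg$mse, 0)
  expect_equal(max(abs(lg$grads$fc2$W)), 0)
  expect_equal(max(abs(lg$grads$fc1$W)), 0)
  for (i in 1:3) expect_equal(max(abs(lg$grads$conv[[i]]$W)), 0)
})

test_that("analytic gradients match central differences for every layer type", {
  withr::with_seed(66, {
    m <- cnn_init(cnn_config(seed = 11))
    X <- array(rnorm(5 * 2 * 128), c(5, 2, 128))
    targets <- class_targets(sample(aami_classes(), 5, replace = TRUE))
    lg <- loss_and_gradients(m, X, targets)
    check <- function(get, set, g, n = 8) {
      v <- get(m)
      for (i in sample(length(v), min(n, length(v)))) {
        d <- 1e-5
        up <- set(m, replace(v, i, v[i] + d))
        dn <- set(m, replace(v, i, v[i] - d))
        num <- (loss_and_gradients(up, X, targets)$mse -
                loss_and_gradients(dn, X, targets)$mse) / (2 * d)
        expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-8), 1e-5)
      }
    }
    for (l in 1:3) {
      check(function(m) m$conv[[l]]$W,
            function(m, v) { m$conv[[l]]$W[] <- v; m },
            as.numeric(lg$grads$conv[[l]]$W))
      check(function(m) m$conv[[l]]$b,
            function(m, v) { m$conv[[l]]$b <- v; m },
            lg$grads$conv[[l]]$b, n = 4)
    }
    check(function(m) m$fc1$W, function(m, v) { m$fc1$W[] <- v; m },
          as.numeric(lg$grads$fc1$W))
    check(function(m) m$fc1$b, function(m, v) { m$fc1$b <- v; m },
          lg$grads$fc1$b, n = 4)
    check(function(m) m$fc2$W, function(m, v) { m$fc2$W[] <- v; m },
          as.numeric(lg$grads$fc2$W))
    check(function(m) m$fc2$b, function(m, v) { m$fc2$b <- v; m },
          lg$grads$fc2$b, n = 4)
  })
})

test_that("a batch of n copies of one item has the single-item mean gradient", {
  withr::with_seed(77, {
    m <- cnn_init(cnn_config(seed = 3))
    x1 <- array(rnorm(2 * 128), c(1, 2, 128))
    t1 <- class_targets("V")
    Xn <- array(0, c(6, 2, 128))
    for (b in 1:6) Xn[b, , ] <- x1[1, , ]
    tn <- t1[rep(1, 6), , drop = FALSE]
    g1 <- loss_and_gradients(m, x1, t1)
    gn <- loss_and_gradients(m, Xn, tn)
    expect_equal(gn$mse, g1$mse, tolerance = 1e-12)
    expect_equal(gn$grads$fc2$W, g1$grads$fc2$W, tolerance = 1e-12)
    expect_equal(gn$grads$conv[[1]]$W, g1$grads$conv[[1]]$W,
                 tolerance = 1e-12)
  })
})

test_that("train_cnn with max_iters = 0 returns the seeded init untouched", {
  toy <- toy_two_class(4)
  cfg <- cnn_config(seed = 5, max_iters = 0)
  fit <- train_cnn(toy, cfg)
  expect_identical(fit$stop_reason, "max_iters")
  expect_equal(nrow(fit$history), 0L)
  init <- cnn_init(cfg, 5)
  expect_identical(fit$model$fc1$W, init$fc1$W)
  expect_identical(fit$model$conv[[2]]$W, init$conv[[2]]$W)
})

test_that("training refuses a single-class dataset with an explicit message", {
  toy <- toy_two_class(4)
  toy$labels[] <- "N"
  expect_error(train_cnn(toy, cnn_config(seed = 1)), "single class")
})

test_that("a separable two-class toy reaches the error floor within 50 iterations", {
  toy <- toy_two_class(20)
  fit <- train_cnn(toy, cnn_config(seed = 1))
  expect_identical(fit$stop_reason, "error_floor")
  expect_lte(utils::tail(fit$history$train_error, 1), 0.03)
  expect_lte(nrow(fit$history), 50)
})

test_that("the learning-factor trace obeys the 1.05/0.70 rule against the MSE trace", {
  co <- small_cohort()
  ts <- build_training_set(co$test[[1]], small_libraries())
  fit <- train_cnn(ts, cnn_config(seed = 2, max_iters = 12))
  h <- fit$history
  expect_gt(nrow(h), 2)
  expect_equal(h$eps[1], 0.001)
  mse_prev <- c(Inf, h$mse)  # mse_0 := +Inf
  for (i in 2:nrow(h)) {
    expected <- if (h$mse[i - 1] < mse_prev[i - 1]) 1.05 else 0.70
    expect_equal(h$eps[i] / h$eps[i - 1], expected, tolerance = 1e-12)
  }
})

test_that("training is deterministic given dataset and seed", {
  toy <- toy_two_class(8)
  f1 <- train_cnn(toy, cnn_config(seed = 9, max_iters = 5))
  f2 <- train_cnn(toy, cnn_config(seed = 9, max_iters = 5))
  expect_identical(f1$model$fc2$W, f2$model$fc2$W)
  expect_identical(f1$history, f2$history)
})

test_that("the compiled and pure-R training engines agree", {
  toy <- toy_two_class(5)
  cfg <- cnn_config(seed = 4, max_iters = 3)
  fr <- train_cnn(toy, cfg, engine = "r")
  fc <- train_cnn(toy, cfg, engine = "cpp")
  expect_equal(fr$history$mse, fc$history$mse, tolerance = 1e-12)
  expect_equal(fr$model$conv[[1]]$W, fc$model$conv[[1]]$W,
               tolerance = 1e-12)
  expect_equal(fr$model$fc2$W, fc$model$fc2$W, tolerance = 1e-12)
})

test_that("prediction is the argmax with ties to the lowest class index", {
  m <- cnn_init(cnn_config(seed = 1))
  # argmax agreement with an exhaustive scan over random models
  withr::with_seed(88, {
    for (i in 1:25) {
      mi <- cnn_init(cnn_config(seed = 2000 + i))
      s <- rnorm(128); tr <- rnorm(128)
      out <- cnn_forward(mi, single = s, trio = tr)
      expect_identical(cnn_predict(mi, s, tr),
                       aami_classes()[which(out == max(out))[1]])
    }
  })
  # an exact two-way tie resolves to the lower index: zero network has
  # all-equal outputs, so the prediction must be the first class, N
  for (i in seq_along(m$conv)) { m$conv[[i]]$W[] <- 0; m$conv[[i]]$b[] <- 0 }
  m$fc1$W[] <- 0; m$fc1$b[] <- 0; m$fc2$W[] <- 0; m$fc2$b[] <- 0
  expect_identical(cnn_predict(m, rnorm(128), rnorm(128)), "N")
})

test_that("run_ensemble trains n distinct, reproducible models from seed+k", {
  toy <- toy_two_class(8)
  cfg <- cnn_config(seed = 30, max_iters = 4)
  ens <- run_ensemble(toy, cfg, n_runs = 3)
  expect_length(ens, 3)
  # run k equals a direct train with seed+k-1
  direct <- train_cnn(toy, cfg, seed = 31)
  expect_identical(ens[[2]]$model$fc1$W, direct$model$fc1$W)
  # distinct initializations
  expect_false(identical(ens[[1]]$model$fc1$W, ens[[3]]$model$fc1$W))
  # byte-identical rerun
  ens2 <- run_ensemble(toy, cfg, n_runs = 3)
  expect_identical(lapply(ens, function(e) e$model$fc2$W),
                   lapply(ens2, function(e) e$model$fc2$W))
  expect_identical(ens[[1]]$model, train_cnn(toy, cfg)$model)
  expect_error(run_ensemble(toy, cfg, n_runs = 0), ">= 1")
})

test_that("CNN models round-trip bit-exactly through JSON", {
  toy <- toy_two_class(5)
  fit <- train_cnn(toy, cnn_config(seed = 12, max_iters = 2))
  path <- file.path(withr::local_tempdir(), "model.json")
  write_cnn(fit$model, path, config_hash = "h1")
  back <- read_cnn(path)
  expect_identical(back$fc1$W, fit$model$fc1$W)
  expect_identical(back$fc2$b, fit$model$fc2$b)
  for (i in 1:3) expect_identical(back$conv[[i]]$W, fit$model$conv[[i]]$W)
  expect_identical(back$config_hash, "h1")
  expect_equal(back$config, fit$model$config)
})
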