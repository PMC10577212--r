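# small shared task so the training tests stay fast
tiny_task <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_events(synth_spec(C = 2, n_per_class = 20, T = 25,
                                       noise_rate = 0.01, seed = 4))
      sp <- train_test_split(ds, 0.5, seed = 2)
      cache <<- list(train = bin_dataset(sp$train), test = bin_dataset(sp$test))
    }
    cache
  }
})

test_that("Xavier initialization is reproducible, bounded and centred", {
  net <- parse_architecture("10-FC40(R)-4", 0.01, 0.05, 0.5)
  n1 <- init_weights(net, 7)
  n2 <- init_weights(net, 7)
  expect_identical(n1$layers[[1]]$W, n2$layers[[1]]$W)
  expect_identical(n1$layers[[1]]$V, n2$layers[[1]]$V)
  expect_false(identical(n1$layers[[1]]$W, init_weights(net, 8)$layers[[1]]$W))

  bound <- sqrt(6 / (10 + 40))
  expect_true(all(abs(n1$layers[[1]]$W) <= bound))
  expect_true(all(abs(n1$layers[[2]]$W) <= sqrt(6 / (40 + 4))))

  # empirical mean of many draws ~ 0 within 3 standard errors
  big <- init_weights(parse_architecture("100-100", 0.01, 0.05, 0.5), 11)
  w <- as.numeric(big$layers[[1]]$W)
  se <- sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w)), 3 * se)
})

test_that("zero learning rate leaves weights unchanged", {
  task <- tiny_task()
  cfg <- train_config(eta = 0, n_epochs = 2, T_E = 0, seed = 3, B = 8)
  net <- build_network("20-FC8-2", 0.01, cfg)
  net <- init_weights(net, cfg$seed)
  fit <- train(net, task$train$x, task$train$labels, cfg, init = FALSE)
  expect_identical(fit$net$layers[[1]]$W, net$layers[[1]]$W)
  expect_identical(fit$net$layers[[2]]$W, net$layers[[2]]$W)
})

test_that("training is bit-reproducible under a fixed seed", {
  task <- tiny_task()
  cfg <- train_config(n_epochs = 3, seed = 5, B = 8, T_E = 5)
  net <- build_network("20-FC8(R)-2", 0.01, cfg)
  f1 <- train(net, task$train$x, task$train$labels, cfg)
  f2 <- train(net, task$train$x, task$train$labels, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$net$layers[[2]]$W, f2$net$layers[[2]]$W)
})

test_that("FS training overfits a single sample with a non-increasing loss trend", {
  task <- tiny_task()
  x <- task$train$x[, , 1, drop = FALSE]
  cfg <- train_config(n_epochs = 20, seed = 2, B = 1, T_E = 5)
  net <- build_network("20-FC8(R)-2", 0.01, cfg)
  fit <- train(net, x, task$train$labels[1], cfg)
  loss <- fit$log$loss
  # the FS loss is quantized through discrete spike times, so descent shows
  # occasional one-step bounces; demand a clearly decreasing trend with at
  # most a few small (> 5 %) upward steps
  ups <- sum(diff(loss) > 0.05 * loss[-length(loss)] + 1e-9)
  expect_lte(ups, 3)
  expect_lt(loss[20], 0.5 * loss[1])
})

test_that("FR and FS training learn the tiny two-class task end to end", {
  task <- tiny_task()
  for (mode in c("fs", "fr")) {
    cfg <- train_config(loss_mode = mode, n_epochs = 30, seed = 1, T_E = 5, B = 8)
    net <- build_network("20-FC32(R)-2", 0.01, cfg)
    fit <- train(net, task$train$x, task$train$labels, cfg)
    ev <- evaluate(fit, task$test$x, task$test$labels)
    expect_gt(ev$accuracy, 0.7)
    expect_s3_class(tidy(ev), "tbl_df")
    expect_equal(glance(ev)$accuracy, ev$accuracy)
  }
})

test_that("spike-count constraint steers the mean spike count toward the target", {
  task <- tiny_task()
  base <- train_config(n_epochs = 15, seed = 6, T_E = 5, B = 8)
  net <- build_network("20-FC16(R)-2", 0.01, base)
  f0 <- train(net, task$train$x, task$train$labels, base)
  constrained <- train_config(n_epochs = 15, seed = 6, T_E = 5, B = 8,
                              loss = loss_config(lambda_s = 0.5, n_target = 0))
  f1 <- train(net, task$train$x, task$train$labels, constrained)
  expect_lt(tail(f1$log$n_s, 1), tail(f0$log$n_s, 1))
})

test_that("accuracy_vs_window ends at the standard accuracy and scans correctly", {
  task <- tiny_task()
  cfg <- train_config(n_epochs = 15, seed = 1, T_E = 5, B = 8)
  net <- build_network("20-FC16(R)-2", 0.01, cfg)
  fit <- train(net, task$train$x, task$train$labels, cfg)
  curve <- accuracy_vs_window(fit, task$test$x, task$test$labels)
  ev <- evaluate(fit, task$test$x, task$test$labels)
  expect_equal(nrow(curve), dim(task$test$x)[2])
  expect_equal(curve$accuracy[nrow(curve)], ev$accuracy)
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
})

test_that("an untrained network on pure noise sits at chance at every window", {
  ds <- generate_events(synth_spec(C = 3, n_per_class = 15, T = 20,
                                   signal_rate = 0, noise_rate = 0.3, seed = 9))
  b <- bin_dataset(ds)
  net <- init_weights(build_network("20-FC16(R)-3", 0.01, train_config()), 2)
  curve <- accuracy_vs_window(net, b$x, b$labels, mode = "fs")
  # binomial tolerance around 1/3 on 45 trials: 4 sigma ~ 0.28
  expect_true(all(abs(curve$accuracy - 1 / 3) < 0.29))
})

test_that("time_delay matches a brute-force scan and handles degenerate curves", {
  expect_equal(time_delay(rep(0.8, 10), 50, 0.01)$steps, 1)
  expect_equal(time_delay(rep(0.8, 10), 90, 0.01)$time, 0.01)
  step_curve <- c(rep(0, 9), rep(0.8, 5))
  expect_equal(time_delay(step_curve, 50, 0.01)$steps, 10)
  expect_equal(time_delay(step_curve, 90, 0.01)$steps, 10)
  expect_equal(time_delay(rep(0, 6), 50, 0.01)$steps, 6)
  set.seed(33)
  for (rep in 1:50) {
    acc <- cumsum(runif(sample(5:30, 1)))
    acc <- acc / max(acc)
    p <- sample(c(50, 90), 1)
    got <- time_delay(acc, p, 0.002)$steps
    ref <- min(which(acc >= (p / 100) * max(acc)))
    expect_equal(got, ref)
    expect_lte(time_delay(acc, 50, 1)$steps, time_delay(acc, 90, 1)$steps)
  }
})

test_that("mean_spike_count averages spikes over neurons and trials", {
  S1 <- array(0, dim = c(2, 4, 1)); S1[1, c(1, 2, 3, 4), 1] <- 1
  traj <- structure(list(list(S = S1, U = S1 * 0, I = S1 * 0)),
                    T = 4L, B = 1L, dt = 0.01, class = "fs_trajectories")
  expect_equal(mean_spike_count(traj), 2)  # 4 spikes / 2 neurons
  silent <- structure(list(list(S = S1 * 0, U = S1 * 0, I = S1 * 0)),
                      T = 4L, B = 1L, dt = 0.01, class = "fs_trajectories")
  expect_equal(mean_spike_count(silent), 0)
  set.seed(12)
  net <- random_small_net(4, c(6, 3))
  x <- array(rpois(4 * 15 * 2, 1), dim = c(4, 15, 2))
  tr <- forward(net, x, n_trials = 2)
  ref <- (sum(tr[[1]]$S) + sum(tr[[2]]$S)) / 9 / 2
  expect_equal(mean_spike_count(tr), ref)
})

test_that("fit objects expose tidy/glance summaries and plots", {
  task <- tiny_task()
  cfg <- train_config(n_epochs = 2, seed = 1, B = 8)
  net <- build_network("20-FC8(R)-2", 0.01, cfg)
  fit <- train(net, task$train$x, task$train$labels, cfg)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(td$kind, c("recurrent_fc", "fully_connected"))
  gl <- glance(fit)
  expect_equal(gl$epochs, 2)
  expect_equal(gl$T_train, 35)  # 25 + T_E 10
  expect_s3_class(autoplot(fit), "ggplot")
  curve <- accuracy_vs_window(fit, task$test$x, task$test$labels)
  expect_s3_class(plot_accuracy_vs_window(curve), "ggplot")
})
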