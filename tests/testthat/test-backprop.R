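test_that("window arithmetic follows sigma = floor(T/D), W = min(6*sigma+1, T)", {
  expect_equal(window_size(100, 8), list(sigma = 12, W = 73))
  expect_equal(window_size(100, 16), list(sigma = 6, W = 37))
  expect_equal(window_size(100, 32), list(sigma = 3, W = 19))
  expect_equal(window_size(120, 8), list(sigma = 15, W = 91))
  expect_equal(window_size(120, 12), list(sigma = 10, W = 61))
  expect_equal(window_size(100, 100), list(sigma = 1, W = 7))
  # D beyond T collapses to the delta window
  expect_equal(window_size(10, 50), list(sigma = 0, W = 1))
  # cap at T when the 3-sigma width exceeds the sequence
  expect_equal(window_size(10, 1), list(sigma = 10, W = 10))
})

test_that("gaussian window weights are negative, symmetric and peaked at zero", {
  cfg <- gaussian_window_config(T = 36, D = 6, A = 200)
  expect_equal(cfg$sigma, 6)
  xs <- -18:18
  g <- gaussian_weight(xs, cfg)
  expect_true(all(g < 0))
  expect_equal(g, rev(g))
  expect_equal(which.max(abs(g)), which(xs == 0))
  expect_equal(abs(gaussian_weight(0, cfg)), 200 / (sqrt(2 * pi) * 6))
  # high-precision scalar check at A=200, sigma=6, x=3
  expect_equal(gaussian_weight(3, cfg),
               -(200 / (sqrt(2 * pi) * 6)) * exp(-9 / 72), tolerance = 1e-12)
})

test_that("time-error assignment: active rule is a truncated window around the first spike", {
  T_ <- 30
  cfg <- gaussian_window_config(T_, D = 10, A = 60)  # sigma = 3
  dl <- 0.5
  ds <- assign_time_error_to_spikes(dl, first_step = 5, T = T_, cfg = cfg)
  expect_equal(ds[5], dl * gaussian_weight(0, cfg))
  expect_equal(ds[7], dl * gaussian_weight(-2, cfg))
  expect_equal(ds[2], dl * gaussian_weight(3, cfg))
  # zero outside |n - m*| <= 3 sigma
  expect_true(all(ds[15:30] == 0))
  expect_true(all(ds[1:14][abs((1:14) - 5) > 9] == 0))
})

test_that("time-error assignment: inactive rule sums the window over all steps", {
  T_ <- 20
  cfg <- gaussian_window_config(T_, D = 7, A = 40)  # sigma = 2
  dl <- -1.3
  ds <- assign_time_error_to_spikes(dl, first_step = NA, T = T_, cfg = cfg)
  # brute-force double loop
  ref <- numeric(T_)
  for (n in 1:T_) {
    for (m in 1:T_) {
      if (abs(m - n) <= 3 * cfg$sigma) ref[n] <- ref[n] + gaussian_weight(m - n, cfg)
    }
  }
  expect_equal(ds, dl * ref, tolerance = 1e-12)
  # interior plateau: central steps all receive the full window sum
  interior <- (3 * cfg$sigma + 1):(T_ - 3 * cfg$sigma)
  expect_lt(diff(range(ds[interior])), 1e-12)
})

test_that("sign rule: assigned spike errors oppose the time error", {
  set.seed(17)
  for (rep in 1:20) {
    T_ <- sample(10:40, 1)
    cfg <- gaussian_window_config(T_, D = sample(c(2, 5, 10), 1))
    dl <- runif(1, -2, 2)
    active <- sample(c(TRUE, FALSE), 1)
    ds <- assign_time_error_to_spikes(dl, if (active) sample.int(T_, 1) else NA,
                                      T_, cfg)
    nz <- ds[ds != 0]
    if (dl != 0) expect_true(all(sign(nz) == -sign(dl)))
  }
})

test_that("delta-window limit assigns -A/sqrt(2*pi) to a single step (or all, if inactive)", {
  cfg <- gaussian_window_config(T = 10, D = 50, A = 20)
  expect_equal(cfg$sigma, 0)
  expect_equal(cfg$W, 1)
  ds <- assign_time_error_to_spikes(1, first_step = 4, T = 10, cfg = cfg)
  expect_equal(ds[4], -20 / sqrt(2 * pi))
  expect_true(all(ds[-4] == 0))
  ds <- assign_time_error_to_spikes(0.5, first_step = NA, T = 10, cfg = cfg)
  expect_equal(ds, rep(-0.5 * 20 / sqrt(2 * pi), 10))
})

test_that("fast-sigmoid surrogate has the documented shape", {
  expect_equal(surrogate_derivative(1, theta = 1, rho = 5), 1)
  expect_equal(surrogate_derivative(2, theta = 1, rho = 5), 1 / 36)
  expect_equal(surrogate_derivative(0, theta = 1, rho = 5), 1 / 36)
  u <- seq(1, 3, by = 0.25)
  expect_true(all(diff(surrogate_derivative(u, 1, 5)) < 0))
  expect_true(all(surrogate_derivative(runif(50, -3, 3), 0.5, 5) <= 1))
})

test_that("zero output error yields zero gradients everywhere", {
  net <- random_small_net(3, c(5, 2))
  x <- array(rpois(3 * 12, 1), dim = c(3, 12))
  tr <- forward(net, x)
  tape <- backward(net, tr, x, array(0, dim = c(2, 12, 1)))
  for (li in 1:2) {
    expect_true(all(tape[[li]]$dW == 0))
    if (!is.null(tape[[li]]$dV)) expect_true(all(tape[[li]]$dV == 0))
  }
})

test_that("single-layer T=1 gradient reduces to dI * input", {
  lay <- layer_fc(2, 1, neuron_params(0.05, 0.5, 0.01))
  lay$W <- matrix(c(0.3, 0.4), 1, 2)
  net <- network(list(lay), 2)
  x <- matrix(c(2, 1), 2, 1)  # T = 1
  tr <- forward(net, array(x, dim = c(2, 1)))
  dl <- array(0.7, dim = c(1, 1, 1))
  tape <- backward(net, tr, x, dl)
  # at T = 1: dI^1 = 0 (no future), so dW must vanish; dU^1 = ds * f'(U^1)
  expect_equal(as.numeric(tape[[1]]$dW), c(0, 0))
  expect_equal(tape[[1]]$dU[1, 1, 1],
               0.7 * surrogate_derivative(tr[[1]]$U[1, 1, 1], 0.5, 5))
})

test_that("production backward equals the independent reverse-accumulation oracle", {
  set.seed(99)
  worst <- 0
  for (rep in 1:50) {
    n_in <- sample(2:5, 1)
    sizes <- sample(2:16, sample(1:2, 1), replace = TRUE)
    net <- random_small_net(n_in, sizes, theta = runif(1, 0.3, 0.8))
    T_ <- sample(5:32, 1)
    x <- matrix(rpois(n_in * T_, 0.8), n_in, T_)
    tr <- forward(net, array(x, dim = c(n_in, T_)))
    C <- net$layers[[length(net$layers)]]$Q
    dl_out <- matrix(rnorm(C * T_), C, T_)
    tape <- backward(net, tr, x, array(dl_out, dim = c(C, T_, 1)))
    ref <- naive_backward(net, naive_forward(net, x), x, dl_out)
    err <- max_tape_rel_err(tape, ref)
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-6)
})

test_that("backward matches the oracle through conv and pooling layers", {
  set.seed(55)
  for (rep in 1:5) {
    p <- neuron_params(0.05, 0.4, 0.01)
    conv <- layer_conv2d(c(2, 4, 4), filters = 2, kernel = 2, stride = 1, params = p)
    pool <- layer_maxpool(conv$out_shape, 3, p)
    fc <- layer_fc(prod(pool$out_shape), 2, neuron_params(0.1, 0.5, 0.01),
                   recurrent = TRUE)
    net <- init_weights(network(list(conv, pool, fc), c(2, 4, 4)),
                        sample.int(1e6, 1))
    T_ <- 10
    x <- matrix(rpois(32 * T_, 0.5), 32, T_)
    tr <- forward(net, array(x, dim = c(2, 4, 4, T_)))
    dl_out <- matrix(rnorm(2 * T_), 2, T_)
    tape <- backward(net, tr, x, array(dl_out, dim = c(2, T_, 1)))
    ref <- naive_backward(net, naive_forward(net, x), x, dl_out)
    expect_lt(max_tape_rel_err(tape, ref), 1e-6)
  }
})

test_that("batched backward equals per-trial backward summed", {
  set.seed(77)
  net <- random_small_net(3, c(6, 2))
  T_ <- 12; B <- 4
  x <- array(rpois(3 * T_ * B, 0.8), dim = c(3, T_, B))
  tr <- forward(net, x, n_trials = B)
  dl <- array(rnorm(2 * T_ * B), dim = c(2, T_, B))
  tape <- backward(net, tr, x, dl)
  acc <- NULL
  for (b in 1:B) {
    tb <- backward(net, forward(net, array(x[, , b], dim = c(3, T_))),
                   x[, , b], array(dl[, , b], dim = c(2, T_, 1)))
    if (is.null(acc)) {
      acc <- tb
    } else {
      for (li in 1:2) {
        acc[[li]]$dW <- acc[[li]]$dW + tb[[li]]$dW
        if (!is.null(acc[[li]]$dV)) acc[[li]]$dV <- acc[[li]]$dV + tb[[li]]$dV
      }
    }
  }
  for (li in 1:2) {
    expect_equal(tape[[li]]$dW, acc[[li]]$dW, tolerance = 1e-10)
    if (!is.null(tape[[li]]$dV)) {
      expect_equal(tape[[li]]$dV, acc[[li]]$dV, tolerance = 1e-10)
    }
  }
})

test_that("wide windows flatten the inactive-neuron error profile toward the FR limit", {
  T_ <- 60
  prof <- function(D) {
    cfg <- gaussian_window_config(T_, D)
    assign_time_error_to_spikes(1, NA, T_, cfg)
  }
  # as D decreases (window widens), the interior profile flattens
  spread <- function(v) {
    inner <- v[(T_ %/% 4):(3 * T_ %/% 4)]
    diff(range(inner)) / max(abs(inner))
  }
  expect_lt(spread(prof(1)), spread(prof(4)))
  expect_lt(spread(prof(1)), 0.1)  # near-constant plateau in the wide limit
})

test_that("max-pool backward routes error to the first spiking input of each block", {
  p <- neuron_params(0.05, 0.4, 0.01)
  pool <- layer_maxpool(c(1, 2, 2), 2, p)
  fcpre <- layer_fc(2, 4, p)  # drives the 4 pool inputs
  fcpre$W <- matrix(c(5, 0, 0, 5, 0, 0, 0, 0), 4, 2)  # inputs 1,2 firable
  fc <- layer_fc(1, 2, neuron_params(0.1, 0.5, 0.01))
  fc$W <- matrix(c(1, 1), 2, 1)
  net <- network(list(fcpre, pool, fc), 2)
  T_ <- 6
  x <- matrix(0, 2, T_); x[1, 1] <- 1; x[2, 1] <- 1  # both pool inputs spike
  tr <- forward(net, array(x, dim = c(2, T_)))
  dl_out <- matrix(1, 2, T_)
  tape <- backward(net, tr, x, array(dl_out, dim = c(2, T_, 1)))
  ds1 <- tape[[1]]$ds  # error arriving at the pre-pool layer's spikes
  spikes <- matrix(tr[[1]]$S[, , 1], 4)
  for (n in 1:T_) {
    active <- which(spikes[1:4, n] == 1)
    routed <- which(abs(ds1[, n, 1]) > 0)
    if (length(active) > 0 && length(routed) > 0) {
      expect_equal(routed, active[1])  # first active index gets all the error
    } else if (length(routed) > 0) {
      expect_equal(routed, 1L)         # all-zero block: first index by convention
    }
  }
})
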