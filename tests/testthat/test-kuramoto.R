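test_that("delay model arithmetic: velocity from mean length and tau", {
  # mean tract length 57.3 mm with tau = 6 ms -> v = 9.55 mm/ms,
  # printed at one decimal (half-up) as 9.6 m/s
  sc <- toy_connectome(3, length_mm = 57.3)
  dm <- build_delay_model(sc, tau_mean = 6, dt = 0.1)
  expect_equal(dm$velocity, 57.3 / 6, tolerance = 1e-12)
  expect_equal(floor(dm$velocity * 10 + 0.5 + 1e-9) / 10, 9.6)

  # uniform 60 mm lengths, tau = 6 -> v = 10 mm/ms, D = 6 ms everywhere
  dm60 <- build_delay_model(toy_connectome(3, length_mm = 60), 6, 0.1)
  expect_equal(dm60$velocity, 10)
  off <- upper.tri(dm60$delays)
  expect_true(all(dm60$delays[off] == 6))
  expect_true(all(dm60$delay_steps[off] == 60L))
  # discretized delays stay within half a step of the exact delays
  expect_true(all(abs(dm60$delay_steps * 0.1 - dm60$delays) <= 0.05 + 1e-12))

  # tau = 0 disables delays
  dm0 <- build_delay_model(sc, 0, 0.1)
  expect_true(all(dm0$delays == 0))
  expect_true(all(dm0$delay_steps == 0L))
  expect_error(build_delay_model(sc, -1, 0.1), "non-negative")
})

test_that("uncoupled oscillators rotate freely at their intrinsic
           frequency", {
  sc <- toy_connectome(3, length_mm = 60)
  dm <- build_delay_model(sc, 0, dt = 1)
  cfg <- sim_config(k = 0, duration = 10, transient = 0, dt = 1,
                    store_stride = 100L, seed = 5L)
  omega <- c(1, 2.5, -0.7)          # rad/s
  theta0 <- c(0.3, 1.1, 2.0)
  sim <- simulate_kuramoto(sc, dm, cfg, omega = omega, theta0 = theta0)
  tt <- (seq_len(ncol(sim$phases)) - 1) * sim$dt_effective
  for (n in 1:3) {
    expected <- (theta0[n] + omega[n] * tt + pi) %% (2 * pi) - pi
    diff <- abs(sim$phases[n, ] - expected)
    expect_lt(max(pmin(diff, 2 * pi - diff)), 1e-9)
  }
})

test_that("two coupled oscillators follow the closed-form phase-difference
           decay, and halving dt changes the result < 1%", {
  sc <- toy_connectome(2, length_mm = 60)
  delta0 <- 2
  run <- function(dt_ms) {
    dm <- build_delay_model(sc, 0, dt = dt_ms)
    cfg <- sim_config(k = 1, duration = 3, transient = 0, dt = dt_ms,
                      store_stride = as.integer(round(0.1 / (dt_ms / 1000))),
                      seed = 1L)
    sim <- simulate_kuramoto(sc, dm, cfg, omega = c(0, 0),
                             theta0 = c(delta0 / 2, -delta0 / 2))
    sim$phases[1, ] - sim$phases[2, ]
  }
  tt <- seq(0, 3 - 0.1, by = 0.1)
  exact <- 2 * atan(tan(delta0 / 2) * exp(-2 * 1 * tt))
  d1 <- run(1); d05 <- run(0.5)
  expect_lt(max(abs(d1 - exact)) / delta0, 0.01)
  expect_lt(max(abs(d05 - exact)) / delta0, 0.01)
  expect_lt(max(abs(d1 - d05)) / delta0, 0.01)
  # and the pair locks: R -> 1 at the end
  expect_gt(Mod(mean(exp(1i * c(d1[length(d1)], 0)))), 0.999)
})

test_that("zero-delay branch and explicit zero-delay matrix are
           bit-identical, and coupling enters only through k * C", {
  set.seed(21)
  n <- 6
  w <- matrix(runif(n * n), n); w <- w + t(w); diag(w) <- 0
  w[1, 2] <- w[2, 1] <- 0           # one absent connection
  sc <- structural_connectome(w, (w > 0) * 50)
  cfg <- sim_config(k = 3, duration = 2, transient = 0, dt = 1,
                    store_stride = 10L, seed = 9L)
  dm0 <- build_delay_model(sc, 0, dt = 1)
  sim_a <- simulate_kuramoto(sc, dm0, cfg)
  # force the delay-aware integration path while keeping every coupled
  # pair at zero delay: a nonzero delay step on the absent connection
  dm_zero <- dm0
  dm_zero$delay_steps[1, 2] <- dm_zero$delay_steps[2, 1] <- 1L
  sim_b <- simulate_kuramoto(sc, dm_zero, cfg)
  expect_identical(sim_a$phases, sim_b$phases)

  # scale C by 2 and k by 1/2 (exact in binary): identical trajectories
  sc2 <- structural_connectome(2 * w, (w > 0) * 50)
  cfg_half <- cfg; cfg_half$k <- cfg$k / 2
  sim_c <- simulate_kuramoto(sc2, build_delay_model(sc2, 0, 1), cfg_half)
  expect_identical(sim_c$phases, sim_a$phases)
})

test_that("R(t) is invariant to a common shift of the initial phases,
           delays included", {
  set.seed(22)
  n <- 5
  w <- matrix(runif(n * n, 0.5, 1), n); w <- w + t(w); diag(w) <- 0
  l <- matrix(runif(n * n, 30, 90), n); l <- (l + t(l)); diag(l) <- 0
  sc <- structural_connectome(w, l)
  dm <- build_delay_model(sc, tau_mean = 6, dt = 1)
  cfg <- sim_config(k = 1, duration = 4, transient = 1, dt = 1,
                    store_stride = 20L, seed = 3L)
  theta0 <- runif(n, 0, 2 * pi)
  omega <- 2 * pi * runif(n, 0.8, 1.2)
  r_base <- order_parameter_series(
    simulate_kuramoto(sc, dm, cfg, omega, theta0)$phases)$values
  r_shift <- order_parameter_series(
    simulate_kuramoto(sc, dm, cfg, omega, theta0 + 1.234)$phases)$values
  expect_equal(r_shift, r_base, tolerance = 1e-8)
})

test_that("simulator rejects inconsistent configuration", {
  sc <- toy_connectome(2)
  dm <- build_delay_model(sc, 6, dt = 0.1)
  cfg <- sim_config(k = 1, duration = 1, dt = 0.2)
  expect_error(simulate_kuramoto(sc, dm, cfg), "discretized at")
  expect_error(sim_config(k = 1, duration = 1, transient = 2), "exceed")
  expect_error(coupling_sweep(sc, dm, cfg, numeric(0)), "non-empty")
})

test_that("frequency draws match the requested mean/SD conventions", {
  set.seed(30)
  cfg_u <- sim_config(1, 1, omega_mean = 60, omega_sd = 1)
  f <- draw_frequencies(2e5, cfg_u)
  expect_true(all(f >= 60 - sqrt(3) - 1e-9 & f <= 60 + sqrt(3) + 1e-9))
  expect_equal(mean(f), 60, tolerance = 0.01)
  expect_equal(sd(f), 1, tolerance = 0.01)
  cfg_n <- sim_config(1, 1, omega_mean = 0.045, omega_sd = 0.01,
                      omega_dist = "normal")
  g <- draw_frequencies(2e5, cfg_n)
  expect_equal(mean(g), 0.045, tolerance = 1e-3)
  expect_equal(sd(g), 0.01, tolerance = 1e-3)
})
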