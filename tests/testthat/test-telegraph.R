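test_that("RTS simulation is seed-deterministic and two-valued", {
  a <- simulate_rts(488, 488, 1, 1e-4, seed = 42)
  b <- simulate_rts(488, 488, 1, 1e-4, seed = 42)
  expect_identical(a$states, b$states)
  expect_identical(a$events, b$events)
  expect_true(all(a$states %in% c(0L, 1L)))
  expect_length(a$states, 1e4)
  c <- simulate_rts(488, 488, 1, 1e-4, seed = 43)
  expect_false(identical(a$states, c$states))
})

test_that("vanishing capture rate from the empty state freezes the trace", {
  tr <- simulate_rts(1e-9, 100, 5, 1e-3, seed = 1, initial_state = 0)
  expect_true(all(tr$states == 0L))
  expect_length(tr$events, 0)
})

test_that("transition count and occupancy match the stationary chain", {
  ## lambda = mu = 100 1/s over 100 s: expected transitions
  ## duration * 2*lambda*mu/(lambda+mu) = 10,000
  tr <- simulate_rts(100, 100, 100, 1e-3, seed = 7)
  expect_lt(abs(length(tr$events) - 1e4), 4 * sqrt(1e4))

  ## ergodicity: time-averaged occupancy near stationary value
  g_hat <- mean(tr$states)
  expect_lt(abs(g_hat - 0.5), 4 * sqrt(0.5 * 0.5 / length(tr$events)))

  ## asymmetric rates: g = lambda/(lambda+mu) = 0.75
  tr2 <- simulate_rts(300, 100, 60, 1e-3, seed = 8)
  expect_lt(abs(mean(tr2$states) - 0.75),
            4 * sqrt(0.75 * 0.25 / length(tr2$events)))
})

test_that("dwell times are exponential with the requested means", {
  ## use the continuous event list (grid dwells are dt-quantized and
  ## would trip a KS test on ties alone)
  tr <- simulate_rts(400, 600, 30, 1e-4, seed = 3)
  dw <- diff(tr$events)
  state_of_dwell <- (tr$state0 + seq_along(dw)) %% 2L
  d1 <- dw[state_of_dwell == 1L]   # occupied dwells, mean 1/mu
  d0 <- dw[state_of_dwell == 0L]   # empty dwells, mean 1/lambda
  expect_gt(length(d1), 5e3)
  ks_1 <- stats::ks.test(d1, "pexp", rate = 600)
  ks_0 <- stats::ks.test(d0, "pexp", rate = 400)
  expect_gt(ks_1$p.value, 0.01)
  expect_gt(ks_0$p.value, 0.01)
})

test_that("grid resampling loses under 1% of events when dt is fine", {
  ## dt = 0.005 / rate
  tr <- simulate_rts(10, 10, 400, 5e-4, seed = 5)
  n_grid <- sum(abs(diff(tr$states)) > 0)
  n_events <- length(tr$events)
  expect_gt(n_events, 1e3)
  expect_lt((n_events - n_grid) / n_events, 0.01)
})

test_that("flicker synthesizer hits the requested 1/f spectrum", {
  expect_identical(synthesize_flicker(0, 1, 1e-3), numeric(1000))
  expect_error(synthesize_flicker(-1, 1, 1e-3), "level")

  x <- synthesize_flicker(1e-9, 100, 1e-3, seed = 9)
  expect_equal(mean(x), 0)
  p <- estimate_psd(x, 10, dt = 1e-3)
  ## level at 10 Hz: 1e-10 V^2/Hz within 15%
  s10 <- mean(p$S[p$f >= 8 & p$f <= 12])
  expect_lt(abs(s10 - 1e-10) / 1e-10, 0.15)
  ## log-log slope -1 +/- 0.1
  sl <- flicker_slope(p, 0.5, 100)
  expect_gt(sl$slope, -1.1)
  expect_lt(sl$slope, -0.9)
  ## total variance ~ level * log(f_high / f_low)
  v_expect <- 1e-9 * log(500 / 0.01)
  expect_lt(abs(var(x) - v_expect) / v_expect, 0.15)
})

test_that("composite trace amplitude follows delta_I = g_m q*/(C_G A)", {
  ## worked numbers: g_m = 1 uS, q* = 0.5 q, C_G * A = 7.1e-17 F
  dev <- device_model(1e-7, 1e-7, C_G = 7.1e-17 / 1e-14, g_m = 1e-6)
  tr <- trap_model(1 / 488, 1 / 488)
  ct <- compose_trace(dev, tr, 0, 0.2, 1e-4, seed = 2,
                      include_dp = FALSE, white_sigma = 0)
  expect_equal(ct$delta_i, 1e-6 * 0.5 * 1.602176634e-19 / 7.1e-17)
  expect_equal(ct$delta_i, 1.128e-9, tolerance = 1e-3)

  ## noise-free composite is exactly two-level, occupied state lower
  expect_setequal(unique(ct$current), c(0, -ct$delta_i))
  expect_identical(ct$current == -ct$delta_i, ct$rts$states == 1L)

  ## sign convention flips with occupied_level
  ct2 <- compose_trace(dev, tr, 0, 0.2, 1e-4, seed = 2,
                       include_dp = FALSE, white_sigma = 0,
                       occupied_level = "high")
  expect_identical(ct2$current == ct2$delta_i, ct2$rts$states == 1L)
})

test_that("composite trace is reproducible and carries its components", {
  a <- ref_composite(seed = 11, duration = 0.5, include_dp = TRUE)
  b <- ref_composite(seed = 11, duration = 0.5, include_dp = TRUE)
  expect_identical(a$current, b$current)
  expect_true(all(a$components))
})
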