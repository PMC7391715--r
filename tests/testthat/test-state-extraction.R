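make_states <- function(s, dt = 1e-3) {
  structure(list(dt = dt, states = as.integer(s), v_g = NA_real_,
                 seed = NA_integer_,
                 events = dt * which(abs(diff(s)) > 0),
                 state0 = s[1]),
            class = "rts_trace")
}

test_that("noiseless two-level trace is decoded exactly", {
  dev <- ref_dev; tr <- ref_trap
  ct <- compose_trace(dev, tr, 0, 2, 1e-4, seed = 21,
                      include_dp = FALSE, white_sigma = 0)
  h <- fit_two_state_hmm(ct, seed = 1)
  expect_identical(h$states$states, ct$rts$states)
  expect_lt(h$emission_sigma, 1e-3 * ct$delta_i)
  expect_equal(h$level_high - h$level_low, ct$delta_i, tolerance = 1e-9)
})

test_that("HMM decodes noisy traces at step-to-noise 5 with 99% accuracy", {
  ## gamma = 100 1/s, 60 s, delta_I / sigma = 5
  dev <- ref_dev
  tr <- trap_model(1 / 100, 1 / 100, alpha = 0.5)
  ct <- compose_trace(dev, tr, 0, 60, 2e-4, seed = 31,
                      include_dp = FALSE, white_sigma = ref_sigma(5))
  h <- fit_two_state_hmm(ct, seed = 1)
  expect_gte(mean(h$states$states == ct$rts$states), 0.99)
  ## recovered rates near 100 1/s
  expect_lt(abs(h$rates$lambda - 100) / 100, 0.1)
  expect_lt(abs(h$rates$mu - 100) / 100, 0.1)
})

test_that("reference-device composite with DP recovers gamma = 488 within 10%", {
  ct <- ref_composite(seed = 4, duration = 5, include_dp = TRUE)
  h <- fit_two_state_hmm(ct, seed = 4)
  expect_lt(abs(h$rates$lambda - 488) / 488, 0.1)
  expect_lt(abs(h$rates$mu - 488) / 488, 0.1)
  expect_gte(mean(h$states$states == ct$rts$states), 0.98)
})

test_that("degenerate traces are rejected with informative errors", {
  expect_error(fit_two_state_hmm(rep(1e-9, 2000), dt = 1e-4),
               "zero variance")
  expect_error(fit_two_state_hmm(rnorm(500), dt = 1e-4), "too short")
  ## pure noise: no two-level structure
  set.seed(9)
  expect_error(fit_two_state_hmm(rnorm(5e4), dt = 1e-4, seed = 1),
               "no two-level structure")
})

test_that("dwell times drop censored edges and count hand-checkable runs", {
  st <- make_states(c(0, 0, 1, 1, 1, 0, 0), dt = 1e-3)
  dw <- suppressWarnings(dwell_times(st))
  expect_equal(dw$emission_dwells, 3e-3)
  expect_length(dw$capture_dwells, 0)
  expect_equal(dw$n_transitions, 2L)
  expect_true(dw$low_statistics)
  expect_warning(dwell_times(st), "200")

  expect_error(dwell_times(make_states(c(0, 0, 1, 1))), "transitions")
})

test_that("dwell-time means recover the simulated time constants", {
  tr <- simulate_rts(488, 488, 50, 5e-5, seed = 12)
  dw <- dwell_times(tr)
  expect_lt(abs(dw$tau_c_hat - 1 / 488) / (1 / 488), 0.05)
  expect_lt(abs(dw$tau_e_hat - 1 / 488) / (1 / 488), 0.05)
  expect_false(dw$low_statistics)
})

test_that("sliding occupancy window behaves on deterministic traces", {
  expect_equal(sliding_g(make_states(rep(1, 100)), theta = 0.01)$g,
               rep(1, 91))
  ## square wave of period P with theta = P gives exactly 1/2
  sq <- make_states(rep(rep(c(1, 0), each = 25), 10))
  gt <- sliding_g(sq, theta = 0.05)
  expect_true(all(gt$g == 0.5))
  ## window longer than the trace
  expect_error(sliding_g(sq, theta = 1), "exceeds")
})

test_that("sliding occupancy mean matches the stationary value", {
  tr <- simulate_rts(488, 488, 20, 1e-4, seed = 13)
  gt <- sliding_g(tr, theta = 0.5)
  expect_true(all(gt$g >= 0 & gt$g <= 1))
  ## variance bound from the analytic windowed-occupancy variance
  v_ana <- autocorr_g(488, 488, 0.5, 0) - 0.25
  expect_lt(abs(mean(gt$g) - 0.5), 4 * sqrt(v_ana))
  ## coarser stride subsamples the same curve
  gt2 <- sliding_g(tr, theta = 0.5, stride = 0.1)
  expect_equal(gt2$g, gt$g[seq(1, length(gt$g), by = 1000)])
})

test_that("occupancy-trace variance shrinks with the window duration", {
  tr <- simulate_rts(488, 488, 20, 1e-4, seed = 14)
  vars <- sapply(c(0.05, 0.2, 1, 4), function(th)
    var(sliding_g(tr, theta = th)$g))
  expect_true(all(diff(vars) < 0))
})

test_that("occupancy curve fit recovers the generating coupling", {
  ## 7 voltages across the transition, alpha = 0.5
  v_gs <- seq(-0.075, 0.075, by = 0.025)
  traces <- lapply(seq_along(v_gs), function(i) {
    tt <- trap_times(ref_trap, ref_dev, v_gs[i])
    list(v_g = v_gs[i],
         trace = simulate_rts(1 / tt$tau_c, 1 / tt$tau_e, 5, 1e-4,
                              seed = 100 + i, v_g = v_gs[i]))
  })
  gc <- g_curve(traces, T = ref_dev$T)
  expect_lt(abs(gc$v0 - 0), 2e-3)                    # midpoint within 2 mV
  expect_lt(abs(gc$alpha - 0.5) / 0.5, 0.1)          # slope within 10%
  ## sensitivity: the slope matches finite differences of the fit
  gc_fd <- g_curve(traces, T = ref_dev$T, derivative = "finite_diff")
  i_mid <- which.min(abs(gc$v_g))
  expect_equal(gc_fd$g_g[i_mid], gc$g_g[i_mid], tolerance = 0.15)

  expect_error(g_curve(traces[1:3]), "4 distinct")
})

test_that("coupling recovery is unbiased over repeated fits", {
  ## 20 seeded replicates at shorter duration; mean alpha within 10%
  v_gs <- seq(-0.075, 0.075, by = 0.025)
  alphas <- vapply(1:20, function(r) {
    traces <- lapply(seq_along(v_gs), function(i) {
      tt <- trap_times(ref_trap, ref_dev, v_gs[i])
      list(v_g = v_gs[i],
           trace = simulate_rts(1 / tt$tau_c, 1 / tt$tau_e, 1, 2e-4,
                                seed = 1000 * r + i, v_g = v_gs[i]))
    })
    g_curve(traces, T = ref_dev$T)$alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 0.5) / 0.5, 0.1)
})
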