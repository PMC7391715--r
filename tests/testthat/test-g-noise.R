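test_that("two-state transition matrix solves the forward equation", {
  expect_equal(transition_matrix(1, 1, 0), diag(2))
  ## hand value: lambda = mu = 1, t = ln(2)/2 -> P[1,1] = 0.75
  P <- transition_matrix(1, 1, log(2) / 2)
  expect_equal(P[1, 1], 0.75)
  expect_equal(P[1, 2], 0.25)
  ## long-time limit: both rows become the stationary distribution
  Pinf <- transition_matrix(300, 100, 1)
  expect_equal(Pinf[1, ], c(0.25, 0.75), tolerance = 1e-10)
  expect_equal(Pinf[2, ], c(0.25, 0.75), tolerance = 1e-10)
  expect_error(transition_matrix(1, 1, -0.1), ">= 0")
})

test_that("transition matrix rows are distributions at every time", {
  for (lt in seq(-4, 1, by = 0.5)) {
    P <- transition_matrix(488, 97, 10^lt)
    expect_equal(rowSums(P), c(1, 1))
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("occupancy-noise density has the exact limits and nulls", {
  ## omega -> 0 limit is 1/(4 gamma)
  expect_equal(sg_theta(0, 488, 1), 1 / (4 * 488))
  expect_equal(sg_theta(0, 488, 1), 5.123e-4, tolerance = 1e-3)
  ## hand value at omega = pi, gamma = 488, theta = 1
  expect_equal(sg_theta(pi, 488, 1),
               2 * 488 * 2 / (pi^2 * (4 * 488^2 + pi^2)))
  ## exact nulls at theta * omega = 2 pi k
  expect_equal(sg_theta(2 * pi * (1:5), 488, 1), rep(0, 5))
  ## nonnegative on a wide grid
  w <- 10^seq(-3, 4, length.out = 200)
  expect_true(all(sg_theta(w, 488, 1) >= 0))
  ## doubling gamma halves the plateau
  expect_equal(sg_theta(0, 2 * 488, 1), sg_theta(0, 488, 1) / 2)
})

test_that("density integrates to the windowed-occupancy variance", {
  ## Wiener-Khinchin: Var[g^Theta] = (1/pi) int_0^inf S_g(omega) d omega
  v_ac <- autocorr_g(50, 50, 0.5, 0) - 0.25
  v_sp <- integrate(function(w) sg_theta(w, 50, 0.5), 0, Inf,
                    rel.tol = 1e-9, subdivisions = 1000)$value / pi
  expect_equal(v_ac, v_sp, tolerance = 1e-6)
})

test_that("autocorrelation decorrelates to the squared stationary occupancy", {
  expect_equal(autocorr_g(50, 50, 0.5, 2), 0.25, tolerance = 1e-8)
  ## asymmetric chain: g_stat = 0.75
  expect_equal(autocorr_g(30, 10, 0.5, 3), 0.5625, tolerance = 1e-8)
})

test_that("autocorrelation matches a long simulated occupancy trace", {
  tr <- simulate_rts(50, 50, 500, 5e-4, seed = 11)
  gt <- sliding_g(tr, 0.5)
  n <- length(gt$g)
  for (lag in c(0, 0.1, 0.25)) {
    k <- round(lag / 5e-4)
    emp <- mean(gt$g[1:(n - k)] * gt$g[(k + 1):n])
    expect_equal(emp, autocorr_g(50, 50, 0.5, lag), tolerance = 5e-3)
  }
})

test_that("band-averaged density is monotone in the window duration", {
  ## at any f >= 1/theta the density falls as the window grows
  for (f in c(1, 10, 50)) {
    s <- vapply(c(1, 2, 5, 10, 20, 40),
                function(th) sg_theta_f(f, 488, th, band_averaged = TRUE),
                numeric(1))
    expect_true(all(diff(s) < 0))
  }
})

test_that("simulated occupancy spectrum reproduces the closed form", {
  ## one-sided estimate = 2 x the closed-form density (spectral
  ## convention regression pin)
  p <- sg_numeric_oracle(50, 0.5, 100, 5e-4, n_reps = 8, seed = 7,
                         segment_seconds = 25)
  pb <- log_bin_psd(p, 3, 0.1, 80)
  pred <- sg_theta_band(pb$f_lo, pb$f_hi, 50, 0.5)
  expect_true(all(abs(pb$S - pred) / pred < 0.2))

  ## low-frequency plateau: window-response-corrected estimate vs 1/(4g)
  x <- 0.5 * 2 * pi * p$f
  corr <- x^2 / 2 / (1 - cos(x))
  low <- p$f <= 0.3
  plat <- mean(p$S[low] * corr[low]) / 2
  expect_lt(abs(plat - 1 / 200) / (1 / 200), 0.1)

  ## longer window, lower density at 10 Hz
  p2 <- sg_numeric_oracle(50, 1, 100, 5e-4, n_reps = 4, seed = 7,
                          segment_seconds = 20)
  at10 <- function(pp) mean(pp$S[pp$f >= 8 & pp$f <= 12])
  expect_lt(at10(p2), at10(p))
})
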