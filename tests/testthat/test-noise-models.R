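dev_std <- device_model(1e-6, 1e-6, C_G = 7.1e-3, tg_delta = 3.8e-3,
                        g_m = 1e-6, N_ot = 1e12, T = 300)

test_that("trap-number noise closed forms and their charge/voltage duality", {
  ## direct evaluation: N_ot = 1e12 /m^2, A = 1e-12 m^2, f = 1 Hz
  d <- device_model(1e-6, 1e-6, C_G = 7.1e-3, N_ot = 1e12)
  expect_equal(sq_trap_number(d, 1), (1.602176634e-19)^2,
               tolerance = 1e-12)

  ## S_VG = S_q / C_total^2 to machine precision
  f <- 10^seq(-1, 3, length.out = 23)
  expect_equal(svg_trap_number(d, f),
               sq_trap_number(d, f) / d$C_total^2)

  ## area scaling: S_q ~ A, S_VG ~ 1/A
  d2 <- device_model(sqrt(2) * 1e-6, sqrt(2) * 1e-6, C_G = 7.1e-3,
                     N_ot = 1e12)
  expect_equal(sq_trap_number(d2, 10) / sq_trap_number(d, 10), 2)
  expect_equal(svg_trap_number(d2, 10) / svg_trap_number(d, 10), 0.5)

  ## direct S_VG value: A = 1e-14 m^2, f = 10 Hz -> 5.09e-9 V^2/Hz
  d3 <- device_model(1e-7, 1e-7, C_G = 7.1e-3, N_ot = 1e12)
  expect_equal(svg_trap_number(d3, 10), 5.09e-9, tolerance = 5e-3)

  expect_error(sq_trap_number(d, 0), "positive")
  expect_error(svg_trap_number(d, -1), "positive")
})

test_that("dielectric-polarization noise follows 2kT tgd/(pi C f)", {
  ## zero loss, zero noise
  expect_equal(sq_dp(1e-15, 0, 300, 10), 0)

  ## carbon-nanotube scenario: 0.2 F/m^2 over 1e-14 m^2, tgd = 5e-3
  c_cnt <- 0.2 * 1e-14
  expect_equal(sq_dp(c_cnt, 5e-3, 300, 10),
               2 * 1.380649e-23 * 300 * 5e-3 * 2e-15 / (pi * 10))
  expect_equal(sq_dp(c_cnt, 5e-3, 300, 10), 2.64e-39, tolerance = 2e-3)

  ## 1/f law and duality
  expect_equal(sq_dp(1e-15, 3.8e-3, 300, 5) / sq_dp(1e-15, 3.8e-3, 300, 10),
               2)
  expect_equal(svg_dp(1e-15, 3.8e-3, 300, 10),
               sq_dp(1e-15, 3.8e-3, 300, 10) / (1e-15)^2)
  ## direct value ~1.0e-9 V^2/Hz
  expect_equal(svg_dp(1e-15, 3.8e-3, 300, 10), 1.0e-9, tolerance = 3e-3)

  ## monotone decreasing in capacitance
  expect_gt(svg_dp(5e-16, 3.8e-3, 300, 10), svg_dp(1e-15, 3.8e-3, 300, 10))
})

test_that("RTS Lorentzian spectrum behaves across occupancy and frequency", {
  v <- 1e-3  # q*/C_total
  q_star <- 0.5 * 1.602176634e-19
  ct <- q_star / v
  ## no switching at g = 0 or 1
  expect_equal(svg_rts_lorentzian(0, 1e-3, q_star, ct, 10), 0)
  expect_equal(svg_rts_lorentzian(1, 1e-3, q_star, ct, 10), 0)
  ## low-frequency plateau at g = 0.5, tau_e = 1 ms: 5e-10 V^2/Hz
  expect_equal(svg_rts_lorentzian(0.5, 1e-3, q_star, ct, 1e-6),
               5e-10, tolerance = 1e-6)
  expect_error(svg_rts_lorentzian(1.2, 1e-3, q_star, ct, 10), "g")
})

test_that("peak RTS noise equals the dense-scan maximum of S(f) * f", {
  ## oracle: dense scan of the Lorentzian weighed against a 1/f
  ## background; its maximum sits at the corner frequency
  q_star <- 0.5 * 1.602176634e-19
  ct <- 2e-18
  tau_e <- 1 / 488
  f0 <- corner_frequency(tau_e, tau_e)
  f_scan <- 10^seq(log10(f0) - 3, log10(f0) + 3, length.out = 1e4)
  S_scan <- svg_rts_lorentzian(0.5, tau_e, q_star, ct, f_scan)
  i_max <- which.max(S_scan * f_scan)
  S_at_peak <- S_scan[i_max]

  peak <- svg_rts_max(q_star, ct, f0)
  expect_lt(abs(S_at_peak - as.numeric(peak)) / as.numeric(peak), 5e-3)
  ## scan locates the corner
  expect_lt(abs(f_scan[i_max] - f0) / f0, 5e-3)
  ## exact coefficient 1/(4 pi), quoted rounded as 0.08
  expect_equal(attr(peak, "coefficient"), 1 / (4 * pi))
  expect_equal(round(attr(peak, "coefficient"), 2), 0.08)
  ## direct value: q*/C = 1 mV, f0 = 10 Hz -> 7.96e-9 V^2/Hz
  expect_equal(as.numeric(svg_rts_max(q_star, q_star / 1e-3, 10)),
               7.96e-9, tolerance = 1e-3)
})

test_that("ideal ISFET signal is Nernstian", {
  expect_equal(nernst_signal(0, 298), 0)
  expect_equal(round(nernst_signal(0.1, 298) * 1e3, 1), 5.9)
  expect_equal(nernst_signal(1, 298), 59.13e-3, tolerance = 1e-3)
  ## linear in delta_pH
  expect_equal(nernst_signal(2, 310), 2 * nernst_signal(1, 310))
})

test_that("corner frequency interpolates between the dwell-time limits", {
  ## symmetric gamma = 488: tau_eff = 1/(2*488), f0 = 488/pi
  expect_equal(corner_frequency(1 / 488, 1 / 488), 488 / pi)
  ## tau_c << tau_e limit: f0 -> 1/(2 pi tau_c) within 1%
  expect_equal(corner_frequency(1e-5, 2e-3), 1 / (2 * pi * 1e-5),
               tolerance = 0.01)
  ## doubling both times halves f0
  expect_equal(corner_frequency(2e-3, 4e-3),
               corner_frequency(1e-3, 2e-3) / 2)
})

test_that("closed-form spectra are positive, finite and 1/f or Lorentzian", {
  f <- 10^seq(-2, 4, length.out = 50)
  for (S in list(sq_trap_number(dev_std, f), svg_trap_number(dev_std, f),
                 sq_dp(dev_std$C_total, 3.8e-3, 300, f),
                 svg_dp(dev_std$C_total, 3.8e-3, 300, f))) {
    expect_true(all(is.finite(S) & S > 0))
    ## pure 1/f: S * f constant
    expect_equal(max(S * f) / min(S * f), 1, tolerance = 1e-10)
  }
  SL <- svg_rts_lorentzian(0.5, 1e-3, 8e-20, 2e-18, f)
  expect_true(all(is.finite(SL) & SL >= 0))
  ## Lorentzian: flat then -2 slope
  expect_equal(SL[1] / SL[2], 1, tolerance = 1e-2)
  expect_equal(SL[50] / SL[49], (f[49] / f[50])^2, tolerance = 1e-2)
})
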