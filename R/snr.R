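#' Input-referred occupancy-factor noise S_gg
#'
#' Divides an occupancy noise density by the squared occupancy slope:
#' \eqn{S_{gg} = S_g / g_g^2}, the occupancy-readout analogue of
#' referring current noise to the gate. A steeper occupancy-voltage
#' slope (larger \eqn{|g_g|}) suppresses the input-referred noise
#' quadratically.
#'
#' @param s_g Occupancy noise density (1/Hz), vector or `psd_result`.
#' @param g_g Occupancy slope dg/dV_G (1/V), nonzero.
#' @return Same shape as `s_g`, in V^2/Hz.
#' @export
s_gg <- function(s_g, g_g) {
  stop_if_not_scalar(g_g, "g_g")
  if (g_g == 0)
    stop("`g_g` = 0: operating point has no sensitivity", call. = FALSE)
  if (inherits(s_g, "psd_result")) {
    s_g$S <- s_g$S / g_g^2
    s_g
  } else {
    s_g / g_g^2
  }
}

## Trapezoid band integral of a density sampled on a grid.
band_integral <- function(f, S, f1, f2) {
  if (f1 <= 0 || f2 <= f1) stop("need 0 < f1 < f2", call. = FALSE)
  if (f1 < min(f) - 1e-12 || f2 > max(f) + 1e-12)
    stop("integration band [", f1, ", ", f2,
         "] outside the frequency grid", call. = FALSE)
  keep <- f >= f1 & f <= f2
  fs <- f[keep]; Ss <- S[keep]
  ## close the band edges by interpolation
  if (length(fs) == 0L || fs[1] > f1) {
    Ss <- c(approx(f, S, f1)$y, Ss); fs <- c(f1, fs)
  }
  if (fs[length(fs)] < f2) {
    Ss <- c(Ss, approx(f, S, f2)$y); fs <- c(fs, f2)
  }
  sum(diff(fs) * (Ss[-1] + Ss[-length(Ss)]) / 2)
}

#' Signal-to-noise ratio of conventional voltage readout
#'
#' \eqn{S/N = \delta V_{Th} / \sqrt{\int_{f_1}^{f_2} S_{V_G}\, df}}:
#' a threshold-voltage signal against the input-referred voltage noise
#' integrated over the measurement band (trapezoid rule on the provided
#' grid).
#'
#' @param delta_v_th Signal: threshold-voltage shift (V), >= 0.
#' @param f Frequency grid (Hz).
#' @param s_vg Input-referred voltage noise density on `f` (V^2/Hz).
#' @param f1,f2 Integration band (Hz), `0 < f1 < f2`, inside the grid.
#' @return Dimensionless S/N.
#' @export
#' @examples
#' f <- 1:101
#' snr_voltage(5.9e-3, f, rep(1e-8, 101), 1, 101)  # = 5.9
snr_voltage <- function(delta_v_th, f, s_vg, f1 = 1, f2 = 100) {
  stop_if_not_scalar(delta_v_th, "delta_v_th", nonneg = TRUE)
  if (any(s_vg[f >= f1 & f <= f2] < 0))
    stop("noise density must be nonnegative on the band", call. = FALSE)
  delta_v_th / sqrt(band_integral(f, s_vg, f1, f2))
}

#' Signal-to-noise ratio of single-trap (occupancy) readout
#'
#' Same form as [snr_voltage()] with the input-referred occupancy noise
#' \eqn{S_{gg}} in place of \eqn{S_{V_G}}:
#' \eqn{S/N = \delta V_{Th} / \sqrt{\int_{f_1}^{f_2} S_{gg}\, df}}.
#'
#' @inheritParams snr_voltage
#' @param s_gg_grid Input-referred occupancy noise density on `f`
#'   (V^2/Hz).
#' @return Dimensionless S/N.
#' @export
snr_gfactor <- function(delta_v_th, f, s_gg_grid, f1 = 1, f2 = 100) {
  snr_voltage(delta_v_th, f, s_gg_grid, f1, f2)
}

#' Parameter sweep of occupancy-readout noise and S/N
#'
#' Sweeps one knob of the single-trap readout -- RTS corner frequency
#' `f0`, operating occupancy `g`, or window duration `theta` -- and
#' tabulates the band-averaged occupancy noise at `f_report`, the
#' input-referred `S_gg`, and the S/N of occupancy readout. The
#' dielectric-polarization (DP) reference of the same device -- its noise
#' level at `f_report` and the S/N of conventional voltage readout
#' against the DP spectrum -- is attached as attributes.
#'
#' For the `f0` and `theta` sweeps the chain is symmetric
#' (\eqn{g = 1/2}, \eqn{\gamma = \pi f_0}); for the `g` sweep the
#' emission time is held fixed at `1/gamma` while the capture time moves
#' with `g`, so the corner frequency rises with `g`. The occupancy noise
#' for asymmetric `g` uses the symmetric closed form evaluated at the
#' pair's effective switching rate \eqn{1/(2\tau_{eff})} -- the
#' Lorentzian-equivalent rate of the asymmetric chain -- an approximation
#' exact at g = 1/2.
#'
#' @param axis `"f0"`, `"g"`, or `"theta"`: the swept parameter.
#' @param values Numeric vector of axis values (Hz, probability, or s).
#' @param device A [device_model()] (DP reference and temperature).
#' @param alpha Occupancy-slope coupling for the logistic `g_g`.
#' @param gamma Symmetric switching rate (1/s) used when it is not the
#'   swept axis.
#' @param theta Window (s) used when not swept.
#' @param g Operating occupancy used when not swept.
#' @param delta_v_th Signal (V); default the ideal ISFET response to
#'   0.1 pH at the device temperature.
#' @param f1,f2 S/N integration band (Hz).
#' @param f_report Reporting frequency (Hz) for the density columns.
#' @return Data frame with columns `value`, `s_g` (1/Hz), `g_g` (1/V),
#'   `s_gg` (V^2/Hz), `snr` plus attributes `dp_level` (V^2/Hz at
#'   `f_report`), `snr_dp` (conventional readout against DP noise) and
#'   `axis`.
#' @export
snr_sweep <- function(axis = c("f0", "g", "theta"), values, device,
                      alpha = 0.5, gamma = 488, theta = 10, g = 0.5,
                      delta_v_th = NULL, f1 = 1, f2 = 100,
                      f_report = 10) {
  axis <- match.arg(axis)
  stopifnot(inherits(device, "device_model"))
  if (length(values) < 1L) stop("empty sweep range", call. = FALSE)
  if (is.null(delta_v_th)) delta_v_th <- nernst_signal(0.1, device$T)

  fgrid <- exp(seq(log(f1), log(f2), length.out = 200L))
  dp_grid <- svg_dp(device$C_total, device$tg_delta, device$T, fgrid)
  dp_level <- svg_dp(device$C_total, device$tg_delta, device$T, f_report)
  snr_dp <- snr_voltage(delta_v_th, fgrid, dp_grid, f1, f2)
  beta <- .qe / (.kB * device$T)

  one <- function(val) {
    gi <- g; th <- theta; gam <- gamma
    if (axis == "f0") gam <- pi * val
    if (axis == "theta") th <- val
    if (axis == "g") gi <- val
    ## asymmetric occupancy: hold tau_e = 1/gam, move tau_c with g
    tau_e <- 1 / gam
    tau_c <- tau_e * (1 - gi) / gi
    rate_eff <- (1 / tau_c + 1 / tau_e) / 2   # 1/(2 tau_eff)
    s_g_rep <- sg_theta_f(f_report, rate_eff, th, band_averaged = TRUE)
    gg <- beta * alpha * gi * (1 - gi)
    sg_grid <- sg_theta_f(fgrid, rate_eff, th, band_averaged = TRUE)
    snr <- snr_gfactor(delta_v_th, fgrid, sg_grid / gg^2, f1, f2)
    c(s_g = s_g_rep, g_g = gg, s_gg = s_g_rep / gg^2, snr = snr)
  }
  rows <- t(vapply(values, one, numeric(4)))
  out <- data.frame(value = values, rows)
  attr(out, "axis") <- axis
  attr(out, "dp_level") <- dp_level
  attr(out, "snr_dp") <- snr_dp
  out
}
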