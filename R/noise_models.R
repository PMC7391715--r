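#' Trap-number charge noise spectrum
#'
#' Charge-referred 1/f noise from fluctuation of the number of active
#' oxide traps: \eqn{S_q = q^2 N_{ot} A / f} (C^2/Hz). Valid in the
#' many-trap regime \eqn{N_{ot} A \gg 1}; `N_ot * A = 1` marks the
#' boundary of the discrete-trap regime.
#'
#' @param device A [device_model()].
#' @param f Frequency (Hz), strictly positive. Vectorised.
#' @return One-sided PSD in C^2/Hz.
#' @export
sq_trap_number <- function(device, f) {
  stopifnot(inherits(device, "device_model"))
  check_freq(f)
  .qe^2 * device$N_ot * device$A / f
}

#' Trap-number input-referred voltage noise spectrum
#'
#' \eqn{S_{V_G} = q^2 N_{ot} / (C_G^2 A f)} (V^2/Hz); equals
#' [sq_trap_number()] divided by `C_total^2`. Scales as 1/A: larger gates
#' have lower input-referred trap noise.
#'
#' @inheritParams sq_trap_number
#' @return One-sided PSD in V^2/Hz.
#' @export
svg_trap_number <- function(device, f) {
  sq_trap_number(device, f) / device$C_total^2
}

#' Dielectric-polarization charge noise spectrum
#'
#' Thermal 1/f charge noise from dipole fluctuations in the gate
#' dielectric: \eqn{S_q = 2 k T\, tg\delta\, C / (\pi f)} (C^2/Hz). This
#' is the "thermal limit" that remains in trap-free devices.
#'
#' @param c_total Total gate capacitance (F).
#' @param tg_delta Dielectric loss tangent (dimensionless).
#' @param T Temperature (K).
#' @param f Frequency (Hz), strictly positive. Vectorised.
#' @return One-sided PSD in C^2/Hz.
#' @export
sq_dp <- function(c_total, tg_delta, T, f) {
  stop_if_not_scalar(c_total, "c_total", positive = TRUE)
  stop_if_not_scalar(tg_delta, "tg_delta", nonneg = TRUE)
  stop_if_not_scalar(T, "T", positive = TRUE)
  check_freq(f)
  2 * .kB * T * tg_delta * c_total / (pi * f)
}

#' Dielectric-polarization input-referred voltage noise spectrum
#'
#' \eqn{S_{V_G} = 2 k T\, tg\delta / (\pi C f)} (V^2/Hz); equals
#' [sq_dp()] divided by `c_total^2`. Monotone decreasing in capacitance.
#'
#' @inheritParams sq_dp
#' @return One-sided PSD in V^2/Hz.
#' @export
svg_dp <- function(c_total, tg_delta, T, f) {
  sq_dp(c_total, tg_delta, T, f) / c_total^2
}

#' RTS Lorentzian input-referred voltage noise spectrum
#'
#' Single-trap random-telegraph noise has a Lorentzian spectrum
#' \deqn{S_{V_G}(f) = \frac{4 g (1-g)^2 \tau_e (q^*/C)^2}
#'                         {1 + (2\pi (1-g) \tau_e f)^2}}
#' with occupancy `g`, emission time `tau_e` and voltage step
#' `q_star / c_total`. The printed capacitance symbol is interpreted as
#' the total gate capacitance `C_G * A` throughout (the convention that
#' makes the formula dimensionally consistent with the maximum-noise
#' estimate of [svg_rts_max()]).
#'
#' @param g Trap occupancy probability in \[0, 1\].
#' @param tau_e Emission time (s).
#' @param q_star Effective trapped charge (C).
#' @param c_total Total gate capacitance (F).
#' @param f Frequency (Hz), strictly positive. Vectorised.
#' @return One-sided PSD in V^2/Hz.
#' @export
svg_rts_lorentzian <- function(g, tau_e, q_star, c_total, f) {
  stop_if_not_scalar(g, "g")
  if (g < 0 || g > 1) stop("`g` must be in [0, 1]", call. = FALSE)
  stop_if_not_scalar(tau_e, "tau_e", positive = TRUE)
  stop_if_not_scalar(q_star, "q_star", positive = TRUE)
  stop_if_not_scalar(c_total, "c_total", positive = TRUE)
  check_freq(f)
  4 * g * (1 - g)^2 * tau_e * (q_star / c_total)^2 /
    (1 + (2 * pi * (1 - g) * tau_e * f)^2)
}

#' Maximum of the RTS voltage noise relative to a 1/f background
#'
#' At occupancy g = 1/2 the RTS Lorentzian, compared against a 1/f
#' background, peaks at its corner frequency `f0`, where its value is
#' exactly \eqn{(1/4\pi)\,(q^*/C)^2/f_0}. The coefficient
#' \eqn{1/4\pi = 0.0796} is conventionally quoted rounded to 0.08.
#'
#' @param q_star Effective trapped charge (C).
#' @param c_total Total gate capacitance (F).
#' @param f0 Lorentzian corner frequency (Hz).
#' @return One-sided PSD value (V^2/Hz) with attributes
#'   `coefficient` (= 1/(4 pi), used in the computation) and
#'   `coefficient_rounded` (= 0.08, the conventional rounding; metadata
#'   only).
#' @export
svg_rts_max <- function(q_star, c_total, f0) {
  stop_if_not_scalar(q_star, "q_star", positive = TRUE)
  stop_if_not_scalar(c_total, "c_total", positive = TRUE)
  stop_if_not_scalar(f0, "f0", positive = TRUE)
  val <- (1 / (4 * pi)) * (q_star / c_total)^2 / f0
  attr(val, "coefficient") <- 1 / (4 * pi)
  attr(val, "coefficient_rounded") <- 0.08
  val
}

#' Ideal ISFET (Nernstian) pH signal
#'
#' Threshold-voltage shift of an ideal ion-sensitive FET for a pH change:
#' \eqn{\delta V_{Th} = \ln(10)\, kT/q \cdot \Delta pH}, about 59 mV per
#' pH unit at room temperature (5.9 mV for 0.1 pH at 298 K). Used as the
#' reference signal in signal-to-noise comparisons.
#'
#' @param delta_ph pH change (dimensionless).
#' @param T Temperature (K).
#' @return Voltage shift (V). Vectorised over `delta_ph`.
#' @export
#' @examples
#' nernst_signal(0.1, 298) * 1e3  # mV
nernst_signal <- function(delta_ph, T = 298) {
  stop_if_not_scalar(T, "T", positive = TRUE)
  log(10) * .kB * T / .qe * delta_ph
}

#' Lorentzian corner frequency of an RTS process
#'
#' \eqn{f_0 = 1/(2\pi \tau_{eff})} with the effective time
#' \eqn{\tau_{eff} = (1-g)\tau_e = \tau_c \tau_e/(\tau_c+\tau_e)}; this is
#' the roll-off frequency of the spectrum in [svg_rts_lorentzian()]. When
#' capture is much faster than emission (high occupancy) it reduces to
#' \eqn{1/(2\pi\tau_c)}.
#'
#' @param tau_c Capture time (s).
#' @param tau_e Emission time (s).
#' @return Corner frequency (Hz).
#' @export
#' @examples
#' corner_frequency(1 / 488, 1 / 488)  # 488 / pi ~ 155 Hz
corner_frequency <- function(tau_c, tau_e) {
  stop_if_not_scalar(tau_c, "tau_c", positive = TRUE)
  stop_if_not_scalar(tau_e, "tau_e", positive = TRUE)
  tau_eff <- tau_c * tau_e / (tau_c + tau_e)
  1 / (2 * pi * tau_eff)
}

check_freq <- function(f) {
  if (!is.numeric(f) || length(f) == 0L || any(!is.finite(f)) ||
      any(f <= 0))
    stop("frequencies must be finite and strictly positive", call. = FALSE)
  invisible(f)
}
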