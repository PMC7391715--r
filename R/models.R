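#' Single-trap kinetic model
#'
#' Describes the voltage-dependent kinetics of one oxide trap near the
#' transistor channel. The trap alternates between empty (state 0) and
#' occupied (state 1); the mean capture time \eqn{\tau_c} (empty-to-occupied)
#' depends exponentially on gate voltage while the mean emission time
#' \eqn{\tau_e} is voltage-independent, the behaviour observed for
#' liquid-gated Si nanowire FETs:
#' \deqn{\tau_c(V_G) = \tau_{c0}\, e^{-q\alpha (V_G - V_0)/kT}, \qquad
#'       \tau_e(V_G) = \tau_{e0}.}
#' The dimensionless coupling \eqn{\alpha} is the ratio of the gate
#' capacitance to the tunnelling capacitance and sets the steepness of the
#' occupancy curve \eqn{g(V_G)}.
#'
#' @param tau_c0 Capture time (s) at the reference voltage `v0`.
#' @param tau_e0 Emission time (s), voltage-independent.
#' @param alpha Dimensionless gate-to-trap coupling, in (0, 1].
#' @param v0 Reference gate voltage (V) where `tau_c = tau_c0`. At this
#'   voltage the occupancy is `tau_e0 / (tau_e0 + tau_c0)`.
#' @param q_star Effective trapped charge (C). Default `0.5 * q`, the
#'   image-charge-corrected value appropriate for a trap in SiO2.
#' @return Object of class `trap_model`.
#' @seealso [device_model()], [trap_times()], [occupancy()]
#' @export
#' @examples
#' trap_model(tau_c0 = 1 / 488, tau_e0 = 1 / 488, alpha = 0.5)
trap_model <- function(tau_c0, tau_e0, alpha = 0.5, v0 = 0,
                       q_star = 0.5 * .qe) {
  stop_if_not_scalar(tau_c0, "tau_c0", positive = TRUE)
  stop_if_not_scalar(tau_e0, "tau_e0", positive = TRUE)
  stop_if_not_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha > 1)
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  stop_if_not_scalar(v0, "v0")
  stop_if_not_scalar(q_star, "q_star", positive = TRUE)
  structure(list(tau_c0 = tau_c0, tau_e0 = tau_e0, alpha = alpha,
                 v0 = v0, q_star = q_star),
            class = "trap_model")
}

#' @export
print.trap_model <- function(x, ...) {
  cat("Single-trap kinetic model\n")
  cat(sprintf("  tau_c0: %.4g s at V0 = %.4g V\n", x$tau_c0, x$v0))
  cat(sprintf("  tau_e0: %.4g s (voltage-independent)\n", x$tau_e0))
  cat(sprintf("  alpha : %.3g    q*: %.4g C\n", x$alpha, x$q_star))
  invisible(x)
}

#' Nanotransistor device model
#'
#' Geometry and small-signal parameters of a (liquid-gated) nanowire FET
#' biosensor. Gate area `A = W * L` and total gate capacitance
#' `C_total = C_G * A` are derived.
#'
#' @param W,L Channel width and length (m).
#' @param C_G Gate capacitance per unit area (F/m^2).
#' @param tg_delta Dielectric loss tangent of the gate insulator
#'   (dimensionless; 3.8e-3 is typical of SiO2).
#' @param g_m Transconductance (S).
#' @param N_ot Areal density of active oxide traps (1/m^2).
#' @param T Temperature (K).
#' @return Object of class `device_model` with derived fields `A` (m^2)
#'   and `C_total` (F).
#' @export
#' @examples
#' # 100 nm x 100 nm liquid-gated Si nanowire FET
#' device_model(W = 100e-9, L = 100e-9, C_G = 7.157e-3,
#'              tg_delta = 3.8e-3, g_m = 1e-6, N_ot = 1e12, T = 300)
device_model <- function(W, L, C_G, tg_delta = 3.8e-3, g_m = 1e-6,
                         N_ot = 1e12, T = 300) {
  for (nm in c("W", "L", "C_G", "tg_delta", "g_m", "N_ot", "T"))
    stop_if_not_scalar(get(nm), nm, positive = TRUE)
  A <- W * L
  structure(list(W = W, L = L, C_G = C_G, tg_delta = tg_delta,
                 g_m = g_m, N_ot = N_ot, T = T,
                 A = A, C_total = C_G * A),
            class = "device_model")
}

#' @export
print.device_model <- function(x, ...) {
  cat("Nanotransistor device model\n")
  cat(sprintf("  W x L : %.4g x %.4g m (A = %.4g m^2)\n", x$W, x$L, x$A))
  cat(sprintf("  C_G   : %.4g F/m^2 (C_total = %.4g F)\n",
              x$C_G, x$C_total))
  cat(sprintf("  tgd   : %.3g   g_m: %.4g S   N_ot: %.4g /m^2   T: %g K\n",
              x$tg_delta, x$g_m, x$N_ot, x$T))
  invisible(x)
}

#' Capture and emission times at a gate voltage
#'
#' Evaluates the trap's mean capture and emission dwell times at gate
#' voltage `v_g`. Emission time is constant; capture time follows the
#' exponential gate-voltage dependence of the trap model (see
#' [trap_model()]).
#'
#' @param trap A [trap_model()].
#' @param device A [device_model()] (supplies the temperature).
#' @param v_g Gate voltage (V).
#' @return Named list with `tau_c` and `tau_e` (s).
#' @export
#' @examples
#' tr <- trap_model(1e-3, 1e-3, alpha = 0.5)
#' dev <- device_model(100e-9, 100e-9, 7.157e-3)
#' trap_times(tr, dev, v_g = 0)        # reference point
#' trap_times(tr, dev, v_g = 0.0598)   # capture accelerated by e^-1.16
trap_times <- function(trap, device, v_g) {
  stopifnot(inherits(trap, "trap_model"), inherits(device, "device_model"))
  stop_if_not_scalar(v_g, "v_g")
  expo <- -.qe * trap$alpha * (v_g - trap$v0) / (.kB * device$T)
  if (abs(expo) > 700)
    stop("capture-time exponent magnitude > 700: check alpha/v_g/T",
         call. = FALSE)
  tau_c <- trap$tau_c0 * exp(expo)
  list(tau_c = tau_c, tau_e = trap$tau_e0)
}

#' Stationary trap occupancy probability (g-factor)
#'
#' The fraction of time the trap is occupied,
#' \eqn{g = \tau_e / (\tau_e + \tau_c)}. With the exponential capture-time
#' model this is a logistic function of gate voltage, nondecreasing in
#' `v_g` for positive coupling.
#'
#' @inheritParams trap_times
#' @return Occupancy probability in (0, 1). Vectorised over `v_g`.
#' @export
#' @examples
#' tr <- trap_model(1 / 488, 1 / 488, alpha = 0.5)
#' dev <- device_model(100e-9, 100e-9, 7.157e-3)
#' occupancy(tr, dev, 0)  # 0.5 at the symmetric point
occupancy <- function(trap, device, v_g) {
  stopifnot(inherits(trap, "trap_model"), inherits(device, "device_model"))
  vapply(v_g, function(v) {
    tt <- trap_times(trap, device, v)
    tt$tau_e / (tt$tau_e + tt$tau_c)
  }, numeric(1))
}

#' Logistic occupancy curve evaluated directly from parameters
#'
#' `g = 1 / (1 + exp(-q alpha (v - v0) / kT))`: the closed form implied by
#' the constant-emission / exponential-capture trap model. Used as the
#' parametric model for [g_curve()] fits and for analytic occupancy
#' slopes.
#'
#' @param v_g Gate voltage(s) (V).
#' @param alpha Coupling (dimensionless).
#' @param v0 Midpoint voltage (V), where g = 1/2.
#' @param T Temperature (K).
#' @return Occupancy values in (0, 1).
#' @export
logistic_g <- function(v_g, alpha, v0, T = 300) {
  1 / (1 + exp(-.qe * alpha * (v_g - v0) / (.kB * T)))
}

#' Analytic occupancy slope dg/dV_G of the logistic model
#'
#' @inheritParams logistic_g
#' @return Slope in 1/V; equals `(q alpha / kT) g (1 - g)`, maximal at
#'   g = 1/2.
#' @export
logistic_gg <- function(v_g, alpha, v0, T = 300) {
  g <- logistic_g(v_g, alpha, v0, T)
  .qe * alpha / (.kB * T) * g * (1 - g)
}
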