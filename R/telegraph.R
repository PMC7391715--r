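#' Simulate a two-state random telegraph signal
#'
#' Event-driven simulation of a continuous-time two-state Markov chain
#' (trap empty = 0, occupied = 1) with capture rate `lambda_rate`
#' (0 to 1) and emission rate `mu_rate` (1 to 0). Dwell times are sampled
#' from exponential distributions and the resulting piecewise-constant
#' state is then resampled onto a uniform grid of step `dt`. Event-driven
#' generation keeps the dwell-time statistics exact; only events shorter
#' than the grid step can be lost in the resampling.
#'
#' @param lambda_rate Capture rate (1/s), transition 0 -> 1.
#' @param mu_rate Emission rate (1/s), transition 1 -> 0.
#' @param duration Trace length (s); must be >= `dt`.
#' @param dt Sampling interval (s). `dt * max(rate) << 1` recommended.
#' @param seed Integer seed; identical seed gives an identical trace.
#' @param initial_state `"stationary"` (default: drawn from the stationary
#'   distribution `lambda/(lambda+mu)`), or 0 or 1.
#' @param v_g Gate voltage metadata (V), stored on the trace.
#' @return An `rts_trace`: list with `dt`, `states` (integer 0/1 on the
#'   grid), `v_g`, `seed`, and the underlying event list `events`
#'   (transition times, s) with `state0` (state before the first event).
#' @export
#' @examples
#' tr <- simulate_rts(488, 488, duration = 1, dt = 1e-4, seed = 1)
#' mean(tr$states)  # close to the stationary occupancy 0.5
simulate_rts <- function(lambda_rate, mu_rate, duration, dt, seed = NULL,
                         initial_state = "stationary", v_g = NA_real_) {
  stop_if_not_scalar(lambda_rate, "lambda_rate", positive = TRUE)
  stop_if_not_scalar(mu_rate, "mu_rate", positive = TRUE)
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  if (duration < dt) stop("`duration` must be >= `dt`", call. = FALSE)

  with_seed(seed, {
    state0 <- if (identical(initial_state, "stationary")) {
      rbinom(1L, 1L, lambda_rate / (lambda_rate + mu_rate))
    } else {
      if (!initial_state %in% c(0, 1))
        stop("`initial_state` must be 0, 1 or \"stationary\"", call. = FALSE)
      as.integer(initial_state)
    }

    ## draw exponential dwells in blocks until the trace is covered
    rate_for <- function(s) if (s == 1L) mu_rate else lambda_rate
    events <- numeric(0)
    t_now <- 0
    s_now <- state0
    ## expected events + slack, drawn in chunks for speed
    repeat {
      n_chunk <- max(64L, ceiling((duration - t_now) *
                                    (lambda_rate + mu_rate)))
      ## alternate states: dwell means alternate between the two rates
      means <- rep(c(1 / rate_for(s_now), 1 / rate_for(1L - s_now)),
                   length.out = n_chunk)
      dw <- rexp(n_chunk) * means
      tt <- t_now + cumsum(dw)
      keep <- tt < duration
      events <- c(events, tt[keep])
      if (!all(keep)) break
      t_now <- tt[n_chunk]
      if (n_chunk %% 2L == 1L) s_now <- 1L - s_now
    }

    n <- floor(duration / dt + 1e-9)
    t_grid <- (seq_len(n) - 1L) * dt
    ## number of transitions at or before each grid time
    k <- findInterval(t_grid, events)
    states <- as.integer((state0 + k) %% 2L)

    structure(list(dt = dt, states = states, v_g = v_g,
                   seed = if (is.null(seed)) NA_integer_ else seed,
                   events = events, state0 = state0),
              class = "rts_trace")
  })
}

#' @export
print.rts_trace <- function(x, ...) {
  cat(sprintf(
    "RTS trace: %d samples at dt = %.3g s (%.4g s), %d events, g-hat = %.3f\n",
    length(x$states), x$dt, length(x$states) * x$dt,
    length(x$events), mean(x$states)))
  invisible(x)
}

#' Synthesize 1/f (flicker) voltage noise
#'
#' Frequency-domain construction of a Gaussian time series whose one-sided
#' power spectral density is `level_at_1hz / f` between `f_low_cutoff` and
#' the Nyquist frequency: Fourier amplitudes proportional to
#' \eqn{f^{-1/2}}, independent uniform phases, conjugate symmetry. The
#' construction gives exact spectral control in O(N log N). Used for the
#' dielectric-polarization noise background, whose spectrum is
#' `2 k T tgd / (pi C_total f)` (see [svg_dp()]).
#'
#' @param level_at_1hz One-sided PSD at 1 Hz (V^2/Hz); `0` returns zeros.
#' @param duration Trace length (s).
#' @param dt Sampling interval (s).
#' @param seed Integer seed.
#' @param f_low_cutoff Spectrum is zeroed below this frequency (Hz);
#'   default `1/duration` (one full period per trace).
#' @return Numeric vector (V), zero mean, length `floor(duration/dt)`.
#'   Total variance is approximately `level * log(f_high/f_low)`.
#' @export
synthesize_flicker <- function(level_at_1hz, duration, dt, seed = NULL,
                               f_low_cutoff = NULL) {
  stop_if_not_scalar(level_at_1hz, "level_at_1hz", nonneg = TRUE)
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  n <- floor(duration / dt + 1e-9)
  if (n < 2L) stop("trace too short", call. = FALSE)
  if (level_at_1hz == 0) return(numeric(n))
  if (is.null(f_low_cutoff)) f_low_cutoff <- 1 / duration
  stop_if_not_scalar(f_low_cutoff, "f_low_cutoff", positive = TRUE)

  with_seed(seed, {
    f <- seq_len(floor(n / 2)) / (n * dt)     # positive-frequency bins
    S <- ifelse(f >= f_low_cutoff, level_at_1hz / f, 0)
    ## one-sided PSD S -> |X_k|^2 = S * n / (2 dt)
    amp <- sqrt(S * n / (2 * dt))
    phase <- runif(length(f), 0, 2 * pi)
    X <- complex(modulus = amp, argument = phase)
    if (n %% 2L == 0L) X[length(X)] <- complex(real = amp[length(X)],
                                               imaginary = 0)
    spec <- complex(length.out = n)
    spec[2:(length(f) + 1L)] <- X
    spec[n:(n - length(f) + if (n %% 2L == 0L) 2L else 1L)] <-
      Conj(X[seq_len(length(f) - (n %% 2L == 0L))])
    x <- Re(fft(spec, inverse = TRUE)) / n
    x - mean(x)
  })
}

#' Compose a synthetic drain-current trace
#'
#' Builds the full measurement model of a single-trap device: a two-level
#' RTS of amplitude \eqn{\Delta I = g_m q^* / (C_G A)}, optionally a 1/f
#' dielectric-polarization background (gate-referred, scaled by the
#' transconductance), and white Gaussian measurement noise:
#' \deqn{I(t) = I_0 - \Delta I\, X_t + g_m\, v_{DP}(t) + w(t)}
#' with \eqn{X_t} the trap state. The occupied trap lowers the current by
#' default (depletion-mode convention); set `occupied_level = "high"` to
#' flip the sign.
#'
#' @param device A [device_model()].
#' @param trap A [trap_model()].
#' @param v_g Gate voltage (V); sets the capture/emission rates via
#'   [trap_times()].
#' @param duration,dt Trace length and sampling interval (s).
#' @param seed Integer seed (drives RTS, DP and white noise).
#' @param include_dp Add dielectric-polarization 1/f noise at the level
#'   implied by the device (`tg_delta`, `C_total`, `T`)?
#' @param white_sigma Standard deviation of white measurement noise (A).
#' @param baseline Baseline drain current \eqn{I_0} (A); default 0 so the
#'   trace carries fluctuations only.
#' @param occupied_level `"low"` (default) or `"high"`: current level of
#'   the occupied state relative to the empty state.
#' @return A `current_trace`: list with `dt`, `current` (A), `v_g`,
#'   `seed`, `delta_i`, component flags, and the generating `rts`
#'   ([simulate_rts()] output) as ground truth.
#' @export
#' @examples
#' dev <- device_model(100e-9, 100e-9, 7.157e-3)
#' tr  <- trap_model(1 / 488, 1 / 488, alpha = 0.5)
#' ct  <- compose_trace(dev, tr, v_g = 0, duration = 0.5, dt = 1e-4,
#'                      seed = 1, white_sigma = 2.8e-10)
compose_trace <- function(device, trap, v_g, duration, dt, seed = NULL,
                          include_dp = TRUE, white_sigma = 0,
                          baseline = 0, occupied_level = c("low", "high")) {
  stopifnot(inherits(device, "device_model"), inherits(trap, "trap_model"))
  occupied_level <- match.arg(occupied_level)
  stop_if_not_scalar(white_sigma, "white_sigma", nonneg = TRUE)

  tt <- trap_times(trap, device, v_g)
  delta_i <- device$g_m * trap$q_star / device$C_total
  sgn <- if (occupied_level == "low") -1 else 1

  with_seed(seed, {
    rts <- simulate_rts(1 / tt$tau_c, 1 / tt$tau_e, duration, dt,
                        seed = NULL, v_g = v_g)
    current <- baseline + sgn * delta_i * rts$states
    if (include_dp) {
      lvl <- svg_dp(device$C_total, device$tg_delta, device$T, 1)
      current <- current + device$g_m *
        synthesize_flicker(lvl, duration, dt, seed = NULL)
    }
    if (white_sigma > 0)
      current <- current + rnorm(length(current), 0, white_sigma)

    structure(list(dt = dt, current = current, v_g = v_g,
                   seed = if (is.null(seed)) NA_integer_ else seed,
                   delta_i = delta_i, baseline = baseline,
                   occupied_level = occupied_level,
                   components = c(rts = TRUE, dp = include_dp,
                                  white = white_sigma > 0),
                   rts = rts),
              class = "current_trace")
  })
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "Current trace: %d samples at dt = %.3g s, delta_I = %.3g A [%s]\n",
    length(x$current), x$dt, x$delta_i,
    paste(names(x$components)[x$components], collapse = "+")))
  invisible(x)
}
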