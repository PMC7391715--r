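#' Transition probability matrix of the two-state trap chain
#'
#' Kolmogorov forward solution for a continuous-time two-state chain with
#' capture rate `lambda_rate` (0 to 1) and emission rate `mu_rate`
#' (1 to 0):
#' \deqn{P(t) = \frac{1}{\lambda+\mu}\begin{pmatrix}\mu & \lambda\\
#'   \mu & \lambda\end{pmatrix} - \frac{e^{-(\lambda+\mu)t}}{\lambda+\mu}
#'   \begin{pmatrix}-\lambda & \lambda\\ \mu & -\mu\end{pmatrix}.}
#'
#' @param lambda_rate,mu_rate Rates (1/s), > 0.
#' @param t Time (s), >= 0.
#' @return 2x2 matrix, `P[i, j] = P(X_t = j-1 | X_0 = i-1)`; rows sum
#'   to 1.
#' @export
#' @examples
#' transition_matrix(1, 1, 0)            # identity
#' transition_matrix(1, 1, log(2) / 2)   # P[1,1] = 0.75
transition_matrix <- function(lambda_rate, mu_rate, t) {
  stop_if_not_scalar(lambda_rate, "lambda_rate", positive = TRUE)
  stop_if_not_scalar(mu_rate, "mu_rate", positive = TRUE)
  stop_if_not_scalar(t, "t", nonneg = TRUE)
  r <- lambda_rate + mu_rate
  stat <- matrix(c(mu_rate, lambda_rate, mu_rate, lambda_rate),
                 2, 2, byrow = TRUE) / r
  trans <- matrix(c(-lambda_rate, lambda_rate, mu_rate, -mu_rate),
                  2, 2, byrow = TRUE) / r
  stat - exp(-r * t) * trans
}

#' Autocorrelation of the windowed occupancy
#'
#' Autocorrelation \eqn{C(s) = E[g^\Theta(t)\, g^\Theta(t+s)]} of the
#' sliding-window occupancy of a stationary two-state chain, by numeric
#' double integration of
#' \deqn{C(s) = \frac{1}{\Theta^2}\int_0^\Theta\!\!\int_s^{s+\Theta}
#'   P(X_{\max(u,v)}=1 \mid X_{\min(u,v)}=1)\,
#'   P(X_{\min(u,v)}=1)\, du\, dv}
#' with the conditional probability from [transition_matrix()] and the
#' stationary marginal \eqn{\lambda/(\lambda+\mu)}. Valid for general
#' asymmetric rates. The time-ordering max/min reduces the integrand to a
#' function of the lag \eqn{w = |u - v|}; integrating out the overlap
#' leaves the one-dimensional form
#' \eqn{C(s) = (g_{stat}/\Theta^2)\int_{s-\Theta}^{s+\Theta}
#' (\Theta - |w - s|)\, p_{11}(|w|)\, dw,}
#' which is integrated piecewise between the kinks at \eqn{w = 0} and
#' \eqn{w = s} by adaptive quadrature.
#'
#' @inheritParams transition_matrix
#' @param theta Window duration (s), > 0.
#' @param s Lag (s), >= 0. Vectorised.
#' @param rel_tol Quadrature relative tolerance.
#' @return `C(s)`; decays to `g_stat^2` for large lags. Variance of
#'   `g^Theta` is `autocorr_g(..., s = 0) - g_stat^2`.
#' @export
autocorr_g <- function(lambda_rate, mu_rate, theta, s, rel_tol = 1e-8) {
  stop_if_not_scalar(lambda_rate, "lambda_rate", positive = TRUE)
  stop_if_not_scalar(mu_rate, "mu_rate", positive = TRUE)
  stop_if_not_scalar(theta, "theta", positive = TRUE)
  r <- lambda_rate + mu_rate
  g_stat <- lambda_rate / r
  ## P(X_|u-v| = 1 | X_0 = 1): entry [2,2] of the transition matrix
  p11 <- function(tau) g_stat + (1 - g_stat) * exp(-r * tau)
  vapply(s, function(si) {
    stop_if_not_scalar(si, "s", nonneg = TRUE)
    fw <- function(w) (theta - abs(w - si)) * p11(abs(w))
    ## piecewise-smooth between the kinks of the weight (w = s) and of
    ## p11(|w|) (w = 0, present only when the windows overlap)
    brk <- sort(unique(pmax(pmin(c(0, si), si + theta), si - theta)))
    pts <- unique(c(si - theta, brk, si + theta))
    val <- sum(vapply(seq_len(length(pts) - 1L), function(i) {
      tryCatch(
        integrate(fw, pts[i], pts[i + 1L], rel.tol = rel_tol,
                  subdivisions = 500L)$value,
        error = function(e) stop("autocorrelation quadrature failed (",
                                 conditionMessage(e), ")", call. = FALSE))
    }, numeric(1)))
    g_stat * val / theta^2
  }, numeric(1))
}

#' Analytic PSD of the windowed occupancy (symmetric RTS)
#'
#' Closed-form spectral density of the sliding-window occupancy
#' \eqn{g^\Theta} for a symmetric chain (\eqn{\lambda = \mu = \gamma},
#' g = 1/2):
#' \deqn{S_g^{(\Theta)}(\omega) = \frac{2\gamma\,(1-\cos\Theta\omega)}
#'   {\Theta^2 \omega^2 (4\gamma^2 + \omega^2)}.}
#' This is the two-sided density in angular frequency (variance =
#' \eqn{(2\pi)^{-1}\int S\,d\omega}); a one-sided estimate on a frequency
#' grid in Hz corresponds to `2 * sg_theta(2*pi*f, ...)` (see
#' [sg_theta_f()]). At \eqn{\omega \to 0} the density tends to
#' \eqn{1/(4\gamma)}; it has exact nulls at \eqn{\Theta\omega = 2\pi k}.
#'
#' Because estimated spectra average over many Fourier bins, pointwise
#' comparison at the nulls is meaningless; `band_averaged = TRUE`
#' replaces \eqn{(1-\cos\Theta\omega)} by its mean value 1, valid for
#' \eqn{\omega \gg 1/\Theta}. For bands extending below \eqn{1/\Theta}
#' use [sg_theta_band()].
#'
#' @param omega Angular frequency (rad/s), >= 0 (the 0 limit is handled
#'   analytically). Vectorised.
#' @param gamma Symmetric switching rate (1/s), > 0.
#' @param theta Window duration (s), > 0.
#' @param band_averaged Replace the cosine oscillation by its mean?
#' @return Density values (1/Hz scale).
#' @export
#' @examples
#' sg_theta(0, 488, 1)        # 1/(4 * 488)
#' sg_theta(pi, 488, 1)       # 2*488*2 / (pi^2 (4*488^2 + pi^2))
sg_theta <- function(omega, gamma, theta, band_averaged = FALSE) {
  stop_if_not_scalar(gamma, "gamma", positive = TRUE)
  stop_if_not_scalar(theta, "theta", positive = TRUE)
  if (any(omega < 0)) stop("`omega` must be >= 0", call. = FALSE)
  num <- if (band_averaged) 1 else 1 - cos(theta * omega)
  out <- 2 * gamma * num / (theta^2 * omega^2 * (4 * gamma^2 + omega^2))
  if (!band_averaged) {
    ## Taylor limit: (1 - cos x) ~ x^2/2 -> S -> gamma/(4 gamma^2 + omega^2)
    small <- theta * omega < 1e-6
    out[small] <- gamma / (4 * gamma^2 + omega[small]^2)
  }
  out
}

#' One-sided occupancy-noise density on a frequency grid in Hz
#'
#' Convenience wrapper: `2 * sg_theta(2*pi*f, gamma, theta, ...)`, the
#' convention that matches a one-sided PSD estimated from a sliding-g
#' time trace ([estimate_psd()] of [sliding_g()] output with stride
#' `dt`).
#'
#' @param f Frequency (Hz), >= 0. Vectorised.
#' @inheritParams sg_theta
#' @return One-sided density (1/Hz).
#' @export
sg_theta_f <- function(f, gamma, theta, band_averaged = FALSE) {
  2 * sg_theta(2 * pi * f, gamma, theta, band_averaged = band_averaged)
}

#' Band-averaged one-sided occupancy-noise density
#'
#' Mean of the exact one-sided density [sg_theta_f()] over a frequency
#' band, by numeric integration. Correct at all frequencies, including
#' bands below \eqn{1/\Theta} where the replace-cosine-by-mean shortcut
#' fails.
#'
#' @param f_lo,f_hi Band edges (Hz), `0 <= f_lo < f_hi`. Vectorised
#'   (pairwise).
#' @inheritParams sg_theta
#' @return Band-mean one-sided density (1/Hz), one value per band.
#' @export
sg_theta_band <- function(f_lo, f_hi, gamma, theta) {
  stopifnot(length(f_lo) == length(f_hi), all(f_hi > f_lo),
            all(f_lo >= 0))
  mapply(function(a, b) {
    integrate(function(ff) sg_theta_f(ff, gamma, theta), a, b,
              rel.tol = 1e-8, subdivisions = 400L)$value / (b - a)
  }, f_lo, f_hi)
}

#' Numeric (simulation) oracle for the occupancy-noise spectrum
#'
#' Brute-force counterpart of [sg_theta()]: simulates `n_reps`
#' independent symmetric RTS traces, computes the sliding-window
#' occupancy with stride `dt`, and averages their Welch PSD estimates.
#' Used to validate the closed form and its spectral convention.
#'
#' @param gamma Symmetric switching rate (1/s).
#' @param theta Window duration (s).
#' @param duration Trace duration (s), much larger than `theta`.
#' @param dt Sampling interval (s).
#' @param n_reps Number of independent traces to average.
#' @param seed Integer seed.
#' @param segment_seconds Welch segment duration (s); default
#'   `duration / 5`.
#' @return A `psd_result` (ensemble-averaged, one-sided, 1/Hz).
#' @export
sg_numeric_oracle <- function(gamma, theta, duration, dt, n_reps = 10L,
                              seed = NULL, segment_seconds = NULL) {
  stop_if_not_scalar(gamma, "gamma", positive = TRUE)
  stop_if_not_scalar(theta, "theta", positive = TRUE)
  if (duration <= 2 * theta)
    stop("`duration` must exceed 2 * theta", call. = FALSE)
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  if (is.null(segment_seconds)) segment_seconds <- duration / 5

  with_seed(seed, {
    acc <- NULL
    for (r in seq_len(n_reps)) {
      tr <- simulate_rts(gamma, gamma, duration, dt)
      gt <- sliding_g(tr, theta)
      p <- estimate_psd(gt, segment_seconds)
      acc <- if (is.null(acc)) p else {
        p$S <- p$S + acc$S
        p
      }
    }
    acc$S <- acc$S / n_reps
    acc$n_segments <- acc$n_segments * n_reps
    acc
  })
}
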