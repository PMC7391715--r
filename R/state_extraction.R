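#' Fit a two-state Gaussian hidden Markov model to a current trace
#'
#' Recovers the two current levels and the trap-state sequence from a
#' noisy RTS trace. A two-state HMM with Gaussian emissions (shared
#' standard deviation) is fitted by expectation-maximization
#' (Baum-Welch), initialized from a two-cluster split of the amplitude
#' histogram, and the state sequence is decoded with the most-probable
#' path (Viterbi) algorithm. Path decoding (rather than per-sample
#' posterior thresholding) avoids spurious single-sample switches that
#' would fragment the dwell-time statistics.
#'
#' State label 1 is assigned to the trap-occupied level: the
#' lower-current level under the default depletion-mode convention
#' (`occupied_level = "low"`).
#'
#' @param trace A `current_trace` (see [compose_trace()]), or a numeric
#'   vector of currents with `dt` supplied.
#' @param dt Sampling interval (s) when `trace` is a bare numeric vector.
#' @param seed Integer seed (used only for the k-means initialization).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   gain per iteration falls below `tol` or after `max_iter` iterations
#'   (the result is then flagged `converged = FALSE`).
#' @param occupied_level `"low"` (default) or `"high"`: which current
#'   level corresponds to the occupied trap.
#' @return An `hmm_result`: list with `level_low`, `level_high` (A),
#'   `emission_sigma` (A), `trans_prob` (2x2 per-step matrix, rows =
#'   from-state 0/1), `rates` (`lambda`, `mu`, 1/s, from the decoded
#'   dwells), `states` ([simulate_rts()]-style `rts_trace` of decoded
#'   states), `loglik`, `n_transitions`, `converged`.
#' @export
fit_two_state_hmm <- function(trace, dt = NULL, seed = NULL,
                              max_iter = 100L, tol = 1e-6,
                              occupied_level = c("low", "high")) {
  occupied_level <- match.arg(occupied_level)
  if (inherits(trace, "current_trace")) {
    x <- trace$current
    dt <- trace$dt
  } else {
    x <- as.numeric(trace)
    if (is.null(dt)) stop("`dt` required for a bare numeric trace",
                          call. = FALSE)
  }
  if (length(x) < 1000L)
    stop("trace too short for HMM fitting (need >= 1000 samples)",
         call. = FALSE)
  if (any(!is.finite(x))) stop("trace contains non-finite values",
                               call. = FALSE)
  if (sd(x) == 0)
    stop("no two-level structure: trace has zero variance", call. = FALSE)

  ## --- initialization: two-cluster split of the amplitude histogram
  init <- with_seed(seed, {
    ctr <- as.numeric(quantile(x, c(0.25, 0.75)))
    if (ctr[1] == ctr[2]) ctr <- ctr + c(-1, 1) * sd(x) / 2
    km <- suppressWarnings(kmeans(x, centers = matrix(ctr, ncol = 1)))
    km
  })
  mu_init <- sort(as.numeric(init$centers))
  assign0 <- as.integer(x > mean(mu_init))          # 1 = upper cluster
  p_switch <- mean(abs(diff(assign0)) > 0)
  p_switch <- min(max(p_switch, 1e-6), 0.4)
  means <- mu_init                                  # [low, high]
  sigma <- sqrt(sum(init$withinss) / length(x))
  if (sigma <= 0) sigma <- sd(x) / 10
  P <- matrix(c(1 - p_switch, p_switch, p_switch, 1 - p_switch), 2, 2,
              byrow = TRUE)
  pi0 <- c(0.5, 0.5)

  ## --- Baum-Welch
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- hmm_estep_cpp(x, means, sigma, P, pi0)
    means_new <- e$gamma_x / e$gamma_sum
    var_new <- sum(e$gamma_xx - 2 * means_new * e$gamma_x +
                     means_new^2 * e$gamma_sum) / length(x)
    ## floor relative to the data scale (currents are ~nA: an absolute
    ## floor would dwarf the true variance)
    sigma <- sqrt(max(var_new, 1e-12 * var(x)))
    rowsum_tr <- rowSums(e$trans)
    P <- e$trans / rowsum_tr
    P[] <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    P <- P / rowSums(P)
    pi0 <- pmin(pmax(e$gamma1, 1e-12), 1)
    pi0 <- pi0 / sum(pi0)
    means <- means_new
    if (is.finite(ll_old) && abs(e$loglik - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- e$loglik
  }
  ## keep state ordering [low, high]
  if (means[1] > means[2]) {
    means <- rev(means)
    P <- P[2:1, 2:1]
    pi0 <- rev(pi0)
  }

  ## a two-component fit of unimodal noise settles at a separation of
  ## about one sigma; genuine RTS is fitted at >= 4 sigma for any trace
  ## the levels can be read from at all
  if ((means[2] - means[1]) < 2 * sigma)
    stop("no two-level structure: fitted level separation (",
         format(means[2] - means[1], digits = 3), " A) is below 2 x ",
         "emission sigma (", format(sigma, digits = 3), " A)",
         call. = FALSE)

  path <- hmm_viterbi_cpp(x, means, sigma, P, pi0)  # 0 = low, 1 = high
  ## map to trap occupancy: occupied (1) = low level by default
  states <- if (occupied_level == "low") 1L - path else path
  n_trans <- sum(abs(diff(states)) > 0)

  st_trace <- structure(list(dt = dt, states = as.integer(states),
                             v_g = if (inherits(trace, "current_trace"))
                               trace$v_g else NA_real_,
                             seed = NA_integer_,
                             events = dt * which(abs(diff(states)) > 0),
                             state0 = states[1]),
                        class = "rts_trace")

  rates <- if (n_trans >= 2L) {
    dw <- dwell_times(st_trace)
    list(lambda = 1 / dw$tau_c_hat, mu = 1 / dw$tau_e_hat)
  } else list(lambda = NA_real_, mu = NA_real_)

  ## per-step transition probabilities in occupancy labelling
  P_occ <- if (occupied_level == "low") P[2:1, 2:1] else P

  structure(list(level_low = means[1], level_high = means[2],
                 emission_sigma = sigma, trans_prob = P_occ,
                 rates = rates, states = st_trace,
                 loglik = e$loglik, n_transitions = n_trans,
                 converged = converged, occupied_level = occupied_level),
            class = "hmm_result")
}

#' @export
print.hmm_result <- function(x, ...) {
  cat("Two-state Gaussian HMM fit\n")
  cat(sprintf("  levels: %.4g / %.4g A, sigma = %.3g A\n",
              x$level_low, x$level_high, x$emission_sigma))
  cat(sprintf("  transitions: %d, rates: lambda = %.4g, mu = %.4g 1/s\n",
              x$n_transitions, x$rates$lambda, x$rates$mu))
  if (!x$converged) cat("  [EM did not converge]\n")
  invisible(x)
}

#' Dwell times and mean capture/emission time constants
#'
#' Converts a decoded (or simulated) state sequence into dwell durations
#' per state and their arithmetic means. Dwells in state 0 end with a
#' capture (their mean estimates \eqn{\tau_c}); dwells in state 1 end
#' with an emission (mean estimates \eqn{\tau_e}). The first and last
#' runs are censored (their true start/end is unobserved) and are
#' discarded, as in single-channel kinetics practice.
#'
#' @param states An `rts_trace` (from [simulate_rts()] or an HMM fit).
#' @return List with `capture_dwells`, `emission_dwells` (s),
#'   `tau_c_hat`, `tau_e_hat` (s), `n_transitions`, and
#'   `low_statistics` (TRUE when `n_transitions <= 200`, too few for a
#'   reliable occupancy estimate; also raised as a warning).
#' @export
#' @examples
#' tr <- simulate_rts(488, 488, 2, 1e-4, seed = 1)
#' dw <- dwell_times(tr)
#' c(dw$tau_c_hat, dw$tau_e_hat)  # both near 1/488 s
dwell_times <- function(states) {
  stopifnot(inherits(states, "rts_trace"))
  s <- states$states
  r <- rle(s)
  if (length(r$lengths) < 3L)
    stop("fewer than 2 transitions: dwell times undefined", call. = FALSE)
  ## drop censored first and last runs
  vals <- r$values[-c(1L, length(r$values))]
  lens <- r$lengths[-c(1L, length(r$lengths))]
  dur <- lens * states$dt
  capture_dwells <- dur[vals == 0L]   # time spent empty before capture
  emission_dwells <- dur[vals == 1L]  # time spent occupied before emission
  n_trans <- length(r$lengths) - 1L
  low_stats <- n_trans <= 200L
  if (low_stats)
    warning("only ", n_trans,
            " transitions (<= 200): occupancy statistics unreliable",
            call. = FALSE)
  list(capture_dwells = capture_dwells,
       emission_dwells = emission_dwells,
       tau_c_hat = mean(capture_dwells),
       tau_e_hat = mean(emission_dwells),
       n_transitions = n_trans,
       low_statistics = low_stats)
}

#' Sliding-window trap occupancy g^Theta(t)
#'
#' Converts a binary trap-state sequence into a continuous occupancy
#' estimate: the fraction of time the trap is occupied within a window of
#' duration `theta` slid along the trace,
#' \eqn{g^\Theta(t) = \Theta^{-1}\int_t^{t+\Theta} 1\{X_s = 1\}\,ds}.
#' Larger windows average over more transition events and therefore give
#' a less noisy occupancy estimate.
#'
#' @param states An `rts_trace`.
#' @param theta Window duration (s); must not exceed the trace duration.
#' @param stride Window step (s); default `dt` (continuous slide, the
#'   convention required when the output feeds a PSD estimate; a coarser
#'   stride subsamples the g trace and aliases its spectrum).
#' @return A `g_trace`: list with `theta`, `stride`, `dt` (= stride),
#'   `t_start` (window start times, s) and `g` values in \[0, 1\]; length
#'   `floor((duration - theta)/stride) + 1`.
#' @export
sliding_g <- function(states, theta, stride = NULL) {
  stopifnot(inherits(states, "rts_trace"))
  stop_if_not_scalar(theta, "theta", positive = TRUE)
  dt <- states$dt
  n <- length(states$states)
  if (is.null(stride)) stride <- dt
  stop_if_not_scalar(stride, "stride", positive = TRUE)

  w <- round(theta / dt)
  if (abs(w * dt - theta) > 1e-9 * theta)
    warning("theta rounded to ", w, " samples (", w * dt, " s)",
            call. = FALSE)
  k <- round(stride / dt)
  if (abs(k * dt - stride) > 1e-9 * stride)
    warning("stride rounded to ", k, " samples (", k * dt, " s)",
            call. = FALSE)
  if (w < 1L || k < 1L) stop("theta and stride must be >= dt", call. = FALSE)
  if (w > n) stop("theta exceeds the trace duration", call. = FALSE)

  cs <- c(0, cumsum(states$states))
  starts <- seq.int(1L, n - w + 1L, by = k)
  g <- (cs[starts + w] - cs[starts]) / w
  structure(list(theta = w * dt, stride = k * dt, dt = k * dt,
                 t_start = (starts - 1L) * dt, g = g),
            class = "g_trace")
}

#' @export
print.g_trace <- function(x, ...) {
  cat(sprintf(
    "Occupancy trace: %d windows of theta = %.4g s (stride %.4g s), mean g = %.3f\n",
    length(x$g), x$theta, x$stride, mean(x$g)))
  invisible(x)
}

#' Occupancy versus gate voltage with logistic fit
#'
#' Estimates the trap occupancy at each gate voltage by time-averaging
#' the state sequence, then fits the logistic model
#' `g = 1/(1 + exp(-q alpha (V - v0)/kT))` (the closed form implied by a
#' constant emission time and exponentially voltage-dependent capture
#' time) by least squares. The occupancy slope \eqn{g_g = \partial g/
#' \partial V_G} -- the sensitivity of an occupancy-based sensor -- is
#' returned as the analytic derivative of the fit (default) or by central
#' finite differences on the raw estimates.
#'
#' @param traces List of `list(v_g =, trace =)` pairs (trace: `rts_trace`),
#'   covering at least 4 distinct voltages spanning the transition.
#' @param T Temperature (K) for the logistic model.
#' @param derivative `"analytic"` (default) or `"finite_diff"`.
#' @return A `g_curve` object: list with `v_g`, `g_hat`, fitted `alpha`,
#'   `v0`, `g_fit` (fitted values), `g_g` (slope on the voltage grid,
#'   1/V) and `derivative`.
#' @export
g_curve <- function(traces, T = 300,
                    derivative = c("analytic", "finite_diff")) {
  derivative <- match.arg(derivative)
  v_g <- vapply(traces, function(p) p$v_g, numeric(1))
  if (length(unique(v_g)) < 4L)
    stop("need >= 4 distinct gate voltages", call. = FALSE)
  g_hat <- vapply(traces, function(p) mean(p$trace$states), numeric(1))
  if (diff(range(g_hat)) < 1e-12)
    stop("flat occupancy curve: no transition in the voltage range",
         call. = FALSE)
  ord <- order(v_g)
  v_g <- v_g[ord]; g_hat <- g_hat[ord]
  fit <- fit_logistic_g(v_g, g_hat, T)
  g_fit <- logistic_g(v_g, fit$alpha, fit$v0, T)
  g_g <- if (derivative == "analytic") {
    logistic_gg(v_g, fit$alpha, fit$v0, T)
  } else {
    ## central differences on the raw estimates, one-sided at the ends
    n <- length(v_g)
    c((g_hat[2] - g_hat[1]) / (v_g[2] - v_g[1]),
      (g_hat[-(1:2)] - g_hat[1:(n - 2)]) / (v_g[-(1:2)] - v_g[1:(n - 2)]),
      (g_hat[n] - g_hat[n - 1]) / (v_g[n] - v_g[n - 1]))
  }
  structure(list(v_g = v_g, g_hat = g_hat, alpha = fit$alpha,
                 v0 = fit$v0, T = T, g_fit = g_fit, g_g = g_g,
                 derivative = derivative),
            class = "g_curve")
}

## Least-squares logistic fit of g(V_G); alpha parameterised in logs so
## the optimizer cannot leave the positive domain.
fit_logistic_g <- function(v_g, g_hat, T = 300) {
  beta0 <- .qe / (.kB * T)
  ## starting values from the logit-linear regression on interior points
  ok <- g_hat > 1e-4 & g_hat < 1 - 1e-4
  if (sum(ok) >= 2) {
    lf <- stats::lm(stats::qlogis(g_hat[ok]) ~ v_g[ok])
    a0 <- max(abs(coef(lf)[2]) / beta0, 1e-3)
    v00 <- -coef(lf)[1] / coef(lf)[2]
  } else {
    a0 <- 0.5
    v00 <- v_g[which.min(abs(g_hat - 0.5))]
  }
  df <- data.frame(v = v_g, g = g_hat)
  fit <- minpack.lm::nlsLM(
    g ~ 1 / (1 + exp(-beta0 * exp(la) * (v - v0))),
    data = df, start = list(la = log(unname(a0)), v0 = unname(v00)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  list(alpha = exp(coef(fit)[["la"]]), v0 = coef(fit)[["v0"]])
}

#' @export
print.g_curve <- function(x, ...) {
  cat("Occupancy curve g(V_G), logistic fit\n")
  cat(sprintf("  alpha = %.4g, v0 = %.4g V, max slope = %.4g 1/V\n",
              x$alpha, x$v0, max(x$g_g)))
  invisible(x)
}
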