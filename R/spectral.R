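#' Welch-averaged one-sided power spectral density
#'
#' Averaged-periodogram PSD estimate: the trace is split into
#' mean-detrended segments of `segment_seconds` with fractional overlap
#' `overlap`, each tapered with a Hann window, and the one-sided
#' periodograms are averaged. Normalization is such that
#' \eqn{\int S\,df} equals the sample variance (Parseval) for broadband
#' inputs.
#'
#' @param trace A `current_trace`, `rts_trace`, `g_trace`, or numeric
#'   vector (then supply `dt`).
#' @param segment_seconds Segment duration (s); the trace must contain at
#'   least two segments' worth of samples.
#' @param overlap Fractional segment overlap in \[0, 1); default 0.5.
#' @param dt Sampling interval (s) for bare numeric input.
#' @return A `psd_result`: list with `f` (Hz, excluding DC), `S` (one-sided
#'   density, input-units^2/Hz), `df`, `n_segments`, `segment_seconds`.
#' @export
#' @examples
#' x <- rnorm(1e4)
#' p <- estimate_psd(x, segment_seconds = 1, dt = 1e-3)
#' sum(p$S) * p$df  # ~ var(x)
estimate_psd <- function(trace, segment_seconds, overlap = 0.5, dt = NULL) {
  if (inherits(trace, "current_trace")) {
    x <- trace$current; dt <- trace$dt
  } else if (inherits(trace, "rts_trace")) {
    x <- as.numeric(trace$states); dt <- trace$dt
  } else if (inherits(trace, "g_trace")) {
    x <- trace$g; dt <- trace$dt
  } else {
    x <- as.numeric(trace)
    if (is.null(dt)) stop("`dt` required for a bare numeric trace",
                          call. = FALSE)
  }
  stop_if_not_scalar(segment_seconds, "segment_seconds", positive = TRUE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)",
                                        call. = FALSE)
  nseg <- floor(segment_seconds / dt)
  n <- length(x)
  if (n < 2 * nseg)
    stop("trace shorter than two segments: reduce `segment_seconds`",
         call. = FALSE)
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq.int(1L, n - nseg + 1L, by = step)

  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  wnorm <- sum(w^2)
  nf <- floor(nseg / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    acc <- acc + (Mod(X[2:(nf + 1L)])^2)
  }
  S <- 2 * dt * acc / (wnorm * length(starts))
  if (nseg %% 2L == 0L) S[nf] <- S[nf] / 2   # Nyquist bin is not doubled
  f <- seq_len(nf) / (nseg * dt)
  structure(list(f = f, S = S, df = 1 / (nseg * dt),
                 n_segments = length(starts),
                 segment_seconds = nseg * dt),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "PSD estimate: %d bins, %.4g-%.4g Hz, %d averaged segments of %.4g s\n",
    length(x$f), min(x$f), max(x$f), x$n_segments, x$segment_seconds))
  invisible(x)
}

#' Average a PSD into logarithmically spaced frequency bands
#'
#' Rebins an estimated PSD onto log-spaced bands (geometric mean
#' frequency, arithmetic mean density). Used before 1/f-containing fits,
#' which are otherwise dominated by the dense high-frequency bins, and
#' for band-averaged comparisons against closed-form spectra.
#'
#' @param psd A `psd_result`.
#' @param bins_per_decade Number of bands per frequency decade.
#' @param f_min,f_max Optional band limits (Hz).
#' @return A `psd_result` with added `f_lo`/`f_hi` band edges and
#'   `n_in_band` counts; empty bands are dropped.
#' @export
log_bin_psd <- function(psd, bins_per_decade = 10, f_min = NULL,
                        f_max = NULL) {
  stopifnot(inherits(psd, "psd_result"))
  if (is.null(f_min)) f_min <- min(psd$f)
  if (is.null(f_max)) f_max <- max(psd$f)
  n_edge <- max(2L, ceiling(log10(f_max / f_min) * bins_per_decade) + 1L)
  edges <- 10^seq(log10(f_min), log10(f_max), length.out = n_edge)
  idx <- findInterval(psd$f, edges, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx < length(edges)
  Sm <- tapply(psd$S[ok], idx[ok], mean)
  fm <- tapply(psd$f[ok], idx[ok], function(z) exp(mean(log(z))))
  nb <- tapply(psd$S[ok], idx[ok], length)
  b <- as.integer(names(Sm))
  structure(list(f = as.numeric(fm), S = as.numeric(Sm),
                 f_lo = edges[b], f_hi = edges[b + 1L],
                 n_in_band = as.integer(nb),
                 df = NA_real_, n_segments = psd$n_segments,
                 segment_seconds = psd$segment_seconds),
            class = "psd_result")
}

#' Fit a Lorentzian plus 1/f model to an estimated PSD
#'
#' Least-squares fit, in log space, of
#' \eqn{S(f) = \frac{plateau}{1 + (f/f_0)^2} + \frac{c_f}{f}} to an
#' estimated spectrum. Parameters are log-parameterised so they stay
#' positive. The spectrum is log-rebinned first (see [log_bin_psd()]) so
#' that the dense high-frequency bins do not dominate the residual.
#'
#' The model has no white (flat) term: spectra whose high-frequency end
#' is limited by white measurement noise should be band-limited with
#' `f_max` below the white floor before fitting.
#'
#' @param psd A `psd_result`.
#' @param bins_per_decade Rebinning density before the fit (applied when
#'   the input grid is uniformly spaced, i.e. not yet log-binned).
#' @param flicker Include the 1/f term? Set `FALSE` for a pure
#'   Lorentzian.
#' @param f_min,f_max Optional frequency band (Hz) restricting the fit.
#' @return List with `plateau`, `f0`, `flicker_coeff` (0 when
#'   `flicker = FALSE`), `converged`, and `residual_rms` (rms of log
#'   residuals).
#' @export
fit_lorentzian_flicker <- function(psd, bins_per_decade = 10,
                                   flicker = TRUE, f_min = NULL,
                                   f_max = NULL) {
  stopifnot(inherits(psd, "psd_result"))
  if (length(psd$f) < 20)
    warning("fewer than 20 frequency points: fit may be unreliable",
            call. = FALSE)
  if (!is.null(f_min) || !is.null(f_max)) {
    keep <- psd$f >= (f_min %||% 0) & psd$f <= (f_max %||% Inf)
    psd$f <- psd$f[keep]; psd$S <- psd$S[keep]
    if (length(psd$f) < 5) stop("fit band contains too few points",
                                call. = FALSE)
  }
  uniform_grid <- length(psd$f) > 2 &&
    diff(range(diff(psd$f))) < 1e-6 * mean(diff(psd$f))
  pb <- if (uniform_grid) log_bin_psd(psd, bins_per_decade) else psd
  ok <- pb$S > 0
  f <- pb$f[ok]; S <- pb$S[ok]
  if (log10(max(f) / min(f)) < 2)
    warning("PSD spans less than a decade each side of any corner",
            call. = FALSE)

  ## initial values by profiling: at fixed f0 the model is linear in
  ## (plateau, flicker_coeff), so scan f0 on a log grid with relative
  ## (1/S-weighted) least squares and keep the best triple
  grid_f0 <- 10^seq(log10(min(f)), log10(max(f)), length.out = 60)
  best <- NULL
  for (f0g in grid_f0) {
    X <- cbind(lor = 1 / (1 + (f / f0g)^2),
               flk = if (flicker) 1 / f)
    ls <- stats::lm.fit(X / S, rep(1, length(f)))
    cf0 <- pmax(ls$coefficients, max(S) * min(f) * 1e-9)
    resid <- log(as.vector(X %*% cf0)) - log(S)
    rss <- sum(resid^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, f0 = f0g, cf = cf0)
  }
  plateau0 <- unname(best$cf[["lor"]])
  f00 <- best$f0
  c0 <- if (flicker) unname(best$cf[["flk"]]) else 0
  df <- data.frame(f = f, lS = log(S))
  converged <- TRUE
  fit <- tryCatch({
    if (flicker) {
      minpack.lm::nlsLM(
        lS ~ log(exp(lp) / (1 + (f / exp(lf0))^2) + exp(lc) / f),
        data = df,
        start = list(lp = log(plateau0), lf0 = log(f00), lc = log(c0)),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      minpack.lm::nlsLM(
        lS ~ log(exp(lp) / (1 + (f / exp(lf0))^2)),
        data = df, start = list(lp = log(plateau0), lf0 = log(f00)),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    }
  }, error = function(e) {
    converged <<- FALSE
    NULL
  })
  if (is.null(fit))
    return(list(plateau = plateau0, f0 = f00,
                flicker_coeff = if (flicker) c0 else 0,
                converged = FALSE, residual_rms = NA_real_))
  cf <- coef(fit)
  list(plateau = exp(cf[["lp"]]), f0 = exp(cf[["lf0"]]),
       flicker_coeff = if (flicker) exp(cf[["lc"]]) else 0,
       converged = converged,
       residual_rms = sqrt(mean(stats::residuals(fit)^2)))
}

#' Convert current noise to input-referred gate-voltage noise
#'
#' Pointwise division of a current-noise density by the squared
#' transconductance: \eqn{S_{V_G} = S_I / g_m^2}.
#'
#' @param s_i Current-noise density (A^2/Hz), vector or `psd_result`.
#' @param g_m Transconductance (S), > 0.
#' @return Same shape as `s_i`, in V^2/Hz.
#' @export
input_referred <- function(s_i, g_m) {
  stop_if_not_scalar(g_m, "g_m", positive = TRUE)
  if (inherits(s_i, "psd_result")) {
    s_i$S <- s_i$S / g_m^2
    s_i
  } else {
    s_i / g_m^2
  }
}

#' Estimate the 1/f spectral slope and level of a PSD
#'
#' Log-log linear regression of S on f, returning the slope and the level
#' extrapolated to 1 Hz. Convenience check for flicker-type spectra.
#'
#' @param psd A `psd_result`.
#' @param f_min,f_max Frequency range used for the regression (Hz).
#' @return List with `slope` and `level_at_1hz`.
#' @export
flicker_slope <- function(psd, f_min = NULL, f_max = NULL) {
  stopifnot(inherits(psd, "psd_result"))
  pb <- if (is.na(psd$df)) psd else log_bin_psd(psd, 10, f_min, f_max)
  ok <- pb$S > 0
  if (!is.null(f_min)) ok <- ok & pb$f >= f_min
  if (!is.null(f_max)) ok <- ok & pb$f <= f_max
  fit <- stats::lm(log10(pb$S[ok]) ~ log10(pb$f[ok]))
  list(slope = unname(coef(fit)[2]),
       level_at_1hz = 10^unname(coef(fit)[1]))
}
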