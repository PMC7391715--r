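#' Read a time trace from a two-column CSV file
#'
#' Reads either a current trace (`time_s,current_A` header) or a state
#' trace (`time_s,state`). Uniform sampling is enforced (relative timing
#' jitter <= 1e-6); non-finite values are rejected with the offending row
#' number.
#'
#' @param path File path.
#' @return A `current_trace` or `rts_trace` depending on the header.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  hdr <- trimws(hdr)
  kind <- if (identical(hdr, c("time_s", "current_A"))) "current"
  else if (identical(hdr, c("time_s", "state"))) "state"
  else stop("malformed header: expected `time_s,current_A` or ",
            "`time_s,state`, got `", paste(hdr, collapse = ","), "`",
            call. = FALSE)
  d <- utils::read.csv(path, colClasses = "numeric")
  if (nrow(d) < 2L) stop("trace needs at least 2 rows", call. = FALSE)
  bad <- which(!is.finite(d[[1]]) | !is.finite(d[[2]]))
  if (length(bad))
    stop("non-finite value at data row ", bad[1], call. = FALSE)
  dts <- diff(d[[1]])
  dt <- median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 1e-6 * dt))
    stop("non-uniform sampling: relative timing jitter exceeds 1e-6",
         call. = FALSE)
  if (kind == "current") {
    structure(list(dt = dt, current = d[[2]], v_g = NA_real_,
                   seed = NA_integer_, delta_i = NA_real_,
                   baseline = NA_real_, occupied_level = "low",
                   components = c(rts = NA, dp = NA, white = NA),
                   rts = NULL),
              class = "current_trace")
  } else {
    s <- d[[2]]
    if (!all(s %in% c(0, 1)))
      stop("state column must contain only 0 and 1", call. = FALSE)
    s <- as.integer(s)
    structure(list(dt = dt, states = s, v_g = NA_real_,
                   seed = NA_integer_,
                   events = dt * which(abs(diff(s)) > 0), state0 = s[1]),
              class = "rts_trace")
  }
}

#' Write a time trace to CSV
#'
#' Inverse of [read_trace()]: writes `time_s,current_A` for a
#' `current_trace` or `time_s,state` for an `rts_trace`, with enough
#' digits for a 12-significant-digit round trip.
#'
#' @param trace A `current_trace` or `rts_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "current_trace")) {
    n <- length(trace$current)
    d <- data.frame(time_s = format((seq_len(n) - 1L) * trace$dt,
                                    digits = 15, scientific = TRUE,
                                    trim = TRUE),
                    current_A = format(trace$current, digits = 15,
                                       scientific = TRUE, trim = TRUE))
  } else if (inherits(trace, "rts_trace")) {
    n <- length(trace$states)
    d <- data.frame(time_s = format((seq_len(n) - 1L) * trace$dt,
                                    digits = 15, scientific = TRUE,
                                    trim = TRUE),
                    state = trace$states)
  } else stop("unsupported trace type", call. = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration with `device`, `trap`, `simulation` and optional
#' `analysis` sections, all in SI units. Unknown keys are rejected by
#' name so that typos cannot silently fall back to defaults.
#'
#' @param path Path to the YAML file.
#' @return List with `device` ([device_model()]), `trap`
#'   ([trap_model()]), `simulation` (list: `duration`, `dt`, `seed`,
#'   `v_g`, ...) and `analysis` (list: `theta`, `stride`, `f1`, `f2`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known_top <- c("device", "trap", "simulation", "analysis")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  check_keys <- function(sec, allowed, name) {
    extra <- setdiff(names(sec), allowed)
    if (length(extra))
      stop("unknown key(s) in [", name, "]: ",
           paste(extra, collapse = ", "), call. = FALSE)
    sec
  }
  dev_keys <- c("W", "L", "C_G", "tg_delta", "g_m", "N_ot", "T")
  trap_keys <- c("tau_c0", "tau_e0", "alpha", "v0", "q_star")
  sim_keys <- c("duration", "dt", "seed", "v_g", "include_dp",
                "white_sigma", "baseline", "occupied_level")
  ana_keys <- c("theta", "stride", "f1", "f2", "segment_seconds")
  device <- do.call(device_model,
                    check_keys(cfg$device, dev_keys, "device"))
  trap <- do.call(trap_model, check_keys(cfg$trap, trap_keys, "trap"))
  sim <- check_keys(cfg$simulation, sim_keys, "simulation")
  ana <- if (is.null(cfg$analysis)) list()
  else check_keys(cfg$analysis, ana_keys, "analysis")
  list(device = device, trap = trap, simulation = sim, analysis = ana)
}

#' Reference device and trap of the measured 100 nm nanowire FET scenario
#'
#' The liquid-gated Si nanowire FET emulated by the synthetic fixtures:
#' 100 nm x 100 nm gate, SiO2 loss tangent 3.8e-3, transconductance
#' 1 uS, and a single trap with symmetric switching rate gamma = 488 1/s
#' at the operating point (g = 0.5) and coupling alpha = 0.5.
#'
#' The gate capacitance per area (2e-4 F/m^2, total 2e-18 F) is not a
#' measured value: the real device's capacitance is not available. It is
#' chosen so that the synthetic device reproduces the qualitative noise
#' hierarchy of the measured one -- a single-trap RTS Lorentzian above
#' the dielectric-polarization background (1.6e-6 vs 5e-7 V^2/Hz at
#' 10 Hz) and a clearly resolvable two-level current trace whose decoded
#' switching rates recover the generating gamma to within a few percent.
#'
#' @return List with `device` ([device_model()]) and `trap`
#'   ([trap_model()]).
#' @export
reference_device <- function() {
  list(device = device_model(W = 100e-9, L = 100e-9, C_G = 2e-4,
                             tg_delta = 3.8e-3, g_m = 1e-6,
                             N_ot = 1e12, T = 300),
       trap = trap_model(tau_c0 = 1 / 488, tau_e0 = 1 / 488,
                         alpha = 0.5, v0 = 0))
}

#' Generate named synthetic fixture scenarios on disk
#'
#' Writes deterministic synthetic data sets emulating the measured
#' device (see [reference_device()]):
#' \describe{
#'   \item{`fig4a`}{40 s composite current trace of the 100 nm x 100 nm
#'     device at the symmetric operating point (gamma = 488 1/s,
#'     g = 0.5) with DP and white noise, plus its config file.}
#'   \item{`trapfree`}{DP + white noise only -- no two-level structure.}
#'   \item{`steep_slope`}{Seven state traces across the occupancy
#'     transition (one per gate voltage) for occupancy-curve fitting.}
#' }
#'
#' @param name Scenario name.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; identical seed gives byte-identical files.
#' @param duration Trace duration (s); default 40 (fig4a/trapfree) or
#'   5 per voltage (steep_slope).
#' @param dt Sampling interval (s).
#' @return Character vector of written file paths, invisibly.
#' @export
make_fixture <- function(name = c("fig4a", "trapfree", "steep_slope"),
                         dir = ".", seed = 1, duration = NULL,
                         dt = 1e-4) {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- reference_device()
  dev <- ref$device; trap <- ref$trap
  paths <- character(0)

  if (name == "fig4a") {
    if (is.null(duration)) duration <- 40
    ct <- compose_trace(dev, trap, v_g = 0, duration, dt, seed = seed,
                        include_dp = TRUE,
                        white_sigma = ct_white_sigma(dev, trap))
    p <- file.path(dir, "fig4a_trace.csv")
    write_trace(ct, p)
    pc <- file.path(dir, "fig4a_config.yaml")
    write_fixture_config(pc, dev, trap, duration, dt, seed)
    paths <- c(p, pc)
  } else if (name == "trapfree") {
    if (is.null(duration)) duration <- 40
    n <- floor(duration / dt + 1e-9)
    lvl <- svg_dp(dev$C_total, dev$tg_delta, dev$T, 1)
    cur <- with_seed(seed, {
      dev$g_m * synthesize_flicker(lvl, duration, dt) +
        rnorm(n, 0, ct_white_sigma(dev, trap))
    })
    ct <- structure(list(dt = dt, current = cur, v_g = 0, seed = seed,
                         delta_i = 0, baseline = 0,
                         occupied_level = "low",
                         components = c(rts = FALSE, dp = TRUE,
                                        white = TRUE),
                         rts = NULL),
                    class = "current_trace")
    p <- file.path(dir, "trapfree_trace.csv")
    write_trace(ct, p)
    paths <- p
  } else { # steep_slope
    if (is.null(duration)) duration <- 5
    v_gs <- seq(-0.075, 0.075, by = 0.025)
    for (i in seq_along(v_gs)) {
      tt <- trap_times(trap, dev, v_gs[i])
      tr <- simulate_rts(1 / tt$tau_c, 1 / tt$tau_e, duration, dt,
                         seed = seed + i, v_g = v_gs[i])
      p <- file.path(dir, sprintf("steep_slope_vg_%+0.3fV.csv", v_gs[i]))
      write_trace(tr, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

## White measurement noise used by the fixtures: delta_I / 4 keeps the
## trace clearly two-level but non-trivial to decode.
ct_white_sigma <- function(dev, trap) {
  dev$g_m * trap$q_star / dev$C_total / 4
}

write_fixture_config <- function(path, dev, trap, duration, dt, seed) {
  cfg <- list(
    device = list(W = dev$W, L = dev$L, C_G = dev$C_G,
                  tg_delta = dev$tg_delta, g_m = dev$g_m,
                  N_ot = dev$N_ot, T = dev$T),
    trap = list(tau_c0 = trap$tau_c0, tau_e0 = trap$tau_e0,
                alpha = trap$alpha, v0 = trap$v0, q_star = trap$q_star),
    simulation = list(duration = duration, dt = dt, seed = seed,
                      v_g = 0),
    analysis = list(theta = 20, f1 = 1, f2 = 100))
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}
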