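# rtsnoise

Noise modelling and analysis for nanoscale field-effect transistor (FET)
biosensors in which a **single oxide trap** produces random telegraph
signal (RTS) current switching — and for the readout strategy that turns
that switching from a nuisance into a signal.

## The science

Conventional FET biosensors read a threshold-voltage shift
δV<sub>Th</sub> against the device's input-referred voltage noise
S<sub>V_G</sub>. At sub-µm gate areas the relevant limits are:

- **trap-number noise** S<sub>V_G</sub> = q²N<sub>ot</sub>/(C_G²·A·f) in
  the many-trap regime,
- **dielectric-polarization (DP) noise**
  S<sub>V_G</sub> = 2kT·tgδ/(π·C·f) — the *thermal limit* that remains
  when no trap is active,
- the **RTS Lorentzian** of a single active trap,
  S<sub>V_G</sub>(f) = 4g(1−g)²τ_e(q*/C)² / (1+(2π(1−g)τ_e f)²), whose
  maximum against a 1/f background is (1/4π)·(q*/C)²/f₀ at the corner
  frequency f₀ — typically one to two orders above the DP level.

The single-trap alternative treats the **trap occupancy probability**
g = τ_e/(τ_e+τ_c) as the sensing signal. g(V_G) is a steep logistic
curve with slope g_g = ∂g/∂V_G; estimating g by a sliding time window Θ
averages over many switching events, giving an occupancy noise spectrum
(symmetric chain, rates λ = μ = γ)

S_g^(Θ)(ω) = 2γ(1−cos Θω) / (Θ²ω²(4γ²+ω²)),

an input-referred noise S<sub>gg</sub> = S_g/g_g², and a signal-to-noise
ratio S/N = δV<sub>Th</sub>/√(∫S<sub>gg</sub> df). For fast RTS, long
windows and steep slopes, S/N *exceeds* the DP-limited conventional
readout — noise suppression beyond the thermal limit, in the spirit of
stochastic resonance.

The package implements all of the above: closed-form models; an
event-driven RTS + 1/f + white-noise trace simulator; two-state Gaussian
HMM state extraction with dwell-time and occupancy statistics; Welch
spectral estimation with Lorentzian + 1/f fitting; the analytic
occupancy-noise model with a brute-force simulation oracle; and S/N
sweeps. See the methods vignette
(`vignettes/single-trap-noise.Rmd`) for the model details and design
decisions.

## Worked example

Simulate the reference scenario — a 100 nm × 100 nm liquid-gated Si
nanowire FET with one trap switching at γ = 488 s⁻¹ (g = 0.5), DP
background and white measurement noise — then recover the trap kinetics
and compare the two readout strategies:

```r
library(rtsnoise)

ref <- reference_device()
ct <- compose_trace(ref$device, ref$trap, v_g = 0, duration = 10,
                    dt = 2e-5, seed = 1, include_dp = TRUE,
                    white_sigma = 4e-9)
fit <- fit_two_state_hmm(ct, seed = 1)
fit
#> Two-state Gaussian HMM fit
#>   levels: -4.028e-08 / -5.583e-11 A, sigma = 8.91e-09 A
#>   transitions: 4896, rates: lambda = 491.5, mu = 487.9 1/s
```

The decoded rates recover the generating 488 s⁻¹ within 1%. The
sliding-window occupancy and its noise:

```r
gt <- sliding_g(fit$states, theta = 1)
p <- estimate_psd(gt, segment_seconds = 2)
mean(p$S[p$f >= 8 & p$f <= 12])              # measured S_g at 10 Hz
#> 6.6e-07  (1/Hz; closed form sg_theta_f(10, 488, 1): 5.2e-07)
```

Signal-to-noise for a 0.1 pH signal (ideal ISFET: 5.95 mV at 300 K),
band 1–100 Hz, window Θ = 20 s, occupancy slope from the logistic model
(α = 0.5, g_g = 4.84 V⁻¹):

```r
gg <- logistic_gg(0, alpha = 0.5, v0 = 0, T = 300)
f <- 10^seq(0, 2, length.out = 200)
dvth <- nernst_signal(0.1, 300)
snr_voltage(dvth, f, svg_dp(ref$device$C_total, ref$device$tg_delta, 300, f))
#> 1.24        # conventional readout against the DP thermal limit
snr_gfactor(dvth, f, s_gg(sg_theta_f(f, 488, 20, band_averaged = TRUE), gg))
#> 80.4        # occupancy readout: ~65x above the thermal-limit readout
```

A command-line front end covering the same pipeline (simulate, extract,
psd, fit-psd, gnoise, snr, sweep, make-fixture, demo) is installed at
`system.file("cli", "rtsnoise.R", package = "rtsnoise")`; YAML config
files with `device`/`trap`/`simulation`/`analysis` sections describe a
scenario (see `inst/extdata/example_config.yaml`).

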