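---
title: "Single-trap noise models for nanotransistor biosensors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trap noise models for nanotransistor biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtsnoise)
```

## The problem

Field-effect transistor (FET) biosensors read a chemical signal — a
threshold-voltage shift $\delta V_{Th}$ caused by analyte binding or a pH
change — against the device's low-frequency noise. When the gate area $A$
shrinks below about 1 µm², the number of active oxide traps becomes
discrete. A device with *no* active trap is limited by thermal
dielectric-polarization (DP) noise; a device with *one* active trap shows
two-level random telegraph signal (RTS) current switching, normally a
nuisance that raises the noise by one to two orders of magnitude.

`rtsnoise` implements the alternative reading of that situation: treat the
trap's occupancy probability $g$ as the *signal*. Because the trap's
capture time depends exponentially on surface potential, $g(V_G)$ is a
steep logistic curve, and monitoring $g$ through a sliding time window
averages over many stochastic switching events. Under the right conditions
(fast RTS, long window, steep $g(V_G)$) the equivalent input-referred noise
of this occupancy readout falls *below* the DP thermal limit of a trap-free
device — an effect analogous to stochastic resonance, where an embedded
noise source makes a sub-threshold signal readable.

The package provides, as separately testable layers:

1. **Closed-form noise models** — trap-number noise
   $S_{V_G}=q^2N_{ot}/(C_G^2Af)$, DP noise
   $S_{V_G}=2kT\,\mathrm{tg}\delta/(\pi C f)$, the RTS Lorentzian
   $S_{V_G}(f)=4g(1-g)^2\tau_e(q^*/C)^2/(1+(2\pi(1-g)\tau_e f)^2)$, its
   maximum $(1/4\pi)(q^*/C)^2/f_0$, and the Nernstian ISFET signal.
2. **A trace simulator** — event-driven two-state Markov RTS, 1/f DP
   background, white measurement noise.
3. **State extraction** — two-state Gaussian hidden Markov model (HMM),
   dwell-time statistics, sliding-window occupancy $g^\Theta(t)$, logistic
   $g(V_G)$ fits.
4. **Spectral estimation** — Welch PSD, Lorentzian + 1/f fits,
   input-referral.
5. **The analytic occupancy-noise model** — transition matrix,
   windowed-occupancy autocorrelation, and the closed-form spectrum
   $S_g^{(\Theta)}(\omega)=2\gamma(1-\cos\Theta\omega)/(\Theta^2\omega^2(4\gamma^2+\omega^2))$
   for the symmetric chain $\lambda=\mu=\gamma$, with a brute-force
   simulation oracle.
6. **Signal-to-noise analysis** — $S_{gg}=S_g/g_g^2$ with
   $g_g=\partial g/\partial V_G$, and
   $S/N=\delta V_{Th}/\sqrt{\int_{f_1}^{f_2}S\,df}$ for both readouts.

## The trap model and its parameters

A single trap is described by (`trap_model()`):

| parameter | meaning | default | why |
|---|---|---|---|
| `tau_c0` (s) | capture time at the reference voltage | 1/488 | symmetric switching rate of the measured 100 nm device at its operating point |
| `tau_e0` (s) | emission time, voltage-independent | 1/488 | emission times of such traps are nearly constant in gate voltage |
| `alpha` | gate-to-trap coupling $C_G/C_j$, in (0, 1] | 0.5 | mid-range coupling; sets the logistic steepness |
| `v0` (V) | voltage where $\tau_c=\tau_{c0}$ | 0 | operating point |
| `q_star` (C) | effective trapped charge | $0.5\,q$ | image-charge screening of a trap in SiO₂ |

The capture time follows
$\tau_c(V_G)=\tau_{c0}\,e^{-q\alpha(V_G-V_0)/kT}$, the minimal model
consistent with a constant emission time and a logistic occupancy
$g=1/(1+e^{-q\alpha(V_G-V_0)/kT})$; its slope is
$g_g=(q\alpha/kT)\,g(1-g)$, maximal at $g=1/2$. Since the published device
characterization gives only the coupling *ratio* concept and the measured
time-constant trends, this exponential form is a modeling choice of this
package, not a transcription.

The device (`device_model()`) carries $W$, $L$, $C_G$, the loss tangent
$\mathrm{tg}\delta$ (3.8×10⁻³ for SiO₂), transconductance $g_m$, trap
density $N_{ot}$ and temperature.

### The reference scenario

`reference_device()` encodes the synthetic stand-in for the measured
100 nm × 100 nm liquid-gated Si nanowire FET: $\gamma=488$ s⁻¹ at $g=1/2$,
$\alpha=0.5$, $g_m=1$ µS, $T=300$ K. Its gate capacitance is **not** a
published number (the real device's value appears only in supplementary
material we do not reproduce); we chose $C_G=2\times10^{-4}$ F m⁻²
($C_{tot}=2\times10^{-18}$ F) so that the synthetic device reproduces the
qualitative noise hierarchy reported for the measured one: the RTS
Lorentzian (1.6×10⁻⁶ V²/Hz at 10 Hz) sits above the DP background
(5.0×10⁻⁷ V²/Hz), and the two-level structure of the composite trace is
clearly resolvable, so the HMM recovers the generating rates to within a
few percent. A larger capacitance (e.g. the 7×10⁻¹⁷ F implied by a DP
level of 1.4×10⁻⁸ V²/Hz at 10 Hz, which we use as a *worked example* for
DP-limited S/N) would make the gate-referred DP fluctuation comparable to
the single-charge step $q^*/C_{tot}$ and bury the RTS — contradicting the
observed clear two-level switching. All S/N conclusions below are
insensitive to this choice: $S_{gg}$ contains no capacitance, and a
smaller capacitance raises both the RTS and DP reference levels together.

## Simulation design

**RTS generation is event-driven.** Dwell times are drawn exponentially
(capture rate $\lambda$, emission rate $\mu$) and the piecewise-constant
path is resampled onto the uniform grid. Per-step Bernoulli simulation
would bias exactly the quantity this package studies — the dwell-time
statistics; with event-driven sampling only events shorter than one grid
step can be lost (fraction $\approx\gamma\,dt$, under 1% for
$dt\le0.005/\gamma$, which the tests enforce). The initial state is drawn
from the stationary distribution to avoid transients. Every stochastic
function takes an integer seed; the same seed reproduces the trace
byte-for-byte.

**1/f noise is synthesized in the frequency domain**: amplitudes
$\propto f^{-1/2}$ scaled to the requested one-sided level, independent
uniform phases, conjugate symmetry, inverse FFT; the band is cut below
$1/\mathrm{duration}$. This gives exact spectral control in $O(N\log N)$;
the total variance is approximately
$\mathrm{level}\times\ln(f_{hi}/f_{lo})$.

**The composite trace** is
$I(t)=I_0-\Delta I\,X_t+g_m v_{DP}(t)+w(t)$ with
$\Delta I=g_m q^*/(C_G A)$. The occupied trap *lowers* the current by
default (depletion-mode convention; `occupied_level = "high"` flips it —
the sign differs between N- and P-type devices and is not fixed by the
physics implemented here).

## State extraction

The HMM is a two-state Gaussian model with shared emission standard
deviation, fitted by Baum–Welch (E-step in compiled code), initialized
from a two-cluster split of the amplitude histogram, and decoded with the
Viterbi path. Posterior thresholding would produce spurious single-sample
switches and fragment the dwell statistics, so the most-probable *path* is
used. Censored first and last dwells are discarded, as in single-channel
kinetics. A fit whose level separation is below $2\sigma$ is rejected as
"no two-level structure": two-component fits of unimodal noise settle
near $1.1\sigma$ separation, genuine RTS at $\ge4\sigma$, so the
threshold cleanly separates the cases. Fewer than ~200 transitions in a
window make the occupancy estimate statistically unreliable; the package
warns at that point. The HMM assumes *static* levels: slow 1/f drift
comparable to the step size degrades it, and drift correction is
deliberately out of scope.

`sliding_g()` computes $g^\Theta(t)$ with stride `dt` by default because
the occupancy spectrum is defined for the continuously slid window;
coarser strides subsample $g^\Theta$ and alias its spectrum (allowed, for
speed, with that caveat).

## Spectral conventions

All densities are **one-sided**, in V²/Hz (or A²/Hz, or 1/Hz for $g$),
the convention of low-frequency noise measurement practice. The Welch
estimator uses Hann windows and 50% overlap; Parseval
($\int S\,df=\sigma^2$) is enforced by tests to 5%. Fits of
Lorentzian + 1/f shapes run on log-binned spectra in log space, otherwise
the dense high-frequency bins dominate; initial values come from a
profiled scan (the model is linear in the plateau and flicker
coefficients at fixed corner). The fit model contains no white term: a
spectrum with a white measurement-noise floor must be band-limited below
the floor (`f_max`).

The closed-form occupancy spectrum is stated in angular frequency. Its
normalization is fixed analytically rather than by calibration: the
sliding window is a moving-average filter, so for the symmetric chain
(autocovariance $e^{-2\gamma|s|}/4$, two-sided density
$\gamma/(4\gamma^2+\omega^2)$, filter gain
$2(1-\cos\Theta\omega)/(\Theta\omega)^2$) the product is exactly
`sg_theta()`, a *two-sided density in* $\omega$ with
$\mathrm{Var}=(2\pi)^{-1}\int S\,d\omega$. A one-sided estimate on a grid
in Hz therefore equals $2\times$`sg_theta(`$2\pi f$`)` — the factor
pinned by a regression test against the simulation oracle
(`sg_numeric_oracle()`). The $(1-\cos\Theta\omega)$ factor has exact
nulls at $f=k/\Theta$, where pointwise comparison with estimated spectra
is meaningless; comparisons therefore use band averages
(`sg_theta_band()` integrates the exact form over each band — correct at
all frequencies — while `band_averaged = TRUE` replaces the oscillation
by its mean, valid for $f\gg1/\Theta$). The $\omega\to0$ limit is
$1/(4\gamma)$.

For asymmetric chains no closed-form spectrum is published; the package
computes the autocorrelation $C(s)$ for general $(\lambda,\mu)$ by exact
1-D reduction of the double integral (triangular overlap weight,
piecewise adaptive quadrature between the kinks at $w=0$ and $w=s$) and,
where a spectrum is needed at $g\ne1/2$, evaluates the symmetric form at
the pair's Lorentzian-equivalent rate $1/(2\tau_{e\!f\!f})$,
$\tau_{e\!f\!f}=\tau_c\tau_e/(\tau_c+\tau_e)$ — exact at $g=1/2$, an
approximation elsewhere.

## Signal-to-noise analysis

Both readouts are scored by
$S/N=\delta V_{Th}/\sqrt{\int_{f_1}^{f_2}S\,df}$ with the ideal
Nernstian signal $\delta V_{Th}=\ln(10)kT/q\cdot\Delta pH$ (5.9 mV for
0.1 pH at 298 K) as the common reference. The integration band is
nowhere stated in the source material; the package defaults to
**1–100 Hz**, bracketing the 10 Hz frequency at which noise levels are
conventionally quoted, and exposes it as a parameter.

One subtlety the closed forms make explicit: the occupancy noise at a
*fixed* frequency is maximal when the chain corner matches that frequency
($2\gamma=\omega$). Consequently $S_{gg}$ at 10 Hz *rises* with corner
frequency up to $f_0\approx10$ Hz and falls beyond it, and the
band-integrated $S/N$ has a shallow (~3%) dip near $f_0\approx f_1$.
"Faster RTS → lower occupancy noise → higher S/N" therefore holds above
these points — which is where the published trend plots evidently live —
and the package's trend tests assert it there (decade steps 1→1000 Hz
for $S/N$; $f_0\ge10$ Hz for $S_{gg}$ at 10 Hz).

With the reference scenario ($\gamma=488$ s⁻¹, $g=1/2$, $\Theta=20$ s,
$\alpha=0.5$):

```{r}
ref <- reference_device()
dev <- ref$device
gg <- logistic_gg(0, alpha = 0.5, v0 = 0, T = dev$T)
f <- 10^seq(0, 2, length.out = 200)
dvth <- nernst_signal(0.1, dev$T)

s_gg_10 <- s_gg(sg_theta_f(10, 488, 20, band_averaged = TRUE), gg)
rts_10 <- svg_rts_lorentzian(0.5, 1/488, ref$trap$q_star, dev$C_total, 10)
dp_10 <- svg_dp(dev$C_total, dev$tg_delta, dev$T, 10)
c(S_gg = s_gg_10, RTS = rts_10, DP = dp_10)

snr_v <- snr_voltage(dvth, f, svg_dp(dev$C_total, dev$tg_delta, dev$T, f))
snr_g <- snr_gfactor(dvth, f,
                     s_gg(sg_theta_f(f, 488, 20, band_averaged = TRUE), gg))
c(conventional = snr_v, occupancy = snr_g)
```

The input-referred occupancy noise sits orders of magnitude below both
the device's own RTS voltage noise and its DP background, and the
occupancy readout's S/N exceeds the DP-limited conventional readout —
the noise-suppression-beyond-the-thermal-limit effect, here as a
reproducible computation.

## What the synthetic data does and does not emulate

The generator reproduces: two-level RTS with exponential dwells and
gate-voltage-dependent capture time, the 1/f DP background at the level
set by $\mathrm{tg}\delta$ and $C_{tot}$, white measurement noise, and
the resulting spectra. It does **not** emulate: multi-trap traces and
inter-trap Coulomb correlation, electrochemical drift and other
non-stationarities, anomalous (>2-level) RTS, amplitude drift, or
frequency-dependent dielectric loss. Tests passing on synthetic traces
therefore validate the estimators under the stated model, not robustness
to those real-data pathologies — in particular the HMM's static-level
assumption is the first thing to break on drifting measurements.

## Numerical choices

- Physical constants: SI-2019 exact values ($k=1.380649\times10^{-23}$
  J/K, $q=1.602176634\times10^{-19}$ C).
- `svg_rts_max()` computes with the exact $1/(4\pi)=0.0796$; the familiar
  0.08 is reported as metadata, never used in arithmetic.
- The capacitance symbol in the RTS Lorentzian is read as the *total*
  capacitance $C_G A$, the interpretation consistent with the peak-noise
  formula.
- EM stops on relative log-likelihood change $<10^{-6}$ or 100
  iterations (then flagged); the emission-variance floor is relative
  ($10^{-12}\,\mathrm{Var}(x)$) so nanoamp-scale traces are not clipped.
- Quadratures: autocorrelation at relative tolerance $10^{-8}$;
  band averages of the occupancy spectrum at $10^{-8}$.
- Degenerate inputs fail fast with named errors (zero-variance trace,
  non-uniform sampling, unknown config keys, empty sweep ranges).

## Problem sizes used in the test suite

Unit and acceptance tests run on deliberately desk-scale problems chosen
for tight Monte-Carlo error at second-scale runtimes: the
closed-form-vs-simulation check uses ten 200 s traces at $dt=10^{-4}$ s
($\gamma=488$ s⁻¹, $\Theta=1$ s, agreement within 20% per log-band over
0.05–50 Hz, plateau within 10%); HMM recovery uses ten 3 s replicates
(~1460 transitions each) at step-to-noise 4. Longer traces only shrink
the Monte-Carlo bars.

## Known limitations

- The asymmetric-chain spectrum is approximated (see above); only the
  autocorrelation is exact for $\lambda\ne\mu$.
- The HMM assumes static levels and white Gaussian emission noise;
  strong 1/f backgrounds inflate the fitted $\sigma$ and, past
  $\sigma_{DP}\sim\Delta I/3$, produce spurious decoded transitions.
- Welch's estimator with per-segment mean removal biases the lowest ~2
  frequency bins low; plateau estimates divide out the known window
  response and average over $f\le0.3$ Hz instead of extrapolating.
- The DP model is frequency-flat in $\mathrm{tg}\delta$; real
  dielectrics deviate at the band edges.
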