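## Shared synthetic scenarios. Everything is generated in code; no data
## files are read.

ref <- reference_device()
ref_dev <- ref$device
ref_trap <- ref$trap

## white-noise sigma giving a target step-to-noise ratio for the
## reference device
ref_sigma <- function(snr = 4) {
  ref_dev$g_m * ref_trap$q_star / ref_dev$C_total / snr
}

## short composite trace of the reference scenario
ref_composite <- function(seed, duration = 5, dt = 2e-5,
                          include_dp = FALSE, snr = 4) {
  compose_trace(ref_dev, ref_trap, v_g = 0, duration = duration,
                dt = dt, seed = seed, include_dp = include_dp,
                white_sigma = ref_sigma(snr))
}
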