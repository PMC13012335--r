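# Shared fixtures: small axes and a brute-force periodic-convolution oracle.

small_axis <- function(n = 256, period = 12.5) {
  time_axis(bin_width = period / n, n_bins = n, period = period)
}

# Independent oracle: periodic convolution as the superposition of many
# linearly shifted aperiodic convolutions (double loop, no FFT).
brute_circular_conv <- function(kernel, weights, n_periods = 10) {
  n <- length(kernel)
  out <- numeric(n)
  for (i in 0:(n - 1)) {
    for (j in 0:(n - 1)) {
      # aperiodic lag i + j folded back into the observation period
      out[((i + j) %% n) + 1] <- out[((i + j) %% n) + 1] + kernel[i + 1] * weights[j + 1]
    }
  }
  out
}

# Brute-force steady-state monoexponential: explicit sum of shifted
# single-pulse kernels from n_pulses preceding excitation pulses.
brute_wrapped_monoexp <- function(tau, axis, n_pulses = 30) {
  t <- bin_centers(axis)
  Reduce(`+`, lapply(0:(n_pulses - 1), function(k) exp(-(t + k * axis$period) / tau)))
}
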