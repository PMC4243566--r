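# Shared fixtures: small parameter sets and a closed-form oracle for the
# triangular kernel shape, independent of the stepping engine.

ref_params <- function(n_inputs = 2L, ...) skan_params(n_inputs, ...)

# closed-form kernel cycle under the register-transfer timing: triggered at
# step 1 (the spike step), r rises by dr per step, peaks at ceil(w/dr) steps,
# descends symmetrically, and the peak value is dr * ceil(w/dr).
kernel_shape_oracle <- function(dr, w) {
  n_up <- as.integer(ceiling(w / dr))
  list(peak = dr * n_up, n_up = n_up, n_down = n_up,
       cycle_steps = 2L * n_up)
}

# simulate one kernel cycle with output feedback disabled (theta unreachable)
simulate_kernel_cycle <- function(dr, w = 10000L, max_steps = 3L * (w %/% dr + 2L)) {
  p <- skan_params(1L, w = w, theta_init = .Machine$integer.max %/% 2L)
  st <- neuron_state(p, dr = dr)
  r <- integer(max_steps)
  for (t in seq_len(max_steps)) {
    st <- neuron_step(st, if (t == 1L) 1L else 0L, p)
    r[t] <- st$r
  }
  r
}

# a fixed two-pattern pair with well-separated ISIs, for network tests
separated_patterns <- function() {
  list(spike_pattern(c(0L, 0L), 20L), spike_pattern(c(0L, 15L), 20L))
}
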