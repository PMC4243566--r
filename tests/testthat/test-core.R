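test_that("kernel flag state machine follows the ramp cycle", {
  w <- 10000L
  # idle kernel starts ramping on a spike
  expect_identical(kernel_flag_update(1L, 0L, 0L, w), 1L)
  # new spike mid-cycle is ignored: the neuron trains on the first spike
  expect_identical(kernel_flag_update(1L, 1L, 500L, w), 1L)
  # cycle complete: flag returns to idle
  expect_identical(kernel_flag_update(0L, -1L, 0L, w), 0L)
  # flip to ramp-down once the accumulator has reached the peak
  expect_identical(kernel_flag_update(0L, 1L, w, w), -1L)
  expect_identical(kernel_flag_update(0L, -1L, 300L, w), -1L)
  # vectorised over channels
  expect_identical(kernel_flag_update(c(1L, 0L), c(0L, -1L), c(0L, 0L), w),
                   c(1L, 0L))
  expect_error(kernel_flag_update(0L, 2L, 0L, w), "flag")
  expect_error(kernel_flag_update(3L, 0L, 0L, w), "binary")
})

test_that("kernel accumulator and slope adaptation follow the feedback rule", {
  p <- ref_params()
  # ramp-up during an output pulse: kernel was late, slope increases
  expect_identical(kernel_accumulate(5000L, 100L, 1L, 1L, p),
                   list(r = 5100L, dr = 101L))
  # ramp-down during an output pulse: kernel was early, slope decreases
  expect_identical(kernel_accumulate(5000L, 100L, -1L, 1L, p),
                   list(r = 4900L, dr = 99L))
  # accumulator clamps at zero; slope untouched without an output pulse
  expect_identical(kernel_accumulate(50L, 100L, -1L, 0L, p),
                   list(r = 0L, dr = 100L))
  # slope saturates at dr_max and at dr_floor
  expect_identical(kernel_accumulate(0L, p$dr_max, 1L, 1L, p)$dr, p$dr_max)
  expect_identical(kernel_accumulate(500L, p$dr_floor, -1L, 1L, p)$dr,
                   p$dr_floor)
})

test_that("soma comparison is strict and never resets the membrane", {
  expect_identical(soma_compare(201, 200), 1L)
  expect_identical(soma_compare(200, 200), 0L)
  expect_identical(soma_compare(0, 0), 0L)
})

test_that("threshold homeostasis rises while spiking, falls on membrane zero", {
  p <- ref_params()  # theta_rise 80, theta_fall 200
  expect_identical(threshold_update(1000L, 1200L, 900L, p), 1080L)
  expect_identical(threshold_update(1000L, 0L, 150L, p), 800L)
  expect_identical(threshold_update(100L, 0L, 150L, p), 0L)   # clamped
  expect_identical(threshold_update(1000L, 500L, 600L, p), 1000L)  # else
})

test_that("kernel cycle is a symmetric triangle matching the closed form", {
  for (dr in c(100L, 137L, 300L, 400L)) {
    ora <- kernel_shape_oracle(dr, 10000L)
    r <- simulate_kernel_cycle(dr)
    expect_identical(max(r), ora$peak)
    expect_identical(which.max(r), ora$n_up)
    rising <- sum(diff(c(0L, r)) > 0L)
    falling <- sum(diff(r) < 0L)
    expect_identical(rising, ora$n_up)
    expect_identical(falling, ora$n_down)
    # peak overshoot is bounded by dr - 1, and zero when dr divides w
    expect_lt(ora$peak - 10000L, dr)
    if (10000L %% dr == 0L) expect_identical(ora$peak, 10000L)
    # kernel returns to rest and stays there
    expect_identical(r[ora$cycle_steps + 1L], 0L)
  }
})

test_that("quiescence is a fixed point and spikes drive immediate membrane rise", {
  p <- ref_params(theta_init = 0L)
  st <- neuron_state(p, dr = c(100L, 100L))
  st0 <- st
  for (i in 1:5) st <- neuron_step(st, c(0L, 0L), p)
  expect_identical(st[c("p", "r", "dr", "theta", "s")],
                   st0[c("p", "r", "dr", "theta", "s")])
  # simultaneous spikes: accumulators integrate the fresh flag, so the
  # membrane is already positive at the arrival step and crosses theta = 0
  st <- neuron_step(st, c(1L, 1L), p)
  expect_identical(st$r, c(100L, 100L))
  expect_identical(st$s, 1L)
  expect_identical(st$theta, p$theta_rise)
  expect_error(neuron_step(st, c(1L, 1L, 0L), p), "n_inputs")
})

test_that("inputs arriving inside a burst are invisible: first-spike training", {
  p <- ref_params(1L)
  run <- function(spike_times, n = 260L) {
    st <- neuron_state(p, dr = 150L)
    out <- vector("list", n)
    for (t in seq_len(n)) {
      st <- neuron_step(st, as.integer(t %in% spike_times), p)
      out[[t]] <- st[c("p", "r", "dr", "theta", "s")]
    }
    out
  }
  # burst entirely within the kernel cycle of its first spike
  expect_identical(run(c(5L, 9L, 23L, 60L)), run(5L))
  # a spike after the cycle completes does retrigger
  expect_false(identical(run(c(5L, 200L)), run(5L)))
})

test_that("parameter validation enforces the slope bound", {
  expect_length(validate_params(ref_params(), PW = 20L), 0L)
  v <- validate_params(ref_params(dr_max = 500L), PW = 20L)
  expect_length(v, 1L)
  expect_match(v, "violation")
  # boundary of the strict inequality counts as a violation
  expect_length(validate_params(ref_params(dr_max = 500L), PW = 20L), 1L)
  # degenerate width: the bound is vacuous
  expect_length(validate_params(skan_params(2L, dr_max = 1L, dr_init = c(1L, 1L)),
                                PW = 0L), 0L)
  # network rule of thumb surfaces as a warning message
  v2 <- validate_params(ref_params(), PW = 20L,
                        net = net_params(2L, inh_max = 10L))
  expect_match(v2, "warning")
})

test_that("parameter constructor rejects inconsistent values", {
  expect_error(skan_params(2L, dr_max = 20000L), "dr_max")
  expect_error(skan_params(2L, dr_floor = 0L), "dr_floor")
  expect_error(skan_params(2L, w = -1L), "non-negative")
  expect_error(skan_params(0L), "n_inputs")
})

test_that("initial slopes are drawn within bounds and reproducibly", {
  p <- ref_params(4L)
  set.seed(11)
  s1 <- neuron_state(p)
  set.seed(11)
  s2 <- neuron_state(p)
  expect_identical(s1$dr, s2$dr)
  set.seed(12)
  draws <- replicate(200, neuron_state(p)$dr)
  expect_true(all(draws >= 100L & draws <= 200L))
})
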