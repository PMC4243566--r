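# Single-neuron reference semantics, register-transfer style: within a step,
# the flag is updated combinationally from the current input and the
# registered (previous-step) state; the accumulator integrates the *new*
# flag; slope and threshold adaptation read only registered values. This
# timing makes the kernel peak exactly at w when dr divides w (overshoot at
# most dr - 1 otherwise) and lets the slope ratchet up to dr_max under
# repeated presentations, giving the converged response latency of about
# w / dr_max steps. The compiled engine (src/engine.cpp) implements the same
# ordering and is checked against these functions in the test suite.

#' Kernel flag state machine
#'
#' One step of the ternary flag `p` controlling a kernel's ramp-up/ramp-down
#' cycle. A spike arriving while the kernel is idle (`p = 0`) starts the ramp
#' up; the flag flips to ramp down once the accumulator has reached the peak
#' height `w`, and returns to idle when the accumulator is back at zero.
#' Spikes arriving while the kernel is active are ignored, so the neuron
#' trains on the first spike of a burst.
#'
#' Vectorised over channels.
#'
#' @param u binary input spike(s) at the current step.
#' @param p_prev previous flag value(s), in `{-1, 0, 1}`.
#' @param r_prev previous accumulator value(s).
#' @param w kernel peak height.
#' @return integer flag value(s) in `{-1, 0, 1}`.
#' @examples
#' kernel_flag_update(1, 0, 0, 10000)    #  1: spike starts the ramp
#' kernel_flag_update(1, 1, 500, 10000)  #  1: new spike ignored mid-cycle
#' kernel_flag_update(0, -1, 0, 10000)   #  0: cycle complete
#' @export
kernel_flag_update <- function(u, p_prev, r_prev, w) {
  if (!all(p_prev %in% c(-1L, 0L, 1L))) stop("flag must be in {-1, 0, 1}")
  if (!all(u %in% c(0L, 1L))) stop("input spikes must be binary")
  up <- (u == 1L & p_prev == 0L) | (p_prev == 1L & r_prev < w)
  down <- (p_prev == 1L & r_prev >= w) | (p_prev == -1L & r_prev > 0L)
  as.integer(up) - as.integer(down)
}

#' Kernel accumulator and slope adaptation
#'
#' One step of the triangular kernel: the accumulator moves by `p * dr`
#' (clamped at zero below) where `p` is the flag in force during the step,
#' and, while the back-propagating output pulse is high, the slope moves by
#' `p_prev * ddr` — up if the kernel was still ramping up when the soma
#' spiked (it peaked too late), down if it was already ramping down (too
#' early). The slope is clamped to `[dr_floor, dr_max]`.
#'
#' The accumulator integrates the freshly updated flag (see
#' [kernel_flag_update()]), while the slope adaptation pairs the registered
#' flag with the registered output — the register-transfer timing under
#' which the kernel peaks at `w` exactly (when `dr` divides `w`) and the
#' ramp-up/ramp-down asymmetry under a rising threshold ratchets the slope
#' toward `dr_max`. Pure function; vectorised over channels.
#'
#' @param r_prev previous accumulator value(s).
#' @param dr_prev previous slope(s).
#' @param p flag value(s) in force during this step.
#' @param s_prev previous binary output of the soma.
#' @param params a [skan_params()] object.
#' @param p_prev previous flag value(s), used for the slope row; defaults to
#'   `p` (the two coincide except at phase transitions).
#' @return list with integer components `r` and `dr`.
#' @examples
#' p <- skan_params(2)
#' kernel_accumulate(5000, 100, 1, 1, p)   # r 5100, dr 101
#' kernel_accumulate(5000, 100, -1, 1, p)  # r 4900, dr 99
#' kernel_accumulate(50, 100, -1, 0, p)    # r clamped at 0, dr unchanged
#' @export
kernel_accumulate <- function(r_prev, dr_prev, p, s_prev, params,
                              p_prev = p) {
  r <- pmax(as.integer(r_prev + p * dr_prev), 0L)
  dr <- as.integer(dr_prev + p_prev * params$ddr * s_prev)
  dr <- pmin(pmax(dr, params$dr_floor), params$dr_max)
  list(r = r, dr = dr)
}

#' Soma threshold comparison
#'
#' The soma spikes while the membrane potential (the sum of all kernel
#' accumulators) strictly exceeds the threshold. The membrane is never reset
#' on spiking, which permits multi-step output pulses whose width carries
#' certainty information.
#'
#' @param membrane membrane potential at the current step.
#' @param theta_prev threshold at the previous step.
#' @return binary output.
#' @examples
#' soma_compare(201, 200)  # 1
#' soma_compare(200, 200)  # 0 (strict inequality)
#' @export
soma_compare <- function(membrane, theta_prev) {
  stopifnot(membrane >= 0, theta_prev >= 0)
  as.integer(membrane > theta_prev)
}

#' Homeostatic threshold update
#'
#' The threshold rises by `theta_rise` at every spiking step (frequency
#' adaptation) and falls by `theta_fall` when the membrane potential returns
#' to zero (clamped at zero below). At equilibrium under repeated noiseless
#' presentations the two balance, giving output pulses of about
#' `theta_fall / theta_rise` steps.
#'
#' @param theta_prev previous threshold.
#' @param membrane_now membrane potential at the current step.
#' @param membrane_prev membrane potential at the previous step.
#' @param params a [skan_params()] object.
#' @return integer threshold.
#' @examples
#' p <- skan_params(2)                    # theta_rise 80, theta_fall 200
#' threshold_update(1000, 1200, 900, p)   # 1080
#' threshold_update(1000, 0, 150, p)      # 800
#' threshold_update(100, 0, 150, p)       # 0 (clamped)
#' @export
threshold_update <- function(theta_prev, membrane_now, membrane_prev, params) {
  stopifnot(theta_prev >= 0, membrane_now >= 0, membrane_prev >= 0)
  if (membrane_now > theta_prev) {
    as.integer(theta_prev + params$theta_rise)
  } else if (membrane_now == 0L && membrane_prev > 0L) {
    max(as.integer(theta_prev - params$theta_fall), 0L)
  } else {
    as.integer(theta_prev)
  }
}

#' Fresh neuron state
#'
#' All kernels idle (`p = 0`, `r = 0`), slopes drawn independently and
#' uniformly from the integer range `params$dr_init` using the current R
#' random number generator, threshold at `theta_init`, output low.
#'
#' @param params a [skan_params()] object.
#' @param dr optional integer vector of initial slopes (overrides the random
#'   draw; recycled to `n_inputs`).
#' @return an object of class `skan_state`: list with `p`, `r`, `dr`
#'   (length-`n_inputs` integer vectors), scalars `theta` and `s`.
#' @examples
#' set.seed(1)
#' st <- neuron_state(skan_params(2))
#' st$dr  # two values in [100, 200]
#' @export
neuron_state <- function(params, dr = NULL) {
  n <- params$n_inputs
  if (is.null(dr)) {
    dr <- as.integer(round(runif(n, params$dr_init[1], params$dr_init[2])))
  } else {
    dr <- rep_len(as.integer(dr), n)
  }
  dr <- pmin(pmax(dr, params$dr_floor), params$dr_max)
  st <- list(p = integer(n), r = integer(n), dr = dr,
             theta = params$theta_init, s = 0L)
  class(st) <- "skan_state"
  st
}

#' Advance a single neuron by one time step
#'
#' Applies, in this order: (a) flag update from the current input and the
#' registered flags and accumulators; (b) kernel accumulate with the new
#' flags, and slope adaptation from the registered flags and output; (c)
#' membrane summation; (d) soma comparison against the registered threshold;
#' (e) threshold update. Apart from the accumulator integrating the fresh
#' flag, every read refers to the state before (a).
#'
#' This is the reference implementation; long simulations run through the
#' compiled engine inside [skan()], which is verified against this function.
#'
#' @param state a `skan_state` object (see [neuron_state()]).
#' @param u binary input vector, one element per channel.
#' @param params a [skan_params()] object.
#' @return the updated `skan_state`.
#' @examples
#' p <- skan_params(2, theta_init = 0)
#' st <- neuron_state(p, dr = c(100, 100))
#' st <- neuron_step(st, c(1, 1), p)  # spikes arrive: r = 100 each, s = 1
#' st$s
#' @export
neuron_step <- function(state, u, params) {
  if (length(u) != params$n_inputs)
    stop("input vector length must equal n_inputs")
  p_new <- kernel_flag_update(u, state$p, state$r, params$w)
  acc <- kernel_accumulate(state$r, state$dr, p_new, state$s, params,
                           p_prev = state$p)
  mem_prev <- sum(state$r)
  mem <- sum(acc$r)
  s_new <- soma_compare(mem, state$theta)
  theta_new <- threshold_update(state$theta, mem, mem_prev, params)
  state$p <- p_new
  state$r <- acc$r
  state$dr <- acc$dr
  state$theta <- theta_new
  state$s <- s_new
  state
}

#' @export
print.skan_state <- function(x, ...) {
  cat("SKAN neuron state\n")
  cat("  p:  ", paste(x$p, collapse = " "), "\n")
  cat("  r:  ", paste(x$r, collapse = " "), "\n")
  cat("  dr: ", paste(x$dr, collapse = " "), "\n")
  cat("  theta:", x$theta, " s:", x$s, "\n")
  invisible(x)
}
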