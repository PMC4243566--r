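# Competitive layer: neurons share the input channels and a single global
# decaying inhibitory counter. While the counter is non-zero no neuron may
# initiate an output pulse (it may continue one already in progress), and
# threshold adaptation is gated so that only the neuron that triggered the
# inhibition adapts. The reference stepper below mirrors the compiled engine.

#' Fresh network state
#'
#' A layer of neurons with independent random initial slopes and a quiescent
#' inhibition counter. Slopes are stored as an `n_inputs x n_neurons` integer
#' matrix; the random heterogeneity is what lets different neurons win
#' different patterns.
#'
#' @param params a [skan_params()] object (shared by all neurons).
#' @param net a [net_params()] object.
#' @param dr optional `n_inputs x n_neurons` matrix of initial slopes.
#' @return an object of class `skan_net_state`: matrices `p`, `r`, `dr`
#'   (channels by neurons), integer vectors `theta`, `s`, scalar `inh`.
#' @examples
#' set.seed(1)
#' ns <- network_state(skan_params(2), net_params(2))
#' dim(ns$dr)
#' @export
network_state <- function(params, net, dr = NULL) {
  nc <- params$n_inputs
  nn <- net$n_neurons
  if (is.null(dr)) {
    dr <- matrix(as.integer(round(runif(nc * nn, params$dr_init[1],
                                        params$dr_init[2]))), nc, nn)
  } else {
    dr <- matrix(as.integer(dr), nc, nn)
  }
  dr[] <- pmin(pmax(dr, params$dr_floor), params$dr_max)
  st <- list(p = matrix(0L, nc, nn), r = matrix(0L, nc, nn), dr = dr,
             theta = rep(params$theta_init, nn), s = integer(nn), inh = 0L)
  class(st) <- "skan_net_state"
  st
}

#' Global inhibition update
#'
#' The inhibition counter acts as a peak detector on the OR of all neuron
#' outputs: held at `inh_max` for the full duration of any output pulse, then
#' decaying by `inh_decay` per step until it reaches zero, at which point any
#' neuron may spike again.
#'
#' @param inh_prev previous counter value.
#' @param any_spike binary: is any neuron's output high this step?
#' @param net a [net_params()] object.
#' @return integer counter value.
#' @examples
#' np <- net_params(2)
#' inhibition_update(37, 1, np)  # reloaded to 100
#' inhibition_update(50, 0, np)  # 49
#' inhibition_update(0, 0, np)   # 0
#' @export
inhibition_update <- function(inh_prev, any_spike, net) {
  stopifnot(inh_prev >= 0, inh_prev <= net$inh_max, any_spike %in% c(0L, 1L))
  if (any_spike == 1L) net$inh_max else max(as.integer(inh_prev - net$inh_decay), 0L)
}

#' Advance a competitive layer by one time step
#'
#' Kernels of every neuron update exactly as in [neuron_step()]. The output
#' rule is gated: neuron `n` emits `s_n(t) = 1` only if its membrane exceeds
#' its threshold *and* either the inhibition counter was zero at `t - 1` or
#' the neuron itself was already spiking (a pulse in progress is never cut).
#' The threshold rises only under the same gate, and falls either when the
#' membrane returns to zero with inhibition clear, or at the falling edge of
#' the neuron's own pulse while inhibition is active — so a losing neuron's
#' threshold is untouched by patterns another neuron answered. Finally the
#' inhibition counter updates from the OR of the new outputs, becoming
#' effective at the next step.
#'
#' With `inh_max = 0` the counter is identically zero and a single-neuron
#' network reproduces [neuron_step()] trajectories exactly.
#'
#' @param state a `skan_net_state` object (see [network_state()]).
#' @param u binary input vector shared by all neurons.
#' @param params a [skan_params()] object.
#' @param net a [net_params()] object.
#' @return the updated `skan_net_state`.
#' @export
network_step <- function(state, u, params, net) {
  if (length(u) != params$n_inputs)
    stop("input vector length must equal n_inputs")
  if (ncol(state$p) != net$n_neurons)
    stop("state neuron count does not match net_params")
  inh_prev <- state$inh
  s_new <- integer(net$n_neurons)
  for (n in seq_len(net$n_neurons)) {
    s_prev <- state$s[n]
    p_new <- kernel_flag_update(u, state$p[, n], state$r[, n], params$w)
    acc <- kernel_accumulate(state$r[, n], state$dr[, n], p_new,
                             s_prev, params, p_prev = state$p[, n])
    mem_prev <- sum(state$r[, n])
    mem <- sum(acc$r)
    gate <- inh_prev == 0L || s_prev == 1L
    sn <- if (mem > state$theta[n] && gate) 1L else 0L
    theta <- state$theta[n]
    if (sn == 1L) {
      theta <- theta + params$theta_rise
    } else if ((mem == 0L && mem_prev > 0L && inh_prev == 0L) ||
               (s_prev == 1L && inh_prev > 0L)) {
      theta <- max(theta - params$theta_fall, 0L)
    }
    state$p[, n] <- p_new
    state$r[, n] <- acc$r
    state$dr[, n] <- acc$dr
    state$theta[n] <- as.integer(theta)
    s_new[n] <- sn
  }
  state$s <- s_new
  state$inh <- inhibition_update(inh_prev, as.integer(any(s_new == 1L)), net)
  state
}

#' @export
print.skan_net_state <- function(x, ...) {
  cat(sprintf("SKAN network state: %d neuron(s) x %d channel(s), inh = %d\n",
              ncol(x$p), nrow(x$p), x$inh))
  cat("  theta:", paste(x$theta, collapse = " "), " s:",
      paste(x$s, collapse = " "), "\n")
  invisible(x)
}
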