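#' Neuron parameter set
#'
#' Bundles the constants governing a single neuron: the kernel peak height
#' (synaptic weight) `w`, the slope-adaptation increment `ddr`, the slope
#' saturation bounds, and the homeostatic threshold increments. Defaults are
#' the reference values used for all headline experiments: `w = 10000`,
#' `ddr = 1`, `dr_max = 400`, initial slopes drawn uniformly from
#' `[100, 200]` (i.e. `100 * (1 + rand)`), `theta_rise = 40 * n_inputs` and
#' `theta_fall = 100 * n_inputs`.
#'
#' All values are non-negative integers: with integer parameters every state
#' variable stays integer forever, so simulations are bit-exact reproducible.
#'
#' @param n_inputs number of input channels.
#' @param w kernel peak height in potential units; the accumulator ramps up
#'   until it exceeds `w`, then back down to zero.
#' @param ddr slope increment applied per time step while the back-propagating
#'   output pulse is high.
#' @param dr_max slope saturation; must satisfy `dr_max < w / PW` for the
#'   pattern width in use (see [validate_params()]).
#' @param dr_floor slope lower bound, at least 1 so a kernel can never freeze
#'   mid-ramp; defaults to `ddr`.
#' @param dr_init length-2 integer vector, bounds of the randomized initial
#'   slope (uniform, inclusive).
#' @param theta_rise threshold increment per spiking step.
#' @param theta_fall threshold decrement when the membrane returns to zero.
#' @param theta_init initial threshold; 0 guarantees the very first
#'   presentation elicits output so adaptation can start.
#' @return an object of class `skan_params` (a named list).
#' @seealso [net_params()], [validate_params()], [skan()]
#' @examples
#' p <- skan_params(n_inputs = 2)
#' p$theta_rise  # 40 * 2
#' @export
skan_params <- function(n_inputs,
                        w = 10000L,
                        ddr = 1L,
                        dr_max = 400L,
                        dr_floor = ddr,
                        dr_init = c(100L, 200L),
                        theta_rise = 40L * n_inputs,
                        theta_fall = 100L * n_inputs,
                        theta_init = 0L) {
  p <- list(n_inputs = as.integer(n_inputs), w = as.integer(w),
            ddr = as.integer(ddr), dr_max = as.integer(dr_max),
            dr_floor = as.integer(dr_floor),
            dr_init = as.integer(dr_init),
            theta_rise = as.integer(theta_rise),
            theta_fall = as.integer(theta_fall),
            theta_init = as.integer(theta_init))
  if (p$n_inputs < 1L) stop("n_inputs must be >= 1")
  vals <- unlist(p)
  if (anyNA(vals) || any(vals < 0L)) stop("all parameters must be non-negative integers")
  if (p$dr_floor < 1L) stop("dr_floor must be >= 1")
  if (length(p$dr_init) != 2L || p$dr_init[1] > p$dr_init[2])
    stop("dr_init must be c(lo, hi) with lo <= hi")
  if (p$dr_init[2] > p$dr_max || p$dr_max > p$w)
    stop("need dr_init_hi <= dr_max <= w")
  class(p) <- "skan_params"
  p
}

#' @export
print.skan_params <- function(x, ...) {
  cat("SKAN neuron parameters (", x$n_inputs, " input channels)\n", sep = "")
  cat(sprintf("  w: %d  ddr: %d  dr in [%d, %d], init U[%d, %d]\n",
              x$w, x$ddr, x$dr_floor, x$dr_max, x$dr_init[1], x$dr_init[2]))
  cat(sprintf("  theta: rise %d / fall %d, init %d\n",
              x$theta_rise, x$theta_fall, x$theta_init))
  invisible(x)
}

#' Network (competition) parameter set
#'
#' Parameters of the shared global inhibitory signal that turns a layer of
#' neurons with common inputs into a winner-take-all classifier. Whenever any
#' neuron's output is high the inhibition counter is held at `inh_max`
#' (peak-detector behaviour); afterwards it decays by `inh_decay` per step,
#' and while it is non-zero no neuron may *initiate* an output pulse.
#'
#' The reference rule of thumb is `inh_max / inh_decay = min(initial slope)`,
#' i.e. 100 / 1 with the default [skan_params()], so inhibition outlasts any
#' competitor kernel still ramping at its initial slope.
#'
#' @param n_neurons number of neurons in the layer.
#' @param inh_max inhibition reload value.
#' @param inh_decay per-step decay, at least 1.
#' @return an object of class `skan_net_params`.
#' @examples
#' net_params(2)
#' @export
net_params <- function(n_neurons = 1L, inh_max = 100L, inh_decay = 1L) {
  np <- list(n_neurons = as.integer(n_neurons),
             inh_max = as.integer(inh_max),
             inh_decay = as.integer(inh_decay))
  if (np$n_neurons < 1L) stop("n_neurons must be >= 1")
  if (np$inh_max < 0L) stop("inh_max must be >= 0")
  if (np$inh_decay < 1L) stop("inh_decay must be >= 1")
  class(np) <- "skan_net_params"
  np
}

#' @export
print.skan_net_params <- function(x, ...) {
  cat(sprintf("SKAN network: %d neuron(s), inh_max %d, inh_decay %d\n",
              x$n_neurons, x$inh_max, x$inh_decay))
  invisible(x)
}

#' Check parameters against the pattern width
#'
#' The slope saturation must satisfy `dr_max < w / PW`: otherwise the kernel
#' triggered by the first spike of a pattern can return to zero before the
#' last spike of the pattern arrives, and the kernels can no longer converge
#' under a common output pulse. With network parameters supplied, the
#' inhibition rule of thumb `inh_max / inh_decay >= min initial slope` is also
#' checked (as a warning, not a violation).
#'
#' @param params a [skan_params()] object.
#' @param PW maximal pattern width in time steps (`>= 0`; the bound is vacuous
#'   at `PW = 0`).
#' @param net optional [net_params()] object.
#' @return character vector of messages, each prefixed `"violation:"` or
#'   `"warning:"`; empty when everything passes.
#' @examples
#' validate_params(skan_params(2), PW = 20)          # character(0)
#' validate_params(skan_params(2, dr_max = 500), 20) # slope bound violated
#' @export
validate_params <- function(params, PW, net = NULL) {
  stopifnot(inherits(params, "skan_params"), PW >= 0)
  out <- character(0)
  if (PW > 0 && params$dr_max >= params$w / PW)
    out <- c(out, sprintf(
      "violation: dr_max (%d) must be < w/PW (%g); kernels cannot span the pattern",
      params$dr_max, params$w / PW))
  if (!is.null(net)) {
    stopifnot(inherits(net, "skan_net_params"))
    if (net$n_neurons > 1L &&
        net$inh_max / net$inh_decay < params$dr_init[1])
      out <- c(out, sprintf(
        "warning: inh_max/inh_decay (%g) below min initial slope (%d); inhibition may expire before competitors finish ramping",
        net$inh_max / net$inh_decay, params$dr_init[1]))
  }
  out
}

#' Connection count of a competitive layer
#'
#' Total connections of a layer: each neuron has one line per input channel
#' plus one output line to and one inhibition line from the global OR gate,
#' i.e. `(n_inputs + 2) * n_neurons`. Linear, not combinatorial, in the number
#' of neurons, because the only inter-neuron coupling is the single shared
#' inhibitory bit.
#'
#' @param n_inputs input channels per neuron.
#' @param n_neurons neurons in the layer.
#' @return integer connection count.
#' @examples
#' connection_count(2, 2)  # 8
#' @export
connection_count <- function(n_inputs, n_neurons) {
  stopifnot(n_inputs >= 0, n_neurons >= 0)
  as.integer((n_inputs + 2) * n_neurons)
}
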