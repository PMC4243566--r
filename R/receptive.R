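# Temporal receptive-field probing. A probe freezes the learnt parameters
# (slopes and threshold), presents one pattern to an idle copy of the neuron,
# and integrates the supra-threshold response:
#   RF = sum_t (membrane(t) - theta) * s(t).
# For a two-input neuron the probe pattern is a single inter-spike interval
# tau, so the receptive field is a curve over tau whose argmax is the ISI the
# neuron expects and whose support is the range of ISIs it tolerates. Probes
# are pure: the fitted object is never modified.

# Accepts a skan fit (with `neuron` selecting a column), a skan_net_state (+
# params), or a bare list(dr, theta, params). Returns list(dr, theta, params).
.frozen_snapshot <- function(object, params = NULL, neuron = 1L,
                             check_idle = TRUE) {
  if (inherits(object, "skan")) {
    if (check_idle && any(object$state$p[, neuron] != 0L))
      stop("probe undefined mid-pattern: snapshot has active kernels")
    list(dr = object$state$dr[, neuron], theta = object$state$theta[neuron],
         params = object$params)
  } else if (inherits(object, "skan_net_state")) {
    if (is.null(params)) stop("supply params with a raw network state")
    if (check_idle && any(object$p[, neuron] != 0L))
      stop("probe undefined mid-pattern: snapshot has active kernels")
    list(dr = object$dr[, neuron], theta = object$theta[neuron],
         params = params)
  } else if (is.list(object) && all(c("dr", "theta", "params") %in%
                                    names(object))) {
    object[c("dr", "theta", "params")]
  } else {
    stop("cannot interpret object as a neuron snapshot")
  }
}

# steps from kernel trigger (inclusive) to its peak: ceil(w / dr)
.peak_steps <- function(dr, w) (w + as.integer(dr) - 1L) %/% as.integer(dr)

# run one frozen presentation; returns engine output with membrane trace.
# An NA offset means the channel receives no spike (missing target spike).
.frozen_run <- function(snap, offsets, record_r = FALSE) {
  p <- snap$params
  nc <- p$n_inputs
  stopifnot(length(offsets) == nc)
  have <- !is.na(offsets)
  dur <- max(c(0L, offsets[have])) + 2L * max(.peak_steps(snap$dr, p$w)) + 4L
  st <- list(p = matrix(0L, nc, 1L), r = matrix(0L, nc, 1L),
             dr = matrix(as.integer(snap$dr), nc, 1L),
             theta = as.integer(snap$theta), s = 0L, inh = 0L)
  class(st) <- "skan_net_state"
  ev <- data.frame(time = as.integer(offsets[have]),
                   channel = seq_len(nc)[have])
  .run_block(st, ev, dur, p, net_params(1L, inh_max = 0L),
             adapt = FALSE, record_mem = TRUE, record_r = record_r)
}

#' Probe a frozen neuron with one pattern
#'
#' Presents the pattern once with all adaptation disabled (slopes and
#' threshold held fixed) and returns the summed supra-threshold response
#' `sum_t (membrane - theta) * s`. Zero means the pattern lies outside the
#' neuron's receptive field. The snapshot must be taken between
#' presentations, with all kernels idle.
#'
#' @param object a [skan()] fit, a `skan_net_state`, or a list with elements
#'   `dr`, `theta`, `params`.
#' @param pattern a [spike_pattern()] (or bare integer offset vector).
#' @param params required when `object` is a raw network state.
#' @param neuron neuron to probe.
#' @return numeric response (potential-time units, `>= 0`).
#' @export
probe_response <- function(object, pattern, params = NULL, neuron = 1L) {
  snap <- .frozen_snapshot(object, params, neuron)
  off <- if (inherits(pattern, "skan_pattern")) pattern$offsets
         else as.integer(pattern)
  run <- .frozen_run(snap, off)
  sum((as.numeric(run$membrane[1, ]) - snap$theta) * run$s[1, ])
}

#' Temporal receptive field of a two-input neuron
#'
#' Evaluates [probe_response()] at every integer inter-spike interval
#' `tau` in `[-PW, PW]` (positive `tau`: channel 2 lags channel 1). The
#' argmax is the ISI the neuron expects; ties resolve to the smallest
#' `|tau|`, negative before positive. The boundaries are the smallest and
#' largest `tau` with a positive response.
#'
#' @param object,params,neuron as in [probe_response()].
#' @param PW half-width of the ISI grid.
#' @return a data.frame of class `skan_rf` with columns `tau`, `value` and
#'   attributes `argmax` and `boundaries`.
#' @examples
#' snap <- list(dr = c(200, 200), theta = 15000, params = skan_params(2))
#' rf <- rf_curve(snap, PW = 10)
#' attr(rf, "argmax")  # 0: equal slopes expect simultaneous spikes
#' @export
rf_curve <- function(object, PW = 20L, params = NULL, neuron = 1L) {
  snap <- .frozen_snapshot(object, params, neuron)
  if (snap$params$n_inputs != 2L)
    stop("rf_curve() needs a two-input neuron; use kernel_peak_alignment() for higher dimensions")
  taus <- seq.int(-PW, PW)
  vals <- vapply(taus, function(tau)
    probe_response(snap, c(max(0L, -tau), max(0L, tau))), numeric(1))
  pos <- taus[vals > 0]
  mx <- max(vals)
  cand <- taus[vals == mx]
  argmax <- cand[order(abs(cand), cand)][1]
  out <- data.frame(tau = taus, value = vals)
  attr(out, "argmax") <- argmax
  attr(out, "boundaries") <- if (length(pos)) range(pos) else c(NA_integer_, NA_integer_)
  attr(out, "theta") <- snap$theta
  class(out) <- c("skan_rf", "data.frame")
  out
}

#' @export
print.skan_rf <- function(x, ...) {
  b <- attr(x, "boundaries")
  cat(sprintf("Temporal receptive field over tau in [%d, %d]\n",
              min(x$tau), max(x$tau)))
  cat(sprintf("  argmax: %d   support: [%s, %s]   mass: %g\n",
              attr(x, "argmax"), b[1], b[2], sum(x$value)))
  invisible(x)
}

#' @export
plot.skan_rf <- function(x, ...) {
  plot(x$tau, x$value, type = "h", xlab = "inter-spike interval (steps)",
       ylab = "receptive field response", ...)
  abline(v = attr(x, "argmax"), col = "red", lty = 2)
  b <- attr(x, "boundaries")
  if (!anyNA(b)) abline(v = b, col = "pink")
  invisible(x)
}

#' Kernel peak alignment on a clean target
#'
#' Presents the noiseless target once with adaptation frozen (kernels reset
#' to idle, slopes and threshold held at their learnt values) and records the
#' first time each channel's kernel attains its maximum. A perfectly trained
#' neuron has all peaks coincide; the root-mean-square of the mean-centred
#' peak times measures how far training ended from the target. Channels
#' whose kernels never triggered (missing spike in the target) are excluded
#' with a warning.
#'
#' @param object,params,neuron as in [probe_response()].
#' @param target a [spike_pattern()] (the clean target).
#' @return list with `peak_times` (named by channel) and `rms`.
#' @examples
#' snap <- list(dr = c(200, 200), theta = 0, params = skan_params(2))
#' kernel_peak_alignment(snap, spike_pattern(c(0, 0), 0))$rms  # 0
#' @export
kernel_peak_alignment <- function(object, target, params = NULL, neuron = 1L) {
  snap <- .frozen_snapshot(object, params, neuron, check_idle = FALSE)
  off <- if (inherits(target, "skan_pattern")) target$offsets
         else as.integer(target)
  run <- .frozen_run(snap, off, record_r = TRUE)
  rtr <- run$r_trace[, 1L, , drop = TRUE]
  if (is.null(dim(rtr))) rtr <- matrix(rtr, nrow = 1L)
  peaks <- apply(rtr, 1L, function(r) {
    if (max(r) == 0L) NA_integer_ else which.max(r)
  })
  if (anyNA(peaks)) {
    warning(sprintf("channel(s) %s never triggered; excluded from alignment",
                    paste(which(is.na(peaks)), collapse = ", ")))
    peaks <- peaks[!is.na(peaks)]
  }
  rms <- if (length(peaks)) sqrt(mean((peaks - mean(peaks))^2)) else NA_real_
  list(peak_times = peaks, rms = rms)
}

#' Learnt-pattern error as a function of spike signal-to-noise ratio
#'
#' For each signal-to-noise ratio and input dimension, trains fresh neurons
#' on streams in which each target spike survives with probability
#' `a / (a + b)` and background spikes arrive at rate `b / (a + b)` per
#' channel per period (so the mean total spike count stays at one per channel
#' per period), then measures the kernel peak-alignment RMS error against the
#' clean target. Error grows with the noise fraction and with the channel
#' count.
#'
#' @param snr character vector of ratios `"a:b"` (e.g. `"1:0"`, `"1:1"`,
#'   `"1:2"`).
#' @param dims input channel counts to test.
#' @param replicates fresh neuron/pattern pairs per cell.
#' @param n_presentations training presentations per replicate.
#' @param PW,T pattern width and presentation period.
#' @return data.frame with columns `snr`, `dimension`, `mean_rms`,
#'   `median_rms`, `n`. The median is reported alongside because heavy noise
#'   occasionally collapses one channel's slope toward its floor (the kernel
#'   then outlasts the presentation period), which inflates the mean of a
#'   cell far beyond its typical replicate.
#' @export
rms_vs_snr <- function(snr = c("1:0", "1:1", "1:2"), dims = c(2L, 4L),
                       replicates = 8L, n_presentations = 500L,
                       PW = 20L, T = 400L) {
  parts <- strsplit(snr, ":", fixed = TRUE)
  stopifnot(all(lengths(parts) == 2L))
  grid <- expand.grid(snr = snr, dimension = dims,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    ab <- as.numeric(parts[[match(grid$snr[g], snr)]])
    p_signal <- ab[1] / sum(ab)
    noise_rate <- ab[2] / sum(ab)
    nc <- grid$dimension[g]
    rmses <- vapply(seq_len(replicates), function(rep) {
      target <- make_target_pattern(nc, PW)
      st <- build_sequence(list(target), 1, n_presentations, T = T,
                           p_signal = p_signal, noise_rate = noise_rate)
      fit <- skan(st, params = skan_params(nc))
      kernel_peak_alignment(fit, target)$rms
    }, numeric(1))
    data.frame(snr = grid$snr[g], dimension = nc,
               mean_rms = mean(rmses, na.rm = TRUE),
               median_rms = stats::median(rmses, na.rm = TRUE),
               n = sum(!is.na(rmses)))
  })
  do.call(rbind, res)
}
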