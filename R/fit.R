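#' Fit adaptive-kernel spiking neurons to a spike stream
#'
#' Runs a layer of `n_neurons` kernel-adapting neurons over a spike stream
#' with adaptation on: kernels ramp on input spikes, slopes adapt under the
#' back-propagating output pulse, thresholds adapt homeostatically, and (for
#' `n_neurons > 1`) a single global decaying inhibitory counter enforces
#' first-spike competition. The learning is unsupervised; any labels in the
#' stream are used only to score per-presentation verdicts.
#'
#' The "fitted coefficients" of the model are the per-channel kernel slopes
#' (which encode the learnt spike-time pattern: a steeper kernel peaks
#' earlier) and the per-neuron threshold (which encodes confidence: the
#' higher the threshold, the narrower the receptive field).
#'
#' @param stream a `skan_stream` (see [build_sequence()],
#'   [drifting_isi_stream()], [read_events()]).
#' @param n_neurons number of competing neurons.
#' @param params a [skan_params()]; defaults to the reference values for the
#'   stream's channel count.
#' @param net a [net_params()]; defaults to the reference inhibition for
#'   `n_neurons > 1` and to no inhibition (`inh_max = 0`) for a single
#'   neuron, which reproduces the plain single-neuron update rules exactly.
#' @param state optional initial `skan_net_state` (otherwise drawn with
#'   [network_state()] from the current RNG).
#' @param trace record per-step membrane, threshold, inhibition and kernel
#'   traces (memory grows with `duration`; keep streams short when tracing).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference stepper,
#'   identical results, much slower).
#' @return an object of class `skan` with components `state` (final), `init`
#'   (initial state), `s` (neuron-by-step binary output matrix), `verdicts`
#'   (per-presentation scoring when the stream is labelled), `converged_at`
#'   (first presentation ending a correct window, or `NA`), and the inputs.
#' @seealso [predict.skan()], [rf_curve()], [kernel_peak_alignment()]
#' @examples
#' set.seed(42)
#' pat <- make_target_pattern(2, 20)
#' st <- build_sequence(list(pat), 1, 60, T = 400)
#' fit <- skan(st)
#' fit
#' coef(fit)
#' @export
skan <- function(stream, n_neurons = 1L, params = NULL, net = NULL,
                 state = NULL, trace = FALSE, engine = c("cpp", "r")) {
  stopifnot(inherits(stream, "skan_stream"))
  engine <- match.arg(engine)
  if (is.null(params)) params <- skan_params(stream$n_channels)
  if (params$n_inputs != stream$n_channels)
    stop("params$n_inputs does not match the stream's channel count")
  if (is.null(net)) {
    net <- if (n_neurons == 1L) net_params(1L, inh_max = 0L)
           else net_params(n_neurons)
  }
  if (net$n_neurons != n_neurons) stop("net$n_neurons does not match n_neurons")
  PW <- .stream_pw(stream)
  if (!is.null(PW)) {
    msgs <- validate_params(params, PW, net)
    for (m in msgs) warning(m, call. = FALSE)
  }
  if (is.null(state)) state <- network_state(params, net)
  init <- state
  res <- .run_block(state, stream$events, stream$duration, params, net,
                    adapt = TRUE, record_mem = trace, record_r = trace,
                    engine = engine)
  fit <- list(call = match.call(), params = params, net = net,
              stream = stream, init = init, state = res$state, s = res$s,
              trace = if (trace) res[c("membrane", "theta_trace",
                                       "inh_trace", "r_trace")])
  if (!is.null(stream$labels) && "pattern_id" %in% names(stream$labels)) {
    fit$verdicts <- .score_presentations(res$s, stream$labels$onset, stream$T,
                                         stream$labels$pattern_id)
    if (n_neurons > 1L)
      fit$converged_at <- detect_convergence(fit$verdicts,
                                             stream$labels$pattern_id)
  }
  class(fit) <- "skan"
  fit
}

.stream_pw <- function(stream) {
  if (is.null(stream$patterns)) return(NULL)
  max(vapply(stream$patterns, function(p) p$PW, integer(1)))
}

#' @export
print.skan <- function(x, ...) {
  nn <- x$net$n_neurons
  cat(sprintf("Kernel-adapting spiking neuron fit: %d neuron(s), %d channel(s), %d steps\n",
              nn, x$params$n_inputs, ncol(x$s)))
  pulses <- vapply(seq_len(nn), function(n)
    length(.rising_edges(x$s[n, ], 0L)), integer(1))
  cat("  output pulses per neuron:", paste(pulses, collapse = " "), "\n")
  cat("  final threshold(s):", paste(x$state$theta, collapse = " "), "\n")
  if (!is.null(x$converged_at))
    cat("  converged at presentation:",
        if (is.na(x$converged_at)) "not converged" else x$converged_at, "\n")
  invisible(x)
}

#' @export
summary.skan <- function(object, ...) {
  nn <- object$net$n_neurons
  pw <- pulse_width_stats(object$s[1, ])
  out <- list(
    n_neurons = nn, n_channels = object$params$n_inputs,
    duration = ncol(object$s),
    coef = coef(object),
    dr_initial = object$init$dr,
    pulse_widths = lapply(seq_len(nn), function(n)
      pulse_width_stats(object$s[n, ])$widths),
    verdicts = object$verdicts,
    converged_at = object$converged_at)
  if (!is.null(object$verdicts)) {
    out$accuracy <- mean(object$verdicts$candidate_correct)
  }
  class(out) <- "summary.skan"
  out
}

#' @export
print.summary.skan <- function(x, ...) {
  cat(sprintf("SKAN fit summary: %d neuron(s), %d channel(s), %d steps\n",
              x$n_neurons, x$n_channels, x$duration))
  cat("Fitted coefficients (kernel slopes and threshold):\n")
  print(x$coef)
  cat("Initial slopes:\n")
  print(x$dr_initial)
  for (n in seq_len(x$n_neurons)) {
    wdt <- x$pulse_widths[[n]]
    cat(sprintf("Neuron %d: %d pulse(s)%s\n", n, length(wdt),
                if (length(wdt))
                  sprintf(", widths %d-%d (median %g)", min(wdt), max(wdt),
                          stats::median(wdt)) else ""))
  }
  if (!is.null(x$accuracy))
    cat(sprintf("Candidate-correct presentations: %.1f%%\n", 100 * x$accuracy))
  if (!is.null(x$converged_at))
    cat("Converged at presentation:",
        if (is.na(x$converged_at)) "not converged" else x$converged_at, "\n")
  invisible(x)
}

#' Fitted coefficients of a neuron layer
#'
#' @param object a [skan()] fit.
#' @param ... unused.
#' @return numeric matrix with one column per neuron: per-channel kernel
#'   slopes (`dr_1`, ...) and the threshold (`theta`).
#' @export
coef.skan <- function(object, ...) {
  m <- rbind(object$state$dr, theta = object$state$theta)
  rownames(m) <- c(paste0("dr_", seq_len(object$params$n_inputs)), "theta")
  colnames(m) <- paste0("neuron_", seq_len(object$net$n_neurons))
  m
}

#' Frozen-parameter prediction on a new stream
#'
#' Runs the fitted layer over `newdata` with all adaptation disabled (slopes
#' and thresholds held at their fitted values, kernels reset to idle), then
#' scores each presentation. Probing is side-effect free: the fit object is
#' unchanged.
#'
#' @param object a [skan()] fit.
#' @param newdata a `skan_stream`.
#' @param type `"verdict"` for the per-presentation scoring data.frame,
#'   `"class"` for the responding-neuron vector (`NA` when no neuron or more
#'   than one responded), `"response"` for the raw binary output matrix.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.skan <- function(object, newdata,
                         type = c("verdict", "class", "response"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "skan_stream"))
  frozen <- object$state
  frozen$p[] <- 0L
  frozen$r[] <- 0L
  frozen$s[] <- 0L
  frozen$inh <- 0L
  res <- .run_block(frozen, newdata$events, newdata$duration,
                    object$params, object$net, adapt = FALSE)
  if (type == "response") return(res$s)
  onsets <- if (!is.null(newdata$labels)) newdata$labels$onset
            else seq(0L, newdata$duration - 1L, by = newdata$T)
  ids <- if (!is.null(newdata$labels) &&
             "pattern_id" %in% names(newdata$labels))
    newdata$labels$pattern_id else rep(NA_integer_, length(onsets))
  v <- .score_presentations(res$s, onsets, newdata$T, ids)
  if (type == "verdict") v else v$neuron
}

#' Residual spike-timing errors of a two-channel fit
#'
#' For a two-input neuron the learnt pattern is summarised by the receptive
#' field's preferred inter-spike interval (ISI). Residuals are the observed
#' per-presentation ISIs of the training stream minus that preferred ISI —
#' the timing errors the fitted neuron attributes to noise.
#'
#' @param object a single-neuron, two-channel [skan()] fit.
#' @param ... unused.
#' @return numeric vector, one residual per presentation with both channels
#'   present (`NA` where a channel is missing).
#' @export
residuals.skan <- function(object, ...) {
  if (object$params$n_inputs != 2L || object$net$n_neurons != 1L)
    stop("residuals are defined for single-neuron, two-channel fits")
  pw <- .stream_pw(object$stream)
  if (is.null(pw)) pw <- object$stream$T %/% 4L
  rf <- rf_curve(object, PW = pw)
  obs <- .observed_isis(object$stream)
  obs - attr(rf, "argmax")
}

# first-spike ISI (channel 2 minus channel 1) per presentation
.observed_isis <- function(stream) {
  if (!is.null(stream$labels) && "isi" %in% names(stream$labels))
    return(stream$labels$isi)
  onsets <- stream$labels$onset
  ev <- stream$events
  idx <- findInterval(ev$time, onsets)
  vapply(seq_along(onsets), function(k) {
    e <- ev[idx == k, , drop = FALSE]
    t1 <- e$time[e$channel == 1L]
    t2 <- e$time[e$channel == 2L]
    if (!length(t1) || !length(t2)) return(NA_real_)
    as.numeric(min(t2) - min(t1))
  }, numeric(1))
}

#' Simulate presentations of the learnt pattern
#'
#' Generates new spike streams from the fitted model: the learnt pattern is
#' the per-channel offset vector that makes all kernel peaks coincide (a
#' steeper kernel peaks earlier, so its spike must arrive later), optionally
#' perturbed by temporal jitter.
#'
#' @param object a [skan()] fit.
#' @param nsim number of streams.
#' @param seed optional RNG seed, as for [stats::simulate()].
#' @param n_presentations presentations per stream.
#' @param sigma temporal jitter standard deviation.
#' @param neuron which neuron's learnt pattern to present.
#' @param ... unused.
#' @return list of `skan_stream` objects (a single stream when `nsim = 1`).
#' @export
simulate.skan <- function(object, nsim = 1, seed = NULL,
                          n_presentations = 20L, sigma = 0, neuron = 1L, ...) {
  if (!is.null(seed)) set.seed(seed)
  off <- learned_offsets(object$state$dr[, neuron], object$params$w)
  pat <- spike_pattern(off, max(off))
  out <- lapply(seq_len(nsim), function(i)
    build_sequence(list(pat), 1, n_presentations, T = object$stream$T,
                   sigma = sigma))
  if (nsim == 1) out[[1]] else out
}

#' Spike-time offsets implied by kernel slopes
#'
#' A kernel triggered at time `t0` peaks `ceiling(w / dr)` steps later
#' (counting the trigger step). The learnt pattern of a neuron is the offset
#' vector that aligns all peaks: each channel's spike must arrive so that
#' its kernel peaks with the others (offsets shifted to start at zero).
#'
#' @param dr integer vector of kernel slopes.
#' @param w kernel peak height.
#' @return integer offset vector.
#' @examples
#' learned_offsets(c(400, 200), 10000)  # steep kernel's spike comes later
#' @export
learned_offsets <- function(dr, w) {
  ps <- (w + as.integer(dr) - 1L) %/% as.integer(dr)
  as.integer(max(ps) - ps)
}

#' Plot a fit: adaptation trace or receptive field
#'
#' With a recorded trace (see `trace` in [skan()]) plots membrane potential,
#' threshold and output pulses over time for one neuron, the classic picture
#' of threshold homeostasis (rising during each pulse, falling when the
#' membrane returns to zero). Without a trace, for a two-channel fit, plots
#' the temporal receptive field.
#'
#' @param x a [skan()] fit.
#' @param neuron neuron to display.
#' @param steps optional step range to display, e.g. `1:4000`.
#' @param ... passed to the underlying plot.
#' @export
plot.skan <- function(x, neuron = 1L, steps = NULL, ...) {
  if (!is.null(x$trace)) {
    mem <- x$trace$membrane[neuron, ]
    th <- x$trace$theta_trace[neuron, ]
    s <- x$s[neuron, ]
    if (is.null(steps)) steps <- seq_along(mem)
    tt <- steps
    op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
    on.exit(par(op))
    plot(tt, mem[steps], type = "l", xlab = "", ylab = "potential",
         main = sprintf("neuron %d", neuron), ...)
    lines(tt, th[steps], col = "red")
    legend("topleft", c("membrane", "threshold"), lty = 1,
           col = c("black", "red"), bty = "n", cex = 0.8)
    plot(tt, s[steps], type = "s", xlab = "time step", ylab = "output s",
         yaxt = "n")
    axis(2, at = c(0, 1))
  } else if (x$params$n_inputs == 2L) {
    pw <- .stream_pw(x$stream)
    if (is.null(pw)) pw <- 20L
    plot(rf_curve(x, PW = pw, neuron = neuron), ...)
  } else {
    stop("nothing to plot: refit with trace = TRUE, or use rf_curve() for 2-channel fits")
  }
  invisible(x)
}
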