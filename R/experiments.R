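# Experiment harnesses: commonest-pattern selection, 1-to-1 classification
# convergence, hidden-process tracking, and output pulse statistics. Every
# experiment is a pure function of its configuration and the RNG state, so
# set.seed() reproduces it bit-exactly. Replicate counts default to
# desk-scale values; raise them for full-scale sweeps.

# Score every presentation of an output matrix: which neurons emitted rising
# edges in each period, how many, and whether the presentation is
# "candidate-correct" (exactly one neuron, exactly one rising edge).
.score_presentations <- function(s_mat, onsets, T, pattern_ids,
                                 s_before = NULL) {
  nn <- nrow(s_mat)
  np <- length(onsets)
  if (is.null(s_before)) s_before <- integer(nn)
  prev <- cbind(s_before, s_mat[, -ncol(s_mat), drop = FALSE])
  edge <- s_mat == 1L & prev == 0L
  # map columns (1-based step t-1 = 0-based time) to presentations
  grp <- findInterval(seq_len(ncol(s_mat)) - 1L, onsets)
  E <- vapply(seq_len(np), function(k)
    as.integer(rowSums(edge[, grp == k, drop = FALSE])), integer(nn))
  E <- matrix(E, nrow = nn)
  n_active <- colSums(E >= 1L)
  total <- colSums(E)
  cc <- n_active == 1L & total == 1L
  winner <- ifelse(n_active == 1L, max.col(t(E >= 1L), "first"), NA_integer_)
  data.frame(presentation = seq_len(np),
             pattern_id = pattern_ids,
             neuron = as.integer(winner),
             n_active = as.integer(n_active),
             n_edges = as.integer(total),
             candidate_correct = cc)
}

#' Score one presentation period of logged outputs
#'
#' A presentation is *candidate-correct* when exactly one neuron emitted
#' exactly one rising edge during the period: a single clean answer. More
#' than one responding neuron, or repeated output spikes from one neuron,
#' both disqualify it.
#'
#' @param s_block binary output matrix for one period, neurons by steps (a
#'   vector is taken as a single neuron).
#' @param s_before per-neuron output value at the step preceding the block
#'   (so a pulse already in progress is not counted as a new edge).
#' @return list with `neurons` (indices that emitted at least one edge),
#'   `edges` (per-neuron rising-edge counts), `candidate_correct`, and
#'   `neuron` (the single responder, or `NA`).
#' @examples
#' classify_presentation(rbind(c(0, 1, 1, 0), c(0, 0, 0, 0)))
#' @export
classify_presentation <- function(s_block, s_before = NULL) {
  if (is.vector(s_block)) s_block <- matrix(s_block, nrow = 1L)
  nn <- nrow(s_block)
  if (is.null(s_before)) s_before <- integer(nn)
  edges <- vapply(seq_len(nn), function(n)
    length(.rising_edges(s_block[n, ], s_before[n])), integer(1))
  act <- which(edges >= 1L)
  list(neurons = act, edges = edges,
       candidate_correct = length(act) == 1L && sum(edges) == 1L,
       neuron = if (length(act) == 1L) act else NA_integer_)
}

#' Detect classifier convergence
#'
#' The network has converged when `window` consecutive presentations are each
#' candidate-correct and the induced pattern-to-neuron map over the window is
#' consistent (the same pattern always answered by the same neuron) and
#' injective (no neuron claims two patterns). Returns the 1-based index of
#' the presentation that completes the first such window, or `NA`.
#'
#' @param verdicts data.frame from [classify_presentation()] scoring (needs
#'   columns `candidate_correct` and `neuron`), or a [skan()] fit's
#'   `verdicts` component.
#' @param labels per-presentation true pattern ids (defaults to the
#'   `pattern_id` column of `verdicts`).
#' @param window run length required, conventionally 20 (long enough that a
#'   correct run by chance is vanishingly unlikely).
#' @return integer index or `NA`.
#' @export
detect_convergence <- function(verdicts, labels = verdicts$pattern_id,
                               window = 20L) {
  stopifnot(is.data.frame(verdicts),
            all(c("candidate_correct", "neuron") %in% names(verdicts)),
            length(labels) == nrow(verdicts), window >= 1L)
  np <- nrow(verdicts)
  if (np < window) return(NA_integer_)
  cc <- verdicts$candidate_correct
  neuron <- verdicts$neuron
  for (k in window:np) {
    idx <- (k - window + 1L):k
    if (!all(cc[idx])) next
    map <- tapply(neuron[idx], labels[idx], function(x) length(unique(x)))
    if (any(map > 1L)) next                       # pattern answered by 2 neurons
    first <- tapply(neuron[idx], labels[idx], `[`, 1L)
    if (anyDuplicated(first)) next                # neuron claims 2 patterns
    return(k)
  }
  NA_integer_
}

#' Commonest-pattern selection experiment
#'
#' A single neuron is shown random sequences drawn from two fresh random
#' patterns `x` and `y` with probabilities `P(x)` and `1 - P(x)`. After the
#' sequence, the evaluation half (presentations `n/2 + 1` to `n`) determines
#' the outcome: `"x"` if the neuron spiked for at least one presentation of
#' `x` and none of `y`, symmetrically `"y"`, otherwise `"both"` or
#' `"neither"`. The selection probability of the commoner pattern rises with
#' `P(x)`, reaching certainty above `P(x) = 0.85`.
#'
#' @param p_x vector of presentation probabilities for pattern `x`
#'   (`>= 0.5`).
#' @param n_sims simulations per probability (fresh patterns and slopes
#'   each).
#' @param n_presentations sequence length.
#' @param n_channels,PW,T stimulus geometry.
#' @param params optional [skan_params()].
#' @return data.frame with one row per probability: counts of the four
#'   outcomes and `fraction_x`, plus attribute `"outcomes"` (per-simulation
#'   outcome matrix, simulations by probabilities).
#' @export
run_selection <- function(p_x = seq(0.5, 1, by = 0.1), n_sims = 50L,
                          n_presentations = 300L, n_channels = 4L,
                          PW = 20L, T = 400L, params = NULL) {
  stopifnot(all(p_x >= 0.5), all(p_x <= 1))
  if (is.null(params)) params <- skan_params(n_channels)
  net <- net_params(1L, inh_max = 0L)
  eval_from <- n_presentations %/% 2L + 1L
  outcomes <- matrix(NA_character_, n_sims, length(p_x),
                     dimnames = list(NULL, paste0("p", p_x)))
  for (j in seq_along(p_x)) {
    for (sim in seq_len(n_sims)) {
      pats <- list(make_target_pattern(n_channels, PW),
                   make_target_pattern(n_channels, PW))
      st <- build_sequence(pats, c(p_x[j], 1 - p_x[j]), n_presentations,
                           T = T)
      state <- network_state(params, net)
      res <- .run_block(state, st$events, st$duration, params, net)
      edges <- .rising_edges(res$s[1L, ], 0L)
      pres <- (edges - 1L) %/% as.integer(T) + 1L
      hit <- unique(st$labels$pattern_id[pres[pres >= eval_from]])
      outcomes[sim, j] <-
        if (all(c(1L, 2L) %in% hit)) "both"
        else if (1L %in% hit) "x"
        else if (2L %in% hit) "y"
        else "neither"
    }
  }
  tab <- t(apply(outcomes, 2L, function(o)
    c(x = sum(o == "x"), y = sum(o == "y"),
      both = sum(o == "both"), neither = sum(o == "neither"))))
  out <- data.frame(p_x = p_x, tab, fraction_x = tab[, "x"] / n_sims,
                    row.names = NULL)
  attr(out, "outcomes") <- outcomes
  out
}

#' Classification-convergence experiment
#'
#' Networks of `n_patterns` neurons learn `n_patterns` mutually exclusive,
#' equally likely random patterns. Each simulation draws fresh patterns and
#' slopes, presents up to `max_presentations` patterns, and stops at the
#' first convergence window (see [detect_convergence()]). The result is the
#' fraction of simulations converged as a function of presentations — a
#' non-decreasing curve bounded by 1.
#'
#' @param n_patterns number of patterns and neurons.
#' @param n_channels input channels per neuron.
#' @param n_sims simulations.
#' @param max_presentations cap per simulation.
#' @param PW,T stimulus geometry.
#' @param sigma temporal jitter standard deviation.
#' @param p_signal,noise_rate spike deletion / background noise levels.
#' @param window convergence run length.
#' @param params,net optional parameter overrides.
#' @param chunk presentations simulated between convergence checks.
#' @return object of class `skan_convergence`: list with `first_convergence`
#'   (per-simulation index, `NA` if never), `fraction` (cumulative converged
#'   fraction by presentation), and the configuration.
#' @export
run_classification <- function(n_patterns = 2L, n_channels = 2L,
                               n_sims = 50L, max_presentations = 800L,
                               PW = 20L, T = 400L, sigma = 0,
                               p_signal = 1, noise_rate = 0,
                               window = 20L, params = NULL, net = NULL,
                               chunk = 25L) {
  if (is.null(params)) params <- skan_params(n_channels)
  if (is.null(net)) net <- net_params(n_patterns)
  first <- rep(NA_integer_, n_sims)
  for (sim in seq_len(n_sims)) {
    pats <- replicate(n_patterns, make_target_pattern(n_channels, PW),
                      simplify = FALSE)
    state <- network_state(params, net)
    verdicts <- NULL
    done <- 0L
    while (done < max_presentations) {
      nk <- min(chunk, max_presentations - done)
      st <- build_sequence(pats, rep(1 / n_patterns, n_patterns), nk,
                           T = T, sigma = sigma, p_signal = p_signal,
                           noise_rate = noise_rate)
      s_before <- state$s
      res <- .run_block(state, st$events, st$duration, params, net)
      state <- res$state
      v <- .score_presentations(res$s, st$labels$onset, T,
                                st$labels$pattern_id, s_before)
      v$presentation <- v$presentation + done
      verdicts <- rbind(verdicts, v)
      done <- done + nk
      hit <- detect_convergence(verdicts, verdicts$pattern_id, window)
      if (!is.na(hit)) {
        first[sim] <- verdicts$presentation[hit]
        break
      }
      # every window ending so far has failed; future windows only need the
      # trailing `window` verdicts, so older history can be dropped
      if (nrow(verdicts) > window)
        verdicts <- verdicts[(nrow(verdicts) - window + 1L):nrow(verdicts), ]
    }
  }
  fraction <- vapply(seq_len(max_presentations), function(k)
    mean(!is.na(first) & first <= k), numeric(1))
  structure(list(first_convergence = first, fraction = fraction,
                 n_patterns = n_patterns, n_channels = n_channels,
                 n_sims = n_sims, max_presentations = max_presentations,
                 PW = PW, T = T, sigma = sigma, window = window),
            class = "skan_convergence")
}

#' @export
print.skan_convergence <- function(x, ...) {
  cat(sprintf(
    "Convergence experiment: %d neurons/patterns, %d channels, sigma = %g\n",
    x$n_patterns, x$n_channels, x$sigma))
  cat(sprintf("  %d/%d simulations converged within %d presentations\n",
              sum(!is.na(x$first_convergence)), x$n_sims,
              x$max_presentations))
  if (any(!is.na(x$first_convergence)))
    cat(sprintf("  median first convergence: %g presentations\n",
                stats::median(x$first_convergence, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.skan_convergence <- function(x, ...) {
  plot(seq_along(x$fraction), x$fraction, type = "l", ylim = c(0, 1),
       xlab = "presentations", ylab = "fraction converged", ...)
  invisible(x)
}

# incremental detect_convergence above trims history; re-check on a window
# boundary is safe because any qualifying window is contained in the last
# `window` verdicts once all previous checks failed.

#' Track a drifting hidden ISI process
#'
#' Trains a two-input neuron on a [drifting_isi_stream()] and, after every
#' `rf_every` presentations, snapshots the frozen receptive field: its
#' argmax (the ISI the neuron currently expects), its support boundaries,
#' the threshold, and the width of the output pulse the presentation evoked
#' (0 when the pattern was missed). The argmax tracks the hidden mean with
#' lag; the mean pulse width correlates with the hidden noise level.
#'
#' @param mu_schedule,sigma_schedule hidden-process schedules, one entry per
#'   presentation (see [drifting_isi_stream()]).
#' @param T presentation period.
#' @param PW receptive-field half-width probed.
#' @param params optional [skan_params()] (two inputs).
#' @param rf_every probe the receptive field every this many presentations.
#' @return data.frame with one row per presentation: `presentation`, `mu`,
#'   `sigma`, `isi` (observed), `pulse_width`, `theta`, and (on probed rows)
#'   `rf_argmax`, `rf_lo`, `rf_hi`.
#' @export
run_tracking <- function(mu_schedule, sigma_schedule = 0, T = 400L,
                         PW = 25L, params = NULL, rf_every = 1L) {
  if (is.null(params)) params <- skan_params(2L)
  stopifnot(params$n_inputs == 2L)
  net <- net_params(1L, inh_max = 0L)
  st <- drifting_isi_stream(mu_schedule, sigma_schedule, T)
  np <- nrow(st$labels)
  state <- network_state(params, net)
  out <- data.frame(presentation = seq_len(np), mu = st$labels$mu,
                    sigma = st$labels$sigma, isi = st$labels$isi,
                    pulse_width = NA_integer_, theta = NA_integer_,
                    rf_argmax = NA_integer_, rf_lo = NA_integer_,
                    rf_hi = NA_integer_)
  ev <- st$events
  grp <- findInterval(ev$time, st$labels$onset)
  for (k in seq_len(np)) {
    e <- ev[grp == k, , drop = FALSE]
    e$time <- e$time - st$labels$onset[k]
    s_before <- state$s
    res <- .run_block(state, e, as.integer(T), params, net)
    state <- res$state
    widths <- pulse_width_stats(res$s[1L, ])$widths
    out$pulse_width[k] <- if (length(widths)) sum(widths) else 0L
    out$theta[k] <- state$theta[1L]
    if (k %% rf_every == 0L && all(state$p == 0L)) {
      rf <- rf_curve(list(dr = state$dr[, 1L], theta = state$theta[1L],
                          params = params), PW = PW)
      out$rf_argmax[k] <- attr(rf, "argmax")
      b <- attr(rf, "boundaries")
      out$rf_lo[k] <- b[1]
      out$rf_hi[k] <- b[2]
    }
  }
  out
}

#' Output pulse widths and running average
#'
#' Widths (in steps) of the maximal runs of 1s in a binary output series,
#' with a running average over the trailing `window` pulses. When `onsets`
#' and `T` are given, also reports per-presentation total pulse width, with
#' missed presentations recorded as 0.
#'
#' @param s binary output vector.
#' @param window running-average span, in pulses.
#' @param onsets optional presentation onsets (0-based steps).
#' @param T presentation period (required with `onsets`).
#' @return list with `widths`, `starts` (0-based step of each rising edge),
#'   `running_avg`, and optionally `per_presentation`.
#' @examples
#' pulse_width_stats(c(0, 1, 1, 1, 0, 1, 0))$widths  # 3 1
#' @export
pulse_width_stats <- function(s, window = 10L, onsets = NULL, T = NULL) {
  stopifnot(all(s %in% c(0L, 1L)))
  r <- rle(as.integer(s))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1L
  widths <- r$lengths[on]
  pulse_starts <- starts[on] - 1L   # 0-based
  ra <- if (length(widths)) {
    vapply(seq_along(widths), function(i)
      mean(widths[max(1L, i - window + 1L):i]), numeric(1))
  } else numeric(0)
  out <- list(widths = widths, starts = pulse_starts, running_avg = ra)
  if (!is.null(onsets)) {
    stopifnot(!is.null(T))
    grp <- findInterval(pulse_starts, onsets)
    pp <- integer(length(onsets))
    if (length(widths)) {
      agg <- tapply(widths, grp, sum)
      pp[as.integer(names(agg))] <- as.integer(agg)
    }
    out$per_presentation <- pp
  }
  out
}

#' Response latencies over a labelled stream
#'
#' For each presentation, the time from the last arriving input spike to the
#' rising edge of the output (`NA` when the presentation evoked no output).
#' Under noiseless repetition of a fixed pattern the latency is
#' non-increasing and converges to about `w / dr_max` steps.
#'
#' @param fit a [skan()] fit on a labelled stream.
#' @param neuron neuron to analyse.
#' @return integer vector, one latency per presentation.
#' @export
response_latencies <- function(fit, neuron = 1L) {
  stopifnot(inherits(fit, "skan"))
  st <- fit$stream
  onsets <- st$labels$onset
  edges <- .rising_edges(fit$s[neuron, ], 0L) - 1L  # 0-based times
  ev <- fit$stream$events
  grp_ev <- findInterval(ev$time, onsets)
  grp_ed <- findInterval(edges, onsets)
  vapply(seq_along(onsets), function(k) {
    t_last <- suppressWarnings(max(ev$time[grp_ev == k]))
    if (!is.finite(t_last)) return(NA_integer_)
    e <- edges[grp_ed == k & edges >= t_last]
    if (!length(e)) NA_integer_ else as.integer(e[1] - t_last)
  }, integer(1))
}
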