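# Stimulus generators. All times live on the integer step grid: presentation
# k (1-based) has onset (k-1)*T, and a pattern places one spike per channel at
# onset + offset with offset in [0, PW]. Channels are numbered from 1. All
# randomness flows through R's RNG, so set.seed() makes every stream
# reproducible bit-exactly.

#' Spatio-temporal spike pattern
#'
#' A target pattern is one spike per channel, at a fixed integer offset within
#' the pattern width `PW` of the presentation onset.
#'
#' @param offsets integer vector of per-channel spike offsets, each in
#'   `[0, PW]`.
#' @param PW maximal pattern width in time steps.
#' @return an object of class `skan_pattern`.
#' @seealso [make_target_pattern()]
#' @export
spike_pattern <- function(offsets, PW) {
  offsets <- as.integer(offsets)
  PW <- as.integer(PW)
  if (PW < 0L) stop("PW must be >= 0")
  if (any(offsets < 0L) || any(offsets > PW))
    stop("offsets must lie in [0, PW]")
  structure(list(offsets = offsets, PW = PW), class = "skan_pattern")
}

#' @export
print.skan_pattern <- function(x, ...) {
  cat(sprintf("Spike pattern: %d channel(s), PW = %d\n  offsets: %s\n",
              length(x$offsets), x$PW, paste(x$offsets, collapse = " ")))
  invisible(x)
}

#' Draw a random target pattern
#'
#' Offsets are independent and uniform on the integers `[0, PW]`.
#'
#' @param n_channels number of channels (`>= 1`).
#' @param PW maximal pattern width in time steps.
#' @return a [spike_pattern()].
#' @examples
#' set.seed(7)
#' make_target_pattern(4, 20)
#' @export
make_target_pattern <- function(n_channels, PW) {
  stopifnot(n_channels >= 1, PW >= 0)
  spike_pattern(sample.int(PW + 1L, n_channels, replace = TRUE) - 1L, PW)
}

#' Temporally jitter a pattern
#'
#' Each offset is independently perturbed by a normal deviate with standard
#' deviation `sigma`, rounded to the nearest integer step and clamped to
#' `[0, T - 1]` relative to the onset. `sigma = 0` is the identity.
#'
#' @param pattern a [spike_pattern()].
#' @param sigma jitter standard deviation in time steps.
#' @param T presentation period (clamp bound).
#' @return integer vector of jittered offsets (the pattern's `PW` no longer
#'   bounds them, so a raw vector is returned rather than a pattern object).
#' @examples
#' pat <- spike_pattern(c(0, 10), 20)
#' identical(jitter_pattern(pat, 0), pat$offsets)
#' @export
jitter_pattern <- function(pattern, sigma, T = 400L) {
  stopifnot(inherits(pattern, "skan_pattern"), sigma >= 0, T >= 1)
  if (sigma == 0) return(pattern$offsets)
  off <- as.integer(round(pattern$offsets + rnorm(length(pattern$offsets), 0, sigma)))
  pmin(pmax(off, 0L), as.integer(T) - 1L)
}

#' Corrupt one presentation with spike deletion and background noise
#'
#' Each target spike is kept independently with probability `p_signal`;
#' independently, every channel receives background spikes from a per-step
#' Bernoulli process with success probability `noise_rate / T`, over the whole
#' period — exact on the discrete grid and indistinguishable from a Poisson
#' process at rates well below one per step. The total expected spike count
#' per channel per period is therefore `p_signal + noise_rate`; the
#' signal-to-noise designs of the noise experiments keep this sum at 1.
#'
#' @param pattern a [spike_pattern()] (offsets relative to the onset).
#' @param p_signal probability a target spike is kept, in `[0, 1]`.
#' @param noise_rate expected background spikes per channel per period.
#' @param T presentation period in steps.
#' @param sigma optional temporal jitter applied to kept target spikes.
#' @return data.frame with integer columns `time` (in `[0, T)`, relative to
#'   the onset) and `channel`, sorted by time.
#' @examples
#' pat <- spike_pattern(c(0, 10), 20)
#' corrupt_presentation(pat, 1, 0, 400)    # exactly the target events
#' corrupt_presentation(pat, 0, 0, 400)    # empty
#' @export
corrupt_presentation <- function(pattern, p_signal, noise_rate, T = 400L,
                                 sigma = 0) {
  stopifnot(inherits(pattern, "skan_pattern"),
            p_signal >= 0, p_signal <= 1, noise_rate >= 0, T >= 1)
  nc <- length(pattern$offsets)
  keep <- if (p_signal >= 1) rep(TRUE, nc) else runif(nc) < p_signal
  off <- if (sigma > 0) jitter_pattern(pattern, sigma, T) else pattern$offsets
  times <- off[keep]
  chans <- seq_len(nc)[keep]
  if (noise_rate > 0) {
    n_noise <- rbinom(nc, as.integer(T), min(noise_rate / T, 1))
    for (ch in which(n_noise > 0L)) {
      times <- c(times, sample.int(T, n_noise[ch]) - 1L)
      chans <- c(chans, rep(ch, n_noise[ch]))
    }
  }
  o <- order(times, chans)
  data.frame(time = as.integer(times[o]), channel = as.integer(chans[o]))
}

.new_stream <- function(events, labels, T, duration, n_channels, patterns = NULL) {
  structure(list(events = events, labels = labels, T = as.integer(T),
                 duration = as.integer(duration),
                 n_channels = as.integer(n_channels), patterns = patterns),
            class = "skan_stream")
}

#' @export
print.skan_stream <- function(x, ...) {
  cat(sprintf("Spike stream: %d channel(s), %d event(s), %d step(s)\n",
              x$n_channels, nrow(x$events), x$duration))
  if (!is.null(x$labels) && nrow(x$labels))
    cat(sprintf("  %d presentation(s), period T = %d\n", nrow(x$labels), x$T))
  invisible(x)
}

#' @export
as.data.frame.skan_stream <- function(x, ...) x$events

#' Build a presentation sequence
#'
#' Presentations occur every `T` steps; at each one a pattern is chosen
#' i.i.d. with the given probabilities, then jitter, deletion and background
#' noise are applied. Ground-truth labels are recorded for the evaluation
#' harness (the learner itself is unsupervised).
#'
#' @param patterns list of [spike_pattern()] objects sharing a channel count.
#' @param probabilities per-pattern selection weights, summing to 1.
#' @param n_presentations number of presentations.
#' @param T presentation period; must exceed the pattern width.
#' @param sigma temporal jitter standard deviation in steps.
#' @param p_signal probability a target spike is kept.
#' @param noise_rate expected background spikes per channel per period.
#' @return a `skan_stream`: `events` (data.frame `time`, `channel`), `labels`
#'   (data.frame `onset`, `pattern_id`), `T`, `duration`, `n_channels`.
#' @examples
#' set.seed(1)
#' pats <- list(make_target_pattern(2, 20), make_target_pattern(2, 20))
#' st <- build_sequence(pats, c(0.6, 0.4), 10, T = 400)
#' table(st$labels$pattern_id)
#' @export
build_sequence <- function(patterns, probabilities, n_presentations,
                           T = 400L, sigma = 0, p_signal = 1, noise_rate = 0) {
  stopifnot(length(patterns) >= 1,
            length(probabilities) == length(patterns),
            all(probabilities >= 0), n_presentations >= 1)
  if (abs(sum(probabilities) - 1) > 1e-8)
    stop("probabilities must sum to 1")
  nc <- length(patterns[[1]]$offsets)
  PW <- max(vapply(patterns, function(p) p$PW, integer(1)))
  if (T <= PW) stop("T must exceed the pattern width (presentations would overlap)")
  ids <- sample.int(length(patterns), n_presentations, replace = TRUE,
                    prob = probabilities)
  onsets <- (seq_len(n_presentations) - 1L) * as.integer(T)
  clean <- p_signal >= 1 && noise_rate == 0 && sigma == 0
  if (clean) {
    # fast path: offsets are fixed per pattern
    off_mat <- vapply(patterns, function(p) p$offsets, integer(nc))
    off_mat <- matrix(off_mat, nrow = nc)
    times <- rep(onsets, each = nc) + as.vector(off_mat[, ids])
    chans <- rep(seq_len(nc), n_presentations)
    o <- order(times, chans)
    events <- data.frame(time = as.integer(times[o]),
                         channel = as.integer(chans[o]))
  } else {
    evs <- vector("list", n_presentations)
    for (k in seq_len(n_presentations)) {
      e <- corrupt_presentation(patterns[[ids[k]]], p_signal, noise_rate,
                                T, sigma)
      if (nrow(e)) e$time <- e$time + onsets[k]
      evs[[k]] <- e
    }
    events <- do.call(rbind, evs)
  }
  labels <- data.frame(onset = onsets, pattern_id = ids)
  .new_stream(events, labels, T, n_presentations * as.integer(T), nc,
              patterns = patterns)
}

#' Two-channel stream from a drifting hidden inter-spike-interval process
#'
#' Per presentation `k` the observed ISI is `round(mu[k] + sigma[k] * z)` with
#' `z` standard normal. Channel 1 spikes at the onset and channel 2 at onset
#' plus ISI; a negative ISI makes channel 2 lead (both spikes are shifted so
#' the earlier one sits at the onset). Used to study how the temporal
#' receptive field tracks the mean and variance of a hidden process.
#'
#' @param mu_schedule per-presentation ISI mean, in steps (may be negative).
#' @param sigma_schedule per-presentation ISI standard deviation; recycled.
#' @param T presentation period; must satisfy `max(|mu|) + 4 max(sigma) < T`.
#' @return a `skan_stream` whose `labels` carry columns `onset`, `isi`
#'   (observed), `mu` and `sigma` (hidden process).
#' @examples
#' set.seed(1)
#' st <- drifting_isi_stream(rep(-5, 10), 0, T = 400)
#' st$labels$isi  # all -5
#' @export
drifting_isi_stream <- function(mu_schedule, sigma_schedule, T = 400L) {
  n <- length(mu_schedule)
  sigma_schedule <- rep_len(sigma_schedule, n)
  stopifnot(n >= 1, all(sigma_schedule >= 0),
            max(abs(mu_schedule)) + 4 * max(sigma_schedule) < T)
  isi <- as.integer(round(mu_schedule + rnorm(n) * sigma_schedule))
  isi <- pmin(pmax(isi, -(as.integer(T) - 1L)), as.integer(T) - 1L)
  onsets <- (seq_len(n) - 1L) * as.integer(T)
  t1 <- onsets + pmax(0L, -isi)
  t2 <- onsets + pmax(0L, isi)
  events <- data.frame(time = c(t1, t2),
                       channel = rep(c(1L, 2L), each = n))
  events <- events[order(events$time, events$channel), , drop = FALSE]
  rownames(events) <- NULL
  labels <- data.frame(onset = onsets, isi = isi,
                       mu = mu_schedule, sigma = sigma_schedule)
  .new_stream(events, labels, T, n * as.integer(T), 2L)
}

# dense 0/1 matrix (channels x steps) from an event list; used by plotting
.events_to_matrix <- function(events, n_channels, n_steps) {
  u <- matrix(0L, n_channels, n_steps)
  if (nrow(events)) u[cbind(events$channel, events$time + 1L)] <- 1L
  u
}
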