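test_that("presentation scoring demands a single clean answer", {
  one <- classify_presentation(rbind(c(0, 1, 1, 0), c(0, 0, 0, 0)))
  expect_true(one$candidate_correct)
  expect_identical(one$neuron, 1L)
  # two responding neurons disqualify
  two <- classify_presentation(rbind(c(0, 1, 0, 0), c(0, 0, 1, 0)))
  expect_false(two$candidate_correct)
  # repeated edges from one neuron disqualify
  rep2 <- classify_presentation(c(0, 1, 0, 1))
  expect_false(rep2$candidate_correct)
  expect_identical(rep2$edges, 2L)
  # a pulse continuing from the previous period is not a new edge
  cont <- classify_presentation(c(1, 1, 0, 0), s_before = 1L)
  expect_identical(cont$edges, 0L)
})

test_that("convergence needs a consistent bijection over the whole window", {
  mk <- function(neuron, cc = TRUE)
    data.frame(candidate_correct = cc, neuron = neuron)
  labels <- rep(c(1L, 2L), 15L)
  # perfect alternation: converged exactly at the window end
  v <- mk(rep(c(1L, 2L), 15L))
  expect_identical(detect_convergence(v, labels, window = 20L), 20L)
  # one miss at presentation 20 restarts the run
  v2 <- v
  v2$candidate_correct[20L] <- FALSE
  expect_identical(detect_convergence(v2, labels, window = 20L), NA_integer_)
  expect_identical(detect_convergence(rbind(v2, mk(rep(c(1L, 2L), 5L))),
                                      rep(c(1L, 2L), 20L), window = 20L),
                   40L)
  # a neuron swapping patterns mid-sequence blocks every window spanning it
  v3 <- mk(c(rep(c(1L, 2L), 8L), rep(c(2L, 1L), 7L)))
  expect_identical(detect_convergence(v3, rep(c(1L, 2L), 15L), window = 20L),
                   NA_integer_)
  # one neuron claiming both patterns is not a bijection
  v4 <- mk(rep(1L, 30L))
  expect_identical(detect_convergence(v4, labels, window = 20L), NA_integer_)
  # but a single-pattern stream converges with a single neuron answering
  expect_identical(detect_convergence(v4, rep(1L, 30L), window = 20L), 20L)
})

test_that("pulse width statistics follow the run-length definition", {
  st <- pulse_width_stats(c(0, 1, 1, 1, 0, 1, 0))
  expect_identical(st$widths, c(3L, 1L))
  expect_identical(st$starts, c(1L, 5L))
  expect_identical(st$running_avg, c(3, 2))
  expect_length(pulse_width_stats(rep(0, 10))$widths, 0L)
  # per-presentation accounting records misses as zero
  s <- c(0, 1, 1, 0,  0, 0, 0, 0,  1, 0, 0, 0)
  pp <- pulse_width_stats(s, onsets = c(0L, 4L, 8L), T = 4L)$per_presentation
  expect_identical(pp, c(2L, 0L, 1L))
})

test_that("degenerate selection sweeps pick the only pattern shown", {
  set.seed(71)
  sel <- run_selection(p_x = 1, n_sims = 6L, n_presentations = 40L)
  expect_identical(unname(sel$fraction_x), 1)
  expect_identical(unname(sel$x), 6L)
})

test_that("selection of the commoner pattern strengthens with its probability", {
  set.seed(72)
  sel <- run_selection(p_x = c(0.5, 0.75, 0.95), n_sims = 12L,
                       n_presentations = 300L)
  expect_true(all(diff(sel$fraction_x) >= 0) ||
              sel$fraction_x[3] > sel$fraction_x[1])
  out <- attr(sel, "outcomes")
  expect_identical(dim(out), c(12L, 3L))
  expect_true(all(out %in% c("x", "y", "both", "neither")))
})

test_that("classification convergence curves are monotone and bounded", {
  set.seed(73)
  cv <- run_classification(n_patterns = 2L, n_channels = 2L, n_sims = 10L,
                           max_presentations = 400L)
  expect_true(all(diff(cv$fraction) >= 0))
  expect_true(all(cv$fraction >= 0 & cv$fraction <= 1))
  conv <- cv$first_convergence[!is.na(cv$first_convergence)]
  expect_gte(length(conv), 1L)
  expect_true(all(conv >= cv$window))
  # the curve value equals the empirical fraction at the cap
  expect_identical(cv$fraction[400L],
                   mean(!is.na(cv$first_convergence)))
})

test_that("tracking follows a drifting hidden ISI with lag", {
  set.seed(74)
  mu <- c(rep(-10, 60), seq(-10, 5, length.out = 60), rep(5, 120))
  tr <- run_tracking(round(mu), 0, T = 400L, PW = 25L, rf_every = 10L)
  probed <- tr[!is.na(tr$rf_argmax), ]
  # locked on the initial plateau (alignment is quantised to one step)
  expect_lte(abs(probed$rf_argmax[probed$presentation == 60L] + 10L), 1L)
  # and on the final plateau, after the lag has been worked off; sustained
  # noiseless training at slope saturation biases alignment by a step or two
  expect_lte(abs(probed$rf_argmax[probed$presentation == 240L] - 5L), 2L)
  # the argmax climbs through the ramp: net movement up, wobble at most 1
  ramp <- probed$rf_argmax[probed$presentation >= 60L]
  expect_true(all(diff(ramp) >= -1L))
  expect_gte(tail(ramp, 1L) - ramp[1L], 12L)
})

test_that("latency improves with adaptation toward w / dr_max", {
  set.seed(75)
  stream <- build_sequence(list(spike_pattern(c(0L, 0L), 0L)), 1, 300L,
                           T = 400L)
  fit <- skan(stream)
  lat <- response_latencies(fit)
  expect_false(anyNA(lat))
  block_med <- tapply(lat, (seq_along(lat) - 1L) %/% 25L, median)
  # monotone non-increasing block medians once the threshold has risen
  expect_true(all(diff(unname(block_med)) <= 0))
  expect_lt(abs(tail(block_med, 1L) - 25), 3)
  # slopes saturate at dr_max
  expect_true(all(fit$state$dr >= fit$params$dr_max - 1L))
})

test_that("converged pulse width settles near theta_fall / theta_rise", {
  set.seed(76)
  stream <- build_sequence(list(spike_pattern(c(0L, 6L), 20L)), 1, 250L,
                           T = 400L)
  fit <- skan(stream)
  pw <- pulse_width_stats(fit$s[1L, ], onsets = stream$labels$onset,
                          T = 400L)$per_presentation
  late <- pw[200:250]
  ratio <- fit$params$theta_fall / fit$params$theta_rise
  expect_lt(abs(mean(late) - ratio), 1)
  # threshold is at equilibrium: change across late presentations is small
  expect_lt(abs(mean(diff(late))), 0.5)
})
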