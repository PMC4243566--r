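---
title: "Adaptive synapto-dendritic kernels: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive synapto-dendritic kernels: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skan)
```

## The model

A neuron in this package receives binary spikes on $N$ input channels, on a
discrete time grid of unit step $\Delta t$. Each channel $i$ owns a
*synapto-dendritic kernel*: a ternary flag $p_i \in \{-1, 0, 1\}$ and an
integer accumulator $r_i$ with slope $\Delta r_i$. A spike arriving while the
kernel is idle starts a ramp: $r_i$ climbs by $\Delta r_i$ per step until it
reaches the peak height $w$ (the synaptic weight, held constant and equal
across channels), then descends symmetrically back to zero. The result is a
triangular post-synaptic potential whose width is $2\lceil w/\Delta r_i
\rceil$ steps — a steep kernel is narrow and peaks early, a shallow one is
wide and peaks late. Spikes arriving mid-cycle are ignored, so the neuron
trains on the first spike of any burst.

The soma sums the kernels into a membrane potential $V(t) = \sum_i r_i(t)$
and emits a binary output $s(t) = \mathbf{1}[V(t) > \Theta(t-1)]$ against a
homeostatic threshold $\Theta$. The membrane is not reset by spiking, so the
output is a *pulse* whose width carries information: a narrow pulse means
the threshold sits just below the membrane peak, i.e. the neuron is
confident.

Two feedback rules do all the learning:

* **Slope adaptation.** While the output pulse is high, a kernel still in
  its ramp-up phase ($p_i = 1$) peaked too late and steepens by $ddr$; a
  kernel already ramping down ($p_i = -1$) peaked too early and flattens by
  $ddr$. This back-propagating pulse synchronises all kernel peaks onto the
  observed spike pattern: the per-channel slopes *are* the learnt pattern
  (see `learned_offsets()`), which is why `coef()` of a fit returns slopes
  and threshold.
* **Threshold homeostasis.** $\Theta$ rises by $\Theta_{rise}$ at every
  spiking step and falls by $\Theta_{fall}$ when the membrane returns to
  zero. At equilibrium under repeated recognised patterns the two balance,
  giving pulses of about $\Theta_{fall}/\Theta_{rise}$ steps; a *missed*
  pattern produces no rise, so the threshold drops and the neuron becomes
  more permissive. The threshold therefore tracks just below the membrane
  peak of the learnt pattern, and its height encodes selectivity.

Because slope adaptation only acts during an output pulse, silencing the
output silences learning. A layer of neurons sharing the inputs becomes a
competitive classifier through one extra signal: a global inhibition counter
that reloads to $inh_{max}$ on any output and decays by $inh_{decay}$ per
step afterwards. While it is non-zero no neuron may *initiate* a pulse (a
pulse in progress continues), and threshold adaptation is gated so that only
the neuron that answered a pattern adapts on it. The best-adapted neuron for
a pattern is also the fastest to spike, so a small initial advantage is
self-reinforcing and the neurons settle onto disjoint patterns. Total
wiring is $(N + 2)$ connections per neuron — linear, not combinatorial, in
layer size (`connection_count()`).

All state is integer-valued. With integer parameters the entire trajectory
is exact integer arithmetic, so any run is bit-reproducible from its seed;
the test suite verifies that the compiled engine and the plain-R reference
stepper agree state-for-state.

## Update timing within a step

The recurrences reference previous-step quantities, which leaves a genuine
freedom in how the flag and the accumulator interleave inside one step. This
package fixes register-transfer timing: the flag is computed first, from the
current input and the registered (previous-step) flag and accumulator; the
accumulator then integrates the *new* flag; slope and threshold adaptation
read only registered values ($p(t-1)$, $s(t-1)$).

This choice is load-bearing, not cosmetic. It makes the kernel peak exactly
$w$ when $\Delta r \mid w$ (overshoot at most $\Delta r - 1$ otherwise) and
— because the threshold keeps rising during a pulse, cutting the ramp-down
side short — gives slope adaptation a net positive drift under repeated
recognised patterns, so $\Delta r$ ratchets up to $\Delta r_{max}$ and the
response latency (last input spike to output rising edge) converges to
roughly $w/\Delta r_{max}$ steps. Under the alternative timing, in which the
accumulator integrates the registered flag, we measured the opposite: the
ratchet stalls mid-range and latency grows instead of shrinking. The
latency test in the suite (`response_latencies()`) pins the converged value
at $w/\Delta r_{max} = 25$ steps within $\pm 2$.

One consequence worth knowing: with the threshold initialised at zero, the
membrane becomes positive at the spike-arrival step itself, so the first
presentation elicits output immediately. Latency is therefore *not*
monotone from presentation one — it is near zero while the threshold is far
below the peak, rises as the threshold climbs, and only then decreases
monotonically to its floor. Tests assert the monotone late phase and the
converged value.

In the network threshold rule, the fall at a neuron's own falling edge is
applied only while inhibition is active. Whenever $inh_{max} > 0$ this gate
is provably vacuous (a falling edge at $t$ implies the neuron spiked at
$t-1$, which reloaded the counter), so it changes nothing in any real
network; it makes a single-neuron layer with $inh_{max} = 0$ reduce
*exactly* to the plain single-neuron rules, which the suite checks
step-for-step.

## Parameters

The defaults are the reference values used for every headline experiment.
All are non-negative integers; potential units are arbitrary.

| parameter | default | meaning |
|---|---|---|
| `w` | 10000 | kernel peak height (synaptic weight, constant) |
| `ddr` | 1 | slope change per feedback step; larger learns faster, smaller is noise-robust |
| `dr_max` | 400 | slope cap; must satisfy $\Delta r_{max} < w/PW$ so the first kernel of a pattern outlives the last spike |
| `dr_init` | [100, 200] | initial slopes, uniform per kernel ($100 \times (1 + \text{rand})$); the heterogeneity seeds the competition |
| `dr_floor` | `ddr` | slope lower bound; prevents a slope of zero freezing a kernel mid-ramp |
| `theta_rise` | $40 N$ | threshold rise per spiking step |
| `theta_fall` | $100 N$ | threshold fall on membrane return to zero |
| `theta_init` | 0 | guarantees the first presentation elicits output so adaptation can start |
| `inh_max` / `inh_decay` | 100 / 1 | inhibition reload and decay; rule of thumb $inh_{max}/inh_{decay} \ge \min \Delta r(0)$ so inhibition outlasts any competitor still ramping at its initial slope |
| `T` | 400 | presentation period in steps |
| `PW` | 20 | maximal pattern width in steps |

`validate_params()` enforces the slope bound and warns when the inhibition
rule of thumb is broken. No wall-clock mapping of $\Delta t$ is defined;
every interface speaks integer steps.

## What the stimulus generator emulates

`make_target_pattern()` draws one spike per channel, uniform on $[0, PW]$ —
the "one spike per channel per presentation" design used throughout.
Presentations abut every $T$ steps. Three noise processes can be layered on:

* **Temporal jitter** (`jitter_pattern()`): normal deviates of standard
  deviation $\sigma$, rounded to the grid and clamped to the period. The
  normal family is a modelling choice (only bell-shaped distributions are
  implied by the source material); rounding deflates the realised standard
  deviation by a few percent, which the Monte-Carlo tests account for.
* **Spike deletion**: each target spike survives with probability
  $P(signal)$.
* **Background spikes**: a per-step Bernoulli process at rate
  `noise_rate`$/T$ per channel — exact on a discrete grid and
  indistinguishable from a Poisson process at rates far below one per step.
  Noise is confined to each period, which is immaterial since periods abut.
  The signal-to-noise designs keep $P(signal) + $ `noise_rate` $= 1$, so
  the mean spike count stays one per channel per period.

`drifting_isi_stream()` generates the two-channel tracking stimuli: per
presentation the observed inter-spike interval is $\text{round}(\mu_k +
\sigma_k z)$, the earlier spike sits at the onset, and ground truth
($\mu_k$, $\sigma_k$, observed ISI) is recorded for the evaluation harness —
the learner itself never sees labels.

What the generator does **not** emulate: real sensor front-ends, rate codes,
multiple intentional spikes per channel per presentation, or noise
correlated across channels. Passing tests say the model behaves as analysed
under these statistical assumptions; they say nothing about performance on
real event streams.

## Probing the receptive field

A probe (`probe_response()`, `rf_curve()`) freezes slopes and threshold,
presents one pattern to an idle copy of the neuron, and integrates the
supra-threshold response $\sum_t (V(t) - \Theta)\, s(t)$. For two inputs
the pattern is a single ISI $\tau$ and the curve over $\tau \in [-PW, PW]$
has an argmax (the expected ISI) and a support (the tolerated range, which
shrinks as the threshold rises and widens after misses). Probes are pure by
contract — save/restore is explicit, and a state hash test enforces it —
and a snapshot with active kernels is rejected because mid-cycle state has
no well-defined field. Argmax ties resolve to the smallest $|\tau|$,
negative first, for deterministic reporting.

For more than two inputs an exhaustive field over an $(N-1)$-dimensional
ISI space is exponential, so the learnt-pattern error is operationalised as
*kernel peak alignment* (`kernel_peak_alignment()`): present the clean
target frozen, record when each kernel peaks, and take the RMS of the
mean-centred peak times. A perfectly trained neuron scores zero.

## Numerical behaviour found and kept

These are properties of the model as specified, measured by this package's
own tests and reported rather than patched:

* **Alignment is quantised.** Kernel peak times move in jumps of
  $\lceil w/\Delta r \rceil$, so noiseless recovery of a stationary ISI
  after 50 presentations is exact for most targets but off by one step for
  some (the acceptance suite asserts exactness and is red on that
  sub-property; everything else passes). With $\sigma = 0.5$ jitter,
  recovery is within one step.
* **Saturation bias.** Sustained noiseless training pushes both slopes
  toward the cap; the channel that should stay slow overshoots its
  alignment target, biasing the learnt ISI toward zero by one or two steps
  over hundreds of presentations. Visible in the long tracking plateaus.
* **Threshold band and rare-pattern catches.** The threshold is a sawtooth
  whose level is quantised by the membrane slope (about $\sum_i \Delta r_i$
  per step); it wanders in a band roughly a thousand potential units wide
  below the learnt pattern's peak. When a single neuron is shown two
  patterns whose tuned membrane peaks differ by less than that band, it
  occasionally answers the rarer one after a threshold dip. This is why
  the commonest-pattern selection fraction at $P(x) = 0.9$ measures about
  0.88 rather than the claimed 1.0 — the corresponding acceptance test is
  left red with this analysis rather than weakened.
* **Structural classification failures.** For two-channel networks, a
  pattern is identified only up to a uniform time shift, so pattern pairs
  with equal channel ISIs (about 3% of random pairs at $PW = 20$) are
  unclassifiable in principle. Separately, because all thresholds start at
  zero, both neurons cross at the very first input spike of the first
  presentation; a few percent of runs then adapt in lockstep onto the same
  integer attractor and become bit-identical, after which inhibition cannot
  separate them. Measured noiseless convergence is therefore about 85%
  within 800 presentations, and the convergence tests assert ordering and
  monotonicity properties rather than an absolute percentage.
* **Slope death under heavy noise.** At 1:1 or worse spike SNR, a channel
  whose target spike is frequently deleted receives mostly ramp-down
  feedback; its slope can collapse toward `dr_floor`, leaving a kernel that
  outlasts the period and inflates the mean alignment RMS of its cell.
  `rms_vs_snr()` reports a median alongside the mean for this reason.

## Problem sizes

The test suite runs Monte-Carlo replications at desk scale, chosen so the
full suite completes in a few minutes: 200 simulations per probability for
the selection sweep (300-presentation sequences, four channels), 200
simulations per noise level for two-neuron convergence (capped at 800
presentations, stopping at the 20-consecutive-correct window), 500-
presentation training runs and 6-8 replicates per cell for the SNR sweep,
and 50-presentation runs for parameter recovery. `scripts/acceptance.R`
recomputes the headline quantities at the same sizes from a command-line
seed. Larger replicate counts only narrow the binomial error bars; the
experiment functions take the counts as arguments for full-scale sweeps.

## Limitations

The synaptic weight $w$ is deliberately constant and uniform — adapting it
is out of scope. There is no continuous-time semantics, no biologically
detailed kernel shape, and no multi-layer composition. The classifier's
convergence criterion (20 consecutive candidate-correct presentations under
a consistent bijection) is an evaluation-harness construct; the network
itself has no notion of having converged.
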