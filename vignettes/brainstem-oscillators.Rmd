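---
title: "Chopper-neuron oscillator microcircuits: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chopper-neuron oscillator microcircuits: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choppernet)
```

## The model

Chopper neurons (T-stellate cells) of the ventral cochlear nucleus fire with
highly regular interspike intervals (ISIs) that are largely independent of
the stimulus frequency, and across species those intervals cluster at
integer multiples of 0.4 ms.  `choppernet` implements the microcircuit
account of that regularity and the analysis layers built on top of it:

1. **Pacemaker.**  Two or three fast chopper neurons, modelled as leaky
   integrate-and-fire (LIF) units with a membrane time constant of 0.8 ms,
   excite one another in a ring.  Each chopper-chopper synapse has a delay
   of 0.4 ms, so the ring circulates one spike and the *population* of fast
   choppers emits an event every 0.4 ms — the clock.  Each individual
   neuron fires every `n_fast * 0.4` ms.
2. **Interval reduction.**  Slow choppers (longer membrane time constant,
   longer absolute refractory period) receive the pacemaker's
   suprathreshold output.  During the absolute refractory period the
   membrane is clamped at the reset potential, so clock ticks that arrive
   inside it are skipped without leaving residual charge; the neuron fires
   at the first tick after.  A refractory period `r` therefore yields
   `ISI = ceil(r / 0.4) * 0.4` (one extra tick when `r` is itself a
   multiple of the clock, since the boundary tick falls exactly at the end
   of the refractory period): ISIs are quantized to the clock even though
   `r` is a continuous parameter.  A refractory period of 1.0 ms gives
   firing on every third input, ISI 1.2 ms.
3. **Enabling vs. initiating.**  Auditory-nerve (AN) input depolarizes the
   choppers with a summed synaptic weight one eighth of a chopper-chopper
   weight.  It *enables* chopping — one network spike on top of the
   AN depolarization crosses threshold — but can never *initiate* it: the
   AN-driven membrane potential stays below threshold, and a single network
   spike from rest stays below threshold too.  Chopping is started by a
   single spike from the onset (trigger) neuron and dies out by itself
   after the AN input ends.
4. **Periodicity analysis.**  A coincidence layer relates the clock to
   pitch.  For a unit with carrier period `tau_c`, intrinsic oscillator
   period `tau_k` and an integrator spanning `n` carrier periods, the
   modulation periods that drive the coincidence detector satisfy the
   integer equation `m * tau_m = n * tau_c - k * tau_k` with small
   integers `m, n, k`.  `solve_coincidence()` enumerates the solutions;
   `response_matrix()` runs the classic 16 x 16 carrier-by-modulation
   experiment with and without the harmonic-suppressing inhibitor.
5. **Ramp decoding.**  The same coincidence principle applied to nested
   oscillations: fast (gamma) cycles nested in the excitation half-phase of
   a slow oscillation gate a linearly ramping neuron, and the
   threshold-crossing time is read out on the lattice
   `p * tau_slow + q * tau_fast`.

## Units and calibration

Potentials are expressed in threshold units (leak reversal 0, threshold 1),
times in milliseconds.  The source model publishes circuit *constraints*
rather than parameter tables, so the following constants are calibrations of
this package, chosen once to realize the documented constraints and kept
fixed:

| constant | value | why |
|---|---|---|
| fast chopper membrane tau | 0.8 ms | stated model constant |
| slow chopper membrane tau | 2 ms | "higher values" for slow chopping |
| threshold / reset | 1 / 0.5 | reset halfway keeps recovery fast enough that a single ring spike plus AN depolarization crosses within one step |
| fast absolute refractory | 0.1 ms | must be well below the 0.8 ms per-neuron period |
| relative refractory | 0.05, tau 0.3 ms | decaying threshold increment; negligible at 0.8 ms, expressed at short intervals |
| chopper-chopper weight | 24 | see below |
| AN summed weight | 24 / 8 = 3 | stated 8:1 weight ratio |
| AN drive level | 0.95 | steady AN depolarization just below threshold |
| network transmitter decay | 0.005 ms | impulse-coupling regime (below) |
| AN-synapse transmitter decay | 2.5 ms | pools five stochastic fibers into a smooth depolarization |
| engine step `dt` | 0.025 ms | resolves every time scale in the model |

The weight calibration solves two inequalities at `dt = 0.025`: with the AN
depolarization present (recovered membrane at ~0.7-0.9), the one-step
voltage increment from a single ring spike, `dt/tau * w * tanh(q/s)`, must
exceed the gap to threshold — so the postsynaptic neuron fires *at the
delivery step* and the population interval equals the synaptic delay
exactly; from rest without AN input, the *total* charge of the same spike
must stay below threshold.  `w = 24` with two quanta per ring spike
satisfies both with ~30% margin on each side.

**Impulse coupling and Euler convergence.**  Network synapses use a very
short transmitter decay (0.005 ms), so a presynaptic spike acts as a
one-step current impulse.  This makes the spike time of the postsynaptic
neuron equal to the delivery time at both `dt = 0.025` and `dt = 0.0125` —
halving the step leaves every spike time bit-identical on the pacemaker
benchmark.  A slower transmitter would smear the crossing over several
steps and add a latency to every hop of the ring, which would detune the
population clock away from the synaptic delay.  The slower AN synapses
(2.5 ms decay) are where the leaky-integrator transmitter pool does real
work, low-pass filtering the five stochastic fibers.

**The trigger pathway** (onset neuron to first chopper) uses the same
weight and delay as the ring but no jitter and a fully saturating quantal
content: initiation is a single, reliable, sharply timed event.  The onset
neuron defaults to single-spike mode with a 2.5 ms latency in the circuit
builders, giving the AN depolarization a few membrane time constants to
charge the choppers first; the Hodgkin-Huxley-type onset mode (sodium,
low-threshold potassium, leak, excitatory input) is available and phasic,
but the circuit experiments use single-spike mode.

## Synaptic delay jitter

The stochastic chopper protocol adds jitter with SD 0.26 ms to the 0.4 ms
delays of the fast-chopper interconnections.  The source material fixes
only the mean and SD of the jitter, so the distribution is a design choice
of this package: delays are drawn from a normal distribution truncated to a
window *symmetric about the mean*.  The lower edge is the physical minimum
synaptic delay (0.15 ms, never below one time step — causality); the upper
edge is its mirror image.  Symmetry keeps the mean delay, and with it the
population clock, unbiased; a one-sided truncation would lengthen every hop
by the truncated mass and drag the ISI peaks off the 0.4 ms grid.  The
price is that for jitter as large as 0.26 ms on a 0.4 ms mean the
*realized* delay SD is below the nominal parameter (about 0.14 ms);
`delay_moments()` gives the exact truncated moments and is the reference
the tests check against.

Under per-event jitter the within-trial clock grid is destroyed, and the
model is honest about the consequences: the fast choppers' ISI histogram
keeps a single peak on the 0.4 ms grid (at 0.8 ms), but a slow chopper's
intervals become first-passage times of the jittered event stream over its
refractory period, and their modes sit just above the refractory period
rather than exactly on grid multiples.  The exact quantization of the
interval bank is a property of the deterministic (jitter-free) circuit,
which is how the bank experiments are run.

## The auditory-nerve generator

The full cochlea (wave-digital filter bank) and hair-cell vesicle cascade
are out of scope; `an_spikes()` is a phenomenological stand-in that keeps
the features the circuit actually consumes:

* **phase locking** — the instantaneous rate follows the
  half-wave-rectified stimulus waveform (vector strength to a 1 kHz carrier
  exceeds 0.5 at high drive);
* **adaptation** — a single-exponential rate factor decaying from 1 to a
  floor of 0.6 with a 10 ms time constant after onset (the source describes
  vesicle depletion qualitatively only);
* **refractoriness** — 1 ms dead-time thinning;
* **stochasticity** — per-sample Bernoulli draws, bit-reproducible given a
  seed.

Five fibers converge on each chopper.  Neither the spontaneous rate nor the
peak driven rate is published; the defaults (0 and 8000 events/s before
thinning at 30 dB re threshold, via the convention
`rate = 250 * 10^(dB/20)`) are conventions of this package, calibrated so
the pooled AN current depolarizes a chopper to ~0.6-0.8 of threshold.  What
the generator does *not* emulate: cochlear filtering and travelling-wave
dispersion, spontaneous-rate classes, long-term adaptation components, and
across-fiber correlation.  Passing tests therefore validate the circuit
logic, not the auditory periphery.

## The periodicity layer

The periodicity network runs on idealized event times rather than on the
spiking engine: triggers at the analytic envelope peaks of the AM stimulus,
oscillator spikes at `tau_k` intervals after each trigger (restarted by the
next trigger, at most `n_osc_spikes` per cycle), one integrator event
`n * tau_c` after each trigger, and a coincidence count whenever an
integrator event falls within half a coincidence window (default 0.05 ms)
of an oscillator spike.  The unit's best modulation frequency follows from
the coincidence equation with `m = 1` and the largest usable oscillator
spike count; `tuned_unit()` constructs units whose BMF is exactly
`CF / ratio` by using an integrator of `ratio + 2` carrier periods and two
oscillator spikes at the carrier period.  In the response-matrix experiment
the 16 characteristic frequencies are log-spaced over three octaves from
960 Hz (a convention — the source does not print them) and the 16
modulation frequencies are the units' BMFs, so the second harmonic of each
BMF lies exactly five columns up, making the harmonic sidebands and their
suppression by the inhibitor directly visible.  The inhibitor is realized
as a veto on coincidences whose oscillator spike belongs to a trigger more
than one modulation cycle after the integrator's own (`m > 1`), not as a
spiking lemniscal model: the source describes the inhibitor's function, not
its dynamics.  One consequence worth noting: harmonic responses arise for
stimuli modulated *faster* than the BMF (an `m`-th harmonic stimulus
satisfies the equation with that `m`); at half the BMF the equation has no
small-integer solution for the default units, so the inhibition tests probe
the 2 x BMF column.

## Numerical choices and degenerate inputs

* Spike times are recorded at the step where threshold is crossed; no
  sub-step interpolation (`dt` is 16x smaller than the smallest interval of
  interest).
* Simultaneous synaptic deliveries in one step are summed before the neuron
  update.
* Delays are rounded to the step grid, never below one step.
* `base_interval()` breaks ties toward the largest base, which excludes the
  degenerate solution where a vanishing base divides everything; candidate
  bases below the grid minimum are simply not searched.
* Regularity bins with fewer than `min_count` ISIs are flagged undefined
  (`NA`), never zero-filled; ISIs are assigned to the bin of their onset
  spike, and the CV uses the population SD (at these counts the difference
  from the sample SD is negligible).
* An all-zero drive yields an empty onset train ("no onset"), an empty
  presynaptic train yields a zero current, and an empty network simulates
  to an empty result — none of these are errors.
* A ramp that never crosses threshold within the decode horizon returns a
  flagged no-coincidence result.  Fast cycles are indexed within the
  excitation half-phase of the slow oscillation; `q` counts complete fast
  cycles only, a documented convention.

## Problem sizes

The bundled experiments are desk-scale: deterministic circuit runs simulate
50-100 ms at `dt = 0.025` ms (2000-4000 steps, under a second); the
stochastic sustained-chopper protocol uses 500 trials of a 25 ms tone burst
(about ten seconds); the response matrix evaluates all 256
carrier-modulation combinations at 150 ms per stimulus (under a second).
The test suite re-runs all of them from scratch.

## Known limitations

* The clock's exactness rests on the impulse-coupling calibration; with
  physiological synaptic kinetics the population interval would exceed the
  synaptic delay by the threshold-crossing latency.
* Per-event delay jitter makes long slow-chopper intervals drift off the
  grid (see above); the model has no phase-correcting mechanism.
* D-stellate-like inhibition is available as a negative synaptic weight but
  is disabled in the default circuits; network termination relies on the
  AN offset, which the simulations verify.
* The periodicity layer idealizes triggers as envelope peaks; an adapter
  from simulated chopper trains to trigger/oscillator events is a natural
  extension but not part of the experiments here.
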