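# choppernet

Spiking simulation of the chopper-neuron oscillator microcircuits of the
auditory brainstem, for researchers studying temporal processing in the
ventral cochlear nucleus and for anyone who wants a small, fully tested
model of how a handful of neurons can build a sub-millisecond clock.

## The science

Chopper neurons (T-stellate cells) fire with highly regular interspike
intervals (ISIs) that cluster at integer multiples of 0.4 ms across
species.  The model implemented here attributes that constant to the
smallest synaptic delay between interconnected chopper neurons:

* **Pacemaker** — two or three mutually excitatory fast leaky
  integrate-and-fire choppers (membrane time constant 0.8 ms) wired in a
  ring with 0.4 ms synaptic delays.  The population emits one event per
  delay: a 0.4 ms clock.  Each neuron fires every `n_fast × 0.4` ms.
* **Interval reduction** — slow choppers with longer absolute refractory
  periods `r` skip clock ticks and fire at
  `ISI = ceil(r / 0.4) × 0.4` ms: intervals are quantized to the clock
  even though `r` is continuous.
* **Enabling, not initiating** — auditory-nerve input (summed weight 8×
  lower than a chopper–chopper synapse) depolarizes the choppers below
  threshold; a single spike from the onset (trigger) neuron starts the
  chopping, and the input's offset stops it.
* **Periodicity analysis** — a coincidence layer ties the clock to pitch
  through the integer equation `m·τ_m = n·τ_c − k·τ_k` (modulation period,
  carrier period, intrinsic oscillation period), including the 16 × 16
  carrier × modulation response-matrix experiment with harmonic-suppressing
  inhibition.
* **Ramp decoding** — the same coincidence principle for cortical nested
  oscillations: integration periods are read out on the lattice
  `p·τ_slow + q·τ_fast`.

Spike-train analytics (PSTH, ISI histograms, Blackburn–Sachs regularity
analysis, base-interval estimation) reproduce the interval structure from
the simulated trains.

## Worked example

```r
library(choppernet)

drive <- step_drive(0.95 / 3, 2, 55, duration = 60)  # auditory-nerve step
spec  <- build_interval_bank(c(0.5, 1.0, 1.7),
                             build_pacemaker(2, drive = drive))
res   <- simulate_network(spec, engine_config(duration = 50))
res
#> <sim_result> pacemaker2+bank: 6 units, 1 trial(s), 50.0 ms
#>   fast1    57 spikes
#>   fast2    56 spikes
#>   onset    1 spikes
#>   slow1    56 spikes
#>   slow2    38 spikes
#>   slow3    23 spikes

unique(round(diff(res$spikes$fast1$trials[[1]]), 3))   # 0.8  (2 × 0.4 clock)
unique(round(diff(res$spikes$slow2$trials[[1]]), 3))   # 1.2  (r = 1.0 skips 2 ticks)
unique(round(diff(res$spikes$slow3$trials[[1]]), 3))   # 2.0  (r = 1.7 skips 4)

pooled <- unlist(lapply(1:3, function(i) isis(res$spikes[[paste0("slow", i)]])$isi))
base_interval(pooled)
#> <base_interval_fit> base 0.400 ms, rms 0.0000 ms, multiples {2, 3, 5}
```

The onset neuron fires once; the fast choppers then chop at exactly 0.8 ms
each (population clock 0.4 ms), and the slow bank emits only multiples of
the clock, from which `base_interval()` recovers 0.400 ms with zero
residual.  The coincidence layer:

```r
u <- periodicity_unit(cf = 4000, tau_k = 0.4, integrator_n = 8)
bmf_of_unit(u)
#> $bmf 833.3  $tau_m 1.2  $k 2  $tuned TRUE    # 8×0.25 − 2×0.4 = 1.2 ms
```

A stochastic protocol (tone burst at the unit's CF through a
phenomenological auditory-nerve generator, delay jitter SD 0.26 ms) is
available via `build_pacemaker(..., an_mode = "an", jitter_sd = 0.26)`, and
a command-line surface via `run_cli()` / `inst/cli/choppernet`
(`simulate`, `analyze`, `periodicity`, `decode`, `make-stimulus`, `demo`).

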