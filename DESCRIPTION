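Package: choppernet
Title: Spiking Oscillator Microcircuits of the Auditory Brainstem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the chopper-neuron oscillator microcircuits of the
    ventral cochlear nucleus: a pacemaker ring of mutually excitatory fast
    leaky integrate-and-fire chopper neurons whose 0.4 ms synaptic delay sets
    a population clock, a bank of slow choppers that skip suprathreshold
    inputs and fire at integer multiples of the clock, a phenomenological
    auditory-nerve spike generator, and an onset (trigger) neuron in
    single-spike or Hodgkin-Huxley-like mode.  Provides spike-train analytics
    (interspike-interval histograms, peri-stimulus time histograms,
    Blackburn-Sachs regularity analysis, base-interval estimation), the
    periodicity/coincidence analysis network with its integer coincidence
    equation and carrier-by-modulation response-matrix experiment, and a
    decoder for ramping activity gated by nested fast/slow oscillations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
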