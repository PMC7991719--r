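---
title: "A spiking-network model of melody memory and stylistic composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking-network model of melody memory and stylistic composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikemelody)
```

## The model in one page

`spikemelody` learns labelled symbolic melodies — sequences of
(pitch, duration) notes tagged with a genre, a composer and a title — in a
network of spiking neurons, and generates new melodies in the style of a
cued genre or composer. Two subsystems cooperate:

* **Sequential memory.** A *pitch subnetwork* (128 minicolumns, one per
  MIDI pitch index) and a *duration subnetwork* (64 minicolumns at 60-tick
  spacing, 60–3840 ticks at 480 ticks per crotchet). Minicolumns are
  arranged in layers; the note at sequence position $i$ activates layer
  $L_i$. Within a layer, columns compete through inhibitory lateral
  connections (winner-take-all); across layers, excitatory synapses carry
  *slot-valued transmission delays*: a synapse from $L_k$ to $L_m$ delivers
  its activity exactly $m-k$ note-slots later, so all of a note's
  predecessors speak at the moment their successor is learned or recalled.
* **Knowledge.** One neuron per distinct genre, composer and title label,
  allocated on first encounter and wired hierarchically
  (genre→composer, genre→title, composer→title), plus feedforward synapses
  into both memory subnetworks and a feedback loop between memory and the
  title cluster. A pool of fast-spiking interneurons with fixed
  (non-plastic) weights gates the clusters during composition.

Every neuron follows the two-variable Izhikevich model

$$\dot v = 0.04v^2 + 5v + 140 - u + I,\qquad \dot u = a(bv - u),$$

with a spike registered when $v$ reaches 30 mV, after which $v \leftarrow c$
and $u \leftarrow u + d$. Excitatory cells use the regular-spiking set
$(a,b,c,d) = (0.01, 0.2, -65, 8)$ — note the model's unusually slow recovery
$a = 0.01$, which we keep as specified rather than substituting the more
common 0.02 — and interneurons the fast-spiking set $(0.1, 0.2, -65, 2)$.
With $b = 0.2$ the RS resting point is $(v,u) = (-70, -14)$, which the test
suite holds stationary to machine precision.

Plastic synapses obey spike-timing-dependent plasticity,

$$\Delta w = \begin{cases} A_+\,e^{\Delta t/\tau_+}, & \Delta t < 0\\
-A_-\,e^{-\Delta t/\tau_-}, & \Delta t > 0,\end{cases}
\qquad \Delta t = t_{\text{pre}} - t_{\text{post}},$$

so causal order potentiates. Defaults $A_+ = 0.1$, $A_- = 0.12$,
$\tau_\pm = 20$ ms, weights clipped to $[0, 10]$.

Notes are encoded by Gaussian tuning curves: column $j$ responds to
stimulus $x$ with current $\lambda\,\sigma^{-1} e^{-(x-\mu_j)^2/\sigma^2}$.
Stimulus distance is measured in column-index units for both grids, so one
width $\sigma = 1$ serves both; $\lambda = \sigma \cdot I_\theta$ so the
peak tuning current equals the calibrated theta drive. Knowledge neurons
receive a fixed current on an exact label match: 5 during learning, 30
during composition.

## Firing bands and the current normalizer

Learning runs in the **theta band** (4–8 Hz; each note occupies a 1 s
slot), composition in the **gamma band** (30–80 Hz; 250 ms slots). The
package *calibrates* the drive current for each band and cell type by
bisection over the monotone rate–current curve (`calibrate_band_current`),
targeting the band midpoints (6 Hz, 50 Hz). Gamma is calibrated on the
250 ms composition slot rather than a full second, because the
regular-spiking cell adapts: a current tuned to 50 Hz over 1 s runs
noticeably hotter in the first quarter second.

All summed drives pass through a **band normalizer** before reaching a
neuron: drives are clipped below at zero, divided by a reference drive
(the slot's maximum within a competing layer, or the nominal external
current for knowledge clusters), raised to a contrast exponent (default 3),
and scaled to the calibrated band current, with saturation there and a
relative activation threshold (default 0.5) below which a column is
treated as subthreshold. Consequences:

* the best-driven column always fires at the band centre — this is what
  the band checks in the tests measure;
* weakly co-driven columns (for example, Gaussian tuning tails at
  $e^{-1} \approx 0.37$ of the peak) stay silent;
* close competitors are pulled apart: the contrast exponent widens the
  first-spike latency gap so the winner-take-all race is decided by drive,
  not by the deterministic tie-break (first spike, then spike count, then
  lowest column), which at a 0.5 ms integration step would otherwise
  engage for drive ratios near 1.

The paper-level description applies normalization to most but not all
membrane equations; we apply it uniformly to every knowledge cluster
(including the genre cue and the 30 mA composition current), because the
stated purpose of those currents is precisely to hold the neurons in the
band.

## Learning procedure

A piece is learned note by note. In each 1 s slot:

1. The genre, composer and title neurons fire together in theta (one
   knowledge slot per note — knowledge stays active throughout a piece),
   and the hierarchy synapses between them are created and potentiated.
2. The note's tuning currents drive layer $L_s$ of both subnetworks; the
   preferring column wins and fires in theta; lateral inhibition silences
   the layer.
3. Excitatory synapses are created (at weight zero) and potentiated by
   STDP: from every earlier winner within the connection horizon (default
   8 slots, delay = layer distance), from every active knowledge neuron to
   the winner, and from the winner back to the title neuron.

Between slots all potentials return to rest (we use the resting fixed
point rather than a literal 0 mV so the membrane equation stays in its
well-defined regime).

**Dendritic delay.** Every slot drive is constant from slot onset, so the
winner and its (delayed) predecessors produce *identical* spike trains:
nearest-neighbour pairing would read $\Delta t = 0$ everywhere and learn
nothing. Physiologically, the postsynaptic somatic spike reaches the
synapse after a short dendritic latency; we model this with a 2 ms shift
of postsynaptic spike times during pairing. Co-active pre/post trains then
read as causal ($\Delta t = -2$ ms) and potentiate — uniformly for
hierarchy, knowledge→memory, inter-layer and both directions of the
memory↔title loop — while genuinely anti-causal order (pre later by more
than the dendritic delay) still depresses. This single convention is what
makes slot-aligned co-activity learnable at all; it is the package's main
modelling addition and is exposed as `dendritic_delay_ms`.

**Shunting winner-take-all.** Lateral inhibition is applied structurally
by the simulator rather than as materialized all-pairs synapses (a 128
column layer would need ~16k bookkeeping rows per layer for fixed, never
consulted weights). Once a neuron spikes, every *other* group member is
held at rest for the remainder of the slot. The clamp matters: purely
subtractive inhibition cannot abort a spike whose quadratic voltage
runaway has already begun, and during development such a trailing loser
spike would mutually silence the winner and drop it out of the gamma band.
With the clamp, exactly the first spiker keeps its slot.

## Composition procedure

A composition request names a cue (`genre:classical` or
`composer:Mozart`), seed notes, and a total length. Per run:

* the cue neuron is driven at the composition current and fires gamma
  throughout;
* the interneuron pool, driven by the cue through fixed weights, fires
  gamma and *gates* the knowledge system: a genre cue silences the
  composer and title clusters, a composer cue silences the title cluster
  (the genre cluster receives no drive in that circuit and is simulated to
  confirm its silence). Pool inhibition is applied as a standing negative
  current on gated neurons — the sustained gamma activity of the pool at
  slot timescale — which also removes the one-step race in which a gated
  cluster could sneak a spike out before the first pool spike arrives. The
  fixed inhibitory weight is twice the calibrated gamma drive, so even a
  feedforward input saturated at the weight cap stays silenced;
* seed notes are presented slot by slot as external tuning drive (external
  presentation overrides recall, as in the learning phase);
* each subsequent slot collects, for every column of the current layer,
  the slot-delayed input from previously active winners plus the cue
  cluster's learned weight, normalizes to gamma, and lets the layer race:
  the first column to spike wins, silences the layer, and its
  (pitch, duration) pair decodes to the next note, which conditions all
  later slots.

A slot in which no column receives positive drive is a **dead end** and
raises a classed error naming the slot; the optional `greedy_restart`
re-seeds the layer pointer from the last emitted note instead (useful for
cyclic material), and is off by default.

The pitch and duration winners are selected independently, as in the
parallel circuits of the architecture; there is no joint competition over
(pitch, duration) pairs. One consequence, worth stating plainly: when two
pieces *by the same composer* pass through the same (layer, column) node,
generation may recombine their continuations, so the output is not
guaranteed to be a substring of any single stored piece. Across composers
with disjoint material this cannot happen, which is the guarantee the
style-consistency tests pin down.

## Synthetic data

`random_walk_corpus()` generates the deterministic test corpora:
scale-constrained random walks over C-major degrees with durations on the
60-tick grid, labels drawn round-robin, everything a pure function of the
spec and seed. With `disjoint_ranges = TRUE` each composer owns a private
pitch range *and* a private duration window, so neither subnetwork can
share a bigram across composers. The duration half of that guarantee is
not cosmetic: durations come from a small set, and during development a
10-piece corpus with shared duration values accumulated enough weight on
shared duration bigrams to out-vote the composer cue and corrupt replay.
The two fixed fixtures are the three-note sonata opening
(`k545_prefix()`: (C5, 960), (E5, 480), (G5, 480)) and the two-piece
shared-prefix corpus (`shared_prefix_fixture()`), whose pieces open with
the same two notes and diverge by genre — the canonical probe of
knowledge-biased competition. The romantic continuation beyond the
divergence point is a minimal fixture convention (repeat the prefix), not
corpus data.

What the synthetic corpora do **not** emulate: real phrase structure,
meter, rests (durations are sounding spans; gaps are dropped on MIDI
read), polyphony (reduced to the highest simultaneous pitch), or the
statistics of any actual composer. Passing tests demonstrate the circuit
mechanisms — band-locked encoding, delayed sequential binding, cue-gated
competition — not musicological fidelity.

## Numerical choices

* Forward Euler at `dt = 0.5` ms with the voltage update split into two
  half-steps (the standard stabilization for this model); the recovery
  variable takes full steps. Spike counts match a 10×-finer independent
  reference integrator within ±1 spike over 1 s for drives 0–20.
* Calibration: bisection to within 10% of the target rate; unreachable
  targets are errors, not silent clamps.
* Determinism: there is no noise source anywhere in the pipeline; learning
  and composition are bit-reproducible given (corpus, config). The only
  RNG use is in the synthetic-data generator and `simulate()`'s seed-piece
  draw, both seed-controlled; the generator restores the caller's RNG
  state.
* Ties in the winner race are broken by first spike, then spike count,
  then lowest column index — fully deterministic, and made largely
  academic by the contrast exponent.
* Serialization: gzip-compressed JSON with full floating-point precision;
  archives are byte-identical across re-runs and weights round-trip
  exactly.

## Problem sizes used by the tests

The suite exercises: a 20-note single-piece replay; a 10-piece, 10-note
capacity corpus with ten composers (each replayed under its own cue); 100
random write→read MIDI round trips; 100 random (seed, length) composition
draws for the length contract; exhaustive checks over all 128 pitch and 64
duration columns for the encoding round trip and the winner-correctness
property. These sizes were chosen to cover every mechanism with margin
while keeping the default suite around a minute.

## Known limitations

* One computational neuron stands for each minicolumn per layer (the
  population within a minicolumn shares a preference, so it is collapsed).
* Weight saturation: after roughly nine repetitions of the same material,
  path weights hit the cap and further exposure changes nothing.
* Heavy cross-piece overlap within a composer can, by design of the
  parallel circuits, recombine stored material (see above); the package
  treats this as generative behaviour, not an error.
* Rests, harmony, dynamics and tempo are out of scope; timing is entirely
  tick-based.

## A worked example

```{r example, eval = FALSE}
fit <- melody_snn(shared_prefix_fixture())
seeds <- data.frame(pitch = name_to_pitch(c("A5", "E4")),
                    duration = c(240L, 120L))
compose(fit, "genre:classical", seeds, length = 4)$notes
compose(fit, "genre:romantic", seeds, length = 4)$notes
```

The classical cue continues the shared prefix with C4, D4; the romantic
cue, from identical seeds, repeats A5, E4 — the cue current is the only
difference between the two runs.
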