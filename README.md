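# spikemelody

A brain-inspired spiking neural network, in R, that **learns symbolic
melodies and composes new ones in a requested style**. Pieces — ordered
(pitch, duration) notes labelled with a genre, composer and title — are
stored in a layered minicolumn memory network trained by
spike-timing-dependent plasticity (STDP), and new melodies are generated by
letting a genre or composer cue bias a winner-take-all competition over the
stored continuations. It is aimed at computational-neuroscience and
algorithmic-composition researchers who want the full mechanism —
spiking dynamics, plasticity, oscillation bands, gating circuits — to be
inspectable and testable rather than wrapped in a black box.

## The model

Every neuron is an Izhikevich cell,

    dv/dt = 0.04 v² + 5 v + 140 − u + I,    du/dt = a (b v − u),

spiking at 30 mV with reset `v ← c`, `u ← u + d`; excitatory cells use the
regular-spiking set (a = 0.01, b = 0.2, c = −65, d = 8), interneurons the
fast-spiking set (0.1, 0.2, −65, 2). Plastic synapses follow the
exponential STDP window `Δw = A₊ e^{Δt/τ₊}` (causal) / `−A₋ e^{−Δt/τ₋}`
(anti-causal), with Δt = t_pre − t_post.

The architecture has two subsystems:

* a **sequential memory** made of a 128-column pitch subnetwork and a
  64-column duration subnetwork (60-tick grid, 480 ticks per crotchet),
  layered by sequence position, with Gaussian tuning-curve input, lateral
  inhibition within a layer, and excitatory synapses whose transmission
  delay equals the layer distance in note-slots;
* a **knowledge hierarchy** of genre, composer and title neurons
  (allocated per label) wired to the memory network, plus a fast-spiking
  interneuron pool with fixed weights that silences the off-circuit
  clusters during composition.

Learning runs in the theta band (4–8 Hz, 1 s per note); composition runs
in the gamma band (30–80 Hz, 250 ms per note). Drive currents for both
bands are calibrated automatically from the rate–current curve. See the
methods vignette (`vignettes/spiking-melody-model.Rmd`) for the full
procedure and the design decisions.

## A worked example

```r
library(spikemelody)

fit <- melody_snn(shared_prefix_fixture())   # two pieces, shared 2-note prefix
fit
#> Spiking melody network
#>   pieces learned: 2 | memory layers: 4
#>   knowledge: 2 genres, 2 composers, 2 titles | 10 interneurons
#>   synapses: 167 (87 plastic) | plastic weights in [1.09, 4.34]
#>   bands: theta 6 Hz at I = 4.5 | gamma 50 Hz at I = 31.7 (RS)

seeds <- data.frame(pitch = name_to_pitch(c("A5", "E4")),
                    duration = c(240L, 120L))
note_list(compose(fit, "genre:classical", seeds, length = 4))
#>   pitch_name midi_index ticks provenance
#> 1         A5         81   240       seed
#> 2         E4         64   120       seed
#> 3         C4         60   240  generated
#> 4         D4         62   120  generated

note_list(compose(fit, "genre:romantic", seeds, length = 4))
#>   pitch_name midi_index ticks provenance
#> 1         A5         81   240       seed
#> 2         E4         64   120       seed
#> 3         A5         81   240  generated
#> 4         E4         64   120  generated
```

Both stored pieces open with the same two notes; the cue current into the
genre cluster is the only difference between the two runs, and it decides
which continuation wins the layer-3 competition (C4 for the classical
piece, A5 for the romantic one). `write_midi()` exports any result as a
standard MIDI file; `read_midi()`/`read_corpus()` import MIDI corpora with
a CSV metadata table (path, title, composer, genre).

A command-line interface wraps the same functions:

```sh
inst/cli/spikemelody learn --metadata corpus/metadata.csv --out model.smz
inst/cli/spikemelody compose --model model.smz --style genre:classical \
    --seed-notes "A5:240,E4:120" --length 20 --out melody.mid
inst/cli/spikemelody demo-encode --midi sonata.mid
```

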