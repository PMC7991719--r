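Package: spikemelody
Title: Spiking Neural Network for Learning and Stylistic Composition of Melodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A brain-inspired spiking neural network that learns symbolic
    melodies (MIDI pitch and duration sequences tagged with genre, composer
    and title) and generates new melodies in a requested genre's or
    composer's style. Individual neurons follow the Izhikevich model with
    regular-spiking and fast-spiking parameter sets; synapses are created
    dynamically and trained with spike-timing-dependent plasticity (STDP).
    Sequential order is stored in a layered minicolumn memory network with
    slot-valued transmission delays and winner-take-all lateral inhibition,
    while a hierarchical knowledge network (genre, composer and title
    clusters plus a fast-spiking interneuron gate) binds style labels to
    melodies. Learning runs in the theta firing band and composition in the
    gamma band. Includes standard MIDI input/output, deterministic synthetic
    corpora for testing, and a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
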