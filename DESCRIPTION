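Package: fscoding
Title: First-Spike Coding and Surrogate-Gradient Training for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and supervised training of discrete-time current-based
    leaky integrate-and-fire (CUBA-LIF) spiking neural networks driven by
    asynchronous event streams (event cameras, silicon cochleas). Implements
    first-spike (FS) temporal decision coding alongside the conventional
    firing-rate (FR) readout: output spike trains are encoded into discrete
    spike times, classification follows the earliest output spike (with a
    maximum-membrane-potential fallback for silent outputs), and learning uses
    a cross-entropy loss on first-spike times whose error is assigned from
    spike times back to spikes through a negative Gaussian window, combined
    with fast-sigmoid surrogate gradients through the spiking non-linearity.
    Includes event-table input/output and spatio-temporal binning, fully
    connected, recurrent, convolutional and max-pooling layers, Adam training
    with layer-specific time constants and thresholds, empty-sequence window
    extension, evaluation metrics (accuracy versus observation window, time
    delay, mean spike count), and a synthetic event-stream generator with
    controllable temporal structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
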