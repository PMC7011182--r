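Package: optophys
Title: Analysis of Optogenetically Evoked Synaptic Currents and Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for patch-clamp and field-potential electrophysiology of
    GABAergic and glutamatergic synapses probed by optogenetic stimulation.
    Implements postsynaptic-current event detection (low-pass peak detection
    against a high-pass noise floor), a circular-shift permutation test for
    stimulus-locked responsiveness, failure-weighted amplitude and kinetic
    metrics, per-pulse charge analysis of short-term plasticity, passive
    membrane and spike-train characterization, reversal-potential fitting with
    Nernst predictions from solution compositions, and population-spike /
    field-EPSP analysis. Includes ground-truth-annotated simulators of every
    recording configuration for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
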