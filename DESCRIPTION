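Package: gmfassess
Title: Weighted-Peak Exposure Assessment for MRI Gradient Magnetic Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for occupational and general-public exposure assessment of
    the time-varying stray magnetic fields produced by MRI gradient coils.
    Implements the frequency-dependent magnetic-flux-density limit curves of
    Directive 2013/35/EU (low, high and limb action levels) and Recommendation
    1999/519/EC (reference levels) as evaluable piecewise functions, the
    weighted-peak exposure index for arbitrary single- or tri-axial
    flux-density waveforms (time-domain and spectral-line back ends, with an
    optional first-order-cascade phase model and instrument-style low-cut
    filter), offset power-law fitting of index-versus-distance profiles with
    solution of the 100 percent "clearance" crossing and an uncertainty
    estimate, and EN 50499 Annex E workplace zone classification (Zone 0, 1a,
    1b, 2). A synthetic gradient-waveform and distance-profile generator with
    known ground truth supports validation, and measured index tables from a
    survey of three clinical 1-1.5 T tomographs are packaged as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    minpack.lm
Config/testthat/edition: 3
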