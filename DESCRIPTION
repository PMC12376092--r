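Package: tdsir
Title: Transition Dipole Strength Analysis of Two-Dimensional Infrared
    Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying protein secondary structure from
    two-dimensional infrared (2D IR) spectroscopy via transition dipole
    strength (TDS) spectra.  Implements penalized least-squares baseline
    correction (Whittaker smoothing with adaptive iteratively reweighted
    weights, airPLS) for linear optical-density spectra, computation of
    the TDS spectrum from the diagonal slice of a 2D IR measurement
    normalized against an N-methylacetamide calibrant and the pump
    envelope, circular-dichroism percent-helicity estimation from mean
    residue ellipticity at 222 nm, and a linear calibration between TDS
    and alpha-helical length that predicts the longest helix in a
    protein from a measured TDS.  A synthetic-spectrum generator with
    known ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
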