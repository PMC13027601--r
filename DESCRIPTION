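Package: mefopt
Title: Spectral Optimization of Metal-Enhanced Fluorescence Nanocomplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models metal-enhanced fluorescence (MEF) of a fluorophore
    molecule coupled to a plasmonic nanosphere or nanorod. Implements both
    the traditional monochromatic description (excitation and emission
    frozen at the fluorophore's spectral peaks) and a spectrally refined
    description in which the near-field enhancement, radiative and
    non-radiative decay rates, quantum yield, and fluorescence enhancement
    factor are weighted by the fluorophore's excitation and emission
    spectra. Electromagnetic responses come from interchangeable desk-scale
    backends: an exact Mie series for spheres, a modified long-wavelength
    approximation (MLWA) for spheroid surrogates of nanorods, and a
    tabulated plug-in for externally computed solver output. Includes
    sweep, peak-tracking, gap-scan, and recommendation tools that select
    the nanorod aspect ratio and excitation wavelength maximizing the
    fluorescence enhancement of a given fluorophore.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
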