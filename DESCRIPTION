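Package: csarelax
Title: Chemical Shift Anisotropy, MAS Sideband, and Spin-Lattice Relaxation Analysis for Solid-State NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for site-specific solid-state NMR characterization of
    small molecules. Converts between chemical shift anisotropy (CSA) tensor
    conventions (frequency-ordered, Haeberlen, Herzfeld-Berger span/skew),
    simulates magic-angle-spinning (MAS) spinning-sideband intensity patterns
    from a CSA tensor by powder averaging and solves the inverse problem of
    recovering span and skew from measured sideband intensities, fits
    spin-lattice relaxation times from Torchia-type magnetization decay
    curves, and inverts a combined CSA plus heteronuclear dipole-dipole
    relaxation model for the site-specific molecular correlation time.
    Ships a fully worked dexamethasone data set (22 carbon sites) together
    with synthetic-data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
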