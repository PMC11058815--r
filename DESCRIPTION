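Package: pennstop
Title: Electronic Stopping Power of Compounds via ELF-Weighted Free-Electron-Gas Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes electronic stopping power and stopping cross-sections of
    protons in compound materials (proton-therapy-relevant polymers in
    particular) by decomposing the material into a statistical ensemble of
    free-electron gases weighted by its optical energy-loss function (the Penn
    method). Provides a Mermin/Lindhard linear-response stopping kernel, a
    loader for tabulated non-linear kernels, ELF sum-rule diagnostics, mean
    excitation energies from logarithmic ELF moments, Bragg-rule combination
    of elemental stopping tables, and relativistic Bethe/CSDA range-shift
    dosimetry for assessing the clinical impact of mean-excitation-energy
    revisions.
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
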