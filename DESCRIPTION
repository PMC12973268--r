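Package: xtbu
Title: Extended Tight-Binding with Spin Polarization, Hubbard +U and Direct-Minimization SCF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained semi-empirical extended tight-binding (GFN2-style)
    electronic-structure engine for molecules, with unrestricted spin-polarized
    Hamiltonians, three on-site Hubbard +U corrections (fully localized limit,
    around-mean-field, and pseudo self-interaction correction), finite-temperature
    Fermi smearing, and two interchangeable self-consistent-field drivers (Pulay
    DIIS extrapolation and geometric direct minimization over orbital rotations).
    Includes diagnostics for self-interaction error (fractional-occupation
    linearity scans, linear-response Hubbard U, spin-state gaps) and a parameter
    workflow layer (Sobol variance-based sensitivity, two-stage derivative-free
    plus quasi-Newton optimization, and two-dimensional parameter scans).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
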