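Package: helixpack
Title: Helix-Bundle Packing Frustration by Umbrella Sampling on Surrogate Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying packing frustration between rigid helical
    bundles: construction of rotated two-bundle systems from PDB structures or
    ideal helices, umbrella-sampling schedules with replica-exchange of biases
    on a parametric free-energy landscape over inter-bundle distance and
    helix rotation angles, WHAM estimation of distance-dependent potentials of
    mean force, basin-integrated binding free energies with block-averaged
    errors and delta-delta-G bookkeeping, enthalpy/entropy/volume
    decomposition of binding profiles, residue-pair nonbonded energetics, and
    structural diagnostics (solvent-accessible and buried surface area,
    contact probabilities, steric-clash scans). A synthetic-data generator
    with analytically known thermodynamics supports end-to-end parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
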