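Package: adiamap
Title: Adiabatic Mapping and Barrier Screening for Enzyme Variant Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for estimating enzymatic reaction barriers of wild-type
    and variant active-site models by constrained adiabatic mapping. Builds
    truncated enzyme models from PDB structures (radius selection, single-gap
    fill, aldehyde capping of cut C-termini), maintains a per-residue fragment
    library so variant structures are assembled by side-chain fragment
    substitution, generates linearly interpolated frames between the
    enzyme-substrate complex and the tetrahedral intermediate with the
    reaction-coordinate atom pair held fixed, drives a pluggable energy
    backend (MOPAC-dialect input writer and output parser for semiempirical
    PM6/MOZYME engines; a deterministic analytic surrogate surface for
    testing), and analyses the resulting energy profiles: barrier extraction,
    configuration-convergence and localized-orbital drift reports, Kabsch
    superposition RMSD, and partial Hessian vibrational analysis for
    transition-state verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
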