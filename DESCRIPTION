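Package: pepshift
Title: Semi-Empirical NMR Chemical Shift Prediction for Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts backbone NMR chemical shifts (CA, CB, C', HN, N, HA)
    from static protein structures by summing geometric descriptors --
    heavy-atom contacts, backbone hydrogen-bond geometry, peptide-group
    magnetic anisotropy, aromatic ring currents and phi/psi dihedral terms --
    onto per-residue random-coil baselines.  Every descriptor is available
    through two provably equivalent execution paths (a per-call reference
    path and a batched, vectorized path with configurable accumulation
    order), together with a validation harness that pools per-nucleus RMS
    and maximum differences between the paths across structure sets.
    Includes a synthetic peptide and helical-assembly builder so all
    geometric descriptors can be tested against exact ground truth, a
    per-nucleus least-squares weight fitter, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
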