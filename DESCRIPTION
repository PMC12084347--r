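Package: diolphase
Title: Quantitative Analysis of Alkanediol Effects on Protein Phase Separation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis toolkit for studies of how alkanediol cosolvents
    modulate the liquid-liquid phase separation of intrinsically disordered
    proteins such as the FUS low-complexity domain. Provides trajectory
    observables for protein-cosolvent simulations (residue contact maps under
    a heavy-atom distance cutoff, intrachain distance scaling, radius of
    gyration, cosolvent contact profiles, atomistic contact maps, radial
    distribution functions, solution density), NMR chemical-shift-perturbation
    and relaxation analysis (indirect referencing, per-residue and
    residue-type-binned shift deviations, cross-condition potency slopes,
    exponential rate fits, heteronuclear NOE), phase-separation assay
    quantification (saturation concentration from dilute-phase absorbance,
    two-wavelength protein/RNA deconvolution, background-corrected turbidity,
    droplet segmentation in fluorescence images), and stability/partition
    analysis (two-state van't Hoff melting fits, NMR-quantified octanol-water
    partition coefficients, cross-assay Pearson correlations with explicit
    outlier exclusion). A synthetic-data module generates every input with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    bio3d,
    tiff,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
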