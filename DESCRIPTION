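Package: edgotype
Title: Structure-Based Edgotyping of Missense Mutations and Bayesian
    Estimation of Their Fitness Effects
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to classify human missense mutations by the way they
    perturb the protein-protein interactome (quasi-wild-type, edgetic, or
    quasi-null) and to estimate the fitness effect (effectively neutral,
    mildly deleterious, or strongly detrimental) of each perturbation
    class. Builds residue-resolved structural interactomes from reference
    PPI edge lists, sequence alignments and chain-pair template
    structures; computes binding-interface residues, solvent
    accessibility and burial from 3D coordinates; applies ClinVar- and
    dbSNP-style filtering with transcript flanking-sequence verification;
    classifies edgotypes from folding and binding free-energy changes;
    and propagates class-conditional edgotype frequencies through a
    Bayesian model with confidence intervals for ratios of proportions.
    Includes a fully synthetic data generator with known ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StructuralPrediction, NetworkInference, VariantAnnotation,
    SomaticMutation, Bayesian
RoxygenNote: 7.3.3
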