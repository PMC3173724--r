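Package: fusionGA
Title: Multiobjective Genetic-Algorithm Design of Constrained Fusion Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence design by multiobjective directed evolution for fusion
    proteins that graft a donor binding motif into a scaffold domain, such as
    the MyoD DNA-binding helix grafted into helix 3 of the Z domain. Provides
    constrained-template construction with conserved binding positions, a
    three-objective fitness (local alignment of predicted secondary structure
    against the target, and spline-integral differences of windowed
    hydropathy and molecular-weight profiles), Pareto-rank driven selection
    with one-point crossover, constrained mutation and elitist replacement,
    plus downstream analysis of Calpha structures and trajectories (Kabsch
    superposition, regional RMSD, RMSF, spline smoothing) and of
    protein-DNA association kinetics (polar reaction-pair criteria and
    relative association rate constants).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'propertyTables.R'
    'template.R'
    'fitness.R'
    'evolution.R'
    'structAnalysis.R'
    'kinetics.R'
    'fixtures.R'
    'io.R'
    'pipeline.R'
    'fusionGA-package.R'
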