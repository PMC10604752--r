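Package: trajtree
Title: Disease-Trajectory Mining from Longitudinal Claims with Elastic
    Principal Trees
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining branching disease-progression trajectories
    from longitudinal diagnosis claims. Diagnosis records (patient, date,
    ICD-9 code) are encoded as per-patient-day cumulative disease states,
    standardized and embedded by principal component analysis, and
    approximated by an elastic principal tree. The tree is rooted at the
    pre-diagnosis (all-zero) state and oriented away from it; each directed
    edge is annotated with the diseases whose mean cumulative count
    increases across the transition and with the branch-only subset unique
    to that edge. A case/control odds-ratio screen selects candidate
    comorbidities, and each patient's final observed state is classified
    onto a single trajectory or into an uncategorized group. A synthetic
    claims generator with a planted branching topology and matched controls
    makes every stage testable without access to protected claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epidemiology, DimensionReduction, Clustering, GraphAndNetwork
RoxygenNote: 7.3.3
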