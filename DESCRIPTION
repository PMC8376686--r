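Package: pprnet
Title: Network Diffusion Modelling of Neurodegenerative Pathology Spread
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward and inverse tools for the Network Diffusion Model (NDM)
    of trans-network pathology spread on brain structural connectomes.
    Provides graph-Laplacian heat-kernel evolution of regional pathology,
    closed-form accumulation of atrophy, and estimation of a per-subject
    Pathology Progression Rate (the diffusivity beta, 1/year) from
    longitudinal regional atrophy via correlation-based onset-time search
    and scalar least squares. Includes cohort-level analyses (CSF biomarker
    z-scoring, Ward hierarchical clustering with Calinski-Harabasz model
    selection, non-parametric group comparisons, baseline regression), a
    fully deterministic synthetic-cohort generator with known ground truth,
    and a command-line interface for reproducible simulate/fit/report runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
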