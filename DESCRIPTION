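Package: latticeAT
Title: On-Lattice Agent-Based Simulation of Adaptive Cancer Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Stochastic 2D on-lattice agent-based simulator of competition
    between drug-sensitive and drug-resistant tumour cells under continuous
    maximum-tolerated-dose therapy and adaptive (on-off) therapy. Supports
    clumped, random and uniform initial placements of resistant cells, static
    cancer-associated fibroblast (CAF) regions that locally promote
    proliferation, per-site carrying capacities of one or two cells,
    neighborhood competition metrics, 30-realization cohort experiments with
    seed-paired treatment comparisons, and a four-lesion virtual patient
    driven by a single systemic dose controller. The update kernel is
    implemented in C++ for speed; all results are reproducible from integer
    seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
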