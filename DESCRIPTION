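Package: photoruler
Title: Photo-Switchable Cross-Linkers as Molecular Rulers for Trimeric
    Channel Gating
Version: 0.1.0
Authors@R:
    person("Photoruler", "Developers", email = "photoruler@example.org",
           role = c("aut", "cre"))
Description: Models azobenzene-based photo-switchable bifunctional
    cross-linkers ("molecular tweezers") as distance rulers for the gating
    of trimeric ion channels. Provides a kinematic conformer sampler for
    the reacted cross-linker in fixed cis or trans configuration, pooled
    stereoisomer distance distributions with Gaussian fits, inter-subunit
    distance measurement on trimeric coordinate files, HOLE-style pore
    radius profiles, cross-link combinatorics on concatenated trimers, and
    the electrophysiology fits (Hill, single-exponential, GHK permeability
    ratios, all-points histogram Gaussian mixtures) used to quantify
    light-gated currents. A synthetic-data module generates every fixture
    deterministically so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
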