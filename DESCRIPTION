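Package: florabias
Title: Detection of Taxonomic Selection Bias in Flora Use Checklists
Version: 0.1.0
Authors@R:
    person("florabias", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether useful plants are selected at random from
    a flora. Given per-family counts of native species and of species with a
    recorded use, the package estimates two-sided interval bounds for each
    family's use proportion under two constructions: an exceedance-pair
    (Clopper-Pearson-style) beta-quantile scheme and the Imprecise Dirichlet
    Model. Families whose interval lies entirely above or below the overall
    flora's interval are flagged as overused or underused. Includes a bundled
    reference dataset of wild food plant use across Brazilian angiosperm
    families, checklist aggregation utilities, a synthetic-flora simulator
    for coverage and power experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
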