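Package: accmap
Title: Brain-Wide Activation Mapping and Behavioral Analytics for Rodent
    Pain-Anxiety Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying brain-wide FOS activation patterns and
    behavioral phenotypes in rodent chronic-pain models. Implements the
    forward-model (Haufe) transformation of linear classifier weights into
    interpretable region-wise activation patterns with shrinkage covariance
    estimation and cumulative contribution curves; computational-ethology
    summaries of labeled behavioral bouts (action proportions, Markov
    transition matrices, hierarchical clustering, t-SNE embedding);
    deterministic scoring of von Frey, open-field and elevated plus-maze
    assays; fiber-photometry dF/F with isosbestic correction and peri-event
    area under the curve; paired-pulse ratios; and a shared
    normality/variance-gated two-group test selector with false discovery
    rate control. A synthetic-data module generates every supported input
    kind with known ground truth so each stage can be validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
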