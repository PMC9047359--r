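Package: chemophylo
Title: Chemotaxonomy from Tandem Mass Spectrometry: Molecular Networking
    and Ancestral State Reconstruction of Chemical Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for chemotaxonomic analysis of
    LC-MS/MS metabolomics data across a phylogeny. Reads MGF spectra and
    feature quantification tables, builds feature-based molecular networks
    with the modified cosine score, annotates features against a spectral
    library, ordinates chemical profiles (PCoA, PERMANOVA on Bray-Curtis
    and Canberra distances), summarises features into chemical classes,
    tests clade-level class enrichment (arcsine-square-root ANOVA with
    Benjamini-Hochberg correction, Tukey post hoc tests and log2 fold
    changes), codes class detections as binary genus-level characters, and
    reconstructs their ancestral states on a phylogeny under the one-rate
    Mk model by maximum likelihood, classifying each chemical class as a
    clade synapomorphy or homoplasy. A synthetic-data module generates
    ground-truthed spectra, feature tables, trees and characters so that
    every stage is testable without raw instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
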