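Package: chctax
Title: Cuticular Hydrocarbon Chemotaxonomy from GC-MS Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying insect cuticular hydrocarbons (CHCs) from
    gas chromatography-mass spectrometry evidence and for comparing population
    CHC profiles as chemotaxonomic characters. Implements nomenclature parsing
    for n-alkanes, alkenes and methyl-branched alkanes; nominal-mass prediction
    of diagnostic electron-impact ions at methyl branch points and of dimethyl
    disulfide (DMDS) adduct fragments, with inversion of observed DMDS
    fragments to the double-bond position; linear temperature-programmed
    retention (Kovats) indices against an n-alkane ladder; peak-area
    normalization, class composition and group contrasts (Student's t, one-way
    ANOVA with Student-Newman-Keuls letters); Bray-Curtis distances, NMDS,
    one-way PERMANOVA and UPGMA clustering; ordinal coding of mean profiles
    into a chemotaxonomic character matrix, UPGMA trees with newick export and
    Robinson-Foulds comparison against trees from independent markers; and a
    seeded logistic-normal simulator of individual-level compositional
    profiles with detection censoring. Bundles reference peak tables for the
    bark beetle Ips subelongatus (six geographic populations, both sexes).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
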