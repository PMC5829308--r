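Package: migut
Title: Market-Integration Gradients and the Gut Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable pipeline linking household market-integration
    measures to gut-microbiome attributes. Extracts latent lifestyle factors
    from style-of-life indicators by maximum-likelihood exploratory factor
    analysis, computes Faith's phylogenetic diversity and weighted UniFrac
    distances from a rooted phylogeny, evaluates a windowed beta-dispersion
    statistic along continuous factor-score gradients, and tests composition
    effects with PERMANOVA, partial distance-based redundancy analysis, and a
    Benjamini-Yekutieli corrected per-taxon correlation screen. A synthetic
    community generator with covariate-dependent diversity and dispersion
    structure makes every stage testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    phyloseq,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
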