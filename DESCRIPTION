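Package: beflink
Title: Linking Soil Microbial Diversity, Neutral Assembly, and Multinutrient Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cross-habitat soil microbiome surveys that
    links microbial diversity to a multinutrient cycling index (MNC) and
    explains the strength of that link through community assembly and
    bacterial-fungal association balance. Provides two-kingdom OTU table
    handling, total-sum and median-of-ratios normalization, multidiversity and
    MNC indices, Bray-Curtis/NMDS ordination with ANOSIM, Sloan neutral
    community model fitting (migration rate, generalized R-squared, per-OTU
    neutrality classes), prevalence-filtered Spearman co-occurrence networks
    with FDR control and kingdom-partitioned negative-association proportions,
    a group-level meta-analysis with random-forest predictor importance, and a
    beta-multinomial synthetic community generator with known ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    randomForest,
    DESeq2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
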