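Package: taxaformer
Title: Microbiome Language Modeling with Rank-Tokenized Transformers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Treats a microbiome sample as a sentence: taxa are tokens,
    ordered by decreasing relative abundance, and a transformer encoder with
    frozen vocabulary embeddings is pre-trained with an ELECTRA
    generator/discriminator scheme (replaced-taxon detection). The frozen
    encoder is then fine-tuned with lightweight classification heads for
    binary host-phenotype prediction, single or ensembled. The package also
    provides feature-ablation taxon attribution with cross-study sign
    validation, quantitative evaluation of contextualized taxon embeddings
    (k-means phylum-purity curves, pathway rank-correlation screens with
    permutation significance, two-sample distribution tests), patient-blocked
    evaluation protocols with AUROC/AUPR, and a synthetic community generator
    with planted ground truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
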