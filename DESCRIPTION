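Package: kgtext
Title: Multi-Modal Knowledge Graph and Literature Embeddings for Drug
    Target and Indication Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates a typed biomedical knowledge graph (drugs, genes,
    diseases, phenotypes, ontology classes) with entity-normalized
    literature abstracts in a single representation-learning framework.
    Edge-labeled random walks over the graph and PubTator-annotated
    abstracts normalized to graph IRIs yield two token-compatible corpora;
    skip-gram with negative sampling (and TransE over triples) learns
    embeddings from either corpus, their concatenation, or their union.
    Supervised classifiers (neural network, random forest, logistic
    regression, Siamese network) over concatenated entity embeddings
    predict drug-target interactions and drug indications, evaluated by
    AUROC, AUPR, per-drug recall and candidate ranking. A synthetic-data
    generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    randomForest,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'classifiers.R'
    'kg-build.R'
    'kg-io.R'
    'kgtext-package.R'
    'predict-eval.R'
    'skipgram.R'
    'walker.R'
    'text-norm.R'
    'synthgen.R'
    'pipeline.R'
    'transe.R'
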