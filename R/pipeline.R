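#' @include synthgen.R walker.R skipgram.R classifiers.R predict-eval.R
NULL

#' End-to-end multi-modal link-prediction pipeline
#'
#' Wires the full method together for one task: removes the task's edges
#' from the graph (`has_target` for drug-target prediction,
#' `has_indication` for indications), generates the edge-labeled walk
#' corpus, normalizes the abstracts into the text corpus, trains skip-gram
#' embeddings for each requested modality (`"kg"`, `"text"`, `"joint"` on
#' the shuffled concatenated corpus, `"concat"` by stacking the kg and
#' text tables with zero fill), builds one shared balanced pair dataset
#' over the selected entity pool, then trains and evaluates one classifier
#' per modality on identical train/test pairs.
#'
#' @param kg a [KnowledgeGraph-class] including the positive edges.
#' @param docs list of [AnnotatedDocument-class].
#' @param map an [idMap()].
#' @param groundTruth data.frame of positive pairs (`drug`, `candidate`).
#' @param task `"target"` or `"indication"`.
#' @param modalities subset of `c("kg", "text", "joint", "concat")`.
#' @param classifierKind passed to [classifierSpec()].
#' @param walkCfg a [walkConfig()].
#' @param sgCfg a [skipGramConfig()].
#' @param poolMode entity-pool mode; see [selectEntityPool()].
#' @param ratio,testFraction passed to [buildPairDataset()].
#' @param seed integer seed driving negative sampling, the joint-corpus
#'   shuffle and classifier initialization.
#' @return list with `reports` (named list of [EvalReport-class]),
#'   `embeddings` (named list of [EmbeddingTable-class]), `dataset`
#'   (train/test [PairDataset-class] list), `corpora`.
#' @export
runPipeline <- function(kg, docs, map, groundTruth, task = "target",
                        modalities = c("kg", "text", "joint"),
                        classifierKind = "ann",
                        walkCfg = walkConfig(seed = deriveSeed(seed, 11L)),
                        sgCfg = skipGramConfig(seed = deriveSeed(seed, 12L)),
                        poolMode = "overlap", ratio = 1, testFraction = 0.2,
                        seed = 1) {
  task <- match.arg(task, c("target", "indication"))
  modalities <- match.arg(modalities,
                          c("kg", "text", "joint", "concat"),
                          several.ok = TRUE)
  predicate <- if (task == "target") "has_target" else "has_indication"
  kgEval <- removeEdgesByPredicate(kg, predicate)
  walks <- generateWalks(kgEval, walkCfg)
  textCorpus <- buildTextCorpus(docs, map)

  # both base tables are always trained: the entity pool is defined by the
  # tokens each modality actually represents
  embKg <- trainSkipgram(walks, sgCfg)
  embText <- trainSkipgram(textCorpus, sgCfg)
  embeddings <- list()
  for (m in modalities) {
    embeddings[[m]] <- switch(m,
      kg = embKg,
      text = embText,
      joint = trainSkipgram(concatCorpora(walks, textCorpus,
                                          seed = deriveSeed(seed, 13L)),
                            sgCfg),
      concat = concatEmbeddings(embKg, embText, policy = "zero_fill"))
  }

  types <- nodeTypes(kg)
  candType <- if (task == "target") "gene" else "disease"
  poolOf <- function(entityType) {
    all <- names(types)[types == entityType]
    selectEntityPool(intersect(all, vocabulary(embKg)),
                     intersect(all, vocabulary(embText)), poolMode)
  }
  drugPool <- poolOf("drug")
  candPool <- poolOf(candType)
  if (!length(drugPool) || !length(candPool))
    stop("empty entity pool under mode '", poolMode, "'")

  dataset <- buildPairDataset(groundTruth, drugPool, candPool, ratio = ratio,
                              seed = deriveSeed(seed, 14L),
                              testFraction = testFraction)
  reports <- lapply(embeddings, function(emb) {
    model <- trainClassifier(classifierSpec(classifierKind), dataset$train,
                             emb, seed = deriveSeed(seed, 15L))
    evaluatePairs(model, dataset$test, emb)
  })
  list(reports = reports, embeddings = embeddings, dataset = dataset,
       corpora = list(walks = walks, text = textCorpus))
}
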