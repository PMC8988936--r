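#' @include AllClasses.R
NULL

#' Accessors for kgtext containers
#'
#' @param x a kgtext object.
#' @return `triples()` the triple data.frame; `nodes()` the node IRIs;
#'   `nodeTypes()` the named entity-type vector; `tripleCount()` /
#'   `nodeCount()` integer counts; `sentences()` the list of token
#'   sentences; `vocabulary()` the token vocabulary; `embeddingVectors()`
#'   the numeric matrix; `embeddingDim()` the vector dimension;
#'   `pairs()` the labeled pair data.frame; `documentText()` the
#'   concatenated `title + " " + abstract`.
#' @name accessors
#' @aliases triples nodes nodeTypes tripleCount nodeCount sentences
#'   vocabulary embeddingVectors embeddingDim pairs documentText
NULL

#' @rdname accessors
#' @export
setGeneric("triples", function(x) standardGeneric("triples"))
#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname accessors
#' @export
setGeneric("nodeTypes", function(x) standardGeneric("nodeTypes"))
#' @rdname accessors
#' @export
setGeneric("tripleCount", function(x) standardGeneric("tripleCount"))
#' @rdname accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))
#' @rdname accessors
#' @export
setGeneric("sentences", function(x) standardGeneric("sentences"))
#' @rdname accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname accessors
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))
#' @rdname accessors
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
#' @rdname accessors
#' @export
setGeneric("pairs", function(x) standardGeneric("pairs"))
#' @rdname accessors
#' @export
setGeneric("documentText", function(x) standardGeneric("documentText"))

#' @rdname accessors
setMethod("triples", "KnowledgeGraph", function(x) x@triples)
#' @rdname accessors
setMethod("nodes", "KnowledgeGraph", function(x) names(x@nodeType))
#' @rdname accessors
setMethod("nodeTypes", "KnowledgeGraph", function(x) x@nodeType)
#' @rdname accessors
setMethod("tripleCount", "KnowledgeGraph", function(x) nrow(x@triples))
#' @rdname accessors
setMethod("nodeCount", "KnowledgeGraph", function(x) length(x@nodeType))
#' @rdname accessors
setMethod("sentences", "Corpus", function(x) x@sentences)
#' @rdname accessors
setMethod("vocabulary", "EmbeddingTable", function(x) rownames(x@vectors))
#' @rdname accessors
setMethod("embeddingVectors", "EmbeddingTable", function(x) x@vectors)
#' @rdname accessors
setMethod("embeddingDim", "EmbeddingTable", function(x) ncol(x@vectors))
#' @rdname accessors
setMethod("pairs", "PairDataset", function(x) x@pairs)
#' @rdname accessors
setMethod("documentText", "AnnotatedDocument",
          function(x) paste(x@title, x@abstract))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
setMethod("adjacency", "KnowledgeGraph", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
setMethod("annotations", "AnnotatedDocument", function(x) x@annotations)

#' @rdname accessors
#' @export
setGeneric("auroc", function(x) standardGeneric("auroc"))
#' @rdname accessors
setMethod("auroc", "EvalReport", function(x) x@auroc)

#' @rdname accessors
#' @export
setGeneric("aupr", function(x) standardGeneric("aupr"))
#' @rdname accessors
setMethod("aupr", "EvalReport", function(x) x@aupr)

#' @rdname accessors
#' @export
setGeneric("perDrugRecall", function(x) standardGeneric("perDrugRecall"))
#' @rdname accessors
setMethod("perDrugRecall", "EvalReport", function(x) x@perDrugRecall)

#' @rdname accessors
#' @export
setGeneric("macroRecall", function(x) standardGeneric("macroRecall"))
#' @rdname accessors
setMethod("macroRecall", "EvalReport", function(x) x@macroRecall)

#' @rdname accessors
#' @export
setGeneric("rankings", function(x) standardGeneric("rankings"))
#' @rdname accessors
setMethod("rankings", "EvalReport", function(x) x@rankings)

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))
#' @rdname accessors
setMethod("lossTrace", "TransEModel", function(x) x@lossTrace)
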