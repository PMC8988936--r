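#' @include utils.R
NULL

#' KnowledgeGraph: a directed, edge-labeled biomedical graph
#'
#' Holds a set of typed nodes and a deduplicated set of directed labeled
#' triples (subject, predicate, object), together with a per-node outgoing
#' adjacency index kept exactly consistent with the triple set.
#'
#' @slot triples data.frame with character columns `subject`, `predicate`,
#'   `object`; one row per distinct triple.
#' @slot nodeType named character vector; names are node IRIs, values are
#'   entity types (`drug`, `gene`, `disease`, `phenotype`, `function_class`
#'   or `other`).
#' @slot adjacency named list, parallel to `nodeType`; each element a
#'   data.frame with columns `predicate`, `object` listing the node's
#'   outgoing edges.
#'
#' @seealso [buildGraph()], [removeEdgesByPredicate()], [writeNTriples()]
#' @exportClass KnowledgeGraph
setClass("KnowledgeGraph",
  representation(triples = "data.frame",
                 nodeType = "character",
                 adjacency = "list"))

setValidity("KnowledgeGraph", function(object) {
  tr <- object@triples
  msgs <- character()
  if (!all(c("subject", "predicate", "object") %in% names(tr)))
    return("'triples' must have columns subject, predicate, object")
  if (nrow(tr)) {
    if (!all(vapply(tr[c("subject", "predicate", "object")], is.character,
                    logical(1))))
      msgs <- c(msgs, "triple columns must be character")
    if (anyDuplicated(tripleKey(tr$subject, tr$predicate, tr$object)))
      msgs <- c(msgs, "duplicate triples")
    if (any(!nzchar(tr$subject)) || any(!nzchar(tr$predicate)) ||
        any(!nzchar(tr$object)))
      msgs <- c(msgs, "empty subject/predicate/object")
    if (!all(tr$subject %in% names(object@nodeType)) ||
        !all(tr$object %in% names(object@nodeType)))
      msgs <- c(msgs, "triple endpoint not registered as a node")
  }
  if (!identical(sort(names(object@adjacency)), sort(names(object@nodeType))))
    msgs <- c(msgs, "adjacency nodes differ from registered nodes")
  nOut <- sum(vapply(object@adjacency, nrow, integer(1)))
  if (nOut != nrow(tr))
    msgs <- c(msgs, "adjacency edge count differs from triple count")
  if (length(msgs)) msgs else TRUE
})

#' Corpus: a list of token sentences
#'
#' A corpus is a list of character vectors; each element is one sentence of
#' whitespace-free tokens (IRIs, relation labels, or lowercased words).
#' `WalkCorpus` marks sentences emitted by graph random walks (corpus 1);
#' `TextCorpus` marks sentences from normalized abstracts (corpus 2).
#'
#' @slot sentences list of character vectors.
#' @aliases WalkCorpus-class TextCorpus-class
#' @exportClass Corpus
#' @exportClass WalkCorpus
#' @exportClass TextCorpus
setClass("Corpus", representation(sentences = "list"))
setClass("WalkCorpus", contains = "Corpus")
setClass("TextCorpus", contains = "Corpus")

setValidity("Corpus", function(object) {
  ok <- vapply(object@sentences, is.character, logical(1))
  if (!all(ok)) return("all sentences must be character vectors")
  if (any(vapply(object@sentences, function(s) any(is.na(s) | !nzchar(s)),
                 logical(1))))
    return("sentences must not contain NA or empty tokens")
  TRUE
})

#' EmbeddingTable: token-to-vector mapping
#'
#' Fixed-dimension real vectors for an ordered vocabulary of tokens,
#' stored as a numeric matrix with tokens as row names.
#'
#' @slot vectors numeric matrix; rows = tokens, columns = dimensions.
#' @seealso [trainSkipgram()], [concatEmbeddings()], [writeVectors()]
#' @exportClass EmbeddingTable
setClass("EmbeddingTable", representation(vectors = "matrix"))

setValidity("EmbeddingTable", function(object) {
  v <- object@vectors
  if (!is.numeric(v)) return("'vectors' must be numeric")
  if (nrow(v) && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
    return("'vectors' must have unique row names (the vocabulary)")
  if (length(v) && any(!is.finite(v))) return("non-finite embedding entries")
  TRUE
})

#' TransEModel: translational knowledge-graph embeddings
#'
#' Entity and relation vectors trained so that for a true triple
#' (s, p, o) the translation s + p lies close to o under the configured
#' L1 or L2 distance; see [trainTransE()].
#'
#' @slot entities numeric matrix of entity vectors (rownames = entity IRIs).
#' @slot relations numeric matrix of relation vectors.
#' @slot config list; the [transeConfig()] used for training.
#' @slot lossTrace numeric; per-epoch mean margin-ranking loss.
#' @exportClass TransEModel
setClass("TransEModel",
  representation(entities = "matrix", relations = "matrix",
                 config = "list", lossTrace = "numeric"))

setValidity("TransEModel", function(object) {
  if (ncol(object@entities) != ncol(object@relations))
    return("entity and relation dimensions differ")
  if (any(!is.finite(object@entities)) || any(!is.finite(object@relations)))
    return("non-finite embedding entries")
  TRUE
})

#' PairDataset: labeled (drug, candidate) pairs
#'
#' @slot pairs data.frame with character columns `drug`, `candidate` and an
#'   integer/numeric column `label` (0/1).
#' @slot split character; `"train"` or `"test"`.
#' @seealso [buildPairDataset()]
#' @exportClass PairDataset
setClass("PairDataset",
  representation(pairs = "data.frame", split = "character"))

setValidity("PairDataset", function(object) {
  p <- object@pairs
  if (!all(c("drug", "candidate", "label") %in% names(p)))
    return("'pairs' must have columns drug, candidate, label")
  if (nrow(p)) {
    if (!all(p$label %in% c(0, 1))) return("labels must be 0/1")
    key <- paste(p$drug, p$candidate, sep = "\r")
    if (any(tapply(p$label, key, function(l) length(unique(l))) > 1L))
      return("a pair appears with both labels")
  }
  if (!object@split %in% c("train", "test", "all"))
    return("split must be 'train', 'test' or 'all'")
  TRUE
})

#' EvalReport: link-prediction evaluation summary
#'
#' @slot auroc area under the ROC curve (ties credited 1/2).
#' @slot aupr area under the precision-recall curve (step integration).
#' @slot perDrugRecall named numeric; recall at score threshold 0.5 for each
#'   drug with at least one positive test pair.
#' @slot macroRecall unweighted mean of `perDrugRecall`.
#' @slot rankings named list; per drug, a data.frame of its test candidates
#'   ordered by descending score with the ranks of known positives.
#' @seealso [evaluatePairs()]
#' @exportClass EvalReport
setClass("EvalReport",
  representation(auroc = "numeric", aupr = "numeric",
                 perDrugRecall = "numeric", macroRecall = "numeric",
                 rankings = "list"))

setValidity("EvalReport", function(object) {
  if (object@auroc < 0 || object@auroc > 1) return("auroc outside [0,1]")
  if (object@aupr < 0 || object@aupr > 1) return("aupr outside [0,1]")
  TRUE
})

#' AnnotatedDocument: a PubTator-style annotated abstract
#'
#' Text plus entity annotations with character offsets.  Offsets are
#' 0-based, end-exclusive, over `title + " " + abstract`.
#'
#' @slot docId document identifier (PMID).
#' @slot title title text.
#' @slot abstract abstract text.
#' @slot annotations data.frame with columns `start`, `end` (integer
#'   offsets), `mention`, `type`, `identifier` (character), sorted by
#'   `start`.
#' @seealso [parsePubtator()], [normalizeDocument()]
#' @exportClass AnnotatedDocument
setClass("AnnotatedDocument",
  representation(docId = "character", title = "character",
                 abstract = "character", annotations = "data.frame"))

setValidity("AnnotatedDocument", function(object) {
  a <- object@annotations
  need <- c("start", "end", "mention", "type", "identifier")
  if (!all(need %in% names(a)))
    return("annotations must have columns start, end, mention, type, identifier")
  if (nrow(a)) {
    txt <- documentText(object)
    if (any(a$start < 0) || any(a$end > nchar(txt)) || any(a$start >= a$end))
      return("annotation offsets out of range")
    if (is.unsorted(a$start)) return("annotations must be sorted by start")
    slice <- substring(txt, a$start + 1L, a$end)
    if (!all(slice == a$mention))
      return("annotation mention does not match the text slice")
  }
  TRUE
})

# --- show methods ---------------------------------------------------------

setMethod("show", "KnowledgeGraph", function(object) {
  tt <- table(object@nodeType)
  cat(sprintf("KnowledgeGraph: %d nodes, %d triples\n",
              length(object@nodeType), nrow(object@triples)))
  if (length(tt))
    cat("  node types: ",
        paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n",
        sep = "")
  pp <- table(object@triples$predicate)
  if (length(pp))
    cat("  predicates: ",
        paste(sprintf("%s=%d", names(pp), pp), collapse = ", "), "\n",
        sep = "")
})

setMethod("show", "Corpus", function(object) {
  n <- length(object@sentences)
  nt <- sum(lengths(object@sentences))
  cat(sprintf("%s: %d sentences, %d tokens\n", class(object), n, nt))
  if (n) {
    ex <- object@sentences[[1L]]
    cat("  [1] ", paste(head(ex, 8L), collapse = " "),
        if (length(ex) > 8L) " ..." else "", "\n", sep = "")
  }
})

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d tokens x %d dimensions\n",
              nrow(object@vectors), ncol(object@vectors)))
})

setMethod("show", "TransEModel", function(object) {
  cat(sprintf("TransEModel: %d entities, %d relations, dim %d, norm %s\n",
              nrow(object@entities), nrow(object@relations),
              ncol(object@entities), object@config$norm))
  if (length(object@lossTrace))
    cat(sprintf("  final mean loss: %.4f\n",
                object@lossTrace[length(object@lossTrace)]))
})

setMethod("show", "PairDataset", function(object) {
  cat(sprintf("PairDataset (%s): %d pairs (%d positive, %d negative)\n",
              object@split, nrow(object@pairs),
              sum(object@pairs$label == 1), sum(object@pairs$label == 0)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: AUROC %.3f, AUPR %.3f, macro recall %.3f (%d drugs)\n",
              object@auroc, object@aupr, object@macroRecall,
              length(object@perDrugRecall)))
})

setMethod("show", "AnnotatedDocument", function(object) {
  cat(sprintf("AnnotatedDocument %s: %d annotations\n  %s\n",
              object@docId, nrow(object@annotations),
              substr(documentText(object), 1, 70)))
})
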