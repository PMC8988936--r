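#' @include AllGenerics.R
NULL

#' Canonical relation vocabulary
#'
#' The relation names used when building the knowledge graph: drug-target,
#' drug-indication, drug-side-effect, gene-disease, disease-phenotype,
#' gene-function, protein-protein and ontology subclass links.
#'
#' @return character vector of relation names.
#' @export
relationVocabulary <- function() {
  c("has_target", "has_indication", "has_sideeffect",
    "has_disease_association", "has_disease_phenotype", "has_function",
    "interacts_with", "subclass_of")
}

#' Default IRI-prefix to entity-type map
#'
#' Nodes are typed by longest-prefix match of their IRI against this map;
#' unknown prefixes fall back to `"other"`.
#'
#' @return named character vector mapping IRI prefixes to entity types.
#' @export
defaultTypeMap <- function() {
  c("stitch:" = "drug", "entrez:" = "gene", "doid:" = "disease",
    "hp:" = "phenotype", "go:" = "function_class")
}

# Construct a deduplicated triple data.frame, validating Triple invariants.
tripleSet <- function(subject = character(), predicate = character(),
                      object = character()) {
  subject <- as.character(subject)
  predicate <- as.character(predicate)
  object <- as.character(object)
  if (length(predicate) == 1L && length(subject) != 1L)
    predicate <- rep(predicate, length(subject))
  if (any(is.na(subject)) || any(is.na(predicate)) || any(is.na(object)) ||
      any(!nzchar(subject)) || any(!nzchar(predicate)) || any(!nzchar(object)))
    stop("triples must have non-empty subject, predicate and object")
  df <- data.frame(subject = subject, predicate = predicate, object = object,
                   stringsAsFactors = FALSE)
  df[!duplicated(tripleKey(df$subject, df$predicate, df$object)), ,
     drop = FALSE]
}

emptyTripleSet <- function() tripleSet()

# Outgoing adjacency, one data.frame(predicate, object) per node.
buildAdjacency <- function(tr, nodeIris) {
  adj <- vector("list", length(nodeIris))
  names(adj) <- nodeIris
  empty <- data.frame(predicate = character(), object = character(),
                      stringsAsFactors = FALSE)
  for (i in seq_along(adj)) adj[[i]] <- empty
  if (nrow(tr)) {
    sp <- split(tr[c("predicate", "object")], tr$subject)
    sp <- lapply(sp, function(d) { rownames(d) <- NULL; d })
    adj[names(sp)] <- sp
  }
  adj
}

typeNodes <- function(iris, typeMap) {
  if (!length(iris)) return(setNames(character(), character()))
  types <- rep("other", length(iris))
  if (length(typeMap)) {
    # longest-prefix match
    prefixes <- names(typeMap)[order(-nchar(names(typeMap)))]
    for (p in prefixes) {
      hit <- types == "other" & startsWith(iris, p)
      types[hit] <- typeMap[[p]]
    }
  }
  setNames(types, iris)
}

#' Build a knowledge graph from triple sets
#'
#' Takes the union of one or more triple sets (data.frames with columns
#' `subject`, `predicate`, `object`, as returned by [loadEdgeTSV()] or
#' [loadOboHierarchy()]), registers every endpoint as a node, and types
#' nodes by longest-prefix match against `typeMap` (unknown prefixes become
#' `"other"`).  The result is order-independent: permuting the input sets
#' yields an identical graph.
#'
#' @param tripleSets list of triple data.frames (a single data.frame is
#'   also accepted).
#' @param typeMap named character vector mapping IRI prefixes to entity
#'   types; see [defaultTypeMap()].
#' @param nodes optional character vector of additional node IRIs to
#'   register even when no triple touches them (isolated entities).
#' @return a [KnowledgeGraph-class].
#' @examples
#' tr <- data.frame(subject = "stitch:00110635", predicate = "has_indication",
#'                  object = "doid:65")
#' buildGraph(list(tr))
#' @export
buildGraph <- function(tripleSets, typeMap = defaultTypeMap(),
                       nodes = NULL) {
  if (is.data.frame(tripleSets)) tripleSets <- list(tripleSets)
  stopifnot(is.list(tripleSets))
  if (length(tripleSets)) {
    all <- do.call(rbind, lapply(tripleSets, function(t)
      tripleSet(t$subject, t$predicate, t$object)))
    tr <- all[!duplicated(tripleKey(all$subject, all$predicate, all$object)), ,
              drop = FALSE]
    # canonical row order: graphs built from permuted inputs are identical
    tr <- tr[order(tr$subject, tr$predicate, tr$object), , drop = FALSE]
    rownames(tr) <- NULL
  } else {
    tr <- emptyTripleSet()
  }
  iris <- sort(unique(c(tr$subject, tr$object, nodes)))
  nodeType <- typeNodes(iris, typeMap)
  new("KnowledgeGraph", triples = tr, nodeType = nodeType,
      adjacency = buildAdjacency(tr, iris))
}

#' Remove all edges with a given predicate
#'
#' Returns a new graph with zero triples of `predicate`; all other triples
#' and all nodes (including nodes left isolated) are preserved, so random
#' walks can still start from them.  The input graph is not modified.
#' Removing an absent predicate returns an identical copy; removal is
#' idempotent and commutes across distinct predicates.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param predicate relation name to delete (e.g. `"has_target"`).
#' @return a [KnowledgeGraph-class].
#' @export
removeEdgesByPredicate <- function(graph, predicate) {
  stopifnot(is(graph, "KnowledgeGraph"), isSingleString(predicate))
  tr <- graph@triples[graph@triples$predicate != predicate, , drop = FALSE]
  rownames(tr) <- NULL
  new("KnowledgeGraph", triples = tr, nodeType = graph@nodeType,
      adjacency = buildAdjacency(tr, names(graph@nodeType)))
}

# membership test used by corpus validation and leakage checks
hasTriple <- function(graph, s, p, o) {
  tr <- graph@triples
  tripleKey(s, p, o) %in% tripleKey(tr$subject, tr$predicate, tr$object)
}
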