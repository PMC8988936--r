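#' @include kg-build.R
NULL

#' Random-walk configuration
#'
#' Settings for edge-labeled iterated random walks of fixed length without
#' restart.  `walkLength` counts node visits per walk; with edge labels on,
#' sentences alternate node, edge, node, ... and have at most
#' `2 * walkLength - 1` tokens.
#'
#' @param walkLength positive integer; node visits per walk.
#' @param numWalks positive integer; walks started per node.
#' @param seed integer RNG seed.
#' @param includeEdgeLabels emit relation labels as tokens between nodes.
#' @return a `WalkConfig` list.
#' @export
walkConfig <- function(walkLength = 10, numWalks = 20, seed = 1,
                       includeEdgeLabels = TRUE) {
  stopifnot(walkLength >= 1, numWalks >= 1)
  structure(list(walkLength = as.integer(walkLength),
                 numWalks = as.integer(numWalks),
                 seed = as.integer(seed),
                 includeEdgeLabels = isTRUE(includeEdgeLabels)),
            class = "WalkConfig")
}

#' Generate the random-walk corpus (corpus 1)
#'
#' Starts `numWalks` walks from every node (nodes iterated in sorted IRI
#' order, one seeded pseudorandom stream, so results are machine
#' independent).  At each step one outgoing `(predicate, object)` edge is
#' chosen uniformly at random; a walk ends early at a sink node, and a
#' walk started at a sink emits the single-node sentence.  The sentence
#' count is exactly `numWalks * nodeCount(graph)`.
#'
#' @param graph a non-empty [KnowledgeGraph-class].
#' @param config a [walkConfig()].
#' @return a [Corpus-class] of class `WalkCorpus`.
#' @export
generateWalks <- function(graph, config = walkConfig()) {
  stopifnot(is(graph, "KnowledgeGraph"), inherits(config, "WalkConfig"))
  iris <- sort(names(graph@nodeType))
  if (!length(iris)) stop("graph is empty")
  n <- length(iris)
  idx <- setNames(seq_len(n), iris)

  # CSR-style out-edge index over integer node ids
  tr <- graph@triples
  deg <- integer(n)
  edgeObj <- integer(0)
  edgePred <- character(0)
  if (nrow(tr)) {
    si <- idx[tr$subject]
    o <- order(si)
    si <- si[o]
    edgeObj <- unname(idx[tr$object[o]])
    edgePred <- tr$predicate[o]
    tb <- tabulate(si, nbins = n)
    deg <- tb
  }
  off <- c(0L, cumsum(deg))  # edges of node i: off[i]+1 .. off[i+1]

  L <- config$walkLength
  W <- n * config$numWalks
  start <- rep(seq_len(n), each = config$numWalks)

  nodePath <- matrix(NA_integer_, nrow = W, ncol = L)
  predPath <- if (L > 1L) matrix(NA_character_, nrow = W, ncol = L - 1L)
  nodePath[, 1L] <- start
  cur <- start
  withSeed(config$seed, {
    if (L > 1L) for (step in seq_len(L - 1L)) {
      act <- which(!is.na(cur) & deg[cur] > 0L)
      if (!length(act)) break
      d <- deg[cur[act]]
      pick <- off[cur[act]] + 1L + as.integer(floor(runif(length(act)) * d))
      # guard against the measure-zero runif()==1 edge
      pick <- pmin(pick, off[cur[act]] + d)
      nxt <- edgeObj[pick]
      nodePath[act, step + 1L] <- nxt
      predPath[act, step] <- edgePred[pick]
      cur[!is.na(cur) & deg[cur] == 0L] <- NA_integer_
      cur[act] <- nxt
    }
  })

  withLabels <- config$includeEdgeLabels
  sent <- vector("list", W)
  for (w in seq_len(W)) {
    np <- nodePath[w, ]
    len <- sum(!is.na(np))
    toks <- iris[np[seq_len(len)]]
    if (withLabels && len > 1L) {
      s <- character(2L * len - 1L)
      s[seq(1L, 2L * len - 1L, by = 2L)] <- toks
      s[seq(2L, 2L * len - 2L, by = 2L)] <- predPath[w, seq_len(len - 1L)]
      toks <- s
    }
    sent[[w]] <- toks
  }
  new("WalkCorpus", sentences = sent)
}

#' Validate a walk corpus against a graph
#'
#' Lists every consecutive `(node, edge, node)` window of the corpus that
#' is not a triple of the graph.  Corpora produced by [generateWalks()]
#' always validate with zero violations.
#'
#' @param corpus a `WalkCorpus` with edge labels.
#' @param graph the [KnowledgeGraph-class] the corpus was generated from.
#' @return data.frame with one row per violation (`sentence`, `position`,
#'   `subject`, `predicate`, `object`); zero rows when valid.
#' @export
validateCorpus <- function(corpus, graph) {
  stopifnot(is(corpus, "Corpus"), is(graph, "KnowledgeGraph"))
  ss <- corpus@sentences
  sentIdx <- integer(); pos <- integer()
  s <- character(); p <- character(); o <- character()
  for (i in seq_along(ss)) {
    tk <- ss[[i]]
    if (length(tk) < 3L) next
    starts <- seq(1L, length(tk) - 2L, by = 2L)
    sentIdx <- c(sentIdx, rep(i, length(starts)))
    pos <- c(pos, starts)
    s <- c(s, tk[starts]); p <- c(p, tk[starts + 1L]); o <- c(o, tk[starts + 2L])
  }
  if (!length(s))
    return(data.frame(sentence = integer(), position = integer(),
                      subject = character(), predicate = character(),
                      object = character(), stringsAsFactors = FALSE))
  ok <- hasTriple(graph, s, p, o)
  data.frame(sentence = sentIdx[!ok], position = pos[!ok], subject = s[!ok],
             predicate = p[!ok], object = o[!ok], stringsAsFactors = FALSE)
}

#' Write / read a plain-text corpus
#'
#' One sentence per line, tokens whitespace-separated; the round trip is
#' the identity.
#'
#' @param corpus a [Corpus-class].
#' @param path file path.
#' @return `writeCorpus()` returns `path` invisibly; `readCorpus()` a
#'   [Corpus-class] of class `corpusClass`.
#' @export
writeCorpus <- function(corpus, path) {
  stopifnot(is(corpus, "Corpus"))
  writeLines(vapply(corpus@sentences, paste, character(1), collapse = " "),
             path)
  invisible(path)
}

#' @rdname writeCorpus
#' @param corpusClass class of the returned corpus (`"WalkCorpus"`,
#'   `"TextCorpus"` or plain `"Corpus"`).
#' @export
readCorpus <- function(path, corpusClass = "WalkCorpus") {
  lines <- readLines(path, warn = FALSE)
  new(corpusClass, sentences = lapply(strsplit(lines, "\\s+"),
                                      function(x) x[nzchar(x)]))
}
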