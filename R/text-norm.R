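#' @include AllGenerics.R
NULL

#' Identifier map from annotation vocabularies to graph IRIs
#'
#' Maps `(entity type, source-vocabulary identifier)` pairs, as found in
#' PubTator annotations (MESH / CHEBI chemical ids, Entrez gene ids, MESH
#' disease ids), to knowledge-graph IRIs.  Identifiers are normalized by
#' uppercasing, so the mixed dialects PubTator emits (`MESH:D001241`,
#' `mesh:d001241`) hit the same key.  Unmapped lookups return `NA`, never a
#' fabricated IRI.
#'
#' @param type character vector of entity types (`Chemical`, `Gene`,
#'   `Disease`, ...).
#' @param id character vector of source identifiers.
#' @param iri character vector of graph IRIs.
#' @return an `IdMap` data.frame with columns `type`, `id`, `iri`.
#' @export
idMap <- function(type = character(), id = character(), iri = character()) {
  stopifnot(length(type) == length(id), length(id) == length(iri))
  df <- data.frame(type = as.character(type), id = as.character(id),
                   iri = as.character(iri), stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$type, toupper(df$id), sep = "|")), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("IdMap", "data.frame")
  df
}

#' @rdname idMap
#' @param path 3-column TSV (`type`, `id`, `iri`), no header.
#' @export
readIdMap <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   col.names = c("type", "id", "iri"))
  idMap(df$type, df$id, df$iri)
}

#' @rdname idMap
#' @param map an `IdMap`.
#' @export
writeIdMap <- function(map, path) {
  writeLines(paste(map$type, map$id, map$iri, sep = "\t"), path)
  invisible(path)
}

idMapLookup <- function(map, type, id) {
  vec <- setNames(map$iri, paste(map$type, toupper(map$id), sep = "|"))
  unname(vec[paste(type, toupper(id), sep = "|")])
}

#' Parse PubTator exchange-format annotated abstracts
#'
#' Reads blocks of the form `PMID|t|title`, `PMID|a|abstract`, followed by
#' tab-separated annotation lines (`PMID, start, end, mention, type,
#' identifier`), blocks separated by blank lines.  Offsets are 0-based and
#' end-exclusive over `title + " " + abstract`.  Annotations whose offsets
#' do not reproduce the stated mention are dropped with a warning giving
#' the count (or raise an error with `strict = TRUE`).
#'
#' @param path path to a PubTator file (or a character vector of lines via
#'   `text`).
#' @param text optional character vector of lines, used instead of `path`.
#' @param strict error (rather than warn) on invalid offsets.
#' @return list of [AnnotatedDocument-class].
#' @export
parsePubtator <- function(path = NULL, text = NULL, strict = FALSE) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(!nzchar(lines)))
  blocks <- lapply(blocks, function(b) b[nzchar(b)])
  blocks <- blocks[lengths(blocks) > 0L]
  nDropped <- 0L
  docs <- lapply(blocks, function(b) {
    tMatch <- regmatches(b, regexec("^([^|]+)\\|t\\|(.*)$", b))
    aMatch <- regmatches(b, regexec("^([^|]+)\\|a\\|(.*)$", b))
    ti <- which(lengths(tMatch) == 3L)
    ai <- which(lengths(aMatch) == 3L)
    if (!length(ti)) {
      pmidGuess <- sub("\\|.*$|\t.*$", "", b[1L])
      stop("PubTator block missing a title line (near PMID ", pmidGuess, ")")
    }
    pmid <- tMatch[[ti[1L]]][2L]
    title <- tMatch[[ti[1L]]][3L]
    abstract <- if (length(ai)) aMatch[[ai[1L]]][3L] else ""
    annLines <- b[-c(ti, ai)]
    txt <- paste(title, abstract)
    ann <- data.frame(start = integer(), end = integer(),
                      mention = character(), type = character(),
                      identifier = character(), stringsAsFactors = FALSE)
    if (length(annLines)) {
      f <- strsplit(annLines, "\t", fixed = TRUE)
      short <- which(lengths(f) < 5L)
      if (length(short))
        stop("malformed annotation line in document ", pmid, ": ",
             annLines[short[1L]])
      apmid <- vapply(f, `[[`, character(1), 1L)
      if (any(apmid != pmid))
        stop("annotation references unknown PMID ",
             apmid[apmid != pmid][1L], " inside block ", pmid)
      ann <- data.frame(
        start = as.integer(vapply(f, `[[`, character(1), 2L)),
        end = as.integer(vapply(f, `[[`, character(1), 3L)),
        mention = vapply(f, `[[`, character(1), 4L),
        type = vapply(f, `[[`, character(1), 5L),
        identifier = vapply(f, function(x)
          if (length(x) >= 6L) x[[6L]] else "", character(1)),
        stringsAsFactors = FALSE)
      valid <- !is.na(ann$start) & !is.na(ann$end) &
        ann$start >= 0L & ann$end <= nchar(txt) & ann$start < ann$end
      valid[valid] <- substring(txt, ann$start[valid] + 1L,
                                ann$end[valid]) == ann$mention[valid]
      if (any(!valid)) {
        if (strict)
          stop("invalid annotation offsets in document ", pmid)
        nDropped <<- nDropped + sum(!valid)
        ann <- ann[valid, , drop = FALSE]
      }
      ann <- ann[order(ann$start, ann$end), , drop = FALSE]
      rownames(ann) <- NULL
    }
    new("AnnotatedDocument", docId = pmid, title = title,
        abstract = abstract, annotations = ann)
  })
  if (nDropped > 0L)
    warning("dropped ", nDropped, " annotations with invalid offsets")
  unname(docs)
}

#' Write documents back to PubTator format
#'
#' @param docs list of [AnnotatedDocument-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePubtator <- function(docs, path) {
  out <- unlist(lapply(docs, function(d) {
    a <- d@annotations
    c(paste0(d@docId, "|t|", d@title),
      paste0(d@docId, "|a|", d@abstract),
      if (nrow(a)) paste(d@docId, a$start, a$end, a$mention, a$type,
                         a$identifier, sep = "\t"),
      "")
  }))
  writeLines(out, path)
  invisible(path)
}

# lowercase word tokenization: split on whitespace, strip edge punctuation
tokenizeWords <- function(x) {
  toks <- unlist(strsplit(tolower(x), "\\s+"))
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

# overlap tie-break: keep the longest annotation; equal lengths, earliest
# start; returns the surviving rows sorted by start
resolveOverlaps <- function(ann) {
  if (nrow(ann) < 2L) return(ann)
  o <- order(-(ann$end - ann$start), ann$start)
  keep <- logical(nrow(ann))
  covered <- matrix(numeric(0), ncol = 2)
  for (i in o) {
    s <- ann$start[i]; e <- ann$end[i]
    clash <- nrow(covered) && any(covered[, 1] < e & s < covered[, 2])
    if (!clash) {
      keep[i] <- TRUE
      covered <- rbind(covered, c(s, e))
    }
  }
  out <- ann[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Normalize an annotated document to graph IRIs
#'
#' Replaces each annotated entity mention whose `(type, identifier)` is in
#' the [idMap()] by its knowledge-graph IRI as a single, case-preserved,
#' atomic token; the remaining text is lowercased and word-tokenized.
#' Unmapped annotations are left as ordinary words.  Overlapping
#' annotations are resolved by keeping the longest (ties: earliest start).
#' For a document with k mapped, non-overlapping annotations the result
#' contains exactly k IRI tokens, and text outside annotated spans is
#' never altered.
#'
#' @param doc an [AnnotatedDocument-class].
#' @param map an [idMap()].
#' @return character vector of tokens.
#' @export
normalizeDocument <- function(doc, map) {
  stopifnot(is(doc, "AnnotatedDocument"))
  txt <- documentText(doc)
  ann <- resolveOverlaps(doc@annotations)
  if (!nrow(ann)) return(tokenizeWords(txt))
  iris <- idMapLookup(map, ann$type, ann$identifier)
  toks <- character(0)
  pos <- 0L  # 0-based cursor
  for (i in seq_len(nrow(ann))) {
    if (ann$start[i] > pos)
      toks <- c(toks, tokenizeWords(substring(txt, pos + 1L, ann$start[i])))
    toks <- c(toks,
              if (!is.na(iris[i])) iris[i] else tokenizeWords(ann$mention[i]))
    pos <- ann$end[i]
  }
  if (pos < nchar(txt))
    toks <- c(toks, tokenizeWords(substring(txt, pos + 1L)))
  toks
}

#' Build the normalized literature corpus (corpus 2)
#'
#' One sentence per document (title + abstract); the IRI-token count of the
#' corpus equals the number of mapped, non-overlapping annotations.
#'
#' @param docs list of [AnnotatedDocument-class].
#' @param map an [idMap()].
#' @return a [Corpus-class] of class `TextCorpus`.
#' @export
buildTextCorpus <- function(docs, map) {
  new("TextCorpus", sentences = lapply(docs, normalizeDocument, map = map))
}

# mapped entity IRIs mentioned in a document, with their annotation types
docEntities <- function(doc, map) {
  ann <- doc@annotations
  if (!nrow(ann)) return(data.frame(iri = character(), type = character()))
  iris <- idMapLookup(map, ann$type, ann$identifier)
  ok <- !is.na(iris)
  unique(data.frame(iri = iris[ok], type = ann$type[ok],
                    stringsAsFactors = FALSE))
}

pairKeyUnordered <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Entity co-occurrence statistics over annotated documents
#'
#' For a set of unordered evaluation pairs, counts in how many documents
#' both members are mentioned; and over all directly co-occurring
#' (Chemical, Gene) and (Chemical, Disease) mention pairs, the fraction
#' that are in the positive set, plus, among the positive pairs, the
#' fraction co-occurring in at least one document.
#'
#' @param docs list of [AnnotatedDocument-class].
#' @param pairsSet data.frame with columns `a`, `b` (IRIs, unordered).
#' @param map an [idMap()].
#' @return list with `pairDocCounts` (named integer, one per input pair),
#'   `coocPositiveFraction`, and `positiveCoocFraction`.
#' @export
cooccurrenceStats <- function(docs, pairsSet, map) {
  posKey <- if (nrow(pairsSet)) unique(pairKeyUnordered(pairsSet$a, pairsSet$b))
            else character()
  counts <- setNames(integer(length(posKey)), posKey)
  coocKeys <- character()
  for (d in docs) {
    ent <- docEntities(d, map)
    if (nrow(ent) < 2L) next
    chems <- ent$iri[ent$type == "Chemical"]
    genes <- ent$iri[ent$type == "Gene"]
    dis <- ent$iri[ent$type == "Disease"]
    dk <- character()
    if (length(chems) && length(genes))
      dk <- c(dk, pairKeyUnordered(rep(chems, each = length(genes)),
                                   rep(genes, length(chems))))
    if (length(chems) && length(dis))
      dk <- c(dk, pairKeyUnordered(rep(chems, each = length(dis)),
                                   rep(dis, length(chems))))
    dk <- unique(dk)
    coocKeys <- c(coocKeys, dk)
    # per-pair document counts consider any co-mention, whatever the types
    cmb <- utils::combn(sort(unique(ent$iri)), 2L)
    allk <- pairKeyUnordered(cmb[1L, ], cmb[2L, ])
    hit <- posKey %in% allk
    counts[hit] <- counts[hit] + 1L
  }
  coocKeys <- unique(coocKeys)
  list(pairDocCounts = counts,
       coocPositiveFraction =
         if (length(coocKeys)) mean(coocKeys %in% posKey) else 0,
       positiveCoocFraction =
         if (length(posKey)) mean(counts > 0L) else 0)
}

#' Drop documents in which any evaluation pair co-occurs
#'
#' Returns exactly the documents in which no evaluation pair has both of
#' its members mentioned (the co-occurrence ablation).  The input list is
#' not modified; an empty pair set returns all documents, and the result
#' shrinks monotonically as pairs are added.
#'
#' @inheritParams cooccurrenceStats
#' @return filtered list of [AnnotatedDocument-class].
#' @export
filterCooccurringDocs <- function(docs, pairsSet, map) {
  if (!nrow(pairsSet)) return(docs)
  posKey <- unique(pairKeyUnordered(pairsSet$a, pairsSet$b))
  keep <- vapply(docs, function(d) {
    ent <- docEntities(d, map)$iri
    if (length(ent) < 2L) return(TRUE)
    cmb <- utils::combn(sort(ent), 2L)
    !any(pairKeyUnordered(cmb[1L, ], cmb[2L, ]) %in% posKey)
  }, logical(1))
  docs[keep]
}
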