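#' @include kg-build.R
NULL

#' Load a typed edge list from TSV
#'
#' Reads a tab-separated edge list (subject in column 1, object in column
#' 2, optional score in column 3), applies IRI prefixes, and returns the
#' deduplicated triple set for a single predicate.  Database dumps in the
#' STITCH/STRING/SIDER style fit this shape.
#'
#' @param path path to the TSV file.
#' @param predicate relation name attached to every row.
#' @param subjectPrefix,objectPrefix strings prepended to the raw
#'   identifiers to form IRIs (e.g. `"stitch:"`, `"entrez:"`).
#' @param header logical; skip a header line.
#' @param scoreColumn optional integer; 1-based column holding a numeric
#'   interaction score.
#' @param minScore optional numeric; with `scoreColumn`, rows scoring below
#'   this threshold are dropped.  Default keeps all rows.
#' @return triple data.frame (columns `subject`, `predicate`, `object`).
#' @export
loadEdgeTSV <- function(path, predicate, subjectPrefix = "",
                        objectPrefix = "", header = FALSE,
                        scoreColumn = NULL, minScore = NULL) {
  stopifnot(isSingleString(predicate))
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty edge file: ", path)
    return(emptyTripleSet())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  expected <- nf[1L]
  if (expected < 2L)
    stop("malformed row at line ", if (header) 2L else 1L,
         ": expected at least 2 tab-separated columns")
  bad <- which(nf != expected)
  if (length(bad))
    stop("malformed row at line ", bad[1L] + if (header) 1L else 0L,
         ": expected ", expected, " columns, found ", nf[bad[1L]])
  subj <- vapply(fields, `[[`, character(1), 1L)
  obj <- vapply(fields, `[[`, character(1), 2L)
  if (!is.null(scoreColumn) && !is.null(minScore)) {
    if (scoreColumn > expected) stop("scoreColumn beyond available columns")
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1),
                                             scoreColumn)))
    keep <- !is.na(sc) & sc >= minScore
    subj <- subj[keep]; obj <- obj[keep]
  }
  out <- tripleSet(paste0(subjectPrefix, subj), predicate,
                   paste0(objectPrefix, obj))
  message(sprintf("loadEdgeTSV: %d rows -> %d distinct %s triples",
                  length(lines), nrow(out), predicate))
  out
}

#' Load subclass links from an OBO flat file
#'
#' Parses `[Term]` stanzas of an OBO 1.2 flat file and emits one triple
#' `(child, subclass_of, parent)` per `is_a:` line of a non-obsolete term.
#' Forward references to undeclared ids are legal in OBO: the triple is
#' still emitted, with a warning.  Ontology edges point child-to-parent
#' only, so random walks can reach superclasses.
#'
#' @param path path to the OBO file.
#' @param predicate relation name for the hierarchy links.
#' @param idPrefix optional prefix replacing the ontology's own (e.g.
#'   mapping `HP:0000001` to `hp:0000001`); by default the `is_a` target
#'   ids are kept as written, lowercasing the CURIE prefix.
#' @return triple data.frame.
#' @export
loadOboHierarchy <- function(path, predicate = "subclass_of",
                             idPrefix = NULL) {
  lines <- readLines(path, warn = FALSE)
  inTerm <- FALSE
  id <- NA_character_
  obsolete <- FALSE
  isa <- character()
  children <- character()
  parents <- character()
  declared <- character()
  flush <- function() {
    if (inTerm && !obsolete && !is.na(id) && length(isa)) {
      children <<- c(children, rep(id, length(isa)))
      parents <<- c(parents, isa)
    }
    if (inTerm && !is.na(id)) declared <<- c(declared, id)
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      flush(); inTerm <- TRUE; id <- NA_character_
      obsolete <- FALSE; isa <- character()
    } else if (grepl("^\\[", ln)) {
      flush(); inTerm <- FALSE
    } else if (inTerm) {
      if (startsWith(ln, "id:")) {
        id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        if (nzchar(tgt)) isa <- c(isa, tgt)
      } else if (grepl("^is_obsolete:\\s*true", ln)) {
        obsolete <- TRUE
      }
    }
  }
  flush()
  normId <- function(x) {
    # lowercase the CURIE prefix (HP:0000001 -> hp:0000001)
    sub("^([A-Za-z]+):", "\\L\\1:", x, perl = TRUE)
  }
  if (!is.null(idPrefix)) {
    children <- paste0(idPrefix, sub("^[A-Za-z]+:", "", children))
    parents <- paste0(idPrefix, sub("^[A-Za-z]+:", "", parents))
  } else {
    undeclared <- setdiff(parents, declared)
    if (length(undeclared))
      warning("is_a references to undeclared terms: ",
              paste(head(undeclared, 5L), collapse = ", "),
              if (length(undeclared) > 5L) ", ..." else "")
    children <- normId(children)
    parents <- normId(parents)
  }
  if (!length(children)) return(emptyTripleSet())
  tripleSet(children, predicate, parents)
}

# --- N-Triples serialization ---------------------------------------------

iriPrefixTable <- function() {
  c("stitch:" = "http://bio2vec.net/CID",
    "entrez:" = "http://www.ncbi.nlm.nih.gov/gene/",
    "doid:"   = "http://purl.obolibrary.org/obo/DOID_",
    "hp:"     = "http://purl.obolibrary.org/obo/HP_",
    "go:"     = "http://purl.obolibrary.org/obo/GO_")
}

expandIri <- function(x, relation = FALSE) {
  out <- x
  if (relation) {
    bare <- !grepl("://", x)
    out[bare] <- paste0("http://bio2vec.net/relation/", x[bare])
    return(out)
  }
  tab <- iriPrefixTable()
  done <- grepl("://", x)
  for (p in names(tab)) {
    hit <- !done & startsWith(x, p)
    out[hit] <- paste0(tab[[p]], substring(x[hit], nchar(p) + 1L))
    done <- done | hit
  }
  out[!done] <- paste0("urn:x-kgtext:", x[!done])
  out
}

compactIri <- function(x) {
  out <- x
  tab <- iriPrefixTable()
  done <- rep(FALSE, length(x))
  rel <- startsWith(x, "http://bio2vec.net/relation/")
  out[rel] <- substring(x[rel], nchar("http://bio2vec.net/relation/") + 1L)
  done <- done | rel
  urn <- !done & startsWith(x, "urn:x-kgtext:")
  out[urn] <- substring(x[urn], nchar("urn:x-kgtext:") + 1L)
  done <- done | urn
  # longest-expansion first so stitch: wins over a bare bio2vec URL
  for (p in names(tab)[order(-nchar(tab))]) {
    hit <- !done & startsWith(x, tab[[p]])
    out[hit] <- paste0(p, substring(x[hit], nchar(tab[[p]]) + 1L))
    done <- done | hit
  }
  out
}

#' Serialize a knowledge graph to N-Triples
#'
#' Writes one `<s> <p> <o> .` line per triple with angle-bracketed IRIs.
#' CURIE-style node names (`stitch:...`, `doid:...`) are expanded through
#' the standard prefix table and relation names through the
#' `http://bio2vec.net/relation/` namespace; anything else is wrapped in a
#' reversible `urn:` namespace.  Lines are written in sorted order, so the
#' serialization of a given triple set is byte-stable.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readNTriples()]
#' @export
writeNTriples <- function(graph, path) {
  stopifnot(is(graph, "KnowledgeGraph"))
  tr <- graph@triples
  lines <- if (nrow(tr)) {
    sort(sprintf("<%s> <%s> <%s> .",
                 expandIri(tr$subject), expandIri(tr$predicate, relation = TRUE),
                 expandIri(tr$object)))
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a knowledge graph from N-Triples
#'
#' Inverse of [writeNTriples()]: parses `<s> <p> <o> .` lines, compacts
#' IRIs back to CURIE form, and rebuilds the graph (typing nodes with
#' `typeMap`).  Unparseable lines raise an error naming the line number.
#'
#' @param path path to the N-Triples file.
#' @param typeMap prefix-to-type map; see [defaultTypeMap()].
#' @return a [KnowledgeGraph-class].
#' @export
readNTriples <- function(path, typeMap = defaultTypeMap()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(buildGraph(list(), typeMap))
  m <- regmatches(lines,
                  regexec("^<([^>]+)> <([^>]+)> <([^>]+)>\\s*\\.\\s*$", lines))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stop("unparseable N-Triples line ", bad[1L], ": ", lines[bad[1L]])
  s <- compactIri(vapply(m, `[[`, character(1), 2L))
  p <- compactIri(vapply(m, `[[`, character(1), 3L))
  o <- compactIri(vapply(m, `[[`, character(1), 4L))
  buildGraph(list(tripleSet(s, p, o)), typeMap)
}
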