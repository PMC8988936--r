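test_that("a minimal PubTator block parses into one annotated document", {
  docs <- parsePubtator(text = pubtatorBlock(
    ann = list(c(0, 7, "Aspirin", "Chemical", "CID2244"))))
  expect_length(docs, 1L)
  d <- docs[[1L]]
  expect_equal(d@docId, "1")
  a <- annotations(d)
  expect_equal(nrow(a), 1L)
  expect_equal(a$mention, "Aspirin")
  expect_equal(a$identifier, "CID2244")
})

test_that("annotations with empty identifiers are kept", {
  docs <- parsePubtator(text = c("1|t|Aspirin", "1|a|Aspirin works.",
                                 "1\t0\t7\tAspirin\tChemical\t", ""))
  expect_equal(annotations(docs[[1L]])$identifier, "")
})

test_that("invalid offsets are dropped with a warning; errors name PMIDs", {
  lines <- c("7|t|Title", "7|a|Some abstract.",
             "7\t0\t5\tTitle\tChemical\tX",
             "7\t0\t5\tWRONG\tChemical\tY", "")
  expect_warning(docs <- parsePubtator(text = lines), "dropped 1")
  expect_equal(nrow(annotations(docs[[1L]])), 1L)
  expect_error(parsePubtator(text = c("9|a|No title here.", "")),
               "missing a title")
  expect_error(parsePubtator(text = c("1|t|T", "1|a|A b.",
                                      "2\t0\t1\tT\tGene\tX", "")),
               "unknown PMID 2")
})

test_that("parsed annotation counts match an offset-check oracle", {
  set.seed(21)
  lines <- character()
  oracle <- 0L
  for (i in 1:100) {
    title <- paste(sample(letters, 5), collapse = "")
    abstract <- paste(rep("word", 10), collapse = " ")
    txt <- paste(title, abstract)
    ann <- list()
    for (j in 1:sample(3, 1)) {
      st <- sample(0:(nchar(txt) - 3), 1)
      en <- st + sample(2:3, 1)
      mention <- if (runif(1) < 0.8) substring(txt, st + 1, en) else "XXXX"
      ann <- c(ann, list(c(st, en, mention, "Gene", "g1")))
      # oracle: annotation survives iff the slice reproduces the mention
      if (substring(txt, st + 1, en) == mention) oracle <- oracle + 1L
    }
    lines <- c(lines, pubtatorBlock(pmid = as.character(i), title = title,
                                    abstract = abstract, ann = ann))
  }
  docs <- suppressWarnings(parsePubtator(text = lines))
  expect_equal(sum(vapply(docs, function(d) nrow(annotations(d)),
                          integer(1))), oracle)
})

test_that("normalization replaces mapped mentions by atomic IRI tokens", {
  docs <- parsePubtator(text = c(
    "1|t|Aspirin study", "1|a|Aspirin inhibits PTGS2.",
    "1\t14\t21\tAspirin\tChemical\tMESH:D001241",
    "1\t31\t36\tPTGS2\tGene\t5743", ""))
  toks <- normalizeDocument(docs[[1L]], toyIdMap())
  expect_equal(toks, c("aspirin", "study", "stitch:CID2244", "inhibits",
                       "entrez:5743"))
})

test_that("identifier dialects are matched case-insensitively", {
  docs <- parsePubtator(text = c("1|t|X", "1|a|Aspirin.",
                                 "1\t2\t9\tAspirin\tChemical\tmesh:d001241",
                                 ""))
  expect_equal(normalizeDocument(docs[[1L]], toyIdMap()),
               c("x", "stitch:CID2244"))
})

test_that("overlapping annotations keep the longest span", {
  txt <- "hypercholesterolemic patients"
  docs <- parsePubtator(text = c(
    "1|t|T", paste0("1|a|", txt),
    "1\t2\t7\thyper\tDisease\tMESH:D999999",
    "1\t2\t22\thypercholesterolemic\tDisease\tMESH:D006937", ""))
  toks <- normalizeDocument(docs[[1L]], toyIdMap())
  expect_equal(toks, c("t", "doid:2487", "patients"))
})

test_that("token conservation and redaction invariance hold", {
  set.seed(31)
  map <- toyIdMap()
  for (rep in 1:10) {
    nw <- sample(5:15, 1)
    words <- sample(c("alpha", "beta", "gamma", "delta."), nw, TRUE)
    mentions <- sample(c("Aspirin", "PTGS2", "unknownase"), 3)
    abstract <- paste(c(words, mentions), collapse = " ")
    # compute offsets of the mentions inside title + " " + abstract
    txt <- paste("T", abstract)
    ann <- lapply(mentions, function(m) {
      st <- regexpr(m, txt, fixed = TRUE)[1] - 1L
      c(st, st + nchar(m), m, switch(m, Aspirin = "Chemical",
                                     PTGS2 = "Gene", "Disease"),
        switch(m, Aspirin = "MESH:D001241", PTGS2 = "5743", ""))
    })
    doc <- parsePubtator(text = pubtatorBlock(title = "T",
                                              abstract = abstract,
                                              ann = ann))[[1L]]
    toks <- normalizeDocument(doc, map)
    nMapped <- sum(mentions %in% c("Aspirin", "PTGS2"))
    expect_equal(sum(grepl("^(stitch|entrez|doid):", toks)), nMapped)
    # stripping IRI tokens leaves exactly the tokenization of the text
    # with mapped mentions excised
    redacted <- txt
    for (m in c("Aspirin", "PTGS2"))
      redacted <- gsub(m, " ", redacted, fixed = TRUE)
    plain <- tolower(unlist(strsplit(redacted, "\\s+")))
    plain <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", plain)
    expect_equal(toks[!grepl("^(stitch|entrez|doid):", toks)],
                 plain[nzchar(plain)])
  }
})

test_that("text corpus IRI-token count equals the mapped-annotation scan", {
  set.seed(41)
  lines <- unlist(lapply(1:50, function(i) {
    mention <- sample(c("Aspirin", "PTGS2", "nothing"), 1)
    abstract <- paste("filler", mention, "more text.")
    st <- regexpr(mention, paste("T", abstract), fixed = TRUE)[1] - 1L
    pubtatorBlock(pmid = as.character(i), title = "T", abstract = abstract,
                  ann = list(c(st, st + nchar(mention), mention,
                               if (mention == "Aspirin") "Chemical"
                               else "Gene",
                               if (mention == "Aspirin") "MESH:D001241"
                               else if (mention == "PTGS2") "5743"
                               else "99")))
  }))
  docs <- parsePubtator(text = lines)
  map <- toyIdMap()
  corp <- buildTextCorpus(docs, map)
  expect_s4_class(corp, "TextCorpus")
  # brute force: count annotations whose (type, id) is in the map
  oracle <- sum(vapply(docs, function(d) {
    a <- annotations(d)
    sum(paste(a$type, toupper(a$identifier)) %in%
        paste(map$type, toupper(map$id)))
  }, numeric(1)))
  expect_equal(sum(grepl("^(stitch|entrez|doid):",
                         unlist(sentences(corp)))), oracle)
  expect_length(sentences(buildTextCorpus(list(), map)), 0L)
})

cooccFixture <- function(nDocs = 60, seed = 51) {
  set.seed(seed)
  ents <- data.frame(
    mention = c("drugA", "drugB", "geneX", "geneY", "disQ"),
    type = c("Chemical", "Chemical", "Gene", "Gene", "Disease"),
    id = c("MESH:DA", "MESH:DB", "11", "12", "MESH:DQ"),
    iri = c("stitch:A", "stitch:B", "entrez:11", "entrez:12", "doid:9"),
    stringsAsFactors = FALSE)
  map <- idMap(ents$type, ents$id, ents$iri)
  lines <- unlist(lapply(seq_len(nDocs), function(i) {
    k <- sample(0:3, 1)
    rows <- if (k) ents[sample.int(nrow(ents), k), , drop = FALSE]
            else ents[0, ]
    abstract <- paste(c("lorem", rows$mention, "ipsum"), collapse = " ")
    txt <- paste("T", abstract)
    ann <- lapply(seq_len(nrow(rows)), function(j) {
      m <- rows$mention[j]
      st <- regexpr(m, txt, fixed = TRUE)[1] - 1L
      c(st, st + nchar(m), m, rows$type[j], rows$id[j])
    })
    pubtatorBlock(pmid = as.character(i), title = "T", abstract = abstract,
                  ann = ann)
  }))
  list(docs = parsePubtator(text = lines), map = map)
}

test_that("co-occurrence statistics match an exhaustive double loop", {
  fx <- cooccFixture()
  pairsSet <- data.frame(a = c("stitch:A", "stitch:B"),
                         b = c("entrez:11", "doid:9"),
                         stringsAsFactors = FALSE)
  st <- cooccurrenceStats(fx$docs, pairsSet, fx$map)
  # oracle: document x pair double loop over mapped mention sets
  docEnts <- lapply(fx$docs, function(d) {
    a <- annotations(d)
    key <- paste(a$type, toupper(a$identifier))
    mk <- setNames(fx$map$iri, paste(fx$map$type, toupper(fx$map$id)))
    list(iri = unique(unname(mk[key[key %in% names(mk)]])),
         type = a$type[key %in% names(mk)])
  })
  for (i in seq_len(nrow(pairsSet))) {
    oracle <- sum(vapply(docEnts, function(e)
      pairsSet$a[i] %in% e$iri && pairsSet$b[i] %in% e$iri, logical(1)))
    expect_equal(unname(st$pairDocCounts[i]), oracle)
  }
  # positive co-occurrence fraction oracle
  posKey <- paste(pmin(pairsSet$a, pairsSet$b),
                  pmax(pairsSet$a, pairsSet$b))
  allCooc <- unique(unlist(lapply(fx$docs, function(d) {
    a <- annotations(d)
    mk <- setNames(fx$map$iri, paste(fx$map$type, toupper(fx$map$id)))
    iri <- unname(mk[paste(a$type, toupper(a$identifier))])
    keep <- !is.na(iri)
    iri <- iri[keep]; ty <- a$type[keep]
    out <- character()
    for (x in unique(iri[ty == "Chemical"]))
      for (y in unique(iri[ty %in% c("Gene", "Disease")]))
        out <- c(out, paste(pmin(x, y), pmax(x, y)))
    out
  })))
  expect_equal(st$coocPositiveFraction,
               if (length(allCooc)) mean(allCooc %in% posKey) else 0)
  expect_equal(st$positiveCoocFraction, mean(st$pairDocCounts > 0))
})

test_that("empty corpora give all-zero statistics", {
  st <- cooccurrenceStats(list(), data.frame(a = "x", b = "y"), toyIdMap())
  expect_equal(unname(st$pairDocCounts), 0L)
  expect_equal(st$coocPositiveFraction, 0)
  expect_equal(st$positiveCoocFraction, 0)
})

test_that("co-occurrence filtering removes exactly the co-mention docs", {
  fx <- cooccFixture(nDocs = 200, seed = 61)
  pairsSet <- data.frame(a = c("stitch:A", "stitch:B"),
                         b = c("entrez:11", "doid:9"),
                         stringsAsFactors = FALSE)
  kept <- filterCooccurringDocs(fx$docs, pairsSet, fx$map)
  # oracle double loop
  mk <- setNames(fx$map$iri, paste(fx$map$type, toupper(fx$map$id)))
  hasPair <- vapply(fx$docs, function(d) {
    a <- annotations(d)
    iri <- unname(mk[paste(a$type, toupper(a$identifier))])
    iri <- unique(iri[!is.na(iri)])
    any(vapply(seq_len(nrow(pairsSet)), function(i)
      pairsSet$a[i] %in% iri && pairsSet$b[i] %in% iri, logical(1)))
  }, logical(1))
  expect_length(kept, sum(!hasPair))
  # empty pair set is the identity; the filter is monotone
  expect_identical(filterCooccurringDocs(fx$docs, pairsSet[0, ], fx$map),
                   fx$docs)
  kept1 <- filterCooccurringDocs(fx$docs, pairsSet[1, , drop = FALSE],
                                 fx$map)
  expect_gte(length(kept1), length(kept))
})
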