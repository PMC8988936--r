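test_that("edge TSV loading applies prefixes and deduplicates", {
  f <- withr::local_tempfile(lines = c("CID1\tP53", "CID1\tP53"))
  suppressMessages(tr <- loadEdgeTSV(f, "has_target", "stitch:", "entrez:"))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$subject, "stitch:CID1")
  expect_equal(tr$predicate, "has_target")
  expect_equal(tr$object, "entrez:P53")
})

test_that("edge TSV triple count matches an independent line-dedup oracle", {
  set.seed(7)
  lines <- sprintf("d%d\tg%d", sample.int(40, 1000, TRUE),
                   sample.int(40, 1000, TRUE))
  f <- withr::local_tempfile(lines = lines)
  suppressMessages(tr <- loadEdgeTSV(f, "has_target", "stitch:", "entrez:"))
  expect_equal(nrow(tr), length(unique(lines)))
})

test_that("edge TSV errors name the malformed line and warn on empty input", {
  f <- withr::local_tempfile(lines = c("a\tb", "only_one_column_extra\tx\ty"))
  expect_error(suppressMessages(loadEdgeTSV(f, "has_target")), "line 2")
  f2 <- withr::local_tempfile(lines = character())
  expect_warning(tr <- loadEdgeTSV(f2, "has_target"), "empty")
  expect_equal(nrow(tr), 0L)
})

test_that("edge TSV score threshold drops low-scoring rows", {
  f <- withr::local_tempfile(lines = c("a\tx\t900", "b\ty\t100"))
  suppressMessages(tr <- loadEdgeTSV(f, "interacts_with",
                                     scoreColumn = 3, minScore = 400))
  expect_equal(tr$subject, "a")
})

oboFixture <- function(terms) {
  unlist(lapply(terms, function(t) {
    c("[Term]", paste0("id: ", t$id),
      if (!is.null(t$isa)) paste0("is_a: ", t$isa, " ! comment"),
      if (isTRUE(t$obs)) "is_obsolete: true", "")
  }))
}

test_that("OBO hierarchy emits one subclass triple per is_a of live terms", {
  f <- withr::local_tempfile(lines = oboFixture(list(
    list(id = "HP:0000001"),
    list(id = "HP:0000002", isa = "HP:0000001"),
    list(id = "HP:0000003", isa = "HP:0000002"))))
  tr <- loadOboHierarchy(f)
  expect_equal(nrow(tr), 2L)
  expect_true(all(tr$predicate == "subclass_of"))
  expect_setequal(tr$subject, c("hp:0000002", "hp:0000003"))
})

test_that("obsolete terms contribute no subclass triples", {
  f <- withr::local_tempfile(lines = oboFixture(list(
    list(id = "HP:0000001"),
    list(id = "HP:0000002", isa = "HP:0000001", obs = TRUE))))
  expect_equal(nrow(loadOboHierarchy(f)), 0L)
})

test_that("OBO triple count equals a text-scan oracle over live stanzas", {
  set.seed(11)
  terms <- lapply(1:50, function(i)
    list(id = sprintf("GO:%07d", i),
         isa = if (i > 1) sprintf("GO:%07d", sample.int(i - 1, 1)),
         obs = runif(1) < 0.2))
  lines <- oboFixture(terms)
  f <- withr::local_tempfile(lines = lines)
  tr <- loadOboHierarchy(f)
  # oracle: grep-count is_a lines inside non-obsolete stanzas
  stanza <- cumsum(lines == "[Term]")
  obsolete <- unique(stanza[grepl("^is_obsolete: true", lines)])
  oracle <- sum(grepl("^is_a:", lines) & !(stanza %in% obsolete))
  expect_equal(nrow(tr), oracle)
})

test_that("forward references are emitted with a warning", {
  f <- withr::local_tempfile(lines = oboFixture(list(
    list(id = "HP:0000002", isa = "HP:0099999"))))
  expect_warning(tr <- loadOboHierarchy(f), "undeclared")
  expect_equal(tr$object, "hp:0099999")
})

test_that("the RDF snippet builds a graph of 6 nodes and 4 triples", {
  tr <- rdfSnippetTriples()
  g <- buildGraph(list(tr))
  # brute-force endpoint union
  expect_equal(nodeCount(g), length(unique(c(tr$subject, tr$object))))
  expect_equal(nodeCount(g), 6L)
  expect_equal(tripleCount(g), 4L)
  expect_equal(unname(nodeTypes(g)["stitch:00110635"]), "drug")
  expect_equal(unname(nodeTypes(g)["hp:0011675"]), "phenotype")
})

test_that("graph building is order-independent and types by longest prefix", {
  s1 <- randomTripleSet(100, seed = 1)
  s2 <- randomTripleSet(100, seed = 2)
  g12 <- buildGraph(list(s1, s2))
  g21 <- buildGraph(list(s2, s1))
  expect_identical(triples(g12), triples(g21))
  expect_identical(nodeTypes(g12), nodeTypes(g21))
  # node count equals brute-force union of endpoint sets
  expect_equal(nodeCount(g12),
               length(unique(c(s1$subject, s1$object, s2$subject,
                               s2$object))))
  gO <- buildGraph(list(data.frame(subject = "x:1", predicate = "p",
                                   object = "y:2")))
  expect_true(all(nodeTypes(gO) == "other"))
})

test_that("an empty input list yields an empty graph", {
  g <- buildGraph(list())
  expect_equal(nodeCount(g), 0L)
  expect_equal(tripleCount(g), 0L)
})

test_that("predicate removal deletes exactly that relation", {
  g <- tinyGraph()
  g2 <- removeEdgesByPredicate(g, "has_target")
  expect_equal(sum(triples(g2)$predicate == "has_target"), 0L)
  expect_equal(tripleCount(g2), tripleCount(g) - 2L)
  # input unmodified, nodes preserved
  expect_equal(tripleCount(g), 5L)
  expect_equal(nodeCount(g2), nodeCount(g))
  # absent predicate is a no-op
  expect_identical(triples(removeEdgesByPredicate(g, "absent_pred")),
                   triples(g))
})

test_that("predicate removal is idempotent and commutes", {
  g <- buildGraph(list(randomTripleSet(200, seed = 5)))
  a <- removeEdgesByPredicate(g, "has_target")
  expect_identical(triples(removeEdgesByPredicate(a, "has_target")),
                   triples(a))
  ab <- removeEdgesByPredicate(a, "has_indication")
  ba <- removeEdgesByPredicate(
    removeEdgesByPredicate(g, "has_indication"), "has_target")
  expect_identical(triples(ab), triples(ba))
  # brute-force count of the survivors
  tr <- triples(g)
  expect_equal(tripleCount(ab), sum(!tr$predicate %in%
                                    c("has_target", "has_indication")))
})

test_that("adjacency is always consistent with the triple set", {
  for (g in list(tinyGraph(),
                 removeEdgesByPredicate(tinyGraph(), "has_target"),
                 buildGraph(list(randomTripleSet(150, seed = 9))))) {
    adj <- adjacency(g)
    rebuilt <- do.call(rbind, lapply(names(adj), function(n) {
      a <- adj[[n]]
      if (!nrow(a)) return(NULL)
      data.frame(subject = n, predicate = a$predicate, object = a$object,
                 stringsAsFactors = FALSE)
    }))
    key <- function(d) sort(paste(d$subject, d$predicate, d$object))
    expect_equal(key(if (is.null(rebuilt)) triples(g)[0, ] else rebuilt),
                 key(triples(g)))
  }
})

test_that("N-Triples serialization round-trips and is byte-stable", {
  g <- buildGraph(list(randomTripleSet(500, nNodes = 80, seed = 3)))
  f <- withr::local_tempfile()
  writeNTriples(g, f)
  g2 <- readNTriples(f)
  key <- function(gr) sort(with(triples(gr), paste(subject, predicate,
                                                   object)))
  expect_equal(key(g2), key(g))
  f2 <- withr::local_tempfile()
  writeNTriples(g2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("empty graphs and bad N-Triples lines are handled", {
  f <- withr::local_tempfile()
  writeNTriples(buildGraph(list()), f)
  expect_equal(tripleCount(readNTriples(f)), 0L)
  f2 <- withr::local_tempfile(lines = "<a> <b> not_a_triple")
  expect_error(readNTriples(f2), "line 1")
})
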