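# Shared fixtures, all generated in code.

# small typed graph: 2 drugs, 2 genes, 1 disease
tinyGraph <- function() {
  tr <- data.frame(
    subject = c("stitch:CID1", "stitch:CID1", "stitch:CID2", "entrez:10",
                "entrez:11"),
    predicate = c("has_target", "has_indication", "has_target",
                  "interacts_with", "has_disease_association"),
    object = c("entrez:10", "doid:1", "entrez:11", "entrez:11", "doid:1"),
    stringsAsFactors = FALSE)
  buildGraph(list(tr))
}

# the four-triple RDF example graph (drug, gene, disease, phenotypes)
rdfSnippetTriples <- function() {
  data.frame(
    subject = c("doid:14557", "entrez:857", "stitch:00110635",
                "stitch:00110635"),
    predicate = c("has_disease_phenotype", "has_disease_association",
                  "has_sideeffect", "has_indication"),
    object = c("hp:0011675", "doid:14557", "hp:0002027", "doid:65"),
    stringsAsFactors = FALSE)
}

randomTripleSet <- function(n, nNodes = 50, seed = 1) {
  set.seed(seed)
  data.frame(subject = sprintf("stitch:CID%d", sample.int(nNodes, n, TRUE)),
             predicate = sample(c("has_target", "has_indication",
                                  "interacts_with"), n, TRUE),
             object = sprintf("entrez:%d", sample.int(nNodes, n, TRUE)),
             stringsAsFactors = FALSE)
}

# one-document PubTator block as a character vector of lines
pubtatorBlock <- function(pmid = "1", title = "Aspirin",
                          abstract = "Aspirin inhibits PTGS2.",
                          ann = list(c(0, 7, "Aspirin", "Chemical",
                                       "MESH:D001241"))) {
  c(paste0(pmid, "|t|", title),
    paste0(pmid, "|a|", abstract),
    vapply(ann, function(a) paste(c(pmid, a), collapse = "\t"),
           character(1)),
    "")
}

toyIdMap <- function() {
  idMap(type = c("Chemical", "Gene", "Disease"),
        id = c("MESH:D001241", "5743", "MESH:D006937"),
        iri = c("stitch:CID2244", "entrez:5743", "doid:2487"))
}

# linearly separable embedding + pair set: positives pair "pos" drugs with
# "pos" genes (first coordinate +1), negatives are mixed
separableFixture <- function(nPairs = 40, d = 8, seed = 3) {
  set.seed(seed)
  drugs <- sprintf("stitch:CID%d", 1:10)
  genes <- sprintf("entrez:%d", 1:10)
  v <- matrix(rnorm(20 * d, sd = 0.05), ncol = d,
              dimnames = list(c(drugs, genes), NULL))
  posEnt <- c(drugs[1:5], genes[1:5])
  v[posEnt, 1] <- v[posEnt, 1] + 1
  v[setdiff(c(drugs, genes), posEnt), 1] <-
    v[setdiff(c(drugs, genes), posEnt), 1] - 1
  # positives: high-affinity entities on both sides; negatives: cross
  # pairs, so the set is separable linearly (drug block) and metrically
  # (entity proximity), which every classifier kind can express
  pos <- expand.grid(drug = drugs[1:5], candidate = genes[1:5],
                     stringsAsFactors = FALSE)
  neg <- expand.grid(drug = drugs[6:10], candidate = genes[1:5],
                     stringsAsFactors = FALSE)
  pairsDf <- rbind(cbind(pos, label = 1), cbind(neg, label = 0))
  list(embeddings = new("EmbeddingTable", vectors = v),
       train = new("PairDataset", pairs = pairsDf, split = "train"))
}

# 30-entity two-relation block graph: drugs a1..a15 linked to targets
# b1..b15 pairwise by r1 (and back by r2)
blockGraphTriples <- function() {
  a <- sprintf("a%02d", 1:15)
  b <- sprintf("b%02d", 1:15)
  rbind(data.frame(subject = a, predicate = "r1", object = b,
                   stringsAsFactors = FALSE),
        data.frame(subject = b, predicate = "r2", object = a,
                   stringsAsFactors = FALSE))
}
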