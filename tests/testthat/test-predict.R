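test_that("entity pools follow set algebra", {
  kg <- c("a", "b", "c")
  tx <- c("b", "c", "d")
  expect_equal(selectEntityPool(kg, tx, "overlap"), c("b", "c"))
  expect_equal(selectEntityPool(kg, tx, "union"), c("a", "b", "c", "d"))
  expect_equal(selectEntityPool(kg, tx, "kg_only"), kg)
  expect_equal(selectEntityPool(kg, tx, "text_only"), tx)
  expect_true(all(selectEntityPool(kg, tx, "overlap") %in%
                  selectEntityPool(kg, tx, "union")))
})

test_that("pair datasets are balanced, disjoint and collision-free", {
  pos <- data.frame(drug = paste0("d", 1:10), candidate = paste0("g", 1:10),
                    stringsAsFactors = FALSE)
  ds <- buildPairDataset(pos, paste0("d", 1:10), paste0("g", 1:20),
                         seed = 1)
  all <- rbind(pairs(ds$train), pairs(ds$test))
  expect_equal(sum(all$label == 1), 10L)
  expect_equal(sum(all$label == 0), 10L)
  negKey <- with(all[all$label == 0, ], paste(drug, candidate))
  posKey <- with(pos, paste(drug, candidate))
  expect_length(intersect(negKey, posKey), 0L)
  expect_equal(nrow(pairs(ds$test)), 4L)  # 20% of 20
})

test_that("an exhausted negative space raises an error", {
  pos <- expand.grid(drug = c("d1", "d2"), candidate = c("g1", "g2"),
                     stringsAsFactors = FALSE)
  expect_error(buildPairDataset(pos, c("d1", "d2"), c("g1", "g2"),
                                seed = 1),
               "insufficient negative space")
})

test_that("large datasets have no split leakage (membership oracle)", {
  set.seed(2)
  pos <- unique(data.frame(drug = sprintf("d%d", sample.int(80, 5000, TRUE)),
                           candidate = sprintf("g%d",
                                               sample.int(120, 5000, TRUE)),
                           stringsAsFactors = FALSE))
  ds <- buildPairDataset(pos, sprintf("d%d", 1:80), sprintf("g%d", 1:120),
                         seed = 3)
  trKey <- with(pairs(ds$train), paste(drug, candidate))
  teKey <- with(pairs(ds$test), paste(drug, candidate))
  expect_length(intersect(trKey, teKey), 0L)
  allNeg <- rbind(pairs(ds$train), pairs(ds$test))
  allNeg <- allNeg[allNeg$label == 0, ]
  expect_length(intersect(paste(allNeg$drug, allNeg$candidate),
                          paste(pos$drug, pos$candidate)), 0L)
  expect_false(any(duplicated(c(trKey, teKey))))
})

test_that("pair features are the stacked entity embeddings, drug first", {
  set.seed(4)
  v <- matrix(rnorm(2 * 128), nrow = 2, dimnames = list(c("d1", "g1"), NULL))
  emb <- new("EmbeddingTable", vectors = v)
  X <- makeFeatures(data.frame(drug = "d1", candidate = "g1"), emb)
  expect_equal(ncol(X), 256L)
  expect_equal(X[1, 1:128], unname(v["d1", ]))
  expect_equal(X[1, 129:256], unname(v["g1", ]))
  Xz <- makeFeatures(data.frame(drug = "d1", candidate = "missing"), emb)
  expect_equal(unname(Xz[1, 129:256]), rep(0, 128))
  expect_error(makeFeatures(data.frame(drug = "d1", candidate = "missing"),
                            emb, zeroFill = FALSE), "missing")
})

test_that("all four classifier kinds separate a separable fixture", {
  fx <- separableFixture()
  for (kind in c("ann", "rf", "lr", "siamese")) {
    model <- trainClassifier(classifierSpec(kind), fx$train,
                             fx$embeddings, seed = 1)
    sc <- predictPairs(model, fx$train, fx$embeddings)
    acc <- mean((sc >= 0.5) == (pairs(fx$train)$label == 1))
    expect_equal(acc, 1.0)
  }
})

test_that("classifier architectures match their stated settings", {
  fx <- separableFixture()
  ann <- trainClassifier(classifierSpec("ann"), fx$train, fx$embeddings,
                         seed = 1)
  expect_equal(ann$fit$hiddenWidth, 2L * 2L * embeddingDim(fx$embeddings))
  rf <- trainClassifier(classifierSpec("rf"), fx$train, fx$embeddings,
                        seed = 1)
  expect_equal(rf$fit$ntree, 50L)
  lr <- classifierSpec("lr")
  expect_equal(lr$penalty, "l2")
  expect_equal(lr$C, 10)
  expect_error(trainClassifier(
    classifierSpec("ann"),
    new("PairDataset",
        pairs = data.frame(drug = "d1", candidate = "g1", label = 1),
        split = "train"),
    fx$embeddings), "single class")
})

test_that("classifier training is deterministic given the seed", {
  fx <- separableFixture()
  for (kind in c("ann", "rf", "siamese")) {
    m1 <- trainClassifier(classifierSpec(kind), fx$train, fx$embeddings,
                          seed = 5)
    m2 <- trainClassifier(classifierSpec(kind), fx$train, fx$embeddings,
                          seed = 5)
    expect_equal(predictPairs(m1, fx$train, fx$embeddings),
                 predictPairs(m2, fx$train, fx$embeddings))
  }
})

# independent O(n^2) metric oracles
refAuroc <- function(scores, labels) {
  p <- which(labels == 1); n <- which(labels == 0)
  tot <- 0
  for (i in p) for (j in n)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(p) * length(n))
}
refAupr <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  tp <- 0; fp <- 0; area <- 0; prevRec <- 0
  nPos <- sum(labels == 1)
  for (i in seq_along(y)) {
    if (y[i] == 1) tp <- tp + 1 else fp <- fp + 1
    if (i < length(y) && scores[o][i + 1] == scores[o][i]) next
    rec <- tp / nPos
    area <- area + (rec - prevRec) * tp / (tp + fp)
    prevRec <- rec
  }
  area
}

test_that("AUROC and AUPR match the concordance / step oracles", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auprScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(aurocScore(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0.0)
  set.seed(6)
  scores <- runif(200); labels <- rbinom(200, 1, 0.4)
  expect_equal(aurocScore(scores, labels), refAuroc(scores, labels),
               tolerance = 1e-9)
  expect_equal(auprScore(scores, labels), refAupr(scores, labels),
               tolerance = 1e-9)
  # with ties
  scoresT <- round(scores, 1)
  expect_equal(aurocScore(scoresT, labels), refAuroc(scoresT, labels),
               tolerance = 1e-9)
  # constant scores give exactly 1/2
  expect_identical(aurocScore(rep(0.7, 50), rep(c(0, 1), 25)), 0.5)
  # third route: an established ROC library agrees
  skip_if_not_installed("pROC")
  expect_equal(aurocScore(scores, labels),
               as.numeric(suppressMessages(pROC::auc(labels, scores))),
               tolerance = 1e-12)
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(7)
  scores <- rnorm(100); labels <- rbinom(100, 1, 0.5)
  a <- aurocScore(scores, labels)
  expect_equal(aurocScore(exp(scores), labels), a, tolerance = 1e-12)
  expect_equal(aurocScore(plogis(3 * scores - 1), labels), a,
               tolerance = 1e-12)
})

test_that("evaluation reports recall per drug and errors on one class", {
  fx <- separableFixture()
  model <- trainClassifier(classifierSpec("lr"), fx$train, fx$embeddings,
                           seed = 1)
  rep <- evaluatePairs(model, fx$train, fx$embeddings)
  expect_s4_class(rep, "EvalReport")
  p <- pairs(fx$train)
  sc <- predictPairs(model, fx$train, fx$embeddings)
  for (d in names(perDrugRecall(rep))) {
    i <- p$drug == d & p$label == 1
    expect_equal(unname(perDrugRecall(rep)[d]), mean(sc[i] >= 0.5))
  }
  expect_equal(macroRecall(rep), mean(perDrugRecall(rep)))
  oneClass <- new("PairDataset",
                  pairs = data.frame(drug = "stitch:CID1",
                                     candidate = "entrez:1", label = 1),
                  split = "test")
  expect_error(evaluatePairs(model, oneClass, fx$embeddings), "one class")
})

test_that("candidate ranking is a deterministic permutation", {
  fx <- separableFixture()
  model <- trainClassifier(classifierSpec("lr"), fx$train, fx$embeddings,
                           seed = 1)
  cands <- sprintf("entrez:%d", 1:10)
  rk <- rankCandidates(model, "stitch:CID1", cands, fx$embeddings,
                       positives = "entrez:3")
  expect_setequal(rk$candidate, cands)
  expect_equal(rk$rank, 1:10)
  expect_true(all(diff(rk$score) <= 0))
  # rank positions agree with an independent sort
  sc <- predictPairs(model, data.frame(drug = "stitch:CID1",
                                       candidate = cands), fx$embeddings)
  oracle <- match("entrez:3", cands[order(-sc, cands)])
  expect_equal(unname(attr(rk, "positiveRanks")["entrez:3"]), oracle)
  # a planted top candidate ranks first
  expect_equal(rk$candidate[1L], cands[which.max(sc)])
})

test_that("benchmark pair lists deduplicate and count unmappable rows", {
  f <- withr::local_tempfile(lines = c("D00002\thsa:10", "D00002\thsa:10",
                                       "D00044\thsa:190"))
  out <- loadBenchmarkPairs(f)
  expect_equal(nrow(out$pairs), 2L)
  expect_equal(out$nUnmapped, 0L)
  drugMap <- data.frame(from = "D00002", to = "stitch:CID123")
  out2 <- loadBenchmarkPairs(f, drugMap = drugMap)
  expect_equal(out2$pairs$drug, "stitch:CID123")
  expect_equal(out2$nUnmapped, 1L)  # the D00044 rows lose their drug id
  f2 <- withr::local_tempfile(lines = "only_one_column")
  expect_error(loadBenchmarkPairs(f2), "line 1")
})

test_that("a Yamanishi-style synthetic fixture reproduces its known count", {
  # synthetic gold-standard list: 120 interactions over 40 drugs, some
  # rows repeated, written in the two-column KEGG dialect
  set.seed(8)
  pairsAll <- unique(data.frame(
    drug = sprintf("D%05d", sample.int(40, 200, TRUE)),
    target = sprintf("hsa:%d", sample.int(60, 200, TRUE)),
    stringsAsFactors = FALSE))
  pairsAll <- pairsAll[1:120, ]
  rows <- rbind(pairsAll, pairsAll[sample.int(120, 30), ])
  rows <- rows[sample.int(nrow(rows)), ]
  f <- withr::local_tempfile(lines = paste(rows$drug, rows$target,
                                           sep = "\t"))
  out <- loadBenchmarkPairs(f)
  expect_equal(nrow(out$pairs), 120L)
  # with a KEGG -> PubChem mapping that misses 5 drugs
  mapped <- unique(rows$drug)
  dm <- data.frame(from = mapped[-(1:5)],
                   to = paste0("stitch:CID", seq_along(mapped[-(1:5)])))
  out2 <- loadBenchmarkPairs(f, drugMap = dm)
  lost <- rows$drug %in% mapped[1:5]
  expect_equal(out2$nUnmapped, sum(lost))
  expect_equal(nrow(out2$pairs),
               nrow(unique(rows[!lost, ])))
})
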