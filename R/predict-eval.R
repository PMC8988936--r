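#' @include AllGenerics.R
NULL

#' Select the evaluation entity pool from two modality vocabularies
#'
#' Set algebra over the tokens available in the knowledge-graph embedding
#' and the literature embedding: `"overlap"` keeps entities represented in
#' both modalities (the strict comparison setting), `"union"` everything
#' represented in either (the extended-coverage setting), `"kg_only"` /
#' `"text_only"` one modality alone.
#'
#' @param kgVocab,textVocab character vectors of entity tokens.
#' @param mode one of `"overlap"`, `"kg_only"`, `"text_only"`, `"union"`.
#' @return sorted character vector.
#' @export
selectEntityPool <- function(kgVocab, textVocab,
                             mode = c("overlap", "kg_only", "text_only",
                                      "union")) {
  mode <- match.arg(mode)
  sort(switch(mode,
    overlap = intersect(kgVocab, textVocab),
    union = union(kgVocab, textVocab),
    kg_only = unique(kgVocab),
    text_only = unique(textVocab)))
}

#' Build balanced train/test pair datasets
#'
#' Restricts the positive pairs to the given pools, draws
#' `ratio * n_positive` negatives uniformly without replacement from
#' `(drugPool x candidatePool) \ positives`, then randomly splits
#' positives and negatives together into train and test (default 80/20).
#' Negatives are sampled once, before splitting, so train and test share a
#' consistent negative pool yet have disjoint pairs.
#'
#' @param positives data.frame with columns `drug`, `candidate`.
#' @param drugPool,candidatePool character vectors of eligible entities.
#' @param ratio negatives per positive (1 = balanced).
#' @param seed integer RNG seed.
#' @param testFraction fraction of pairs held out for testing.
#' @return list with `train` and `test` [PairDataset-class] objects.
#' @export
buildPairDataset <- function(positives, drugPool, candidatePool, ratio = 1,
                             seed = 1, testFraction = 0.2) {
  stopifnot(is.data.frame(positives), ratio > 0,
            testFraction > 0, testFraction < 1)
  keep <- positives$drug %in% drugPool & positives$candidate %in% candidatePool
  pos <- unique(positives[keep, c("drug", "candidate")])
  nPos <- nrow(pos)
  if (!nPos) stop("no positive pairs fall inside the entity pools")
  space <- as.numeric(length(drugPool)) * length(candidatePool)
  nNeg <- round(ratio * nPos)
  if (space - nPos < nNeg)
    stop("insufficient negative space: need ", nNeg, " but only ",
         space - nPos, " non-positive pairs exist")
  posKey <- paste(pos$drug, pos$candidate, sep = "\r")
  withSeed(seed, {
    negDrug <- character(0); negCand <- character(0)
    while (length(negDrug) < nNeg) {
      m <- max(2L * (nNeg - length(negDrug)), 100L)
      d <- drugPool[sample.int(length(drugPool), m, replace = TRUE)]
      g <- candidatePool[sample.int(length(candidatePool), m, replace = TRUE)]
      key <- paste(d, g, sep = "\r")
      ok <- !(key %in% posKey) &
        !(key %in% paste(negDrug, negCand, sep = "\r")) & !duplicated(key)
      negDrug <- c(negDrug, d[ok]); negCand <- c(negCand, g[ok])
    }
    negDrug <- negDrug[seq_len(nNeg)]; negCand <- negCand[seq_len(nNeg)]
    all <- data.frame(
      drug = c(pos$drug, negDrug),
      candidate = c(pos$candidate, negCand),
      label = c(rep(1, nPos), rep(0, nNeg)),
      stringsAsFactors = FALSE)
    testIdx <- sample.int(nrow(all), round(testFraction * nrow(all)))
    list(
      train = new("PairDataset", pairs = all[-testIdx, , drop = FALSE],
                  split = "train"),
      test = new("PairDataset", pairs = all[testIdx, , drop = FALSE],
                 split = "test"))
  })
}

#' Feature vectors for (drug, candidate) pairs
#'
#' The feature vector of a pair is the drug embedding concatenated with
#' the candidate embedding (drug block first), dimension `2 d`.
#'
#' @param pairsDf data.frame with columns `drug`, `candidate` (or a
#'   [PairDataset-class]).
#' @param embeddings an [EmbeddingTable-class].
#' @param zeroFill entities missing from the vocabulary get an all-zero
#'   block; otherwise they raise an error.
#' @return numeric matrix, one row per pair.
#' @export
makeFeatures <- function(pairsDf, embeddings, zeroFill = TRUE) {
  if (is(pairsDf, "PairDataset")) pairsDf <- pairsDf@pairs
  v <- embeddings@vectors
  d <- ncol(v)
  grab <- function(tok) {
    out <- matrix(0, nrow = length(tok), ncol = d)
    hit <- tok %in% rownames(v)
    if (!zeroFill && any(!hit))
      stop("entity missing from embedding vocabulary: ", tok[!hit][1L])
    out[hit, ] <- v[tok[hit], , drop = FALSE]
    out
  }
  cbind(grab(pairsDf$drug), grab(pairsDf$candidate))
}

# --- ranking metrics ------------------------------------------------------

#' Threshold-free ranking metrics for scored pairs
#'
#' `aurocScore()` is the rank-concordance AUROC with tied scores credited
#' 1/2 (so a constant-score model scores exactly 0.5); `auprScore()` is
#' the step-integrated area under the precision-recall curve, with tied
#' scores processed as one block.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return numeric scalar in `[0, 1]`.
#' @export
aurocScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: test set has one class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname aurocScore
#' @export
auprScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  nPos <- sum(labels == 1)
  if (nPos == 0) stop("AUPR undefined: no positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # group tied scores into single steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / nPos
  sum(prec * diff(c(0, rec)))
}

#' Evaluate a trained classifier on a test pair set
#'
#' Scores every test pair and reports AUROC (ties 1/2), AUPR (step
#' integration), per-drug recall — the fraction of a drug's positive test
#' pairs scoring at least `threshold`, macro-averaged over drugs with at
#' least one positive — and per-drug candidate rankings (ties broken by
#' candidate IRI for determinism).
#'
#' @param model a `PairClassifier`.
#' @param test a [PairDataset-class] containing both classes.
#' @param embeddings the [EmbeddingTable-class] used in training.
#' @param threshold score cutoff for per-drug recall.
#' @param zeroFill as in [trainClassifier()].
#' @return an [EvalReport-class].
#' @export
evaluatePairs <- function(model, test, embeddings, threshold = 0.5,
                          zeroFill = TRUE) {
  stopifnot(is(test, "PairDataset"))
  p <- test@pairs
  scores <- predictPairs(model, p, embeddings, zeroFill = zeroFill)
  au <- aurocScore(scores, p$label)
  ap <- auprScore(scores, p$label)
  drugsWithPos <- sort(unique(p$drug[p$label == 1]))
  rec <- vapply(drugsWithPos, function(d) {
    i <- p$drug == d & p$label == 1
    mean(scores[i] >= threshold)
  }, numeric(1))
  ranks <- lapply(drugsWithPos, function(d) {
    i <- which(p$drug == d)
    o <- i[order(-scores[i], p$candidate[i])]
    data.frame(candidate = p$candidate[o], score = scores[o],
               label = p$label[o], rank = seq_along(o),
               stringsAsFactors = FALSE)
  })
  names(ranks) <- drugsWithPos
  new("EvalReport", auroc = au, aupr = ap,
      perDrugRecall = rec, macroRecall = mean(rec), rankings = ranks)
}

#' Rank candidate entities for one drug
#'
#' Scores each candidate pair `(drug, candidate)` and returns candidates
#' sorted by descending score, ties broken by lexicographic IRI.  If known
#' positives are supplied, their rank positions are attached.
#'
#' @param model a `PairClassifier`.
#' @param drug drug IRI.
#' @param candidates character vector of candidate IRIs.
#' @param embeddings the [EmbeddingTable-class] used in training.
#' @param positives optional character vector of known-true candidates.
#' @param zeroFill as in [trainClassifier()].
#' @return data.frame (`candidate`, `score`, `rank`), with attribute
#'   `positiveRanks` when `positives` is given.
#' @export
rankCandidates <- function(model, drug, candidates, embeddings,
                           positives = NULL, zeroFill = TRUE) {
  df <- data.frame(drug = drug, candidate = candidates,
                   stringsAsFactors = FALSE)
  sc <- predictPairs(model, df, embeddings, zeroFill = zeroFill)
  o <- order(-sc, candidates)
  out <- data.frame(candidate = candidates[o], score = sc[o],
                    rank = seq_along(o), stringsAsFactors = FALSE)
  if (!is.null(positives))
    attr(out, "positiveRanks") <-
      setNames(match(positives, out$candidate), positives)
  out
}

#' Load a benchmark interaction-pair list
#'
#' Parses two-column interaction lists in the style of the Yamanishi gold
#' standards (e.g. KEGG drug ID, protein ID per row), optionally maps each
#' column through an identifier-mapping table, and returns the distinct
#' mapped pairs plus a count of rows that could not be mapped.
#'
#' @param path two-column TSV of interacting pairs.
#' @param drugMap,targetMap optional two-column data.frames (`from`, `to`)
#'   mapping raw identifiers to graph IRIs.
#' @return list with `pairs` (data.frame `drug`, `candidate`) and
#'   `nUnmapped`.
#' @export
loadBenchmarkPairs <- function(path, drugMap = NULL, targetMap = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(list(pairs = data.frame(drug = character(),
                                   candidate = character()),
                nUnmapped = 0L))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 2L)
  if (length(bad))
    stop("malformed row at line ", bad[1L], ": expected 2 columns")
  drug <- vapply(f, `[[`, character(1), 1L)
  cand <- vapply(f, `[[`, character(1), 2L)
  applyMap <- function(x, map) {
    if (is.null(map)) return(x)
    unname(setNames(map$to, map$from)[x])
  }
  drug <- applyMap(drug, drugMap)
  cand <- applyMap(cand, targetMap)
  ok <- !is.na(drug) & !is.na(cand)
  pairsDf <- unique(data.frame(drug = drug[ok], candidate = cand[ok],
                               stringsAsFactors = FALSE))
  rownames(pairsDf) <- NULL
  list(pairs = pairsDf, nUnmapped = sum(!ok))
}
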