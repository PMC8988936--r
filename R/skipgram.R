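#' @include AllGenerics.R
NULL

#' Skip-gram training configuration
#'
#' Hyperparameters for skip-gram with negative sampling.  The defaults —
#' embedding dimension 128, context window 10, 5 negatives drawn from the
#' unigram^0.75 noise distribution — are the settings used throughout the
#' pipeline for both the walk corpus and the literature corpus.
#'
#' @param dimension embedding dimension.
#' @param window maximum context window (shrunk dynamically per position).
#' @param negatives noise words per positive example.
#' @param minCount discard tokens with corpus frequency below this.
#' @param epochs passes over the corpus.
#' @param learningRate initial learning rate (decays linearly).
#' @param sample frequency-subsampling threshold (canonical word2vec
#'   default 1e-3); tokens with corpus frequency above it are randomly
#'   skipped, which stops very frequent tokens (relation labels, stop
#'   words) from dragging all vectors onto a common direction.  0
#'   disables.
#' @param seed integer RNG seed.
#' @return a `SkipGramConfig` list.
#' @export
skipGramConfig <- function(dimension = 128, window = 10, negatives = 5,
                           minCount = 1, epochs = 5, learningRate = 0.025,
                           sample = 1e-3, seed = 1) {
  stopifnot(dimension >= 1, window >= 1, negatives >= 0, minCount >= 1,
            epochs >= 1, learningRate > 0, sample >= 0)
  structure(list(dimension = as.integer(dimension),
                 window = as.integer(window),
                 negatives = as.integer(negatives),
                 minCount = as.integer(minCount),
                 epochs = as.integer(epochs),
                 learningRate = learningRate, sample = sample,
                 seed = as.integer(seed)),
            class = "SkipGramConfig")
}

#' Train skip-gram embeddings on a token corpus
#'
#' Learns one vector per vocabulary token (frequency >= `minCount`) by
#' skip-gram with negative sampling.  Training is single-threaded with a
#' private seeded RNG, so identical `(corpus, config)` inputs reproduce
#' the embedding table bit-for-bit.
#'
#' @param corpus a [Corpus-class] (walks, text, or their concatenation).
#' @param config a [skipGramConfig()].
#' @return an [EmbeddingTable-class].
#' @export
trainSkipgram <- function(corpus, config = skipGramConfig()) {
  stopifnot(is(corpus, "Corpus"), inherits(config, "SkipGramConfig"))
  ss <- corpus@sentences
  if (!length(ss) || !sum(lengths(ss))) stop("empty corpus")
  freq <- table(unlist(ss, use.names = FALSE))
  freq <- freq[freq >= config$minCount]
  if (!length(freq)) stop("empty vocabulary after min_count filtering")
  # deterministic vocabulary order: frequency desc, then token
  ord <- order(-as.integer(freq), names(freq))
  vocab <- names(freq)[ord]
  counts <- as.integer(freq)[ord]
  lut <- setNames(seq_along(vocab), vocab)
  enc <- lapply(ss, function(s) {
    ids <- lut[s]
    as.integer(ids[!is.na(ids)]) - 1L
  })
  enc <- enc[lengths(enc) > 0L]
  mat <- .sgnsTrain(enc, counts, config$dimension, config$window,
                    config$negatives, config$epochs, config$learningRate,
                    config$sample, as.double(config$seed))
  rownames(mat) <- vocab
  new("EmbeddingTable", vectors = mat)
}

#' Concatenate two corpora into one shuffled corpus
#'
#' Multiset union of the sentences of both corpora, with sentence order
#' shuffled deterministically by `seed` (avoids block-ordering artifacts
#' when jointly training embeddings over graph walks and literature).
#'
#' @param c1,c2 [Corpus-class] objects.
#' @param seed integer RNG seed for the shuffle.
#' @return a [Corpus-class].
#' @export
concatCorpora <- function(c1, c2, seed = 1) {
  stopifnot(is(c1, "Corpus"), is(c2, "Corpus"))
  ss <- c(c1@sentences, c2@sentences)
  perm <- withSeed(seed, sample.int(length(ss)))
  new("Corpus", sentences = ss[perm])
}

#' Concatenate two embedding tables token-wise
#'
#' Output vectors have dimension `d1 + d2`.  Under `"intersect"` the
#' vocabulary is the intersection of both tables; under `"zero_fill"` it is
#' the union, with zeros filling the block of the table a token is missing
#' from (how zero-shot entities — present in only one modality — still get
#' a representation).
#'
#' @param e1,e2 [EmbeddingTable-class] objects.
#' @param policy `"intersect"` or `"zero_fill"`.
#' @return an [EmbeddingTable-class].
#' @export
concatEmbeddings <- function(e1, e2, policy = c("intersect", "zero_fill")) {
  policy <- match.arg(policy)
  v1 <- e1@vectors; v2 <- e2@vectors
  if (!nrow(v1) && !nrow(v2)) stop("both embedding tables are empty")
  tokens <- if (policy == "intersect")
    sort(intersect(rownames(v1), rownames(v2)))
  else sort(union(rownames(v1), rownames(v2)))
  if (!length(tokens)) stop("empty vocabulary after intersection")
  out <- matrix(0, nrow = length(tokens), ncol = ncol(v1) + ncol(v2),
                dimnames = list(tokens, NULL))
  i1 <- tokens %in% rownames(v1)
  i2 <- tokens %in% rownames(v2)
  if (ncol(v1)) out[i1, seq_len(ncol(v1))] <- v1[tokens[i1], , drop = FALSE]
  if (ncol(v2)) out[i2, ncol(v1) + seq_len(ncol(v2))] <-
    v2[tokens[i2], , drop = FALSE]
  new("EmbeddingTable", vectors = out)
}

#' Write / read embeddings in word2vec text format
#'
#' Header line `vocab_size dim`, then one line per token with its vector;
#' round trips are equal to within 1e-6 per coordinate.
#'
#' @param table an [EmbeddingTable-class].
#' @param path file path.
#' @return `writeVectors()` returns `path` invisibly; `readVectors()` an
#'   [EmbeddingTable-class].
#' @export
writeVectors <- function(table, path) {
  v <- table@vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(v), ncol(v)), con)
  if (nrow(v)) {
    body <- vapply(seq_len(nrow(v)), function(i)
      paste(rownames(v)[i], paste(sprintf("%.8g", v[i, ]), collapse = " ")),
      character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname writeVectors
#' @export
readVectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hd <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  n <- hd[1L]; d <- hd[2L]
  mat <- matrix(0, nrow = n, ncol = d)
  toks <- character(n)
  if (n) {
    parts <- strsplit(lines[1L + seq_len(n)], " ", fixed = TRUE)
    for (i in seq_len(n)) {
      toks[i] <- parts[[i]][1L]
      mat[i, ] <- as.numeric(parts[[i]][-1L])
    }
  }
  rownames(mat) <- toks
  new("EmbeddingTable", vectors = mat)
}

#' Cosine similarity between two tokens of an embedding table
#'
#' @param table an [EmbeddingTable-class].
#' @param a,b tokens.
#' @return numeric cosine similarity.
#' @export
cosineSimilarity <- function(table, a, b) {
  v <- table@vectors
  x <- v[a, ]; y <- v[b, ]
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

# row-wise cosine between two matrices of equal shape
rowCosine <- function(x, y) {
  rowSums(x * y) / sqrt(rowSums(x^2) * rowSums(y^2))
}
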