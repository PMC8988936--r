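#' @include AllGenerics.R
NULL

#' TransE training configuration
#'
#' @param dimension embedding dimension.
#' @param margin ranking margin gamma (> 0).
#' @param norm `"L1"` or `"L2"` distance.
#' @param learningRate SGD learning rate (constant).
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param negativesPerPositive corrupted triples sampled per positive.
#' @param seed integer RNG seed.
#' @return a `TransEConfig` list.
#' @export
transeConfig <- function(dimension = 128, margin = 1, norm = c("L1", "L2"),
                         learningRate = 0.01, epochs = 100, batchSize = 64,
                         negativesPerPositive = 1, seed = 1) {
  norm <- match.arg(norm)
  stopifnot(margin > 0, dimension >= 1, learningRate > 0, epochs >= 1,
            negativesPerPositive >= 1)
  structure(list(dimension = as.integer(dimension), margin = margin,
                 norm = norm, learningRate = learningRate,
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 negativesPerPositive = as.integer(negativesPerPositive),
                 seed = as.integer(seed)),
            class = "TransEConfig")
}

transeDistance <- function(diff, norm) {
  if (norm == "L1") rowSums(abs(diff)) else sqrt(rowSums(diff^2))
}

#' Score a triple under a TransE model
#'
#' Returns the translation distance `d(s + p, o)` under the model's
#' configured norm; 0 means the triple is satisfied exactly, larger means
#' less plausible.  Vectorized over triples.
#'
#' @param model a [TransEModel-class].
#' @param s,p,o character vectors of subject, predicate and object names.
#' @return non-negative numeric vector of distances.
#' @export
transeScore <- function(model, s, p, o) {
  E <- model@entities; R <- model@relations
  miss <- setdiff(c(s, o), rownames(E))
  if (length(miss)) stop("unknown entity: ", miss[1L])
  if (length(setdiff(p, rownames(R)))) stop("unknown relation")
  diff <- E[s, , drop = FALSE] + R[p, , drop = FALSE] - E[o, , drop = FALSE]
  unname(transeDistance(diff, model@config$norm))
}

#' Margin-ranking loss over aligned positive/negative batches
#'
#' Sum over pairs of `max(0, margin + d(s+p,o) - d(s'+p,o'))`, the hinge
#' form of the pairwise ranking objective (an un-hinged sum is unbounded
#' below and untrainable).
#'
#' @param model a [TransEModel-class].
#' @param positives,negatives data.frames with columns `subject`,
#'   `predicate`, `object`, aligned row by row.
#' @return non-negative numeric scalar.
#' @export
transeLoss <- function(model, positives, negatives) {
  if (nrow(positives) != nrow(negatives))
    stop("positive and negative batches must be aligned 1:1")
  dp <- transeScore(model, positives$subject, positives$predicate,
                    positives$object)
  dn <- transeScore(model, negatives$subject, negatives$predicate,
                    negatives$object)
  sum(pmax(0, model@config$margin + dp - dn))
}

# scatter-add rows of `grad` into `mat` at (possibly duplicated) indices
scatterAdd <- function(mat, idx, grad) {
  acc <- rowsum(grad, group = idx)
  rows <- as.integer(rownames(acc))
  mat[rows, ] <- mat[rows, , drop = FALSE] + acc
  mat
}

#' Train a TransE model over a triple set
#'
#' Minibatch SGD on the margin-ranking loss with uniform corruption: for
#' each positive, a coin flip replaces the head or the tail with a
#' uniformly random entity (collisions with true triples are tolerated
#' during training, per the original protocol).  Entity vectors are
#' renormalized to unit L2 norm at the end of each epoch; the per-epoch
#' mean loss is recorded in the model's `lossTrace`.
#'
#' @param triplesDf triple data.frame (or a [KnowledgeGraph-class]).
#' @param config a [transeConfig()].
#' @return a [TransEModel-class].
#' @export
trainTransE <- function(triplesDf, config = transeConfig()) {
  if (is(triplesDf, "KnowledgeGraph")) triplesDf <- triplesDf@triples
  stopifnot(inherits(config, "TransEConfig"), nrow(triplesDf) >= 1)
  ents <- sort(unique(c(triplesDf$subject, triplesDf$object)))
  rels <- sort(unique(triplesDf$predicate))
  nE <- length(ents)
  if (nE < 2L) stop("corruption impossible: graph has a single entity")
  d <- config$dimension
  lut <- setNames(seq_len(nE), ents)
  rlut <- setNames(seq_along(rels), rels)
  si <- unname(lut[triplesDf$subject])
  pidx <- unname(rlut[triplesDf$predicate])
  oi <- unname(lut[triplesDf$object])
  nT <- length(si)
  lr <- config$learningRate
  margin <- config$margin
  L1 <- config$norm == "L1"
  npp <- config$negativesPerPositive

  trace <- numeric(config$epochs)
  withSeed(config$seed, {
    bound <- 6 / sqrt(d)
    E <- matrix(runif(nE * d, -bound, bound), nrow = nE)
    R <- matrix(runif(length(rels) * d, -bound, bound),
                nrow = length(rels))
    R <- R / sqrt(rowSums(R^2))
    for (ep in seq_len(config$epochs)) {
      E <- E / sqrt(rowSums(E^2))
      ord <- sample.int(nT)
      epLoss <- 0
      nPairs <- 0L
      for (b0 in seq(1L, nT, by = config$batchSize)) {
        bi <- ord[b0:min(b0 + config$batchSize - 1L, nT)]
        if (npp > 1L) bi <- rep(bi, npp)
        m <- length(bi)
        sb <- si[bi]; pb <- pidx[bi]; ob <- oi[bi]
        corruptHead <- runif(m) < 0.5
        re <- sample.int(nE, m, replace = TRUE)
        sn <- ifelse(corruptHead, re, sb)
        on <- ifelse(corruptHead, ob, re)
        dpos <- E[sb, , drop = FALSE] + R[pb, , drop = FALSE] -
          E[ob, , drop = FALSE]
        dneg <- E[sn, , drop = FALSE] + R[pb, , drop = FALSE] -
          E[on, , drop = FALSE]
        if (L1) {
          distP <- rowSums(abs(dpos)); distN <- rowSums(abs(dneg))
        } else {
          distP <- sqrt(rowSums(dpos^2)); distN <- sqrt(rowSums(dneg^2))
        }
        viol <- margin + distP - distN
        act <- viol > 0
        epLoss <- epLoss + sum(viol[act])
        nPairs <- nPairs + m
        if (any(act)) {
          if (L1) {
            gP <- sign(dpos[act, , drop = FALSE])
            gN <- sign(dneg[act, , drop = FALSE])
          } else {
            gP <- dpos[act, , drop = FALSE] / pmax(distP[act], 1e-12)
            gN <- dneg[act, , drop = FALSE] / pmax(distN[act], 1e-12)
          }
          # d loss/d(s) = gP, d/d(o) = -gP, d/d(s') = -gN, d/d(o') = gN,
          # d/d(p) = gP - gN
          E <- scatterAdd(E, c(sb[act], ob[act], sn[act], on[act]),
                          rbind(-lr * gP, lr * gP, lr * gN, -lr * gN))
          R <- scatterAdd(R, pb[act], -lr * (gP - gN))
        }
      }
      trace[ep] <- epLoss / max(nPairs, 1L)
    }
    E <- E / sqrt(rowSums(E^2))
    rownames(E) <- ents
    rownames(R) <- rels
    new("TransEModel", entities = E, relations = R,
        config = unclass(config), lossTrace = trace)
  })
}

#' Rank entities for (subject, predicate, ?) queries
#'
#' For each query, every entity is scored as a candidate object and ranked
#' by ascending distance (ties get their average rank); reports the mean
#' rank of the true object and hits@k.  Filtered mode excludes other
#' known-true objects of the same (subject, predicate) from the ranking.
#'
#' @param model a [TransEModel-class].
#' @param queries data.frame with columns `subject`, `predicate`, `object`
#'   (the true object).
#' @param k hits cutoff.
#' @param filtered logical; apply the filtered protocol.
#' @param knownTriples triple data.frame of known-true triples (required
#'   when `filtered = TRUE`).
#' @return list with `meanRank`, `hits`, and the per-query `ranks`.
#' @export
rankTriples <- function(model, queries, k = 10, filtered = FALSE,
                        knownTriples = NULL) {
  E <- model@entities; R <- model@relations
  norm <- model@config$norm
  if (filtered && is.null(knownTriples))
    stop("filtered ranking needs 'knownTriples'")
  ranks <- vapply(seq_len(nrow(queries)), function(i) {
    s <- queries$subject[i]; p <- queries$predicate[i]; o <- queries$object[i]
    trans <- E[s, ] + R[p, ]
    diff <- sweep(E, 2L, trans, "-")
    sc <- transeDistance(diff, norm)
    if (filtered) {
      others <- knownTriples$object[knownTriples$subject == s &
                                    knownTriples$predicate == p &
                                    knownTriples$object != o]
      sc[rownames(E) %in% others] <- Inf
    }
    rank(sc, ties.method = "average")[[o]]
  }, numeric(1))
  list(meanRank = mean(ranks), hits = mean(ranks <= k), ranks = ranks)
}
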