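#' @include AllGenerics.R
NULL

#' Classifier specification
#'
#' Defaults follow the pipeline's fixed settings: the neural network (ann)
#' has a single hidden layer twice the size of the input vector, ReLU
#' hidden activation, a sigmoid output, cross-entropy loss and the RMSprop
#' adaptive per-parameter optimizer; the random forest (rf) uses 50 trees,
#' Gini impurity and a minimum of one training sample per leaf; logistic
#' regression (lr) uses an L2 penalty with inverse regularization C = 10;
#' the Siamese network uses twin weight-shared ReLU encoders over the two
#' entity vectors, an absolute-difference merge and a sigmoid head.
#'
#' @param kind one of `"ann"`, `"rf"`, `"lr"`, `"siamese"`.
#' @param ... overrides for the kind's hyperparameters.
#' @return a `ClassifierSpec` list.
#' @export
classifierSpec <- function(kind = c("ann", "rf", "lr", "siamese"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    ann = list(hiddenFactor = 2, epochs = 100, batchSize = 128,
               learningRate = 0.001, optimizer = "rmsprop"),
    rf = list(nTrees = 50, criterion = "gini", minLeaf = 1),
    lr = list(penalty = "l2", C = 10),
    siamese = list(merge = "absdiff", epochs = 100, batchSize = 128,
                   learningRate = 0.001, optimizer = "rmsprop"))
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) stop("unknown hyperparameter for ", kind, ": ", bad[1L])
  defaults[names(override)] <- override
  structure(c(list(kind = kind), defaults), class = "ClassifierSpec")
}

# --- RMSprop-trained dense networks --------------------------------------

rmspropStep <- function(cache, grad, lr, rho = 0.9, eps = 1e-8) {
  cache <- rho * cache + (1 - rho) * grad^2
  list(cache = cache, delta = lr * grad / sqrt(cache + eps))
}

# Single hidden layer: ReLU(X W1 + b1) W2 + b2 -> sigmoid.
trainAnn <- function(X, y, spec, seed) {
  nIn <- ncol(X)
  h <- as.integer(spec$hiddenFactor * nIn)
  n <- nrow(X)
  withSeed(seed, {
    W1 <- matrix(rnorm(nIn * h, sd = sqrt(2 / nIn)), nIn, h)
    b1 <- numeric(h)
    W2 <- matrix(rnorm(h, sd = sqrt(2 / h)), h, 1)
    b2 <- 0
    cW1 <- W1 * 0; cb1 <- b1; cW2 <- W2 * 0; cb2 <- 0
    lr <- spec$learningRate
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = spec$batchSize)) {
        bi <- ord[b0:min(b0 + spec$batchSize - 1L, n)]
        Xb <- X[bi, , drop = FALSE]; yb <- y[bi]
        Z1 <- sweep(Xb %*% W1, 2L, b1, "+")
        H <- Z1 * (Z1 > 0)
        p <- plogis(drop(H %*% W2) + b2)
        dz <- (p - yb) / length(bi)          # d BCE / d logit
        gW2 <- crossprod(H, dz)
        gb2 <- sum(dz)
        dH <- tcrossprod(dz, W2[, 1L]) * (Z1 > 0)
        gW1 <- crossprod(Xb, dH)
        gb1 <- colSums(dH)
        s <- rmspropStep(cW2, gW2, lr); cW2 <- s$cache; W2 <- W2 - s$delta
        s <- rmspropStep(cb2, gb2, lr); cb2 <- s$cache; b2 <- b2 - s$delta
        s <- rmspropStep(cW1, gW1, lr); cW1 <- s$cache; W1 <- W1 - s$delta
        s <- rmspropStep(cb1, gb1, lr); cb1 <- s$cache; b1 <- b1 - s$delta
      }
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, hiddenWidth = h)
  })
}

predictAnn <- function(fit, X) {
  Z1 <- sweep(X %*% fit$W1, 2L, fit$b1, "+")
  H <- Z1 * (Z1 > 0)
  plogis(drop(H %*% fit$W2) + fit$b2)
}

# Twin weight-shared encoders over the drug and candidate halves of the
# feature vector; |h_drug - h_cand| merge, sigmoid head.
trainSiamese <- function(X, y, spec, seed) {
  d <- ncol(X) %/% 2L
  n <- nrow(X)
  Xd <- X[, seq_len(d), drop = FALSE]
  Xc <- X[, d + seq_len(d), drop = FALSE]
  withSeed(seed, {
    W <- matrix(rnorm(d * d, sd = sqrt(2 / d)), d, d)
    b <- numeric(d)
    v <- matrix(rnorm(d, sd = sqrt(2 / d)), d, 1)
    cc <- 0
    cW <- W * 0; cb <- b; cv <- v * 0; ccc <- 0
    lr <- spec$learningRate
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = spec$batchSize)) {
        bi <- ord[b0:min(b0 + spec$batchSize - 1L, n)]
        Ad <- sweep(Xd[bi, , drop = FALSE] %*% W, 2L, b, "+")
        Ac <- sweep(Xc[bi, , drop = FALSE] %*% W, 2L, b, "+")
        Hd <- Ad * (Ad > 0); Hc <- Ac * (Ac > 0)
        M <- abs(Hd - Hc)
        p <- plogis(drop(M %*% v) + cc)
        dz <- (p - y[bi]) / length(bi)
        gv <- crossprod(M, dz)
        gc <- sum(dz)
        dM <- tcrossprod(dz, v[, 1L])
        S <- sign(Hd - Hc)
        dAd <- dM * S * (Ad > 0)
        dAc <- -dM * S * (Ac > 0)
        gW <- crossprod(Xd[bi, , drop = FALSE], dAd) +
          crossprod(Xc[bi, , drop = FALSE], dAc)
        gb <- colSums(dAd) + colSums(dAc)
        s <- rmspropStep(cv, gv, lr); cv <- s$cache; v <- v - s$delta
        s <- rmspropStep(ccc, gc, lr); ccc <- s$cache; cc <- cc - s$delta
        s <- rmspropStep(cW, gW, lr); cW <- s$cache; W <- W - s$delta
        s <- rmspropStep(cb, gb, lr); cb <- s$cache; b <- b - s$delta
      }
    }
    list(W = W, b = b, v = v, c = cc, encoderWidth = d)
  })
}

predictSiamese <- function(fit, X) {
  d <- fit$encoderWidth
  Ad <- sweep(X[, seq_len(d), drop = FALSE] %*% fit$W, 2L, fit$b, "+")
  Ac <- sweep(X[, d + seq_len(d), drop = FALSE] %*% fit$W, 2L, fit$b, "+")
  M <- abs(Ad * (Ad > 0) - Ac * (Ac > 0))
  plogis(drop(M %*% fit$v) + fit$c)
}

#' Train a pair classifier on embedding features
#'
#' Builds the feature matrix (drug embedding concatenated with candidate
#' embedding; see [makeFeatures()]) for the training pairs and fits the
#' classifier described by `spec`.  Both classes must be present.  All
#' four kinds expose a confidence score in `[0, 1]` through
#' [predictPairs()], and training is deterministic given `seed`.
#'
#' @param spec a [classifierSpec()].
#' @param train a [PairDataset-class].
#' @param embeddings an [EmbeddingTable-class].
#' @param seed integer RNG seed.
#' @param zeroFill give all-zero blocks to entities missing from the
#'   embedding vocabulary (otherwise missing entities are an error).
#' @return a `PairClassifier` list with elements `kind`, `spec`, `fit`.
#' @export
trainClassifier <- function(spec, train, embeddings, seed = 1,
                            zeroFill = TRUE) {
  stopifnot(inherits(spec, "ClassifierSpec"), is(train, "PairDataset"))
  p <- train@pairs
  if (!nrow(p)) stop("empty training set")
  y <- p$label
  if (length(unique(y)) < 2L)
    stop("training set contains a single class")
  X <- makeFeatures(p, embeddings, zeroFill = zeroFill)
  fit <- switch(spec$kind,
    ann = trainAnn(X, y, spec, seed),
    siamese = trainSiamese(X, y, spec, seed),
    rf = withSeed(seed,
      randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                 ntree = spec$nTrees,
                                 nodesize = spec$minLeaf)),
    lr = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = 1 / (spec$C * nrow(X)),
                        standardize = FALSE))
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 featureDim = ncol(X)),
            class = "PairClassifier")
}

#' Confidence scores for labeled or unlabeled pairs
#'
#' @param model a `PairClassifier` from [trainClassifier()].
#' @param pairsDf data.frame with columns `drug`, `candidate` (or a
#'   [PairDataset-class]).
#' @param embeddings the [EmbeddingTable-class] used in training.
#' @param zeroFill as in [trainClassifier()].
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predictPairs <- function(model, pairsDf, embeddings, zeroFill = TRUE) {
  stopifnot(inherits(model, "PairClassifier"))
  if (is(pairsDf, "PairDataset")) pairsDf <- pairsDf@pairs
  X <- makeFeatures(pairsDf, embeddings, zeroFill = zeroFill)
  switch(model$kind,
    ann = predictAnn(model$fit, X),
    siamese = predictSiamese(model$fit, X),
    rf = unname(predict(model$fit, X, type = "prob")[, "1"]),
    lr = drop(predict(model$fit, X, type = "response")))
}
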