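#' @include kg-build.R text-norm.R
NULL

#' Synthetic-world configuration
#'
#' Parameters of the synthetic knowledge graph and abstract generator.
#' Entities carry latent unit-norm factors of dimension `latentDim`;
#' relations are planted by thresholding factor inner products at the
#' quantile matching each relation's density, so graph structure and text
#' co-occurrence carry partially overlapping signal.  `co_mention_lift` is
#' the relative probability that a truly linked (drug, gene) or
#' (drug, disease) pair is co-mentioned in a document versus an unlinked
#' pair; `text_overlap_fraction` is the fraction of mentionable entities
#' covered by the identifier map (entities outside it appear in text only
#' as plain words — the zero-shot scenario).
#'
#' @param n_drugs,n_genes,n_diseases,n_phenotypes,n_classes entity counts.
#' @param n_docs number of synthetic abstracts.
#' @param co_mention_lift real > 1 (1 = no text signal).
#' @param mention_noise rate in `[0, 1]` of extra off-topic phenotype
#'   mentions per document.
#' @param pairs_per_doc expected number of focal entity pairs mentioned
#'   per document.
#' @param lit_known_fraction fraction of linked pairs that are
#'   "literature-known": linked co-mentions concentrate on this subset,
#'   mimicking how real abstracts restate the same established relations
#'   repeatedly while most database links are never discussed.
#' @param text_overlap_fraction fraction of entities present in the IdMap.
#' @param topic_concentration strength of the topical coupling between a
#'   document's filler vocabulary and the latent factors of the entities
#'   it mentions (0 = topic-free text).  Real abstracts discuss a pair in
#'   words correlated with its biology; this is what lets text embeddings
#'   generalize beyond directly co-mentioned pairs.
#' @param latentDim latent factor dimension.
#' @param densities named numeric; edge density per relation.
#' @param kg_signal_drop fraction of side-relation edges removed after
#'   generation (0 = keep all).
#' @param seed integer RNG seed.
#' @return a `SynthConfig` list.
#' @export
synthConfig <- function(n_drugs = 200, n_genes = 300, n_diseases = 100,
                        n_phenotypes = 60, n_classes = 30, n_docs = 2000,
                        co_mention_lift = 18, mention_noise = 0.1,
                        pairs_per_doc = 2, lit_known_fraction = 0.273,
                        text_overlap_fraction = 1, topic_concentration = 4,
                        latentDim = 4,
                        densities = c(has_target = 0.025,
                                      has_indication = 0.025,
                                      has_sideeffect = 0.05,
                                      has_disease_association = 0.03,
                                      has_disease_phenotype = 0.05,
                                      has_function = 0.03,
                                      interacts_with = 0.01),
                        kg_signal_drop = 0, seed = 42) {
  stopifnot(n_drugs >= 1, n_genes >= 1, n_diseases >= 1, n_phenotypes >= 1,
            n_classes >= 1, n_docs >= 1, co_mention_lift >= 1,
            pairs_per_doc >= 1, lit_known_fraction > 0,
            lit_known_fraction <= 1, topic_concentration >= 0,
            mention_noise >= 0, mention_noise <= 1,
            text_overlap_fraction >= 0, text_overlap_fraction <= 1,
            kg_signal_drop >= 0, kg_signal_drop < 1)
  if (any(densities > 1) || any(densities < 0))
    stop("densities must be in [0, 1]: more edges than the pair space")
  structure(as.list(environment()), class = "SynthConfig")
}

#' Named synthetic-world presets
#'
#' `"default"`: the standard study conditions (200 drugs, 300 genes, 100
#' diseases, 2,000 docs, full text overlap).  `"complementary"`: a smaller
#' world where only 60% of entities appear in text and half of the
#' side-relation edges are removed from the graph, so some planted pairs
#' are recoverable only from text and some only from the graph.
#' `"null"`: the default world with `co_mention_lift = 1` (no text
#' signal); dropping the drug-side relations from its graph removes the
#' graph signal too.
#'
#' @param name preset name.
#' @param seed integer RNG seed.
#' @return a [synthConfig()].
#' @export
synthPreset <- function(name = c("default", "complementary", "null"),
                        seed = 42) {
  switch(match.arg(name),
    default = synthConfig(seed = seed),
    complementary = synthConfig(n_drugs = 100, n_genes = 150,
                                n_diseases = 60, n_phenotypes = 40,
                                n_classes = 20, n_docs = 1200,
                                text_overlap_fraction = 0.6,
                                kg_signal_drop = 0.5, seed = seed),
    null = synthConfig(co_mention_lift = 1, seed = seed))
}

synthIris <- function(config) {
  list(drug = sprintf("stitch:CID%05d", seq_len(config$n_drugs)),
       gene = sprintf("entrez:%d", 1000L + seq_len(config$n_genes)),
       disease = sprintf("doid:%d", seq_len(config$n_diseases)),
       phenotype = sprintf("hp:%07d", seq_len(config$n_phenotypes)),
       class = sprintf("go:%07d", seq_len(config$n_classes)))
}

# threshold factor inner products at the density quantile; returns index
# pairs (i, j) of planted edges
thresholdEdges <- function(Fa, Fb, density, excludeDiag = FALSE) {
  S <- Fa %*% t(Fb)
  if (excludeDiag) diag(S) <- -Inf
  pool <- S[is.finite(S)]
  tau <- quantile(pool, 1 - density, names = FALSE)
  hit <- which(S > tau & is.finite(S), arr.ind = TRUE)
  data.frame(i = hit[, 1L], j = hit[, 2L])
}

# degree-balanced planting for the predicted relations: accept pairs in
# descending inner-product order subject to per-entity quotas, so planted
# degrees are near-constant.  Without the caps, binomial degree noise is
# itself predictive (entity-identity memorization), which would
# contaminate both the signal and the null evaluations.
plantBalanced <- function(Fa, Fb, density, slack = 1.25) {
  na <- nrow(Fa); nb <- nrow(Fb)
  m <- round(density * na * nb)
  rowQuota <- ceiling(slack * density * nb)
  colQuota <- ceiling(slack * density * na)
  S <- Fa %*% t(Fb)
  o <- order(S, decreasing = TRUE)
  ri <- (o - 1L) %% na + 1L
  ci <- (o - 1L) %/% na + 1L
  rc <- integer(na); cc <- integer(nb)
  keepI <- integer(m); keepJ <- integer(m)
  got <- 0L
  for (t in seq_along(o)) {
    i <- ri[t]; j <- ci[t]
    if (rc[i] < rowQuota && cc[j] < colQuota) {
      got <- got + 1L
      keepI[got] <- i; keepJ[got] <- j
      rc[i] <- rc[i] + 1L; cc[j] <- cc[j] + 1L
      if (got == m) break
    }
  }
  data.frame(i = keepI[seq_len(got)], j = keepJ[seq_len(got)])
}

#' Generate a synthetic knowledge graph with planted ground truth
#'
#' Draws unit-norm latent factors for every entity and plants each
#' relation by thresholding factor inner products at its density quantile;
#' the two predicted relations (`has_target`, `has_indication`) are
#' planted degree-balanced — highest-affinity pairs accepted under
#' per-entity quotas — so that per-entity link counts are not themselves
#' predictive.  Shared factors across `has_target`, `has_indication` and
#' the side relations make the modalities informative about each other.  Protein
#' interactions are stored as two directed triples; ontology classes form
#' a similarity-based `subclass_of` tree, with phenotypes and gene
#' functions attached to their nearest class.  The returned graph contains
#' the positive edges; the ground-truth pair sets are returned separately.
#'
#' @param config a [synthConfig()].
#' @return a `SyntheticWorld` list: `kg` ([KnowledgeGraph-class]),
#'   `groundTruth` (list of `target` and `indication` pair data.frames),
#'   `factors` (named matrix of latent factors), `config`.
#' @export
generateSyntheticKG <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  iris <- synthIris(config)
  withSeed(config$seed, {
    k <- config$latentDim
    fac <- lapply(iris, function(v) {
      M <- matrix(rnorm(length(v) * k), ncol = k)
      M <- M / sqrt(rowSums(M^2))
      rownames(M) <- v
      M
    })
    dens <- config$densities
    edge <- function(typeA, typeB, density, excludeDiag = FALSE) {
      e <- thresholdEdges(fac[[typeA]], fac[[typeB]], density, excludeDiag)
      data.frame(subject = iris[[typeA]][e$i], object = iris[[typeB]][e$j],
                 stringsAsFactors = FALSE)
    }
    balancedEdge <- function(typeA, typeB, density) {
      e <- plantBalanced(fac[[typeA]], fac[[typeB]], density)
      data.frame(subject = iris[[typeA]][e$i], object = iris[[typeB]][e$j],
                 stringsAsFactors = FALSE)
    }
    target <- balancedEdge("drug", "gene", dens[["has_target"]])
    indication <- balancedEdge("drug", "disease", dens[["has_indication"]])
    sideeffect <- edge("drug", "phenotype", dens[["has_sideeffect"]])
    geneDis <- edge("gene", "disease", dens[["has_disease_association"]])
    disPheno <- edge("disease", "phenotype", dens[["has_disease_phenotype"]])
    geneFun <- edge("gene", "class", dens[["has_function"]])
    ppi <- edge("gene", "gene", dens[["interacts_with"]], excludeDiag = TRUE)
    ppi <- rbind(ppi, data.frame(subject = ppi$object, object = ppi$subject))

    # subclass tree over classes: parent = most similar earlier class
    Sc <- fac$class %*% t(fac$class)
    parent <- vapply(seq_len(config$n_classes), function(i) {
      if (i == 1L) NA_integer_ else which.max(Sc[i, seq_len(i - 1L)])
    }, integer(1))
    classSub <- data.frame(
      subject = iris$class[which(!is.na(parent))],
      object = iris$class[parent[!is.na(parent)]],
      stringsAsFactors = FALSE)
    # phenotypes attach to their most similar class
    Sp <- fac$phenotype %*% t(fac$class)
    phenoSub <- data.frame(subject = iris$phenotype,
                           object = iris$class[max.col(Sp)],
                           stringsAsFactors = FALSE)

    mk <- function(df, pred) tripleSet(df$subject, pred, df$object)
    side <- list(mk(sideeffect, "has_sideeffect"),
                 mk(geneDis, "has_disease_association"),
                 mk(disPheno, "has_disease_phenotype"),
                 mk(geneFun, "has_function"),
                 mk(ppi, "interacts_with"),
                 mk(classSub, "subclass_of"),
                 mk(phenoSub, "subclass_of"))
    if (config$kg_signal_drop > 0) {
      side <- lapply(side, function(t) {
        keep <- sort(sample.int(nrow(t),
                                round((1 - config$kg_signal_drop) * nrow(t))))
        t[keep, , drop = FALSE]
      })
    }
    kg <- buildGraph(c(list(mk(target, "has_target"),
                            mk(indication, "has_indication")), side),
                     nodes = unlist(iris, use.names = FALSE))
    factors <- do.call(rbind, fac)
    list(kg = kg,
         groundTruth = list(
           target = data.frame(drug = target$subject, candidate = target$object,
                               stringsAsFactors = FALSE),
           indication = data.frame(drug = indication$subject,
                                   candidate = indication$object,
                                   stringsAsFactors = FALSE)),
         factors = factors, config = config)
  })
}

zipfLexicon <- function(n = 500) sprintf("filler%03d", seq_len(n))

# Source-vocabulary IDs and mention words per entity, PubTator dialects
synthSourceIds <- function(config) {
  iris <- synthIris(config)
  data.frame(
    iri = c(iris$drug, iris$gene, iris$disease, iris$phenotype),
    type = rep(c("Chemical", "Gene", "Disease", "Phenotype"),
               c(config$n_drugs, config$n_genes, config$n_diseases,
                 config$n_phenotypes)),
    id = c(sprintf("MESH:D%06d", seq_len(config$n_drugs)),
           sprintf("%d", 1000L + seq_len(config$n_genes)),
           sprintf("MESH:D%06d", 500000L + seq_len(config$n_diseases)),
           sprintf("HP:%07d", seq_len(config$n_phenotypes))),
    mention = c(sprintf("drugane%d", seq_len(config$n_drugs)),
                sprintf("gene%d", seq_len(config$n_genes)),
                sprintf("malady%d", seq_len(config$n_diseases)),
                sprintf("phenotype%d", seq_len(config$n_phenotypes))),
    stringsAsFactors = FALSE)
}

#' Generate synthetic PubTator abstracts with calibrated co-mentions
#'
#' Each document mentions about `pairs_per_doc` focal (drug, gene) or
#' (drug, disease) pairs plus optional off-topic phenotype mentions and
#' Zipf-distributed filler words.  Each focal slot is linked in the
#' ground truth with the probability that makes the co-mention lift —
#' the mean probability that a linked pair is co-mentioned relative to an
#' unlinked pair — equal `co_mention_lift`; linked slots are drawn from
#' the `lit_known_fraction` "literature-known" subset of linked pairs, so
#' known pairs are restated in several abstracts while the remaining
#' links never reach the text.  Filler words are drawn from a Zipf
#' lexicon tilted toward the latent factors of the document's entities
#' (strength `topic_concentration`), so abstracts are topical the way
#' real ones are and text embeddings can generalize beyond direct
#' co-mentions.  When `co_mention_lift = 1` the text channel is switched
#' off entirely: every slot is a uniform draw from the whole pair space
#' and filler words are topic-free, so the text carries no signal at
#' all.  Annotations carry correct offsets and
#' source-vocabulary IDs; the IdMap covers
#' `ceiling(text_overlap_fraction * n_entities)` entities, sampled at
#' random.  The stream round-trips losslessly through [parsePubtator()].
#'
#' @param world result of [generateSyntheticKG()].
#' @param config a [synthConfig()]; defaults to the world's own.
#' @return list with `docs` (list of [AnnotatedDocument-class]) and
#'   `idMap` (an [idMap()]).
#' @export
generateSyntheticAbstracts <- function(world, config = world$config) {
  stopifnot(inherits(config, "SynthConfig"))
  src <- synthSourceIds(config)
  gt <- world$groundTruth
  L <- nrow(gt$target) + nrow(gt$indication)
  U <- as.numeric(config$n_drugs) * config$n_genes +
    as.numeric(config$n_drugs) * config$n_diseases - L
  lambda <- config$co_mention_lift
  # Per-slot linked probability solving the lift equation, including the
  # cross-pair background: a document with s focal pairs co-mentions
  # s^2 - s additional (drug, partner) combinations that land uniformly
  # on the pair space.  With s = 1 + Poisson(pairs_per_doc - 1),
  # E[s] = pairs_per_doc and E[s^2 - s] = pairs_per_doc^2 - 1.
  sRate <- config$pairs_per_doc
  xRate <- config$pairs_per_doc^2 - 1
  x0 <- xRate / (L + U)
  piLinked <- (lambda * sRate / U + (lambda - 1) * x0) /
    (sRate / L + lambda * sRate / U)
  if (lambda > 1 && piLinked > 1)
    stop("co_mention_lift ", lambda, " is not achievable under this ",
         "configuration: the cross-pair co-mention background caps the ",
         "lift at about ",
         round(1 + (sRate / L) / x0, 1))
  linkedPool <- rbind(gt$target, gt$indication)
  linkedKey <- paste(linkedPool$drug, linkedPool$candidate, sep = "\r")
  lex <- zipfLexicon()
  lexP <- (1 / seq_along(lex))^1  # Zipf weights
  byIri <- split(src, src$iri)
  phenoIris <- src$iri[src$type == "Phenotype"]

  drugIris <- src$iri[src$type == "Chemical"]
  geneIris <- src$iri[src$type == "Gene"]
  disIris <- src$iri[src$type == "Disease"]
  beta <- if (lambda == 1) 0 else config$topic_concentration
  withSeed(deriveSeed(config$seed, 1L), {
    lexFac <- matrix(rnorm(length(lex) * config$latentDim),
                     ncol = config$latentDim)
    lexFac <- lexFac / sqrt(rowSums(lexFac^2))
    nMap <- ceiling(config$text_overlap_fraction * nrow(src))
    mapped <- src[sample.int(nrow(src), nMap), , drop = FALSE]
    map <- idMap(mapped$type, mapped$id, mapped$iri)

    known <- linkedPool[sample.int(nrow(linkedPool),
                                   ceiling(config$lit_known_fraction *
                                           nrow(linkedPool))), ,
                        drop = FALSE]
    randomPair <- function() {
      d <- drugIris[sample.int(length(drugIris), 1L)]
      c2 <- if (runif(1) < config$n_genes /
                  (config$n_genes + config$n_diseases))
        geneIris[sample.int(length(geneIris), 1L)]
      else disIris[sample.int(length(disIris), 1L)]
      c(d, c2)
    }
    docs <- vector("list", config$n_docs)
    for (i in seq_len(config$n_docs)) {
      nSlots <- 1L + rpois(1L, config$pairs_per_doc - 1)
      focal <- unlist(lapply(seq_len(nSlots), function(.) {
        if (lambda == 1) return(randomPair())  # null world: no distinction
        if (runif(1) < piLinked) {
          r <- known[sample.int(nrow(known), 1L), ]
          c(r$drug, r$candidate)
        } else {
          repeat {
            pr <- randomPair()
            if (!(paste(pr[1L], pr[2L], sep = "\r") %in% linkedKey))
              return(pr)
          }
        }
      }))
      nExtra <- rpois(1L, 3 * config$mention_noise)
      extra <- if (nExtra)
        phenoIris[sample.int(length(phenoIris), min(nExtra,
                                                    length(phenoIris)))]
      else character()
      ents <- c(focal, extra)
      # topical filler vocabulary, tilted toward the entities' factors
      docP <- lexP
      if (beta > 0) {
        topic <- colMeans(world$factors[focal, , drop = FALSE])
        nt <- sqrt(sum(topic^2))
        if (nt > 0) docP <- lexP * exp(beta * drop(lexFac %*% (topic / nt)))
      }
      nFill <- 8L + rpois(1L, 6)
      fill <- sample(lex, nFill, replace = TRUE, prob = docP)
      pos <- sort(sample.int(nFill + 1L, length(ents), replace = TRUE))
      words <- character(0)
      entAt <- integer(length(ents))
      wi <- 0L
      for (j in seq_along(ents)) {
        seg <- if (pos[j] - 1L >= wi + 1L) fill[(wi + 1L):(pos[j] - 1L)]
               else character(0)
        words <- c(words, seg, byIri[[ents[j]]]$mention[1L])
        entAt[j] <- length(words)
        wi <- pos[j] - 1L
      }
      if (wi < nFill) words <- c(words, fill[(wi + 1L):nFill])
      title <- paste(sample(lex, 3L, replace = TRUE, prob = docP),
                     collapse = " ")
      abstract <- paste(words, collapse = " ")
      # offsets over title + " " + abstract
      wStart <- c(0L, cumsum(nchar(words) + 1L))[seq_along(words)] +
        nchar(title) + 1L
      ann <- do.call(rbind, lapply(seq_along(ents), function(j) {
        e <- byIri[[ents[j]]]
        data.frame(start = wStart[entAt[j]],
                   end = wStart[entAt[j]] + nchar(e$mention[1L]),
                   mention = e$mention[1L], type = e$type[1L],
                   identifier = e$id[1L], stringsAsFactors = FALSE)
      }))
      ann <- ann[order(ann$start, ann$end), , drop = FALSE]
      ann <- ann[!duplicated(ann$start), , drop = FALSE]
      rownames(ann) <- NULL
      docs[[i]] <- new("AnnotatedDocument", docId = as.character(i),
                       title = title, abstract = abstract,
                       annotations = ann)
    }
    list(docs = docs, idMap = map)
  })
}

#' Uniformly remove edges or documents
#'
#' Removes `dropFraction` of a graph's triples, or of a document list,
#' uniformly at random; `round((1 - dropFraction) * n)` items survive.
#' Deterministic given `seed`.
#'
#' @param x a [KnowledgeGraph-class] or a list of
#'   [AnnotatedDocument-class].
#' @param dropFraction fraction in `[0, 1]` to remove.
#' @param seed integer RNG seed.
#' @return same type as `x`.
#' @export
degrade <- function(x, dropFraction, seed = 1) {
  stopifnot(dropFraction >= 0, dropFraction <= 1)
  if (is(x, "KnowledgeGraph")) {
    n <- nrow(x@triples)
    keep <- withSeed(seed, sort(sample.int(n, round((1 - dropFraction) * n))))
    tr <- x@triples[keep, , drop = FALSE]
    rownames(tr) <- NULL
    new("KnowledgeGraph", triples = tr, nodeType = x@nodeType,
        adjacency = buildAdjacency(tr, names(x@nodeType)))
  } else if (is.list(x)) {
    n <- length(x)
    keep <- withSeed(seed, sort(sample.int(n, round((1 - dropFraction) * n))))
    x[keep]
  } else stop("degrade() expects a KnowledgeGraph or a document list")
}

#' Write the synthetic world in the pipeline's input formats
#'
#' Emits TSV edge lists per relation, an OBO-style hierarchy for the
#' subclass links, a PubTator stream, the IdMap TSV and ground-truth pair
#' TSVs into a directory, exercising exactly the loaders the pipeline
#' consumes ([loadEdgeTSV()], [loadOboHierarchy()], [parsePubtator()],
#' [readIdMap()]).
#'
#' @param world result of [generateSyntheticKG()].
#' @param abstracts result of [generateSyntheticAbstracts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticInputs <- function(world, abstracts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- triples(world$kg)
  for (p in setdiff(unique(tr$predicate), "subclass_of")) {
    sub <- tr[tr$predicate == p, ]
    writeLines(paste(sub$subject, sub$object, sep = "\t"),
               file.path(dir, paste0(p, ".tsv")))
  }
  sub <- tr[tr$predicate == "subclass_of", ]
  terms <- sort(unique(c(sub$subject, sub$object)))
  stanzas <- unlist(lapply(terms, function(t) {
    isa <- sub$object[sub$subject == t]
    c("[Term]", paste0("id: ", t), paste0("is_a: ", isa), "")
  }))
  writeLines(stanzas, file.path(dir, "hierarchy.obo"))
  writePubtator(abstracts$docs, file.path(dir, "abstracts.pubtator"))
  writeIdMap(abstracts$idMap, file.path(dir, "idmap.tsv"))
  for (task in names(world$groundTruth)) {
    gtd <- world$groundTruth[[task]]
    writeLines(paste(gtd$drug, gtd$candidate, sep = "\t"),
               file.path(dir, paste0("ground_truth_", task, ".tsv")))
  }
  invisible(dir)
}
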