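---
title: "Multi-modal embeddings of knowledge graphs and literature for drug-target prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal embeddings of knowledge graphs and literature for drug-target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Curated databases (drug-target, drug-indication, drug-side-effect,
gene-disease, protein-protein links, ontology hierarchies) and the
biomedical literature describe overlapping but complementary slices of
pharmacology.  An entity may be well characterized in one source and
absent from the other — the zero-shot situation in which a model trained
on a single modality has nothing to say.  `kgtext` implements a
representation-learning pipeline that puts both modalities into one token
space so that a single embedding model, and the classifiers built on top
of it, can draw on either.

The pipeline:

1. **Knowledge graph.**  Typed edge lists and ontology `is_a` hierarchies
   are merged into a directed, edge-labeled graph whose nodes are IRIs
   (`stitch:` chemicals, `entrez:` genes, `doid:` diseases, `hp:`
   phenotypes, `go:` classes) and whose edges carry relations such as
   `has_target`, `has_indication`, `has_sideeffect`,
   `has_disease_association`, `interacts_with` and `subclass_of`.
   Ontology edges point child to parent so that walks can reach
   superclasses.  Symmetric protein interactions are stored as two
   directed triples.
2. **Corpus 1 — graph walks.**  From every node, `numWalks` iterated
   random walks of fixed length `walkLength` without restart emit
   sentences that alternate node and relation tokens.  Out-edges are
   sampled uniformly; a sink ends the walk early.
3. **Corpus 2 — normalized abstracts.**  PubTator-annotated abstracts are
   parsed, and each annotated mention whose `(type, identifier)` is
   covered by an identifier map is replaced by its graph IRI as a single
   atomic token; remaining text is lowercased and word-tokenized.  The
   two corpora now overlap at the token level.
4. **Embeddings.**  Skip-gram with negative sampling learns one vector
   per token from either corpus, from both by vector concatenation, or
   jointly from the shuffled concatenation of the corpora.  TransE offers
   a translation-based alternative trained directly on the triples.
5. **Prediction.**  A pair classifier (neural network, random forest,
   logistic regression, or Siamese network) is trained on the drug
   embedding concatenated with the candidate embedding, on a balanced
   dataset (negatives sampled uniformly outside the positive set, then an
   80/20 train/test split), and evaluated by AUROC, AUPR, per-drug recall
   and per-drug candidate ranking.

Before walking, all edges of the predicted relation are removed
(`has_target` when predicting targets, `has_indication` for indications),
so the model can never read the answer off the graph.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| `walkLength` | 10 node visits | sentence length is at most `2*walkLength - 1` tokens |
| `numWalks` | 20 per node | with the default world this gives a corpus of ~14k sentences |
| skip-gram `dimension` | 128 | fixed design choice used throughout |
| skip-gram `window` | 10 | covers most of a walk sentence and a good part of an abstract |
| skip-gram `negatives` | 5 | noise words per positive, unigram^0.75 distribution |
| skip-gram `epochs`, `minCount`, `sample` | 5, 1, 1e-3 | `minCount = 1` keeps every walked entity; `sample` is the canonical word2vec subsampling threshold — without it, very frequent tokens (relation labels, stop words) drag all vectors onto a common direction at this corpus scale |
| TransE `margin`, `norm`, `learningRate`, `batchSize` | 1.0, L1, 0.01, 64 | plain constant-rate SGD; entity vectors renormalized to unit L2 norm each epoch |
| ANN | hidden = 2x input, ReLU, sigmoid, cross-entropy, RMSprop, 100 epochs, batch 128 | architecture fixed; schedule is a package choice |
| RF | 50 trees, Gini, min leaf 1 | via `randomForest` |
| LR | L2, C = 10 | via ridge `glmnet` with `lambda = 1/(C n)` |
| Siamese | one shared dense layer of width d, ReLU, absolute-difference merge, sigmoid head | encoder depth is a package choice |

The printed TransE ranking objective lacks an explicit positive part; it
is implemented as the hinge `max(0, margin + d(s+p,o) - d(s'+p,o'))`,
since the raw sum is unbounded below and untrainable.  Corruption
sampling is uniform over entities and unfiltered during training
(collisions with true triples tolerated); evaluation offers a filtered
mode.

Per-drug recall is not uniquely defined by a threshold-free ranking; the
package reports the fraction of a drug's positive test pairs scoring at
least 0.5, macro-averaged over drugs with at least one positive, and
additionally returns full per-drug rankings so a hits@k summary can be
computed from the same report.

## The synthetic world

`generateSyntheticKG()` and `generateSyntheticAbstracts()` build
desk-scale inputs with known ground truth.  Design:

* Every entity carries a latent factor on the unit sphere
  (`latentDim = 4`).  Unit norm matters: with unnormalized factors,
  high-norm entities become hubs and per-entity link counts alone
  predict links — a leakage channel that would contaminate both the
  signal and the null experiments.
* Side relations (`has_sideeffect`, `has_disease_association`,
  `has_disease_phenotype`, `has_function`, `interacts_with`) are planted
  by thresholding factor inner products at each relation's density
  quantile.  The two predicted relations are planted degree-balanced:
  highest-affinity pairs accepted under per-entity quotas (25% slack),
  for the same anti-leakage reason.
* Documents mention about `pairs_per_doc = 2` focal (drug, gene) or
  (drug, disease) pairs plus Zipf-distributed filler words.  A focal
  slot is a ground-truth pair with a probability calibrated so that the
  co-mention lift — how much likelier a linked pair is to be co-mentioned
  than an unlinked one — matches `co_mention_lift` (default 18),
  accounting for the cross-pair background that multi-pair documents
  create.  Linked slots are drawn from a "literature-known" subset
  (`lit_known_fraction = 0.273`) so that, as in real corpora, roughly a
  quarter of database links are ever discussed in text, repeatedly,
  while the rest never appear.
* Filler words are drawn with affinity (`topic_concentration = 4`)
  between word factors and the document's entity factors: abstracts are
  topical, which is precisely what lets text embeddings generalize
  beyond directly co-mentioned pairs.
* `text_overlap_fraction` controls how many entities the identifier map
  covers; entities outside it appear in text only as plain words — the
  zero-shot scenario.
* Setting `co_mention_lift = 1` switches the text channel off coherently:
  focal pairs become uniform draws from the whole pair space and filler
  text becomes topic-free.  Combined with removing the factor-planted
  relations from the graph, this produces a world with no learnable
  signal, used as the null control.

Presets: `"default"` (200 drugs, 300 genes, 100 diseases, 60 phenotypes,
30 classes, 2,000 documents), `"complementary"` (smaller; 60% text
coverage and half the side edges dropped, so some pairs are recoverable
only from text and some only from the graph), and `"null"`.

What the generator does **not** emulate: real biomedical language (filler
words are synthetic), annotation errors and species ambiguity in NER,
realistic ontology semantics beyond `is_a` chains, or the extreme scale
and skew of Medline.  Passing the end-to-end tests therefore shows that
the pipeline recovers plantable low-rank structure through both
modalities at desk scale — not that it reproduces production-scale
biomedical performance.

## Numerical and design choices

* **Determinism.**  Every stochastic step takes a seed; skip-gram runs
  single-threaded with a private RNG and is bit-reproducible; walks
  iterate nodes in sorted IRI order; ranking ties break lexicographically.
* **AUROC/AUPR.**  AUROC counts tied scores as half-concordant, so a
  constant-score model scores exactly 0.5.  AUPR uses step integration
  with tied scores processed as one block.
* **Overlapping annotations** keep the longest span (ties: earliest
  start).  Invalid offsets are dropped with a warning count, or raise an
  error in strict mode.
* **Negative sampling order.**  Negatives are drawn once, before the
  80/20 split, so train and test share a consistent negative pool and
  are pair-disjoint by construction.
* **STITCH-style score columns** can be thresholded at load time; the
  default keeps all rows.
* **Identifier dialects** are normalized by uppercasing
  (`MESH:D001241` = `mesh:d001241`); gene identifiers may be bare
  numbers.  Whether to restrict genes to one species is a choice made
  when constructing the identifier map, not hard-coded.
* Titles are normalized together with abstracts (offsets run over
  `title + " " + abstract`, the PubTator convention).

## Problem sizes

The shipped experiments run on the default preset (about 690 graph
nodes, 5,000 triples, 14k walk sentences, 2,000 abstracts), the smaller
complementary preset, and toy graphs for the TransE checks.  One full
multi-modality run trains three skip-gram models and three classifiers
in a few minutes on a single CPU; `scripts/acceptance.R` repeats the
whole set of experiments from scratch.

## Known limitations

* Skip-gram and TransE are the only embedding families; no TransH/R, no
  subword or contextual models.
* Walks are first-order and unweighted; no node2vec-style biases.
* Probability calibration of classifier scores is out of scope; scores
  are used for ranking and a fixed 0.5 recall threshold.
* The benchmark loader expects two-column interaction lists with
  optional identifier maps; it does not download datasets.
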