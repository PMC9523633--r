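---
title: "Mining literature knowledge graphs for drug repurposing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining literature knowledge graphs for drug repurposing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgmine)
```

## The problem

Semantic predications extracted from the biomedical literature — assertions
like *(drug, TREATS, disease)* normalized to UMLS concept identifiers — form
a knowledge graph whose missing edges are candidate discoveries. `kgmine`
implements the full path from a raw predication table to ranked repurposing
hypotheses for Alzheimer's disease and related dementias: statistical
filtering, relevance calibration, knowledge-graph-embedding (KGE) training,
time-sliced evaluation, and candidate ranking.

This vignette documents the models, their assumptions, the tunable
parameters, and the numerical and design choices, in the package's own
terms.

## Rule-based filtering

Predications whose subject or object belongs to a generic semantic group
(Activities & Behaviors, Concepts & Ideas, Objects, Occupations,
Organizations, Phenomena) carry little repurposing signal and are removed
first (`semantic_type_filter()`). The bundled semantic-type-to-group table
(`semantic_group_map()`) is a compact editable subset of the UMLS Semantic
Network grouping — the full (licensed) network is not shipped — and unmapped
types pass through rather than being silently dropped. One deliberate edit:
the `food` type is grouped with Chemicals & Drugs rather than Objects, so
that dietary-supplement concepts survive the generic-Objects blocklist; a
caller studying other domains can supply their own mapping.

Each remaining triple then receives three statistics computed from the
deduplicated graph's head-by-tail adjacency matrix $M$ (entries count
distinct triples per head–tail pair; a binary 0/1 mode is available):

* the subject's out-degree $A_{\mathrm{out}}(i) = \sum_j M_{ij}$,
* the object's in-degree $A_{\mathrm{in}}(i) = \sum_j M_{ji}$,
* the subject–object association
  $G^2 = 2 \sum_{\mathrm{cells}} O \log (O/E)$ of the $2 \times 2$
  co-occurrence table, where $E$ is the standard independence expectation —
  the product of a cell's marginal sums divided by $N^{k-1}$ for a
  $k$-dimensional table. `independence_expectation()` and `g_squared()`
  accept arrays of any rank, so a three-way subject–predicate–object table
  can be scored too; the default pipeline uses the $2 \times 2$
  subject–object table because the association of interest is between the
  two concepts, irrespective of predicate.

$G^2$ is computed over pre-deduplication *mention* counts: repeated
assertion in the literature is evidence of association strength, which
dedup-level counts would erase (a triple-level mode exists for corpora
without meaningful mention multiplicity). Cells with $O = 0$ contribute
zero (the $x \log x \to 0$ limit); $O > 0$ with $E = 0$ is impossible for
co-occurrence tables and raises an error.

The three scores are min–max normalized to $[0, 1]$ across triples — a
constant component normalizes to all zeros rather than dividing by zero —
and summed into a composite in $[0, 3]$ (`composite_scores()`). The
composite is *directional*: the subject contributes its out-degree and the
object its in-degree, consistent with subject-to-object edges; a `total`
endpoint mode uses $A_{\mathrm{in}} + A_{\mathrm{out}}$ for both. The
top-$k$ triples by composite are retained (`select_top_k()`), with the
highest scores kept by default: the blocklist has already removed the
generic hub concepts, so remaining high-centrality, high-association
triples are the well-attested ones. `keep = "low"` inverts this for users
who prefer to prune hubs. The cutoff is a *rank* cutoff $k$, not a score
threshold — it directly controls the output size, which is the reason the
filter exists (keeping the graph small enough to embed). Whitelisted
concepts (e.g. `default_ad_whitelist()`) survive unconditionally at any
$k$, including $k = 0$, so disease-relevant triples can never be pruned.
Ties break deterministically by score, then lexicographic
(head, relation, tail). After filtering, entity and relation indices are
always rebuilt from the surviving triples, so embedding matrices never
carry orphaned rows.

## Relevance calibration

The second filter is a binary triple-correctness classifier over the
deterministic text template `SUBJECT [SEP] PREDICATE [SEP] OBJECT [SEP]
SENTENCE`. The interface is a plain `function(texts) -> [0, 1]`, so a
transformer fine-tuned elsewhere can be injected; the built-in
`train_baseline_classifier()` is a ridge-penalized logistic regression
(`glmnet`, fixed $\lambda = 0.01$, no internal randomness beyond the seed)
on binary token-presence features. It is a genuinely lightweight text
classifier, adequate for calibration experiments and for validating the
filter stage's contracts; it is not a language model. Filtering is applied
per predication (mentions of the same triple from different sentences are
scored separately — a bad extraction should not doom a well-attested
triple), with a default retention threshold of 0.5, configurable.
Classifier quality is summarized by precision, recall and F1
(`evaluate_classifier()`); undefined ratios (empty denominators) are
reported as 0 and flagged rather than returned as `NaN`.

## Embedding models and training

Three scoring functions $f(h, r, t)$ over entity/relation embeddings of
dimension $d$:

| family   | score                                     | character |
|----------|-------------------------------------------|-----------|
| TransE   | $-\lVert h + r - t \rVert_p$, $p \in \{1,2\}$ | translational, asymmetric |
| DistMult | $\sum_i h_i r_i t_i$                      | bilinear, symmetric in $h,t$ |
| ComplEx  | $\mathrm{Re}\sum_i h_i r_i \bar t_i$      | complex bilinear, handles asymmetry |

Training (`kge_train()`) minimizes the logistic loss
$\sum \log(1 + e^{-y f(h,r,t)})$ with labels $y = +1$ for observed triples
and $-1$ for negatives, by mini-batch SGD on the summed batch loss.
Negatives come from uniform corruption (`corrupt_triples()`): a fair coin
picks head or tail, and the replacement entity is uniform over all entities
except the original. Corruption does not filter accidental true triples by
default — with one negative per positive this follows the simplest
standard recipe — but `filter_negatives = TRUE` re-labels accidental
positives.

Defaults and rationale:

* `dim = 250`, `learning_rate = 0.01`, L2 for TransE — the configuration
  used for full-scale corpora; examples and tests use `dim = 32`, ample for
  the synthetic corpus's latent dimension of 8.
* `epochs = 200`, `batch_size = 512`, `negatives = 1` — desk-scale
  defaults, all configurable.
* Initialization is uniform on $(-6/\sqrt d,\, 6/\sqrt d)$, the original
  translational-model recipe, seed-controlled.
* TransE entity vectors are re-normalized to unit L2 norm after every
  update step (only relations are unconstrained), which bounds the score
  scale; DistMult and ComplEx run unconstrained, with no additional
  regularization or margin.
* Plain SGD, no momentum: the simplest optimizer faithful to a stated
  learning rate.

Analytic gradients are verified against central finite differences
(`gradient_check()`, step $10^{-5}$, max relative error below $10^{-4}$).
Two numerical details are deliberate: the loss uses a softplus form stable
to $|f| \sim 10^3$, and the scoring code multiplies the two *entity*
factors first, which makes DistMult's symmetry
$f(h,r,t) = f(t,r,h)$ and ComplEx's antisymmetry under purely imaginary
relations hold *bitwise* in floating point, not merely to tolerance.
Training is bitwise deterministic given the seed. Checkpoints are plain
text (CSV matrices + JSON sidecar) via `write_kge_model()`.

## Link-prediction evaluation and time slicing

`rank_query()` ranks the true entity among all substitutions of one side of
a test triple: rank $= 1 + \#\{\text{strictly better}\} +
\#\{\text{exact ties}\}/2$. The mean-rank tie policy avoids
order-of-enumeration bias; a constant model yields the expected rank
$(n+1)/2$. The *filtered* protocol removes candidates that would form a
known true triple (other than the query) before ranking, and is the default
— standard practice for these models, and the protocol under which a
filtered rank can never exceed the raw rank. `kge_evaluate()` averages
head- and tail-corruption queries (one each per test triple) into MR, MRR
and Hits@k, with Hits monotone in $k$ and MRR $\ge$ 1/MR by Jensen's
inequality.

`time_slice_evaluate()` is the package's answer to "would this model have
predicted new knowledge?": deduplicate, split by each triple's *earliest*
publication year (train strictly before the boundary year, validate on the
two boundary years, test after — defaults 2019/2020), train on the past
only, and rank the future. Triples with missing years are excluded and
counted. Validation/test triples whose entities or relations never occur in
training cannot be ranked and are excluded (counted in `n_unrankable`); the
filtered protocol uses known triples from all slices. Train/test leakage is
structurally impossible (the slices partition distinct triples) and is
asserted in tests.

## Candidate ranking

For a category (drugs and chemicals default to TREATS/PREVENTS; dietary
supplements to AFFECTS, where direct treatment assertions are rare),
`enumerate_candidates()` forms the full head × relation × disease-tail
product, `score_and_rank()` scores it and by default keeps only *novel*
triples (absent from training — repurposing seeks new links), and
`frequency_rank()` counts how often each head appears among the per-(relation,
tail) top-$N$ lists ($N = 10$), per relation. The frequency of an entity is
therefore bounded by the number of disease tails, and the counts are
invariant to group processing order.

## The synthetic corpus generator

`generate_kg()` emulates the statistical structure the pipeline assumes:
entities at isotropic Gaussian latent positions $x_i \in \mathbb{R}^8$,
relations as translation vectors $v_r$ (s.d. 0.5), and a triple rule-true
iff $\lVert x_h + v_r - x_t \rVert_2 < \tau$. The default $\tau = 1.85$ was
chosen once from the latent geometry (the distance of two standard Gaussian
points is $\sqrt{2\chi^2_8}$; $\tau = 1.85$ puts roughly 0.8% of pairs
within range) to yield a sparse graph of about 3,000 true triples at the
default 300 entities and 4 relations — a scale at which the full pipeline
runs in seconds per stage on one CPU. A bilinear rule variant
($\sum_i x_{h,i} w_{r,i} x_{t,i} > \tau$, default $\tau = 8$, unit-scale
weights) provides a regime matched to DistMult/ComplEx rather than TransE.

Emitted predications duplicate each true triple across 1–3 synthetic
citations, add 5% uniformly random false triples, and draw publication
years from a mixture placing about 60% of triples before the training
boundary, 22% in the validation years, and 18% after — so both evaluation
slices are well populated. Withheld from the corpus are (a) a 10% held-out
sample of rule-true triples for link-prediction evaluation and (b) *planted
repurposing pairs*: half of the (candidate-head, TREATS, disease-tail)
rule-true triples, the recovery target for candidate ranking. The candidate
category mixes these true heads with an equal number of decoy heads that
have no TREATS edge into any disease tail, so planted-versus-decoy rank
comparisons are balanced. Disease tails are the most-treated entities (so
they have enough structure to be learnable), and category heads and tails
are never assigned blocked semantic types.

`generate_annotations()` produces the calibration stand-in: label 1 for
rule-true, 0 for noise, flipped with probability `annotation_noise`
(default 0.1), with synthetic sentences whose vocabulary correlates with
the true label so the annotations are learnable. By default the majority
class is downsampled to balance the two classes, the way manual annotation
sets are normally constructed (and without which a majority-class predictor
would look falsely competent).

What the generator does *not* emulate: real MEDLINE vocabulary or sentence
text, citation-network structure, the heavy-tailed degree distributions of
real SemMedDB, extraction-error correlations, or concept-frequency drift
over time (years are independent of structure by design — which is exactly
what the shuffled-year control in the test suite exploits). Passing tests
therefore demonstrate that the machinery is correct and that recoverable
structure *is* recovered far above chance; they do not certify performance
numbers on real literature, which depend on corpus version and scale.

## Problem sizes and runtime

The test suite and the acceptance script run the study conditions at 300
entities, 4 relations, ~3,000 rule-true triples, embedding dimension 32,
200 epochs — about 4–5 s per training run and about a minute for the whole
suite. Full-scale corpora (hundreds of thousands of triples, dim 250) use
the same code paths; training cost grows linearly in triples × epochs ×
dim.

## Known limitations

* The composite filter's three components are summed unweighted; no
  data-driven weighting is attempted.
* The baseline relevance classifier is a bag-of-tokens linear model; its
  metrics on synthetic annotations say nothing about transformer-level
  performance on real sentences.
* Uniform negative sampling can draw false negatives (unfiltered by
  default); with one negative per positive this mildly biases scores on
  dense graphs.
* Entities or relations appearing only after the time-slice boundary are
  unrankable by construction and excluded from metrics rather than scored
  by a cold-start heuristic.
* `frequency_rank()` depends on the chosen disease-tail universe and $N$;
  entity frequencies are comparable only within one configuration.
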