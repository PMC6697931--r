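---
title: "Ranking biomedical abstracts by clinical relevance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking biomedical abstracts by clinical relevance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

In precision oncology, treatment decisions hinge on published evidence about
the clinical implications of the variants found in a patient's tumor. A
search over entity-matched abstracts returns everything that mentions the
gene or variant, most of it basic science. `clinrank` addresses this with a
*learning-free ranking over learned, query-independent scores*: two
classifiers are trained once over the whole index, their outputs are
normalized and multiplied, and ranking a query's candidate set is a plain
descending sort.

For a document $d$ with raw classifier outputs $c(d)$ (cancer relatedness)
and $l(d)$ (clinical relevance), both min-max normalized over the indexed
corpus to $[0,1]$,

$$\mathrm{RankScore}(d) = \tilde{c}(d) \cdot \tilde{l}(d).$$

The product is deliberately conjunctive: a document must be both about
cancer and clinically oriented to rank high. Alternative sort keys are kept
for comparison: the publication year times the rank score (recency-boosted),
the cancer score alone, and a query-specific vector-space `keyword_score`.

# Silver-standard corpus construction

No purpose-built training corpus for "clinically relevant cancer abstract"
exists at useful scale, so labels are derived from membership in a curated
variant-interpretation knowledge base:

- every curated record is **clinical-positive**;
- records whose disease annotation is outside cancer are **cancer-negative**
  (and excluded from the type task); all other records are cancer-positive;
- the three most frequent cancer types keep their own class; every other
  cancer type folds into `general_cancer`;
- negatives are a seeded uniform sample of pool abstracts containing no
  term from a user-supplied cancer-term list (case-insensitive,
  token-boundary matching). The term list is an input, not a built-in: only
  a tiny default ships for tests.

This construction has a known bias, which the package inherits by design:
the clinical classifier mostly learns to separate *clinically relevant
cancer* text from *non-cancer* text, because no large corpus of clinically
irrelevant cancer documents is available as a negative class.
`build_training_corpus()` implements exactly these rules and nothing more.

# Features and learners

Documents are represented as word n-grams (default unigrams + bigrams) of
the title-plus-abstract text, weighted by smoothed tf-idf

$$w(t,d) = \mathrm{tf}(t,d)\cdot\left(\ln\frac{1+N}{1+\mathrm{df}(t)}+1\right),$$

with vectors L2-normalized, so a term occurring in every document still
carries weight and cosines live in $[0,1]$. Feature selection keeps the $K$
terms with the largest $\chi^2$ statistic of the term's presence/absence
against the task label (2×C contingency table). We compute $\chi^2$ on
document occurrence rather than summed counts because abstracts are short
and presence is the meaningful signal at this scale; ties are broken
alphabetically so selection is deterministic. Defaults
(`feature_config()`): n-gram range (1,2), minimum document frequency 2,
lowercasing on, $K = 20{,}000$ — standard values for abstract-length text,
all overridable.

Two learners are supported, chosen to bracket the linear/non-linear
spectrum at this corpus size:

- **linear SVM** (`e1071`), raw score = signed decision value; multi-class
  (cancer type) via one-vs-rest with argmax over decision values;
- **random forest** (`ranger`), raw score = positive-class vote fraction.

Hyper-parameters come from a seeded randomized search (SVM cost log-uniform
over $[10^{-3}, 10^3]$; forest size 100–500, depth ∈ {unbounded, 10, 20},
node size ∈ {1, 5, 10}) evaluated by mean macro-F1 over 5 stratified CV
folds; the selection criterion is macro-F1 because the silver-standard
classes are imbalanced. The best configuration is refit on the full
training set. All sampling (splits, folds, draws, forests) is derived from
explicit seeds, and forests run single-threaded, so training is
bit-reproducible.

# Query semantics and ranking

A query is sets of genes, variants and keywords (at least one slot
non-empty) plus an optional cancer type. Filtering is two-stage: the cancer
type, when present, restricts to documents classified as that type; then a
candidate must contain at least one queried gene (matched on normalized
gene id after synonym expansion), variant (matched on canonical form), or
keyword (case-insensitive token match). The three slots combine with OR —
matching the disjunctive behavior assumed by the evaluation protocol —
and keyword matching is exact token equality after lowercasing, without
stemming, the simplest reproducible rule.

Score normalization is corpus-wide rather than per result set: the
classifier scores are query-independent and precomputed at indexing time,
so their normalization must not depend on the query. The degenerate case
(all raw scores equal) maps to 1.0 — a corpus with no ordering information
should not zero out the other factor of the product. The keyword score is a
classic L2-normalized tf-idf cosine; we intentionally do not emulate any
particular search server's practical scoring (length norms, BM25
variants), since all claims are about the relative behavior of ranking
schemes. Rankings are total orders: descending sort value, ties broken by
ascending document id.

# Entity annotation

The annotators are deliberately simple, transparent stand-ins for
full-scale NER services, adequate for corpora where mentions are injected
or ingested:

- **Genes/drugs**: dictionary matching over a TSV lexicon
  (id, canonical, synonyms). A synonym mapping to two ids is a load-time
  error. Matching is token-boundary aligned (neighbors must be
  non-alphanumeric; hyphens inside a surface are literal, so `B-RAF1`
  matches while `xBRAFx` does not). Gene symbols of ≤ 4 characters are
  matched case-sensitively — short symbols collide with ordinary words —
  and longer synonyms case-insensitively; drug matching is fully
  case-insensitive. Overlaps resolve longest-match-first, leftmost on ties
  (`nab-paclitaxel` beats its contained `paclitaxel`).
- **Variants**: an ordered regex grammar covering protein substitutions in
  short form, `p.` forms with 1- and 3-letter codes, `c.` substitutions and
  small indels, and rsIDs — the classes that dominate abstract-level variant
  mentions. Fusions and CNVs are out of scope. Canonical forms keep `p.`/`c.`
  text verbatim minus whitespace, uppercase short forms, lowercase rsIDs.
  Query variants are compared on canonical form; folding `Val600Glu` to
  `V600E` is available (`fold_aa = TRUE`) but off by default, since silent
  normalization can surprise users comparing against verbatim strings.

Precomputed annotations from external services can be ingested through the
JSONL `mentions` field, bypassing the stand-ins entirely.

# Evaluation metrics

Conventions, where the literature admits variants:

- **AP**: relevant documents absent from the ranking contribute zero (the
  sum of precisions at relevant ranks is divided by the total number of
  relevant documents).
- **nDCG**: binary gains with $1/\log_2(i+1)$ discount; the ideal ranking
  places all relevant documents first.
- **Rel-vs-IrRel**: mean 1-based rank of relevant documents divided by the
  mean rank of irrelevant ones, computed in the *full* ranking; undefined
  (reported `NA`) without irrelevant judgments. It is the filtering-robust
  metric: a system that filters aggressively has systematically larger
  absolute ranks, which cancel in the ratio.
- **Restricted P@k / R@k**: the ranking is first restricted to judged
  documents; `k` indexes the restricted list. Suited to small judged sets
  where conventional P@k is near zero everywhere.
- **"# best" counts** in the ranker comparison credit every ranker tied for
  the minimal ratio on a query.
- Multi-rater Likert consolidation removes pairs rated 5 by one rater and 1
  by another, then majority-votes per-rater binarized scores. The
  binarization threshold is a parameter (default 4, i.e. scores 4–5 count
  as relevant) and exact ties are discarded, mirroring the removal of
  contested pairs; neither choice is canonical, hence both are explicit
  parameters rather than constants.

# The synthetic generator

`generate_corpus()` emulates precisely the structure the pipeline assumes,
and nothing more: three document classes (clinically relevant cancer, basic
cancer science, non-cancer) with class-conditional unigram vocabularies.
Each token is drawn from a shared pool with probability `overlap`, else
from the class vocabulary, both Zipf-weighted; `overlap = 0` gives disjoint
vocabularies and maximal separability, `overlap = 1` makes classes
indistinguishable, so classifier quality must degrade monotonically in
between. Entities (synthetic gene symbols with synonyms, grammar-generated
variants, drug names) are injected as whole tokens at token boundaries with
recorded ground-truth spans, which makes the annotators exactly recoverable
oracles. Gold sets and judgments follow the class signal: for a query gene,
clinical-cancer documents carrying it are relevant, other documents
carrying it are irrelevant.

Defaults (1000 documents, class mixture 0.4/0.3/0.3, vocabulary 120 words
per class, overlap 0.2, mean length 60 tokens, gene/variant/drug injection
rates 0.8/0.3/0.3, 30 genes, years 2000–2020) describe a corpus a desk-scale
experiment can train on: large enough for an 85/15 split with 5-fold CV per
class, small enough to regenerate freely. The generator does **not** emulate
real biomedical language — no syntax, no topical correlation between
entities and content words, no class imbalance at real-world severity — so
passing tests demonstrate correct mechanics and the qualitative orderings
(rank score above keyword baseline when relevance follows the class signal),
not absolute performance on real literature.

# Numerical and degenerate-input choices

- Unknown publication years use sentinel 0, which sorts below all real
  years under the recency-boosted key.
- `normalize_scores()` on a constant vector returns all 1.0; on a single
  document, 1.0.
- Documents with no vocabulary term have an all-zero tf-idf vector (cosine
  0 against everything) rather than being an error.
- Stratified splitting rounds the per-stratum train size to the exact
  fraction (within one document) and refuses strata of fewer than two
  documents, as well as train fractions of 0 or 1.
- The binary SVM's decision-value sign is explicitly oriented to the
  positive class (the underlying library's sign depends on label order).
- Linear models persist exactly (weights and biases as TSV); forests are
  not text-serializable and must be refit — with fixed seeds this is exact.

# Problem sizes used by the shipped tests

The test suite exercises the full pipeline at sizes chosen for fast,
convincing checks: corpora of 80–1000 documents for pipeline and recovery
tests (1000 with unigram features and a 500-term cap for the parameter
recovery and ranking-separation experiments, 5 seeds each), 10,000
lightweight documents for mixture-convergence checks, and exhaustive
enumeration of all judged sequences up to length 6 for metric-oracle
equivalence.

# Known limitations

- The annotators are dictionary/regex stand-ins; abbreviation resolution,
  species disambiguation and fusion/CNV variants are out of scope.
- The clinical classifier's negative class is non-cancer text (see the
  corpus-construction bias above).
- Ranking quality claims are relative (between sort keys on the same
  corpus); absolute figures on real literature require full-scale corpora
  and external annotation services.
- The vector-space score is corpus-dependent through idf; scores are
  comparable within one index, not across indexes.
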