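---
title: "Models and methods in genelit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in genelit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `genelit`, the parameter choices
that matter, the design decisions taken where several defensible options
existed, and what the synthetic ground-truth tests do and do not establish
about real literature data.

## Text preprocessing and TF-IDF

`preprocess()` applies seven steps in a fixed order: replacement of
non-alphanumeric characters by spaces, whitespace tokenisation, stop-word
removal (a frozen English list bundled under `inst/extdata/`, compared
case-insensitively), lower-casing, removal of tokens shorter than three
characters, removal of pure-integer tokens, and stemming. Two dialect
choices deserve a note:

* **Stemming.** The stemmer follows the classic Porter measure-based steps
  with one deliberate deviation: step 4 does not delete a final `-ate`.
  Under the strict algorithm, `disambiguations` →
  `disambiguation` → (step 2) `disambiguate` → (step 4) `disambigu`, while
  `disambiguated` stops at `disambiguate` — the family fractures. Keeping
  `-ate` intact lets the final-`e` rule unify `-ate`, `-ated`, `-ating` and
  `-ation` forms at a common stem ending in `at` (all three example forms
  map to `disambiguat`), which is the behaviour the pipeline is calibrated
  to and the conformance test pins.
* **Hyphens become spaces**, so `RNA-seq` tokenises to `rna` + `seq` (both
  survive the three-character rule). Deleting the hyphen instead would glue
  unrelated morphemes (`rnaseq`), and the separator-equivalence of the
  entity matcher already covers hyphen variation where it matters. The
  filters are re-applied after stemming because a stem can fall below three
  characters (`use` → `us`); this makes the token stream idempotent under
  re-preprocessing.

`fit_vectorizer()` extracts uni- to tetra-grams, keeps n-grams with corpus
count ≥ 2 and document frequency strictly below 0.6 (we read the frequency
bound as *document* frequency — the standard vectoriser semantics — since a
corpus-proportion reading would make the count and frequency filters nearly
redundant on short texts), and applies TF-IDF with the smoothed add-one
convention `idf = log((1 + N) / (1 + df)) + 1` followed by L2 row
normalisation. The convention is pinned by an oracle test against an
independently coded formula at 1e-9.

## Synonym safety

`build_gene_dictionary()` unions synonyms per symbol, always includes the
symbol itself, removes synonyms case-insensitively identical to a disease
name (case-insensitive because capitalisation of disease eponyms is
inconsistent across sources), and computes four ambiguity classes. Nested
detection requires word-boundary containment, case-insensitive: `insulin`
is nested in `insulin receptor`, but `star` is not nested in `start`.
Disease names with commas also gain a fully reversed variant — for
multi-comma names we reverse *all* segments (`"Severe, Acquired, Anemia"` →
`"Anemia Acquired Severe"`), the natural generalisation of the one-comma
rule.

`compute_safety_features()` builds the usage features per (symbol, synonym):
candidate totals and per-synonym contribution, character length, summed
character information content (−log2 of each character's frequency,
estimated from the working corpus' titles and abstracts with add-one
smoothing), the number of other synonyms containing the synonym, the two
conditional mention probabilities estimated from candidate documents (zero
when the conditioning set is empty), and an is-symbol flag.

`classify_unsafe()` scores synonyms with positive-unlabelled bagging
(`pu_bag_train()`): the initial positive class is the union of the English,
short and promiscuous classes; each bag bootstraps provisional negatives
from the unlabelled pool (balanced bags, bootstrap size = positive-set
size), fits a random forest, and held-out scores are averaged. The
refinement loop runs five rounds; the interactive relabelling the loop was
designed around is replaced by an optional labels table merged as known
positives/negatives from round two on. The final label is the disjunction
of the four rules (English word, < 3 characters, score > 0.5, promiscuous),
so three of the four rules are classifier-independent and the labelling is
monotone in the score threshold.

One PU-specific hazard shaped a default: hidden positives drawn into a
bag's provisional negatives form a feature-identical cluster that a fully
grown tree can memorise and generalise into an inverted rule. The random
forest therefore uses `nodesize = 10` (within the usual leaf-size range for
this model family); the deeper fix is in the generator design (below).

## Entity tagging

`compile_pattern()` turns a synonym into a case-insensitive matcher that
treats any single separator from `{"", "-", " ", "/"}` between alphanumeric
runs as equivalent (`ErbB-1` matches `erbB1`, `ERBB1`, `ErbB 1`) and uses
lookarounds so matches cannot start or end inside a longer alphanumeric
token (`STAR` does not match in `START`). Greek-letter expansion is not
performed; the separator class is the configurable extension point.
`find_candidates()` scans title + abstract + keywords, joined with a
`" ||| "` separator no fuzzy pattern can bridge, and resolves overlaps by
longest-match exclusivity across the *whole* dictionary: a span matched by
a synonym is discarded when a strictly longer match of any dictionary
synonym covers it. An enumeration oracle (all separator surface variants,
token-bounded substring search) checks equivalence on randomised fixtures.

## Co-citation communities and the 0.1% rule

`build_cocitation()` increments the weight of an unordered candidate pair
once per third publication citing both; a brute-force triple-enumeration
oracle pins it. Communities come from igraph's weighted fast-greedy
modularity maximisation per connected component, with nodes inserted in
sorted order for deterministic tie-breaking; two-node components are kept
as one community (modularity is degenerate there and the greedy
implementation would otherwise split a single co-cited pair). A community
is linked iff `(#members with ≥1 safe mention) / (#members with only unsafe
mentions) > 0.001`; members with both safe and unsafe mentions count in the
numerator only. When no member is unsafe-only the denominator is zero and
we link iff any safe member exists — the rule's limit behaviour.

Disconnected candidates with a safe mention are linked directly. The rest
are classified by PU bagging with a ridge-regularised logistic base model
(50 bags) over TF-IDF features of titles, abstracts and keywords (keywords
always included), positives = linked members, known negatives = rejected
members, link threshold 0.5 on the mean held-out score. When the unlabelled
pool is smaller than 1000, an auxiliary negative class of up to 1000
publications mentioning other genes is added (capped at the available pool
in small corpora). The full hyper-parameter sweep over eight classifier
families is configuration, not behaviour: the package exposes `lambda`,
`ntree` and `nodesize` through `model_params` and defaults to the logistic
model for text and the random forest for safety features.

## Trend detection

`assemble_series()` builds ten cumulative yearly categories per gene.
Citation categories are attributed by the **citing** publication's flags in
the citing publication's year: a big-pharma paper citing an annotated paper
adds one big-pharma citation; being cited *by* a non-pharma paper adds
nothing to the pharma categories. Years before the grid fold into the first
cumulative value.

`train_forecaster()` fits a GRU encoder-decoder preceded by an additive
attention layer over the encoder states (scores
`tanh(h_j W1 + h_T W2 + b) · v`, softmax weights, context vector fed to
every decoder step together with the previous value). Series are min-max
scaled on the training window; constant series have a degenerate scaler,
map to zeros, and are excluded from the loss. The optimiser is RMSprop, the
loss is squared error on log1p-transformed scaled values (our reading of
"log error"), training uses teacher forcing, decoding is free-running, and
30% of series are held out for validation. The default desk-scale
architecture is one encoder and one decoder layer of 5 units — the 5-unit
width is the selected operating point of the model family, and the stacked
five-layer variant is available through `n_layers` (the analytic backprop
is layer-general and gradient-checked at depth 2 in the tests). The
vignette-level problem sizes (200–500 series, 250 epochs) are the package's
default study conditions; the architecture trains in seconds at that scale.

`mase()` divides the mean absolute forecast error by the error of the
repeat-last-value naive forecast; the break-even value is 1 (values below 1
beat naive — a "below 0" reading that sometimes circulates is a slip, since
MASE is a ratio of nonnegative errors).

**Trendiness.** Fold change is `(predicted + 1) / (realised + 1)` — the
pseudo-count guards against empty categories. The direction (predicted over
realised) is chosen deliberately: the statistic is the **right-tail area**
of a Gaussian KDE (bandwidth 0.1) fitted to the log2 fold changes within
the gene's volume bin, bounded on the left by the gene's own value, so a
gene whose literature outgrew its forecast has a small fold change, sits in
the left tail, and gets trendiness near 1. This keeps the three desired
properties simultaneously: trendiness is a tail probability in [0, 1], it
is strictly decreasing in fold change within a bin, and burst genes score
high. (With the opposite fold-change direction the last two properties
contradict each other.) The KDE is fitted on the log2 scale because the
quantity is multiplicative; the tail integral has the closed form
`mean(pnorm((x_i − x_g) / h))`, which the tests verify against numerical
quadrature at 1e-6. Bins with fewer than two genes merge into their lower
neighbour. "Initial number of publications" for binning is the cumulative
count at the last training year.

## Topics

`fit_topics()` factorises the TF-IDF matrix by multiplicative-update NMF
under the Frobenius objective (convergence when the relative
reconstruction-error change drops below 1e-12, seeded random
initialisation), or by collapsed Gibbs LDA over the raw counts behind the
same nonnegative `W`/`H` interface. NMF weights are not probabilities, so
`topic_timeline()` L1-normalises the document rows before taking per-year
means and standard deviations; all-zero rows normalise to uniform. No
automatic choice of K is provided — perplexity-style selection is known to
disagree with interpretability here, so K is the user's call.
`top_phrases()` hard-assigns documents to their argmax topic and ranks
phrases by summed TF-IDF within the topic's documents.

## Recommender

`pagerank()` is a standard damped (0.85) power iteration with uniform
dangling-mass redistribution, converged to 1e-10 and normalised to sum 1;
it is implemented in the package (not delegated) so the test suite can
check it against an independent dense implementation. Review scores sum the
PageRank of cited publications, normalised by the hypothetical
all-citing review (= total mass = 1). `recommend()` scores combinations in
two modes: **literal** applies the printed row-sum formula, which double
counts multiply-cited publications; **union** binarises the row sum first,
so the score is the covered PageRank mass. Union is the default because it
matches the stated goal of minimising overlap, and coverage is submodular
there, which also justifies the greedy fallback: combination spaces larger
than `max_combinations` (default 1e5) switch to greedy forward selection
with a notice, and greedy union-mode selection is guaranteed ≥ (1 − 1/e) of
the exhaustive optimum. Each combination carries the mean year of covered
publications and the mean (normalised) topic profile — the aggregation over
cited publications is our choice, flagged as such.

## The synthetic worlds: what passing tests show

The generators are the package's study conditions, fixed once:

* `gen_lexicon()` plants one ambiguous synonym on ~`ambiguity_rate` of
  genes, split evenly over English words, two-character tokens, promiscuous
  tokens and nested tokens. Promiscuous and nested tokens are formatted
  like official symbols — in real dictionaries promiscuous synonyms are
  mostly former official symbols, and this prevents the safety classifier
  from succeeding (or failing) on token shape alone. A quarter of genes get
  a safe nested sibling synonym, reflecting that nested synonym pairs are
  common and mostly safe; nestedness alone must not predict safety.
* `gen_lexicon_corpus()` writes documents in which a gene's own synonyms
  co-occur while ambiguous tokens also appear in background documents with
  no gene context — the usage signature (high totals, low conditional
  probabilities) the safety features are designed to detect.
* `gen_field_corpus()` plants a partition: three fields of 60 documents,
  co-citation pair probability 0.2 within and 0.005 across fields
  (stochastic-block-style, one citing document per sampled pair), 25% of
  candidate documents disconnected, field 1 truly about the target gene
  (60% safe-synonym rate, 50% ambiguous rate), other fields using the
  ambiguous token at rate 0.7 in its other meaning.
* `gen_timeseries()` draws yearly new counts as Poisson around per-gene
  exponential growth (base rate U(0.5, 3), growth rate U(0.02, 0.09) per
  year, citations 3–10 per publication, review/trial/pharma thinning rates
  0.2/0.05/0.08), with bursts multiplying new counts by 4 from a planted
  year in 2014–2017 onward.
* `gen_topic_corpus()` samples document mixtures from a Dirichlet
  (concentration 3, so documents are topically peaked but not pure — with a
  much larger concentration all documents share the same mixture and the
  factorisation becomes unidentifiable) around a year-indexed drift
  schedule, over disjoint per-topic vocabularies.

Passing the planted-recovery tests shows the machinery is implemented
correctly and recovers structure when it is present at realistic
signal-to-noise. It does **not** show that real MEDLINE-scale performance
matches: real corpora have heavier-tailed vocabulary, citation graphs far
sparser than the planted partition, genuinely ambiguous borderline
synonyms, and non-stationary publication dynamics. Absolute headline
numbers from full-corpus runs (database-wide recall/precision, per-category
MASE medians, the share of disconnected publications) depend on those
resources and are out of scope here.

## Numerical and degenerate-input choices

* Ties in greedy modularity are fixed by sorted node insertion; community
  ids are arbitrary but stable.
* `nmi()` returns 0 when either variable is constant; entropies use natural
  logarithms and the normaliser is `sqrt(H(A) H(B))`.
* Co-occurrence is union-normalised (Jaccard); `normalise = "min"` is the
  alternative reading of "normalized by the total number of publications
  presenting those tags".
* Organisation matching is token-bounded case-insensitive substring over
  punctuation-stripped strings, big > medium on double matches.
* PageRank on an empty edge set returns the uniform distribution;
  `mase()` returns 0 when both the forecast and the naive errors are zero
  and `Inf` when only the naive error is.
* Missing safety features label a synonym unsafe (conservative), with a
  warning.

## Known limitations

* The stemmer is English-only and the `-ate`-preserving dialect, while
  self-consistent, differs from strict Porter on `-ate` words (`activate` →
  `activat`, not `activ`).
* Longest-match exclusivity is global across the dictionary; a corpus where
  one gene's safe synonym is nested inside another gene's synonym will
  credit only the longer match even if the shorter gene is the true topic.
* The forecaster's free-running decoder compounds errors over long
  horizons; six years is the tested operating range.
* Greedy recommendation guarantees hold in union mode only; literal-mode
  scores are not submodular.
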