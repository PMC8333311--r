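# genelit

Mining the biomedical literature for genes: disambiguation, publication
trends, topics, and review recommendation.

## The problem

Gene names are ambiguous. A gene symbol such as `STAR` is also an English
word; `ARP1` has been a synonym of seven different genes; `insulin` is nested
inside `insulin receptor`. Naively matching synonym lists against titles and
abstracts therefore floods any downstream analysis with false positives.
`genelit` implements a disambiguation-first pipeline over a publication
corpus and its citation graph:

1. **Synonym safety.** Gene synonyms gathered from source tables are classed
   as *nested*, *promiscuous*, *English* or *short*, and engineered usage
   features (candidate totals, per-synonym contribution, character
   information content, conditional mention probabilities) feed a
   positive-unlabelled (PU) bagged random forest. A synonym is **unsafe** iff
   it is an English word, shorter than three characters, promiscuous, or its
   ensemble score exceeds 0.5.
2. **Co-citation disambiguation.** Candidate publications for a gene are
   joined into a weighted co-citation graph (edge weight = number of third
   papers citing both endpoints), broken into communities by fast-greedy
   modularity maximisation. A community is linked to the gene iff the ratio
   of members with a safe-synonym mention to members with only unsafe
   mentions exceeds 0.1%. Disconnected candidates with a safe mention are
   linked directly; the rest are scored by PU bagging (50 bags, logistic
   base model) over TF-IDF uni- to tetra-grams.
3. **Trend detection.** Per gene, ten cumulative yearly series
   (publications, reviews, trials, big/medium-pharma publications, and the
   corresponding citation categories, attributed by the *citing* paper's
   flags) are forecast by a small GRU encoder-decoder with an attention
   layer over the encoder states (min-max scaling, RMSprop, log-error loss).
   Forecast quality is measured by MASE (mean absolute scaled error; 1 =
   break-even with a repeat-last-value naive forecast). **Trendiness** of a
   gene is the right-tail probability of its fold change
   `(predicted + 1) / (realised + 1)` under a Gaussian kernel density
   (bandwidth 0.1) fitted within its publication-volume bin (five bins at
   the 20/40/60/80/100th percentiles of volume at the end of training) —
   genes whose literature outgrew the forecast sit in the left tail and get
   trendiness near 1.
4. **Topics and reviews.** Non-negative matrix factorisation (or collapsed
   Gibbs LDA) over TF-IDF matrices yields per-gene topic timelines (per-year
   mean ± sd of normalised document-topic weights), and a recommender ranks
   review combinations by PageRank-weighted citation coverage, either
   literally (row-sum formula) or with overlap removed (union mode).

Synthetic-data generators (`gen_lexicon()`, `gen_field_corpus()`,
`gen_timeseries()`, `gen_topic_corpus()`) plant known ground truth —
ambiguous synonyms, field communities sharing an ambiguous token, publication
bursts, drifting topic mixtures — so every stage is testable end to end
without downloading any external resource.

## A worked example

Disambiguate a planted world in which three research fields share the
ambiguous token `"orca"`, but only one field truly writes about the gene
`TGT1`:

```r
library(genelit)
library(dplyr)

w   <- gen_field_corpus(seed = 1)     # corpus + citations + lexicon + truth
ann <- disambiguate(w$corpus, w$citations, w$lexicon, "TGT1", seed = 1)
count(ann, provenance)
#> # A tibble: 3 × 2
#>   provenance      n
#>   <chr>       <int>
#> 1 classifier      2
#> 2 community      46
#> 3 safe-direct    13
length(intersect(ann$pub_id, w$truth$annotations)) / length(w$truth$annotations)
#> [1] 1
```

All 60 field-1 documents are annotated (one field-2 document sneaks in
through the classifier, for a precision of 60/61): 46 documents through
their linked co-citation community, 13 disconnected documents through a
direct safe-synonym mention, and 2 ambiguous disconnected documents through
the PU text classifier.

Forecast publication dynamics and score trendiness:

```r
ts   <- gen_timeseries(seed = 11, n_genes = 500, burst_fraction = 0.1,
                       burst_multiplier = 4)
pubs <- filter(ts$series, category == "publications")
fc   <- train_forecaster(pubs, train_end = 2013, units = 5, seed = 2)
res  <- forecast_result(pubs, forecast_series(fc, pubs), train_end = 2013)
tr   <- compute_trendiness(res) |> left_join(ts$truth, by = "gene")
median(tr$trendiness[tr$burst])      # genes with a planted burst
#> [1] 0.9584629
quantile(tr$trendiness[!tr$burst], 0.9)
#>       90%
#> 0.7671099
```

The planted-burst genes' median trendiness (0.96) clears the 90th percentile
of the unbursted background (0.77): a burst that the gene's own history
cannot explain is exactly what the statistic flags.

## Package shape

Every user-facing function takes a data frame first and returns a tibble, so
stages compose with the pipe. Fitted objects (`genelit_pu`,
`genelit_topics`, `genelit_forecaster`, `genelit_eval`) support broom-style
`tidy()`/`glance()`, and result types have `autoplot()`/`plot_*()` methods.
A thin command-line wrapper over the same functions ships in
`inst/cli/genelit`. The methods vignette
(`vignettes/genelit-methods.Rmd`) documents the models, parameter choices
and limitations.
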