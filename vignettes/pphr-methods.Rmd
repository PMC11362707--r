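---
title: "Physician recommendation from consultation histories: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physician recommendation from consultation histories: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pphr)
```

## The problem

On a web-based consultation platform a patient types a free-text medical
question and must be routed to a physician. Department-level triage is too
coarse: sub-specialties overlap, department names differ between
institutions, and patients describe symptoms colloquially rather than with
disease names. `pphr` implements a patient-physician hybrid recommender
(PPHR) that ranks individual physicians for a new question using only the
platform's own consultation history — question texts, who answered what,
and how fast.

## The model

The engine runs three steps on top of a text-embedding backend.

**Step 1 — candidate generation (PFB).** Every historical question is
embedded as a unit vector; a new question $q$ retrieves its `top_m`
(default 50) nearest historical questions by cosine similarity
$\cos(u, v) = u \cdot v / (\lVert u\rVert\,\lVert v\rVert)$. The
physicians who answered those questions become *direct* candidates. A
physician matched by several questions gets

$$\mathrm{init\_score}_i = \max_j \cos(q, d_{ij}), \qquad
  n_i = \#\{\text{matched questions}\},$$

the maximum being used because a physician's best-matching past case is
the evidence of competence, not their average.

**Step 2 — semantic expansion (PPH).** Each physician also has a profile:
the top 20 TF-IDF keywords of the concatenation of all questions ever
addressed to them,

$$\mathrm{TFIDF}(t, d) = \mathrm{TF}(t, d) \cdot \mathrm{IDF}(t),$$

embedded with the same backend; profile cosine gives a
physician-physician similarity matrix. For a direct candidate $i$ and any
other physician $j$,

$$\mathrm{physician\_score}_j =
  \mathrm{init\_score}_i \times \mathrm{expand\_score}_{ij},$$

and $j$ joins the pool iff this product exceeds the expansion threshold
(default 0.7). Direct candidates keep $\mathrm{expand\_score} = 1$, so
the product identity holds for every emitted candidate (the test suite
asserts it bit-exactly). The gate applies to the *product*, not to the
profile similarity alone, so weak seeds cannot propagate. Expansion is
single-hop: expanded candidates do not seed further expansion, which
keeps the gate meaningful (chained products would decay below it anyway).

**Step 3 — response-rate ranking (PPHR).** Per-physician response
metrics come from the corpus: rate $R_i = N_R/N$ and winsorized mean
response time $S_T/N_R$. The final score is

$$\mathrm{score}_i = R_i^{\,e} \times A_i,$$

where $A_i$ aggregates candidate $i$'s matched occurrences of
`physician_score` and $e$ is a configurable exponent (default 1). For a
direct candidate the default aggregation is
$A_i = n_i \times \mathrm{physician\_score}_i$; for an expanded candidate
it is the sum of the retained seed products. The top-K by this score
(default K = 14) is the recommendation.

### A note on the ranking formula

The product-with-threshold expansion (Step 2) is fully specified; the
exact algebra combining $n$, the similarity aggregate, and the response
rate in Step 3 is a design choice of this package. We picked
$R \times \sum_{\text{occurrences}} \mathrm{physician\_score}$ as the
default because it is monotone in each ingredient separately (the test
suite asserts rank monotonicity in $R$), reduces to pure similarity
ranking when rates are equal and each physician matches once, and
produces final scores on the scale of a few units for typical
similarity values around 0.9 and double-digit match counts. Both the
aggregation (`"count"` vs `"sum_sim"`) and the rate exponent are
configuration, and every saved engine state records the variant used, so
results are always attributable to a named scoring rule.

### Ablation modes

`recommend(engine, text, mode = ...)` exposes the two ablations through
the same retrieval pass, so a comparison isolates exactly one mechanism:
`"PFB"` ranks direct candidates by `init_score` (no profiles, no rates),
`"PPH"` adds expansion but ranks by the similarity aggregate alone, and
`"PPHR"` is the full model.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `top_m` | 50 | similar-question pool before grouping by physician |
| `threshold` | 0.7 | expansion gate on the score product (also the relevance gate in evaluation) |
| `k` | 14 | recommendation list length; the operating point used throughout |
| `aggregation` | `"count"` | how a direct candidate's matches combine: $n \times$ best similarity, or the sum of matched similarities |
| `rate_exponent` | 1 | strength of the response-rate weighting |
| winsor quantiles | 0.05 / 0.95 | clamp for response times, linear-interpolation empirical quantiles (`stats::quantile` type 7) |
| `tfidf_top_n` | 20 | keywords per physician profile |

`top_m` bounds how many distinct physicians can ever be direct
candidates, so it should comfortably exceed the largest K you evaluate.
The winsor quantile definition is documented because quantile conventions
differ; type 7 interpolates linearly between order statistics, so on the
integer grid `1:100` the 5%/95% bounds are 5.95 and 95.05.

## Embedding backends

The engine is encoder-agnostic behind `fit_backend()`:

* `hash_ngram_backend(dim = 256, ngram = 3)` — the default and the test
  backend. Character n-grams are hashed by fixed polynomial arithmetic on
  Unicode code points into `dim` buckets; the count vector is
  L2-normalized. It is fully deterministic, platform-stable, and needs no
  training or download. It captures lexical overlap, not meaning — which
  is exactly what the synthetic corpora exercise.
* `paragraph_vector_backend(dim = 64, seed = 42)` — a corpus-trained
  static paragraph embedding (random-indexing family): each vocabulary
  word gets a hash-seeded Gaussian vector and a document is the
  TF-IDF-weighted sum, L2-normalized. It is the non-contextual baseline
  for encoder comparisons.
* `transformer_backend(model_id, encode_fun)` — delegates to a
  user-supplied pretrained sentence encoder (e.g. a multilingual SBERT
  served from another process). Without an `encode_fun` it raises an
  explicit backend-unavailable error; the package never silently falls
  back to another encoder, because silently swapping encoders would
  invalidate any saved similarity structure.

All vectors are unit-norm, so cosine reduces to a dot product and the
nearest-neighbour search is an exact matrix product, asserted equal to a
brute-force cosine sort in the tests. Ties break by ascending id.

## The synthetic corpus generator

Real consultation corpora are private, so the package ships a generator
(`generate_corpus()`) whose defaults define the study conditions used
across the test suite:

* **Topics.** 5 topic vocabularies of 40 words plus 30 shared everyday
  words; each physician specialises in 1–2 topics; each question is a bag
  of tokens from its physician's topic with a 5% off-topic noise rate.
  Questions are word bags, not grammatical sentences: the pipeline
  consumes token statistics and embeddings only, so fluency is irrelevant
  to the contracts under test.
* **Response behaviour.** Per-physician response rates are uniform on
  (0.4, 0.9), giving a pooled rate near 65%, typical of consultation
  platforms where roughly a third of requests go unanswered.
* **Response times.** Lognormal with meanlog $\log 80$ and sdlog 1.1
  (median 80 min; 5th/95th percentiles ≈ 13 and 490 min), reproducing the
  right skew that motivates winsorization.
* **Rate-time coupling.** `rate_time_link = -2` shifts each physician's
  meanlog by $-2(R_i - 0.65)$: physicians who answer more also answer
  faster. This coupling is what makes response-rate weighting improve
  service quality; with `rate_time_link = 0` the two are independent and
  rate weighting cannot systematically help the service-quality metric.

What the generator does **not** emulate: colloquial phrasing, spelling
noise, multi-intent questions, department-name ambiguity, temporal drift
in physician activity, or any correlation between question difficulty and
response behaviour. Passing tests therefore demonstrate the pipeline's
contracts and the mechanisms' directions, not clinical-grade retrieval
quality on real text.

## Evaluation suite

* **Hit ratio / mean rank** for labeled queries; mean rank averages over
  hit queries only, since rank is undefined for a miss.
* **Precision / recall / F1** under the relevance rule: a candidate is
  relevant when its `physician_score` exceeds 0.7. False negatives are
  relevant candidates in the scored pool that top-K truncation left out,
  and counts are micro-averaged over queries. Note that each mode's
  relevant set is its own scored pool: expansion enlarges the PPHR pool
  and hence its recall denominator. With few physicians and a large K the
  lists saturate and this definition can favour the retrieval-only
  ablation — on desk-scale synthetic corpora the F1 comparison between
  modes should be read with that in mind; the hqos comparison is not
  affected.
* **hqos_prop**: the fraction of recommended slots whose physician's
  winsorized mean response time beats the corpus-level mean of winsorized
  per-request times (a corpus-level figure, not a mean of per-physician
  means; physicians with no responses count as not-fast).
* **K sweep** over K = 2..20 in steps of 2: per mode, every query is
  scored once at the largest K and smaller K are truncations of that
  ranking, so curves share one retrieval pool and differences across K
  are not resampling noise.
* **Aggregates**: mean with sample (n−1) SD at full precision, rounded
  only at presentation; `compare_ratings()` wraps the Mann-Whitney
  rank-sum test for Likert rating vectors.

Harmonic-mean rounding: an F1 printed from unrounded precision/recall can
differ in the last digit from the harmonic mean of the *printed*
precision/recall (e.g. 0.7126 and 0.8202 give 0.76262, which prints as
76.26 rather than 76.25); report footers should state which convention a
table uses.

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7), documented above.
* Ties: similarity search by ascending id; TF-IDF keywords by ascending
  term; final ranking by descending `physician_score` then ascending
  code. All deterministic.
* TF-IDF: relative-frequency TF with smoothed IDF
  $\ln((1+N)/(1+df)) + 1$ by default (keeps single-document corpora
  usable); the plain $\ln(N/df)$ variant is a switch.
* Questions emptied by stop-wording fall back to their normalized text as
  one token, so every record stays embeddable; physicians whose entire
  corpus is stop-worded get no profile and can never be expansion
  targets (warned).
* Unanswered requests carry no response time (enforced at ingest);
  physicians with no answers have rate 0 and an absent mean time.
* Engine snapshots are plain text; on load, response rates and mean
  times are recomputed from the stored exact counts so a decimal
  round-trip cannot perturb ranking scores.

## Problem sizes used in the checks

The test suite and the acceptance script size their corpora so every run
fits comfortably on one CPU: module tests use 100–400-question corpora;
the response-rate recovery property uses 10,000 questions and 25
physicians (±0.05 around the true rates for physicians with ≥200
questions); the service-quality dominance property uses 20 seeded
1200-question corpora with 30 queries each — large enough that
per-physician mean times concentrate and the fast/slow classification
reflects the rate-time coupling rather than sampling noise; the
acceptance script runs a 2200-question corpus with 200 held-out labeled
queries through the full K sweep in all three modes.

## Known limitations

* The default hash n-gram encoder measures lexical overlap; synonymous
  questions with disjoint wording will not retrieve each other. Plug in a
  sentence encoder via `transformer_backend()` for semantic matching.
* Expansion quality is bounded by profile quality: physicians with few
  questions get noisy TF-IDF profiles.
* The scoring rule in Step 3 is one member of a family (see above);
  cross-study comparisons must name the variant.
* Response-rate weighting assumes the rate is a stable property of the
  physician; it is not re-estimated online, and a platform with strong
  seasonal activity patterns would need windowed stats.
* No per-patient personalisation: two patients typing the same question
  get the same list.
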