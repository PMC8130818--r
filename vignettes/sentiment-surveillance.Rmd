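---
title: "Hybrid rule-based ensemble sentiment surveillance: models and methods"
author: "sentitrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid rule-based ensemble sentiment surveillance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sentitrace)
```

## The surveillance problem

Public-health teams increasingly monitor social media to gauge public
sentiment toward interventions — the motivating case is attitudes toward
COVID-19 contact tracing apps in the UK during March–October 2020, where
uptake depended on public trust and the privacy debate around centralized
versus decentralized exposure matching. The raw material is a stream of
short posts from two platforms; the analytical product is a set of
aggregates: the overall positive/neutral/negative mix, a weekly sentiment
trend combined across platforms, county-level sentiment maps from geo-tagged
posts, and sentiment-stratified term tables for qualitative reading.

`sentitrace` implements that pipeline end to end: strict corpus IO, a
two-step thematic keyword filter, a hybrid rule-based ensemble classifier,
validation and weight tuning, and the temporal/spatial aggregations — plus a
synthetic corpus generator with known ground truth so that every stage is
testable without any platform data.

## Corpus construction

Posts enter as delimited or JSON-lines records (`read_posts()`). Validation
is total: every row is either accepted or produces a diagnostic with its row
number; duplicate ids, empty texts, and timestamps without an explicit time
zone are hard errors. Zone-less timestamps are rejected rather than assumed
because weekly binning on the UTC calendar must be unambiguous.

Thematic filtering is the two-step scheme typical of pandemic social-media
studies: a first pass with pandemic-level keywords (configurable, since
upstream data sources apply their own predefined lists) and a second pass
with eleven contact-tracing-app phrases shipped as `app_keyword_spec()`.
Matching defaults to *token-phrase* semantics — a phrase matches a
contiguous run of whole tokens after lowercasing and punctuation stripping,
so `"tracking"` matches `"tracking!"` but not `"backtracking"`. Substring
matching is available by flag, but it inflates false positives on short
keywords, which is why it is not the default. The corpus window
(`corpus_window()`) is inclusive on both UTC calendar dates; language
filtering uses a declared per-post language field (language identification
is out of scope — posts without one are flagged through with a warning);
posts without geographic metadata are retained by the window filter and
excluded only from spatial aggregation.

## The scoring channels

Two continuous polarity channels score each post on $[-1, 1]$.

**Channel A** (`score_text()`) is a valence rule scorer in the established
normalized-lexicon convention. Each lexicon hit contributes its dictionary
valence $v \in [-4, 4]$; a booster immediately before a hit adds its
increment toward the hit's sign; a negator within the preceding three tokens
multiplies the (boosted) valence by $-0.74$ — a sign flip with dampening,
reflecting that "not good" is bad but less bad than "bad". The raw sum $s$
is normalized to

$$\mathrm{score}(s) = \frac{s}{\sqrt{s^2 + \alpha}}, \qquad \alpha = 15,$$

which maps any sum into $(-1, 1)$, is exactly 0 for texts with no lexicon
hits, and saturates as evidence accumulates. The constants ($\alpha = 15$,
window 3, factor $-0.74$) are the conventional values from the valence-
lexicon literature; capitalization and exclamation emphasis exist behind a
flag, default off, to keep the default scorer minimal and auditable.

**Channel B** (`score_text_mean()`) is a mean-polarity scorer: each hit
contributes $v/4$, a negator immediately before a hit multiplies it by
$-0.5$, and the score is the mean over hits. Channel B reacts to *average*
tone where channel A reacts to *accumulated* tone; the two disagree exactly
where an ensemble is useful.

Posts are scored whole, without sentence splitting, because posts are short
and the pipeline assigns one label per post. Preprocessing strips URLs and
user mentions and detaches hashtag markers; all of this is configurable at
the tokenizer.

Both channels are registered in a scorer registry (`register_scorer()`)
behind a common contract — vectorized text in, scores in $[-1,1]$ (or one
of the three labels) out — verified on a probe battery at registration.
Any external scorer satisfying the contract can be plugged in; the package
never downloads one.

## The hybrid ensemble

The ensemble (`sentiment_ensemble()`) combines the channels in three steps:

1. **Weighted average**: $s = w_A s_A + w_B s_B$ with $w_A + w_B = 1$.
   Defaults $w_A = 0.48$, $w_B = 0.52$ give the mean-polarity channel the
   slightly higher weight, following the original tuning's finding that it
   was marginally more accurate on positive sentiment.
2. **Thresholding**: positive iff $s \ge 0.05$, negative iff $s \le -0.05$,
   neutral otherwise. The $\pm 0.05$ band is the established convention for
   normalized valence scores; boundaries belong to the non-neutral classes
   so that the neutral band is open.
3. **Rule-based fusion** with a contextual classifier channel. Under the
   default rule, the lexicon ensemble governs positive sentiment and the
   contextual channel governs the rest:

   | lexicon label | contextual label | final |
   |---|---|---|
   | positive | any | positive |
   | neutral  | $c$ | $c$ |
   | negative | $c$ | $c$ |

   The underlying if-else description is ambiguous about *which* channel's
   "positive" triggers the positive branch. We resolve it as above (the
   lexicon label decides), and ship the alternative reading — branch on the
   contextual label — as `fusion = "contextual_branch"`, so the choice is a
   config switch rather than a silent assumption. Note the consequence of
   the default: cell (negative, positive) fuses to *positive*, because the
   contextual channel is trusted whenever the lexicon is not positive.

The contextual channel in this package is a deterministic keyword-table
classifier (`keyword_context_classifier()`): majority sign of valence
tokens with negation flips, neutral on ties. It is a transparent stand-in
occupying the slot a pretrained transformer would fill in production; the
package's contribution is the fusion and validation machinery, which is
agnostic to what fills the slot.

## Tuning and validation

`tune_weights()` grid-searches $w_A$ (default grid $0.40, 0.42, \dots,
0.60$) on a labelled corpus, evaluating the *full* classifier at each
point. The objective is macro-averaged recall over the three classes —
balanced, so the dominant positive class cannot mask collapse on the rare
classes; the original study reports only "manual validation", so the
objective is our documented choice. Ties break toward $w_A = 0.5$, then
toward the smaller $w_A$, making selection reproducible. Validation
(`validate_scored()`) reports the $3 \times 3$ confusion matrix in fixed
class order (positive, neutral, negative; gold in rows) with one-vs-rest
sensitivity $TP/(TP+FN)$ and specificity $TN/(TN+FP)$ per class.

## Aggregation

- **Weekly series** (`weekly_series()`): ISO-8601 weeks on UTC dates, one
  point per ISO week intersecting the corpus span, empty weeks emitted with
  $n = 0$ and an `NA` mean rather than dropped. "Weighted" cross-platform
  combination defaults to post-count weighting, which is identical to
  pooling all of the week's posts — the natural reading when platforms are
  combined because each alone is small; equal platform weighting is a flag.
  Note the span March 1 – October 31 2020 (245 days, i.e. 35 rolling weeks)
  intersects **36** ISO weeks, 2020-W09 through 2020-W44, with the first
  and last partial; with ISO binning the series therefore has 36 bins.
- **Region summaries** (`region_summaries()`): each geo-resolvable post is
  assigned to exactly one region — its region code if present, else
  point-in-polygon (ray casting) against GeoJSON boundaries. Posts with no
  geographic metadata or coordinates outside every polygon are excluded and
  counted as unresolvable, mirroring analyses that map only geo-tagged
  posts. Regions in the lookup with no posts appear with $n=0$, never with
  fabricated scores. Rankings require $n \ge 5$ by default so single-post
  counties cannot dominate top-k lists; the threshold is a parameter.
- **Term tables** (`term_frequencies()`): word-cloud input, stratified by
  sentiment and optionally by time window, with stopwords and the thematic
  filter keywords themselves excluded (the terms that *defined* the corpus
  carry no information within it). Ranking is count-descending with
  lexicographic tie-breaks, so output is stable.

## The synthetic corpus generator

`generator_spec()` defaults encode the emulated study conditions: 10,000
posts split 8000/2000 across the two platform roles, class proportions
76/12/12 (positive/neutral/negative), the March 1 – October 31 2020 span,
and UK county region labels (60% of posts geo-tagged, a deliberate mix of
geo-resolvable and not). Texts are composed from class-conditional pools:
positive and negative posts draw `separability × terms_per_post` words from
the fixture lexicon's signed terms, the rest from a curated neutral pool;
neutral posts draw noise words only. One pandemic keyword and one app
keyword are planted per post (rate configurable) so generated corpora
survive the two-step filter. All pools are mutually disjoint and disjoint
from the filter keywords, so keyword presence never leaks class
information. A single seeded generator drives every draw; identical spec
and seed reproduce the corpus exactly.

What the generator deliberately does **not** emulate: real linguistic
structure (syntax, sarcasm, deceptive language), bot/duplicate traffic,
platform-specific formats, or label noise in the gold standard. Passing
recovery tests on generated corpora therefore demonstrates that the
*pipeline machinery* is correct — filters select exactly the planted
subset, aggregation is conservative, classification recovers a separable
signal — not that any fixed lexicon achieves a particular accuracy on real
social-media language.

## Numerical and testing choices

- Scores serialize at full double precision (`%.17g`), so write/read is the
  identity; polarity bounds are checked on both write and read.
- The normalization limit (score $\to 1$ as the raw sum grows) is checked
  at $s = 10^6$ within $10^{-6}$.
- Test problem sizes are chosen to keep the suite fast while leaving
  sampling error far below the asserted tolerances: proportion recovery
  uses $n = 10{,}000$ (±3 percentage points asserted, binomial standard
  error ≈ 0.4 points), the step-change recovery uses 20 seeds × 2,000
  posts with a 0.76 → 0.40 step in the positive share (two-proportion test
  at $\alpha = 0.01$), and oracle equalities (pooled means, count
  conservation) are exact to $10^{-12}$.
- The end-to-end recovery tests run at `separability = 0.9`; at
  separability 0 the class signal vanishes by construction and recovery
  collapses to the neutral class, which the suite also asserts.

## A worked sketch

```{r, eval = FALSE}
spec <- generator_spec(n_posts = 2000, seed = 42)
corpus <- generate_corpus(spec)
analysed <- apply_window(two_step_filter(corpus),
                         corpus_window("2020-03-01", "2020-10-31"))
ens <- sentiment_ensemble()          # 0.48/0.52, thresholds +/- 0.05
scored <- predict(ens, analysed)
overall_proportions(scored)
plot(weekly_series(scored))
head(region_rankings(region_summaries(scored, uk_counties()),
                     direction = "most_negative"))
```

## Known limitations

The packaged lexicon is a compact fixture sufficient for testing and for
separable synthetic corpora; production surveillance should load a
full-size valence lexicon via `read_lexicon()` and register production
scoring channels. The contextual stand-in shares the lexicon's vocabulary,
so on synthetic corpora the channels are correlated in a way a transformer
channel would not be. Point-in-polygon assignment uses planar ray casting,
adequate at county scale but not on polygons crossing the antimeridian.
Event attribution for trend changes is out of scope: the weekly series
reports *when* sentiment shifted, not *why*.
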