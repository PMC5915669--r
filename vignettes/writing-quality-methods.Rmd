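---
title: "Measuring writing quality in online health communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring writing quality in online health communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohcread)
```

## The problem

Members of online health communities — including communities centred on
depression, bipolar disorder and schizophrenia — communicate almost
entirely in writing. Language impairment associated with these
conditions may surface as posts that are harder to read and use a less
diverse vocabulary, and sustained participation may change both.
`ohcread` implements a reproducible pipeline for asking two questions
of any post corpus: do communities differ in writing quality, and does
an individual member's writing change over their posting history?

The pipeline works on JSON Lines corpora of posts (community label,
member id, timestamp, submission/comment kind, body text) and never
requires the original social-media data: a synthetic corpus generator
with known ground truth makes every stage testable.

## Inclusion rules

Three filters define the analyzable corpus, applied in a fixed order:

1. posts whose trimmed body equals a platform deletion marker are
   dropped. `"[deleted]"` and `"[removed]"` are both matched by
   default; both are markers a platform substitutes for an author- or
   moderator-removed body, and a body that merely *contains* the marker
   is kept.
2. posts with fewer than five words are dropped ("yes", "sure" —
   automatic rather than effortful writing). The word count uses the
   same tokenizer as the metrics, so "word" has exactly one definition
   in the package.
3. only *regular members* are kept: members with at least four
   surviving posts in a community. Membership is evaluated per
   community; a member active in two communities is assessed
   independently in each.

Because the short-post filter precedes the membership count, a member
with four posts of which one is short is excluded. The filter order is
part of the contract and is pinned by tests.

## Per-post scores

Four readability grade formulas are computed from scratch on each post
— Flesch-Kincaid grade, SMOG index, Gunning Fog index and Linsear Write
— together with their arithmetic mean (`mean4`) and lexical diversity
(type-token ratio on lowercased tokens). Tokenization, sentence
segmentation and syllable counting are deliberately simple,
deterministic rules:

* sentences split on runs of `.!?` or blank lines, with a whole-text
  fallback so every document has at least one sentence;
* words split on whitespace with edge punctuation stripped;
  punctuation-only tokens vanish;
* syllables are counted as vowel runs (`a e i o u y`), minus a terminal
  silent "e" (unless the word ends in consonant + "le"), plus one per
  digit group, clamped to at least one.

Design choices worth knowing:

* **Complex words** (Gunning Fog) are simply words of three or more
  syllables, with no proper-noun or suffix exclusions: the classical
  exclusions are under-specified and common implementations disagree,
  so the package uses the reproducible core definition.
* **Linsear Write** samples the first 100 words; posts shorter than
  that (the vast majority of online-community posts) use the whole
  text. For longer posts the span's sentence count is the number of
  sentences needed to cover 100 words.
* **Digits** count one syllable per digit group, so numbers are words
  rather than errors.
* Lexical diversity is computed per post and then averaged per member,
  mirroring the readability path; pooling a member's posts before the
  type-token ratio would conflate post length with diversity.

A known property of this family of metrics is that the Gunning Fog
index runs far above the other three on informal text (its complex-word
term is scaled by 100); the four grades remain strongly positively
correlated, which is what the composite mean relies on, and the package
tests that correlation on synthetic corpora rather than assuming it.

## Aggregation: one member, one vote

Community summaries use a two-step mean: post scores are averaged
within member, then member means are averaged across the community, so
a member with 400 posts counts exactly as much as a member with 4.
Standard errors use the sample (n−1) standard deviation over the
square root of the member count.

The composite readability score is min-max normalized **within
community** over member means: the community's lowest-scoring member
maps to 0 and the highest to 1. This follows the procedural definition
of the original analysis, but note the caveat: normalized scores from
different communities live on different scales, so cross-community
differences of normalized scores mix scales. The package therefore
also reports the raw `mean4` composite, and offers a per-metric
normalization variant (`add_normalized_scores(variant =
"per_metric")`) for sensitivity analysis. A degenerate community in
which every member has the same mean maps everyone to 0.5 with a
warning.

## Inference

Pairwise community contrasts use independent two-sample t-tests on
member-level values. Welch's unequal-variance test is the default —
community variances differ visibly in practice — with pooled variance
behind `var_equal = TRUE`. The family of all pairs within one score is
adjusted with the Hommel closed-testing procedure (via
`stats::p.adjust`), which controls the family-wise error rate and is
uniformly more powerful than Bonferroni-Holm; the package's tests
verify it against an exhaustive Simes-per-subset closed-testing oracle
and verify family-wise error control by simulation. Effect sizes are
Cohen's d with pooled n−1 weights, reported as magnitudes (direction
lives in the t statistic and the 95% CI) and labelled with the
conventional bands 0.01/0.2/0.5/0.8/1.2/2.0 (very small … huge); a d
between two thresholds gets both names, e.g. `0.97` is
"large-very large".

## Longitudinal trends

For each member, every score is regressed by ordinary least squares on
the *interaction sequence* — the rank 1…n of the post in the member's
posting order, ties in timestamps broken by post id — rather than on
calendar time, because the question is what each act of participation
does, not what a month does. Each member contributes one slope per
score regardless of post count, and community trend summaries are the
unweighted mean (SE) of member slopes. Sign convention: readability
improving means a negative grade slope; diversity improving means a
positive slope.

A normalized-composite slope (`norm_mean4`, post-level min-max within
community before fitting) is included for completeness, but its scale
depends on each community's own score range and is not comparable
across communities or to unnormalized slopes.

## The synthetic corpus generator

`generate_corpus()` produces corpora whose ground truth is known
exactly, so recovery tests exercise the whole chain from raw text to
inference rather than any single stage:

* **Vocabulary**: pseudo-words concatenated from consonant-vowel-
  consonant units, so the syllabifier recovers the constructed count
  exactly (verified at build time). A fraction `p_poly` of the
  vocabulary is polysyllabic (3-4 units), the rest easy (1-2 units).
  Syllable counts alternate along the frequency-rank order and class
  sizes are deterministic, so the Zipf-weighted mean syllables per word
  is identical across realizations; without this, which words happened
  to land on the top Zipf ranks dominated between-replicate variance
  of the community mean grade.
* **Members** get baseline parameters jittered around the community's
  (`member_sd_poly`, `member_sd_sentlen`), creating real
  between-member variance; posts get words drawn with probability
  `p_poly` from the polysyllabic class and Zipf-weighted ranks within
  class (`zipf_exponent` is the diversity knob).
* **Trends** are injected on the generative parameters (`trend_poly`,
  `trend_sentlen` — per-interaction drifts on the member's
  polysyllable probability and sentence length), never on scores
  directly, so slope recovery validates metric computation and
  regression together. The two knobs are separate because their units
  differ (probability vs words per sentence).
* **Contamination**: posts are replaced by a `"[deleted]"` marker or a
  1-3 word stub at configurable rates, exercising the filters.
* **Determinism**: one seed, threaded through a single RNG stream,
  yields byte-identical corpora and manifests; the caller's RNG state
  is restored afterwards.

Default conditions emulate short informal health-community posts:
4-8 posts per regular member, 20-60 words per post, ~10 words per
sentence, 15% polysyllabic draws and a Zipf exponent of 0.8, giving
community mean composite grades around 8-9 and type-token ratios
around 0.85-0.90 — the ranges seen in real online health communities.
What the generator does **not** emulate: real English morphology,
markdown/URLs, reply threading, topic structure, or members whose
style changes non-linearly. Passing recovery tests therefore show the
pipeline is correct and well-calibrated, not that any particular real
community behaves like the generator.

## Calibration of experimental conditions

Recovery experiments are specified in grade units (a Cohen's d of 0.5
between communities; a slope of −0.05 grades per interaction), while
the generator's knob is a probability. `calibrate_grade_shift()` and
`calibrate_trend()` convert between the two by Monte Carlo probing:
central differences of the simulated mean grade around `p_poly`
estimate the local derivative d(mean grade)/d(p_poly) (≈ 24-25 grades
per unit probability under default conditions) and, for d targets, the
between-member SD of the mean grade (≈ 1.1 grades). Because the grade
response is mildly nonlinear in `p_poly` (the SMOG square root), the
calibration runs in two stages: a provisional answer from a first
probe at the reference point, then re-estimation centred at the
midpoint of the contrast or trend trajectory. For the same reason the
vocabulary's polysyllabic fraction (`vocab_p_poly`) is a separate,
fixed parameter: shifting or trending the draw probability must not
also recompose the lexicon, or probe derivatives would measure a
different quantity than the trajectory traverses. Probe simulations
are seeded and run at execution time.

## Numerical and degenerate-input choices

* Empty documents and documents with no countable words are errors at
  scoring time; the filters remove them first in the pipeline.
* Punctuation-only "sentences" collapse into their neighbours; a
  punctuation-only text is a single sentence with zero words (scoring
  error, filtered upstream).
* Zero-variance t-tests (both groups constant) are flagged
  `degenerate` with `NA` statistics rather than raising.
* Tied timestamps order by post id, making trend fits reproducible.
* p-values below 0.001 are *displayed* as `<.001` in reports; stored
  values keep full precision.

## Problem sizes used in the validation suite

The shipped tests run the recovery experiments at 200 members per
community (500 replicates for the effect-size experiment, 200
replicates of 20-post members for the trend experiment) and the null
family-wise error simulation at 2000 replicates of six 100-member
communities on member-level scores. These sizes give Monte Carlo error
comfortably below the margins being asserted while keeping a full test
run in the minutes range on one core.

## Known limitations

* The syllabifier is a heuristic; on real English it disagrees with
  dictionary syllabification for a few percent of words ("science",
  "every"). Within the package this is harmless — every consumer uses
  the same rules, and the synthetic vocabulary is built to satisfy
  them exactly — but absolute grade levels on real text will differ
  slightly from dictionary-based implementations.
* Min-max normalization within community makes normalized scores
  scale-dependent (see above); prefer `mean4` for cross-community
  effect sizes.
* Slopes assume a linear change over the interaction sequence;
  segmented or saturating change is out of scope.
* Member-level t-tests treat members as independent; cross-posting
  members appear once per community.
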