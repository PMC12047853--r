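---
title: "Methods: mining antibiotic-ineffectiveness discussions from social media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining antibiotic-ineffectiveness discussions from social media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abxtalk)
```

`abxtalk` packages the quantitative pipeline of an infodemiology study of
patient-reported antibiotic ineffectiveness on French-language social
media: retrieval filtering, author demographics, short-text topic
discovery, quality-of-life (QoL) impact classification, and summary-table
aggregation. This vignette documents the models, their assumptions, the
parameters that matter, and the numerical and design choices made where
the problem was genuinely open.

## Corpus inclusion and the exclusion cascade

A message belongs to the study corpus iff it satisfies a *conjunction*:
at least one antibiotic keyword or synonym **and** at least one phrase of
the inefficiency lexical field, both within the same message. The
inefficiency field combines fixed phrases (*inefficace*, *sans effet*,
*aucun effet*, ...) with a negation family — *ne* ... *pas* around an
efficacy verb (*marcher*, *fonctionner*, *agir*, *soulager*, ...) with at
most 5 intervening tokens. The gap limit trades recall (long
insertions: "ne me soulage vraiment pas du tout") against precision
(unrelated *ne*/*pas* pairs spanning clause boundaries); 5 tokens covers
the pronoun-plus-adverb insertions that actually occur in forum French.

All matching is case- and accent-insensitive on token boundaries
(`fold_text()` lowercases and folds diacritics), because forum spelling
of French accents is unreliable; token anchoring prevents substring
artefacts ("antidouleur" never matches "douleur").

Retained messages then pass a removal cascade in a **fixed order**:
non-target language, then animal-related vocabulary, then study-specific
exclusion words. The order is a design choice — the underlying study
design lists the rules without one — and exists purely to make removal
attribution deterministic: each removed post is charged to the *first*
rule that fires, so the filter report always balances
(input = output + sum of removals) and is auditable.

Language detection is a stopword-profile score (French, English, Spanish
function-word lists; argmax of hit counts, ties to the target language).
Texts shorter than 4 tokens, or with no profile hit at all, are tagged
`undetermined` and **kept**: a removal rule should only act on positive
evidence. The study-specific exclusion-word list of the original design
is not public, so the package ships a small configurable placeholder
(`default_lexicons()$exclusion_words`); replicating the original
filtering requires substituting the study list via `read_lexicons()`.

`anonymize_posts()` replaces author handles by a salted one-way hash and
masks `@`-mentions and URLs; it is idempotent so re-running a pipeline
never double-mangles stored text.

## Author demographics

**Gender** is a transparent additive evidence model, not a classifier: a
first name in the username scores 3 for its gender, a gendered username
affix 1, and each gendered lexical-field phrase or adjective/participle
agreement (*allée* vs *allé*, *inquiète* vs *inquiet*) in the user's
messages 1 per occurrence. Weights are a design choice (the evidence
kinds are given, their combination is not): a first name is near-decisive
in practice, content markers accumulate. Scores are sums, hence
permutation-invariant over posts and monotone as posts are added. The
prediction compares the two scores; ties — including the all-zero case —
yield `unknown`, which is excluded from gender-share denominators (the
package always prints the denominator it used).

**Age** is two-stage. Regular expressions scan all of a user's posts for
"j'ai N ans", bare "N ans" (rejected when one of the three preceding
tokens is a duration guard: *depuis*, *pendant*, *pris*, ...), and
"né(e) en YYYY" converted with the post's year; values outside 10–100
are rejected; multiple matches resolve by majority, then by the most
recent post. Only users with **no** regex match fall through to a
gradient-boosted regression on stylometric features (post count, mean
length, exclamation/emoticon/question rates, sentiment-lexicon rates,
first-person rate, dominant source one-hot). The model's probabilistic
nature is surfaced as a central 80% prediction interval from companion
quantile models (`reg:quantileerror`, α = 0.1/0.9). An untrained model is
a hard error, never a silent default.

## The biterm topic model

Forum messages are short, so per-document topic mixtures are poorly
identified. The biterm topic model instead pools the whole corpus: every
unordered pair of token positions within a message (the *biterm*; the
whole short message is the co-occurrence window, a message of n tokens
yields n(n−1)/2 biterms, repeated tokens yield self-pairs) is drawn from
one of K corpus-wide topics, each topic a distribution over tokens.

Fitting is collapsed Gibbs sampling over biterm assignments with the
conditional

$$P(z_b = k \mid \mathbf{z}_{-b}) \propto (n_k + \alpha)\,
\frac{(n_{w_1|k} + \beta)(n_{w_2|k} + \beta)}
     {(2n_k + V\beta)(2n_k + 1 + V\beta)},$$

counts excluding biterm *b* (the second numerator factor gains +1 when
w₁ = w₂). Parameter estimates are posterior means over post-burn-in
samples: φ_{w|k} = (n̄_{wk} + β)/(2n̄_k + Vβ), θ_k = (n̄_k + α)/(B + Kα);
both normalize exactly because the averaged counts inherit the balance
Σ_w n_{wk} = 2n_k. An empty topic degenerates to the uniform smoothing
column 1/V, and β → ∞ drives all topics uniform — both covered by tests.

Defaults: α = 50/K, β = 0.01 (the conventional choices for this model
family), 1000 sweeps, burn-in 500, thinning 10. The default K = 13
matches the number of main themes this analysis design reports;
since no selection rule is documented, `btm_sweep_k()` provides a UMass
coherence sweep rather than a guess. Identical seeds give identical
states (the sampler uses R's RNG).

**Correctness oracle.** `btm_enumerate_posterior()` enumerates all K^B
assignment configurations of a tiny corpus and computes the collapsed
posterior in closed form (ratios of Gamma functions). The test suite and
the acceptance script require the empirical Gibbs assignment frequencies
(50 000 post-burn-in sweeps) to match these exact marginals within 0.02
— an end-to-end check of the sampler, not of any shared code path.

**Document assignment** is single-topic (each message gets exactly one
theme): P(k|d) averages P(k|b) ∝ θ_k φ_{w₁|k} φ_{w₂|k} over the
document's biterms, ties break to the lowest topic index,
single-token documents use P(k|w) ∝ θ_k φ_{w|k}, and empty documents are
reported as unassigned and excluded from topic-share denominators.

**Characteristic tokens.** Topics are named manually from their top 15
tokens after cross-topic reweighting: weight(t,k) = φ_{t|k} / Σ_{k'≠k}
φ_{t|k'}. A token spread evenly over all topics scores 1/(K−1) and never
looks characteristic; K = 1 falls back to raw φ. "Inverse of the
probability in other topics" is read as the inverse of the **sum** over
other topics; the inverse-product and inverse-max readings order the
extreme cases identically but were not adopted, and a tf-idf-style
reweighting is a plausible alternative reading of the same description.
Ties break by raw φ, then token id.

**Preprocessing** lowercases, folds accents, splits on non-letters,
drops tokens under 3 characters and stopwords, and indexes the
vocabulary by first occurrence (deterministic ids). The default stopword
list adds the retrieval lexicons to the French function-word list:
keyword-retrieved corpora contain their query terms in essentially every
document, where they would otherwise surface as one shared
high-probability token in every topic.

## Two-stage QoL impact classification

The architecture is one binary *gate* (any impact?) plus five
one-vs-rest domain models (physical, psychic, activity, relational,
financial), all gradient-boosted trees (depth 4, 200 rounds, η = 0.3,
fixed seed) over a shared feature vector: sentiment-lexicon hits,
first-person and negation counts, verb-tense markers, punctuation,
length, and one hit count per QoL-domain lexical field. Count features
are exactly additive over text concatenation. Domain models are trained
on impact-positive examples only and evaluated only when the gate fires
(probability ≥ 0.5, configurable): a gate-negative message can never
carry a category, which the tests assert as an invariant. Domain models
use `scale_pos_weight` class balancing — the financial domain occurs in
~1% of impact-bearing messages, and without reweighting its predicted
probabilities stall below any reasonable threshold. A single-class
training target is a hard error naming the model.

The original study's annotated training corpus is unavailable; the
**architecture** is the reproduced object, and the bundle ships trained
on synthetic labeled posts. Summaries report *both* percentage
conventions in use for such tables — share of impact-bearing messages,
and share of all domain mentions — each with its denominator, because
the two look confusingly similar (78% vs 39% for the same count) and
published tables mix them.

## The synthetic corpus generator

`generation_config()` defaults encode the study conditions: 86.22%
female authors, ages from a normal(35, 10) truncated to 10–100 by
rejection (analytic truncated mean 35.18), 1 + Poisson(0.62) posts per
user (mean 1.62), activity from January 2014 to July 2020 with
November–March monthly volume elevated by a factor 2, 13 planted topics
over a 260-token pseudo-vocabulary, 63% impact-bearing messages with
per-domain probabilities 0.78/0.65/0.31/0.25/0.01, and distractor rates
of 5/4/4/3% for the four filter-violation kinds. Where the study design
states no value (seasonal amplitude, age SD, marker injection rates,
distractor rates, source weights), values were chosen once as realistic
for this kind of cohort and are documented here, not tuned.

Impact-category sets are drawn by rejection conditioned on non-emptiness
using fixed-point-adjusted Bernoulli parameters, so the per-domain
marginals among impact-bearing messages equal the configured values
*exactly* (naive conditioning would inflate them by ≈4%). Gender markers
are injected into 80% of posts and explicit age statements into 50%, so
both the regex path and the model-fallback path of the demographics
module are exercised; writing style varies with age (younger authors:
more exclamations and emoticons, shorter messages), which is the
learnable signal for the age model. Topic content is sampled from
planted distributions that put 97% of their mass on disjoint
100-token blocks (Dirichlet weights within the block), making recovery
quantifiable by best-permutation alignment.

The generated "French" is a controlled pseudo-lexicon
(consonant-vowel-syllable tokens) embedded in real French marker
phrases. It exercises every rule path — folding, boundaries, negation
windows, agreements — but it is **not** natural language: vocabulary
collisions, sarcasm, misspellings, code-switching and topic drift are
absent. Passing recovery tests therefore validates the machinery and its
contracts, not field performance on real forums; real-corpus lexicons
would also need the original study's exclusion-word list. Topic-recovery
evaluations add the generator's non-topical scaffold tokens
(`generator_scaffold_tokens()`: templates, markers, fillers) to the
stopword list, since by construction these carry author attributes or
filter fate, never the latent theme.

## Numerical choices and degenerate inputs

* Percentages: half-up rounding everywhere (matching every printed value
  this table style uses), with an epsilon absorbing binary float error
  at .5 boundaries; 2 decimals for source/topic/cohort shares, integer
  percent for QoL shares. `audit_percentages()` recomputes every emitted
  percentage from its own printed count and denominator.
* Probability vectors must normalize within 1e-10 (φ, θ) and 1e-12
  (planted topics); the Gibbs-vs-enumeration tolerance is 0.02 at
  50 000 samples.
* Degenerate inputs have defined behaviour rather than crashes: empty
  filter input gives a zeroed report; K > B warns and runs; empty topics
  give uniform φ columns; empty documents are unassigned; documents with
  fewer than 2 tokens contribute no biterm and are flagged; an untrained
  model (age or impact) is a hard error.
* Test problem sizes: marginal checks at 10⁴ users, topic recovery at
  K = 3, V = 300, ≈2000 documents, classifier recovery at ≈4000 posts —
  large enough for the stated tolerances to be meaningful under CLT/
  binomial bands, small enough to run in about a minute each.

## Known limitations

The gender procedure is binary by design of the reproduced method; the
language detector is a coarse profile scorer, not a fielded identifier;
the inefficiency negation window is a heuristic with a fixed gap; the
impact models trained on synthetic posts transfer nothing to real text
(the architecture, features and contracts are the artifact); and
cross-platform deduplication, HTML handling and live collection are out
of scope.
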