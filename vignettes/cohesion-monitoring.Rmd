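---
title: "Monitoring group cohesion in text-based support groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring group cohesion in text-based support groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osgcohesion)
```

## The problem

In a synchronous, text-only online support group (OSG) a therapist
facilitates 6–10 participants over a 90-minute session. Group cohesion —
statements expressing warmth, mutual support, gratitude, belonging, shared
experience — is one of the clearest markers of a session that is working,
and its absence or breakdown is something a facilitator wants to see
*during* the session, not in a post-hoc transcript analysis. `osgcohesion`
scores each chat message for cohesion, adjusts the score with linguistic
rules, and aggregates it into an interval-level session signal.

The pipeline has six stages: synthetic-corpus simulation (when no real
transcripts are available), lexicon expansion, ensemble classification,
rule-based adjustment, interval aggregation, and evaluation with an
active-learning loop. `run_pipeline()` wires them together.

## The classifier

Messages are featurised with TF-IDF over unigrams and bigrams. The
vocabulary is capped at the `max_features = 5000` most frequent n-grams
(ties broken lexicographically); inverse document frequencies use the
smoothed form `log((1 + N)/(1 + df)) + 1` and document vectors are
L2-normalised. When a cohesion lexicon is available, one engineered
column is appended: `log(1 + k)` where `k` counts lexicon phrase matches
in the message. This is an interpretation choice — the expanded lexicon
could instead have served purely as an annotation aid — and it is
deliberately a single column so that it informs, but cannot dominate, the
n-gram evidence.

Five classifiers are trained on these features: multinomial naive Bayes
(Laplace smoothing, α = 1), a random forest (300 trees), a linear-kernel
SVM, ridge logistic regression (λ = 1/n, the analogue of an
L2-regularised default), and a multilayer perceptron with one hidden
layer of 100 tanh units. The MLP is trained full-batch with Adam
(learning rate 0.01, weight decay 1e-4, at most 500 iterations with a
relative loss tolerance of 1e-6); a quasi-Newton trainer would keep a
workspace quadratic in the weight count, which is impractical at
thousands of TF-IDF inputs, while full-batch Adam is deterministic under
a fixed seed. Multinomial naive Bayes is likewise implemented in the
package because the commonly available naive Bayes uses a Gaussian
likelihood, which is mismatched to sparse non-negative text features.

Each classifier's positive-class F1 (positive class = cohesion
throughout) is measured on a stratified 20% held-out split, and the top
three form the voting committee; ties are broken by alphabetical
classifier name so that refits are reproducible. A post's outcome is the
label agreed by **at least 2 of the 3** committee members, each member
voting by thresholding its positive probability at 0.5. The committee's
mean probability is kept as the *raw score* — the soft quantity the rule
layer adjusts — and the decision's confidence is the F1-weighted share of
members agreeing with the outcome, so confidence is 1 exactly when the
vote is unanimous and at least `min(w_i + w_j)/(w_1 + w_2 + w_3)` for a
2-of-3 split.

## The word embedding

`train_embeddings()` builds the symmetric co-occurrence matrix over a
10-token window for all terms with frequency ≥ 2, transforms it to
positive pointwise mutual information, and takes the top-`dimension`
(default 100) SVD factors, scaling by the square root of the singular
values. This count-based factorisation is the deterministic counterpart
of window-based neural embeddings (which implicitly factorise shifted
PMI): it satisfies the same contracts — co-occurring terms get high
cosine similarity, rare terms are filtered, every vector has the
configured length — while making lexicon expansion exactly reproducible,
with no dependence on thread scheduling or stochastic gradient order.
Singular-vector signs are pinned (largest-magnitude loading positive) so
repeated runs agree bit-for-bit. When the corpus supports fewer than
`dimension` factors the remaining columns are zero.

Seed expressions are grouped by the eight cohesion themes; multiword
seeds are embedded as the mean of their in-vocabulary token vectors. Each
seed contributes up to `top_k = 10` neighbours with cosine similarity
≥ `min_similarity = 0.5`; both cutoffs are exposed because no principled
value exists — the defaults are conservative enough that template-sharing
noise words still enter rarely on realistic data. Out-of-vocabulary seeds
are skipped with a warning rather than an error: a small corpus simply
cannot attest every theme.

## The rule layer

The rules operate on the raw ensemble probability (the "calculated
cohesion score"); applying them to the probability rather than to the
binary vote is an interpretation, recorded here, chosen because it lets
rules *veto* a positive classification — which negation must be able to
do. Application order is forced by the semantics:

1. **Negation** (message-level cue from a closed list: *not, no, never,
   n't, none, nobody, nothing, without, hardly*, with clitic splitting):
   score set to 0, nothing else applies. Negation scope is
   message-global; scoped negation resolution is out of scope and this is
   flagged as a simplification, not a claim about intent.
2. **Past tense** (any verb tagged simple past or past participle by the
   rule-based tagger): × 0.5 — a cohesive event reported in the past is
   assumed to have a subsided effect.
3. **Empathy** (cue-phrase match, e.g. "I can relate", "sending hugs"):
   × 2.0, denoting intensity. The cue list ships with the package and can
   be overridden by file.
4. **Intensifiers** (boosters from the published VADER booster list,
   shipped as a static file): × 1.25 per booster, at most 2 counted. The
   magnitude is a package choice — the booster concept comes from
   sentiment analysis without a prescribed factor for this score — sized
   so that one booster alone cannot push 0.39 across the 0.5 threshold.
5. **Person**: when second- or third-person pronouns occur the
   first-person flag is false; the associated multiplier defaults to 1.0
   (flag recorded, score untouched), the conservative reading since no
   score effect is defined for it.
6. Clamp to [0, 1]; final label = (adjusted score ≥ 0.5).

Consequences worth knowing: the layer is monotone in the raw score for
fixed flags; zero is absorbing; with all multipliers at 1 and no negation
it is the identity. Because negation is message-global, cohesion
statements that *contain* a negation ("I can't wait to chat with you all
next week") are zeroed — a genuine false-negative mode that the synthetic
corpus deliberately includes.

The part-of-speech component is a closed-vocabulary rule tagger
(irregular-verb list plus an *-ed* suffix heuristic with an exception
list); no statistical tagger is used. This overshoots on deverbal
adjectives ("tired") and undershoots on rare irregulars, which is
acceptable because only the binary past-tense flag feeds the rules.

## Interval aggregation

For interval length T (default 30 minutes) on a session of duration D
(default 90), `beta_series()` anchors `ceiling(D/T)` half-open intervals
`[t, t+T)` at 0. A post exactly at the session end is counted in the last
interval, so every post lands in exactly one (conservation is tested).
β = cohesion posts / all posts per interval; an interval with no posts
has **undefined** β (serialised as null/empty), never 0 — an empty room
is not an uncohesive room, and a dashboard consumer must be able to tell
the difference. Per-participant series apply the same formula to the
participant's own posts.

## The dictionary baseline

The comparison method is a closed-vocabulary category counter: per
category, the percentage of message tokens matching any pattern (trailing
`*` = prefix wildcard); a category is "met" when its percentage exceeds
zero (the any-match reading — no percentile criterion is defined for this
rule); the message is cohesion when ≥ 3 of the 5 categories {we,
positive_emotion, family, friend, affiliation} are met. The proprietary
dictionary that inspired the format cannot be redistributed, so the
package ships small open stand-in lists (clearly labelled synthetic) and
accepts user-supplied `.dic` files in the same format. The baseline's
characteristic failure is by design: cohesion phrased without we-language
("I feel like I've suddenly inherited a whole group of sisters") meets
fewer than three categories and is missed.

## Active learning

`active_learning_round()` samples every fifth message (positions 1, 6,
11, … — 20% of the transcript, `ceiling(n/5)` messages), obtains oracle
labels (a CSV adapter lets human scorers fill that role; simulations use
gold labels), and builds the confusion matrix of the ensemble's vote
against the oracle. Feedback enters twice: terms recurring among false
negatives (frequency ≥ 2, not function words, not already in the lexicon)
are appended with provenance `human_added`, and the ensemble is refit on
the training data augmented with the labeled sample. The loop stops when
F1 ≥ 0.80 (the deployment threshold) or after a bounded number of rounds
(default 5) to guarantee termination. Precision/recall/F1 are kept at
full precision and rounded to two decimals only in reports.

## The synthetic generator

Real OSG transcripts are private clinical data, so the generator emulates
their structure: sessions of `messages_per_session` posts with uniform
order-statistic timestamps over 90 minutes (no arrival model is specified
anywhere; exchangeable-uniform is the simplest defensible choice),
participants assigned uniformly, and every tenth post from the therapist.
Each post's gold label is Bernoulli(`cohesion_rate`) and, independently,
Bernoulli(`trap_rate`) decides whether it is drawn from a *trap*
template on the matching label side — negated cohesion, outside-group
support and non-cohesive "we" as hard negatives; idioms, empathy and
cohesion without we-language as hard positives. This construction keeps
the marginal cohesion fraction at `cohesion_rate` (binomially) while
keeping `trap_rate` of the corpus adversarial to keyword matching.
Templates are hand-written slot grammars (booster slot, tense variants)
seeded with the documented theme and trap examples; no neural generation,
so gold labels are correct by construction. The default
`cohesion_rate = 0.2` is a free parameter — no true base rate for
cohesion statements in real sessions is published — and the evaluation
conditions in the tests and acceptance script use 0.3 with
`trap_rate = 0.1`.

**What passing tests do and do not show.** Template-generated text has a
small, repetitive vocabulary, so the ensemble separates it almost
perfectly (held-out F1 near 1); the interesting behaviour is downstream —
which constructs the rules rescue or veto, how β recovers the planted
rate, how the baseline degrades. Results on this corpus validate the
machinery and its contracts, not clinical performance on real chat
language, which has spelling variation, idiolects, topic drift and
ambiguity the generator does not model (nor does it model emoji use,
which is excluded throughout).

## Determinism and problem sizes

One root seed drives everything: per-stage seeds are derived as
`(seed * 1009 + offset) mod 2147483629` with fixed per-stage offsets, and
every stochastic component (split, forest, SVM probability calibration,
MLP initialisation, generator) is seeded from it; repeated runs are
byte-identical on disk. The packaged experiments use 20 sessions × 100
messages (2000 training posts) with 5 held-out sessions, and the interval-
recovery experiment uses 200 replicate sessions of 60 posts — sizes chosen
so the full suite exercises every stage, including two ensemble refits, in
a few minutes on a single core while leaving binomial interval bands
(±3·√(p(1−p)/n)) narrow enough to be informative.

## Known limitations

- Negation is message-global: one negation zeroes an entire post.
- The rule tagger is a heuristic; messages mixing tenses or using rare
  irregular pasts can be misflagged.
- The engineered lexicon feature treats all lexicon phrases equally; no
  per-phrase weighting.
- The stand-in dictionaries are small open lists; results with a real
  licensed dictionary will differ.
- Interactional structure (who replies to whom) and emoji are not used.
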