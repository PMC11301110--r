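# osgcohesion

Detecting and monitoring **group cohesion** in therapist-facilitated,
text-based online support groups (OSGs).

Group cohesion — the sense of warmth, acceptance, mutual support and
belonging among group members — is a clinically meaningful indicator of an
effective support-group session, but in a text-only chat a facilitator has
no nonverbal cues and can miss it (or its breakdown) in real time.
`osgcohesion` implements a message-level cohesion classifier and an
interval-level session monitor:

1. **Ensemble classifier.** Messages are featurised with TF-IDF over
   unigrams and bigrams (vocabulary capped at 5000 terms, plus one
   engineered feature counting cohesion-lexicon matches). Five classifiers
   are trained — multinomial naive Bayes, random forest, linear SVM, a
   single-hidden-layer MLP, and ridge logistic regression — and the three
   with the best held-out positive-class F1 form a committee. A post's
   label is decided by **2-of-3 majority vote**; the committee's mean
   positive-class probability is the raw cohesion score, and each decision
   carries a confidence
   `sum(F1 of agreeing members) / sum(F1 of committee)`.
2. **Lexicon expansion.** Seed "we-talk" keywords (`we`, `us`, `our
   group`) and theme phrases are expanded with a word embedding trained on
   the session corpus (PPMI co-occurrence + truncated SVD), pulling in
   contextually similar expressions.
3. **Linguistic rules.** The raw score is adjusted by hand-coded rules:
   negation sets it to 0; past tense multiplies it by 0.5; an empathy cue
   doubles it; each intensity booster ("very", "so much") multiplies it by
   1.25 (capped at two); the result is clamped to [0, 1] and thresholded
   at 0.5 into the final label.
4. **Interval score.** For each half-open interval `[t, t + T)` of a
   session (T = 30 min on a 90-min timeline),

   `beta = |C(t, t+T)| / |A(t, t+T)|`

   where `A` is the set of posts in the interval and `C` the subset whose
   final label is cohesion — the quantity a live dashboard would plot per
   group and per participant.
5. **Dictionary baseline.** A closed-vocabulary comparison rule: a message
   is cohesion when at least 3 of the 5 wildcard dictionary categories
   {we, positive emotion, family, friend, affiliation} register a match
   (shipped with small open stand-in word lists, not the proprietary
   tool's dictionary).
6. **Active learning.** Every fifth message (20%) of a new transcript is
   scored by an oracle (human scorers in production, gold labels in
   simulation); the confusion matrix yields precision/recall/F1, recurring
   terms from false negatives grow the lexicon, and the ensemble is refit
   with the newly labeled sample, iterating until F1 ≥ 0.80.

Because real OSG chat corpora are private clinical data, the package
includes a synthetic-transcript generator whose templates plant the eight
cohesion themes (gratitude, belonging, shared experience, ...) alongside
the constructs that defeat keyword matching: negated cohesion, support
from outside the group, non-cohesive "we", and cohesion expressed without
any we-language.

## Worked example

```r
library(osgcohesion)

corpus <- generate_corpus(gen_config(n_sessions = 20, messages_per_session = 100,
                                     cohesion_rate = 0.3, trap_rate = 0.1, seed = 7))
emb   <- train_embeddings(corpus$text)
lex   <- expand_seeds(emb)
model <- fit_ensemble(corpus, lexicon = lex, seed = 7)
model
#> <ensemble_model> features: 787 (+ lexicon)
#>   val F1: logistic_regression=1.000 mlp=1.000 naive_bayes=0.968 random_forest=1.000 svm=1.000
#>   selected: logistic_regression, mlp, random_forest

test   <- generate_corpus(gen_config(n_sessions = 1, messages_per_session = 100,
                                     cohesion_rate = 0.3, trap_rate = 0.1, seed = 42))
scored <- score_messages(model, test)
head(scored[, c("message_id", "raw_score", "adjusted_score", "fired_rules", "final_label")], 5)
#>   message_id raw_score adjusted_score fired_rules  final_label
#> 1 S001-M0001   0.0124         0.0124  ""           non_cohesion
#> 2 S001-M0002   0.986          0       "negation"   non_cohesion
#> 3 S001-M0003   0.940          0.470   "past_tense" non_cohesion
#> 4 S001-M0004   0.0124         0.0124  ""           non_cohesion
#> 5 S001-M0005   0.00627        0.00627 "person"     non_cohesion
```

Message 2 shows the rule layer at work: the ensemble is 99% sure the post
mentions cohesion, but it is a *negated* cohesion statement ("we are not
close at all ..."), so the score is vetoed to 0.

```r
scored$timestamp <- test$timestamp
beta_series(scored, interval_minutes = 30, session_minutes = 90)
#>   scope t_start interval_minutes n_posts n_cohesion   beta
#> 1 group       0               30      30          2 0.0667
#> 2 group      30               30      31          7 0.226
#> 3 group      60               30      39          8 0.205
```

The session's cohesion level is low in the first half hour and roughly
one post in five thereafter. Against the gold labels, the full pipeline
and the dictionary baseline give:

```r
eval_report(confusion_matrix(scored$final_label, test$gold_label), "pipeline")
#> Scoring round            Precision    Recall        F1
#> pipeline                      1.00      0.61      0.76
eval_report(confusion_matrix(baseline_transcript(test)$label, test$gold_label), "dictionary")
#> Scoring round            Precision    Recall        F1
#> dictionary                    1.00      0.18      0.30
```

Both methods are precise, but the keyword-bound dictionary rule misses
most cohesion that is phrased without we-language, while the learned
pipeline recovers much more of it — and its misses are concentrated in
exactly the hard constructs the generator plants (idioms, cohesion
statements containing negation).

## Vignette

`vignettes/cohesion-monitoring.Rmd` documents the model, its parameters
and defaults, the synthetic-data assumptions, numerical conventions and
known limitations.
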