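# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) assign(key, builder(), envir = .fx)
  .fx[[key]]
}

# the default synthetic training corpus of the end-to-end checks
fixture_corpus <- function() {
  memo("corpus", function()
    generate_corpus(gen_config(n_sessions = 20L, messages_per_session = 100L,
                               cohesion_rate = 0.3, trap_rate = 0.1, seed = 7L)))
}

# a held-out transcript from independent sessions (active-learning rounds)
fixture_test_corpus <- function() {
  memo("test_corpus", function()
    generate_corpus(gen_config(n_sessions = 5L, messages_per_session = 100L,
                               cohesion_rate = 0.3, trap_rate = 0.1, seed = 11L)))
}

fixture_embeddings <- function() {
  memo("embeddings", function() train_embeddings(fixture_corpus()$text))
}

fixture_lexicon <- function() {
  memo("lexicon", function() expand_seeds(fixture_embeddings()))
}

fixture_model <- function() {
  memo("model", function()
    fit_ensemble(fixture_corpus(), lexicon = fixture_lexicon(), seed = 7L))
}

# construct linguistic flags directly (rule-layer fuzzing)
make_flags <- function(past = FALSE, negation = FALSE,
                       person = "first_plural", intensifiers = 0L) {
  first <- any(c("first_singular", "first_plural") %in% person) &&
    !any(c("second", "third") %in% person)
  structure(list(
    tokens = c("x"), pos_tags = c("WORD"),
    has_past_tense = past, has_negation = negation,
    person = person, first_person = first,
    intensifier_count = as.integer(intensifiers), is_question = FALSE
  ), class = "linguistic_flags")
}

# integer confusion matrix realising exact precision/recall fractions
cm_exact <- function(tp, fp, fn, tn = 0L) {
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}
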