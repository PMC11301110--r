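test_that("F1 follows from printed precision/recall pairs at 2 decimals", {
  # integer matrices realising the exact precision/recall fractions
  m <- metrics(cm_exact(tp = 5148L, fp = 52L, fn = 4752L))   # p=.99 r=.52
  expect_equal(round(m$precision, 2), 0.99)
  expect_equal(round(m$recall, 2), 0.52)
  expect_equal(round(m$f1, 2), 0.68)
  m <- metrics(cm_exact(tp = 686L, fp = 14L, fn = 294L))     # p=.98 r=.70
  expect_equal(round(m$f1, 2), 0.82)
  m <- metrics(cm_exact(tp = 828L, fp = 1472L, fn = 2772L))  # p=.36 r=.23
  expect_equal(round(m$f1, 2), 0.28)
  m <- metrics(cm_exact(tp = 10L, fp = 0L, fn = 0L, tn = 5L))
  expect_equal(m$f1, 1)
})

test_that("metrics handle degenerate matrices per convention", {
  expect_error(metrics(cm_exact(0L, 0L, 0L, 0L)), "empty")
  m <- metrics(cm_exact(tp = 0L, fp = 0L, fn = 3L, tn = 5L))
  expect_true(is.na(m$precision))          # no positive prediction
  m <- metrics(cm_exact(tp = 0L, fp = 3L, fn = 2L, tn = 5L))
  expect_equal(m$f1, 0)                    # p + r = 0
})

test_that("confusion counts match an independent per-example recount", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(2:60, 1)
    pred <- sample(c("cohesion", "non_cohesion"), n, replace = TRUE)
    gold <- sample(c("cohesion", "non_cohesion"), n, replace = TRUE)
    cm <- confusion_matrix(pred, gold)
    recount <- table(factor(pred, c("cohesion", "non_cohesion")),
                     factor(gold, c("cohesion", "non_cohesion")))
    expect_equal(cm$tp, recount["cohesion", "cohesion"][[1]])
    expect_equal(cm$fp, recount["cohesion", "non_cohesion"][[1]])
    expect_equal(cm$fn, recount["non_cohesion", "cohesion"][[1]])
    expect_equal(cm$tn, recount["non_cohesion", "non_cohesion"][[1]])
    expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, n)
    m <- metrics(cm)
    if (!is.na(m$f1) && !is.na(m$precision) && !is.na(m$recall) &&
        m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall))
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    }
  }
})

test_that("the stop rule triggers at the 0.80 deployment threshold", {
  r82 <- eval_report(cm_exact(686L, 14L, 294L))
  expect_true(stop_rule(r82))                         # f1 = 0.82
  r68 <- eval_report(cm_exact(5148L, 52L, 4752L))
  expect_false(stop_rule(r68))                        # f1 = 0.68
  r80 <- eval_report(cm_exact(80L, 20L, 20L))         # p = r = f1 = 0.80
  expect_true(stop_rule(r80))
})

test_that("report table rounds to two decimals", {
  tab <- format_report_table(list(eval_report(cm_exact(686L, 14L, 294L),
                                              round_id = "Second")))
  expect_match(tab[1], "Precision")
  expect_match(tab[2], "0.98")
  expect_match(tab[2], "0.70")
  expect_match(tab[2], "0.82")
})

test_that("a model scored against its own predictions is perfect", {
  model <- fixture_model()
  lex <- fixture_lexicon()
  test <- fixture_test_corpus()[1:200, ]
  own <- stats::setNames(predict_ensemble(model, test)$vote_label,
                         test$message_id)
  res <- active_learning_round(model, test, own, train = fixture_corpus(),
                               lexicon = lex, k = 5L, seed = 21L)
  expect_equal(res$report$counts$fp, 0L)
  expect_equal(res$report$counts$fn, 0L)
  expect_equal(nrow(res$lexicon$expanded), nrow(lex$expanded))
})

test_that("every fifth message gives a 20% human-scoring sample", {
  msgs <- tibble::tibble(message_id = sprintf("m%04d", 1:1000),
                         text = rep("we are friends", 1000))
  expect_equal(nrow(sample_every_kth(msgs, 5L)), 200L)
})

test_that("active learning grows the lexicon and never loses recall", {
  model <- fixture_model()
  lex <- fixture_lexicon()
  train <- fixture_corpus()
  test <- fixture_test_corpus()
  oracle <- stats::setNames(test$gold_label, test$message_id)

  r1 <- active_learning_round(model, test, oracle, train = train,
                              lexicon = lex, round_id = 1L, seed = 11L)
  expect_gte(nrow(r1$lexicon$expanded), nrow(lex$expanded))
  train2 <- rbind(train[, c("text", "gold_label")],
                  r1$scored[, c("text", "gold_label")])
  r2 <- active_learning_round(r1$model, test, oracle, train = train2,
                              lexicon = r1$lexicon, round_id = 2L, seed = 11L)
  expect_gte(r2$report$recall, r1$report$recall)
  expect_gte(nrow(r2$lexicon$expanded), nrow(r1$lexicon$expanded))
})

test_that("a sampled message missing from the oracle is named in the error", {
  model <- fixture_model()
  test <- fixture_test_corpus()[1:20, ]
  oracle <- stats::setNames(test$gold_label[-1], test$message_id[-1])
  expect_error(
    active_learning_round(model, test, oracle, train = fixture_corpus(),
                          lexicon = fixture_lexicon()),
    test$message_id[1], fixed = TRUE)
})
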