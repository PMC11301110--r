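test_that("tfidf vectorizer caps vocabulary and L2-normalises", {
  texts <- c("we are friends", "we love this group", "my scan is tomorrow",
             "thank you all so much")
  vec <- fit_tfidf(texts, feature_config(max_features = 10L))
  expect_lte(length(vec$vocab), 10L)
  X <- transform_tfidf(vec, texts)
  norms <- sqrt(Matrix::rowSums(X^2))
  expect_true(all(abs(norms - 1) < 1e-8 | norms == 0))
  # unseen-vocabulary text maps to a zero row, not an error
  X0 <- transform_tfidf(vec, "qqqq zzzz")
  expect_equal(sum(X0), 0)
  expect_equal(nrow(transform_tfidf(vec, character())), 0L)
})

test_that("2-of-3 vote matches brute-force majority on all label patterns", {
  f1 <- c(a = 0.79, b = 0.77, c = 0.82)
  for (bits in 0:7) {
    lab <- as.integer(intToBits(bits))[1:3]
    probs <- stats::setNames(ifelse(lab == 1L, 0.9, 0.1), names(f1))
    v <- vote(probs, f1)
    brute <- if (sum(lab) >= 2L) "cohesion" else "non_cohesion"
    expect_equal(v$vote_label, brute)
    expect_equal(v$raw_score, mean(probs))
    # confidence: weighted share of agreeing members; 1 iff unanimous
    agree <- (if (brute == "cohesion") lab == 1L else lab == 0L)
    expect_equal(v$confidence, sum(f1[agree]) / sum(f1))
    expect_equal(v$confidence == 1, all(agree))
    expect_gte(v$confidence, min(f1[1] + f1[2], f1[1] + f1[3], f1[2] + f1[3]) / sum(f1))
  }
  v0 <- vote(c(a = 0, b = 0, c = 0), f1)
  expect_equal(v0$vote_label, "non_cohesion")
  expect_equal(v0$raw_score, 0)
  expect_equal(v0$confidence, 1)
  expect_error(vote(c(a = 0.5, b = 0.5), f1), "3 probabilities")
  expect_error(vote(c(a = 0.5, b = 0.5, c = 1.5), f1), "0, 1")
})

test_that("top-3 selection uses F1 with name-order tie-breaks", {
  expect_equal(select_top3(c(svm = 0.5, naive_bayes = 0.5, mlp = 0.5,
                             random_forest = 0.5, logistic_regression = 0.5)),
               c("logistic_regression", "mlp", "naive_bayes"))
  expect_setequal(select_top3(c(a = 0.9, b = 0.1, c = 0.8, d = 0.7, e = 0.2)),
                  c("a", "c", "d"))
})

test_that("ensemble fit validates inputs", {
  small <- tibble::tibble(text = rep("hi there", 10),
                          gold_label = rep(c("cohesion", "non_cohesion"), 5))
  expect_error(fit_ensemble(small), "at least 20")
  onecls <- tibble::tibble(text = sprintf("msg %d", 1:30),
                           gold_label = rep("non_cohesion", 30))
  expect_error(fit_ensemble(onecls), "single class")
})

test_that("fitted ensemble beats chance and respects the feature cap", {
  model <- fixture_model()
  # oracle: the majority class is non_cohesion, so a majority-class
  # baseline never predicts a positive and its positive-class F1 is 0
  maj <- names(which.max(table(fixture_corpus()$gold_label)))
  base_f1 <- f1_binary(rep(maj, nrow(fixture_corpus())),
                       fixture_corpus()$gold_label)
  expect_equal(base_f1, 0)
  expect_true(all(model$val_f1 > 0.5))
  expect_true(all(model$val_f1 > base_f1))
  expect_length(model$selected, 3L)
  expect_lte(length(model$vectorizer$vocab), 5000L)

  # deterministic refit on a smaller corpus selects the same committee
  co <- fixture_corpus()[1:400, ]
  m1 <- fit_ensemble(co, seed = 3L)
  m2 <- fit_ensemble(co, seed = 3L)
  expect_identical(m1$selected, m2$selected)
  expect_equal(m1$val_f1, m2$val_f1)
})

test_that("prediction is order-preserving, deterministic and handles fixtures", {
  model <- fixture_model()
  empty <- predict_ensemble(model, tibble::tibble(text = character()))
  expect_equal(nrow(empty), 0L)

  msgs <- tibble::tibble(
    message_id = c("a", "b"),
    text = c("Thank you everyone, this is such a great group.",
             "my scan is scheduled for thursday morning"))
  s1 <- predict_ensemble(model, msgs)
  s2 <- predict_ensemble(model, msgs)
  expect_identical(s1, s2)
  expect_equal(s1$message_id, c("a", "b"))
  # regression: the gratitude fixture is recognised, plain logistics is not
  expect_equal(s1$vote_label, c("cohesion", "non_cohesion"))
  expect_true(all(s1$raw_score >= 0 & s1$raw_score <= 1))
  expect_true(all(s1$confidence >= 0 & s1$confidence <= 1))
})

test_that("model persistence round-trips predictions", {
  model <- fixture_model()
  dir <- withr::local_tempdir()
  save_ensemble(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_ensemble(dir)
  txt <- tibble::tibble(text = "I am glad to be part of this group")
  expect_identical(predict_ensemble(model, txt), predict_ensemble(back, txt))
  expect_error(load_ensemble(withr::local_tempdir()), "no fitted model")
})
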