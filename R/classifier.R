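# Ensemble cohesion classifier: five learners on TF-IDF features, top-3
# selection by held-out F1, 2-of-3 majority vote with F1-weighted confidence.

#' Fit the five-classifier cohesion ensemble
#'
#' Trains naive Bayes, random forest, SVM, MLP and logistic regression on
#' TF-IDF unigram+bigram features (capped vocabulary, optional lexicon-match
#' feature). Each classifier's positive-class F1 is measured on a stratified
#' 20% held-out split, and the three best (ties broken by name) form the
#' voting committee.
#'
#' @param train A data frame with columns `text` and `gold_label`
#'   (`cohesion` / `non_cohesion`); at least 20 rows and both classes.
#' @param config A [feature_config()].
#' @param lexicon Optional `cohesion_lexicon` for the engineered feature.
#' @param seed Integer seed controlling the split and all stochastic
#'   learners.
#' @param val_fraction Held-out fraction for per-classifier F1.
#' @return Object of class `ensemble_model`: `vectorizer`, `classifiers`,
#'   `val_f1` (named, all five), `selected` (3 names), `config`, `seed`.
#' @export
fit_ensemble <- function(train, config = feature_config(), lexicon = NULL,
                         seed = 1L, val_fraction = 0.2) {
  stopifnot(is.data.frame(train), all(c("text", "gold_label") %in% names(train)))
  if (nrow(train) < 20L)
    stop("need at least 20 training examples", call. = FALSE)
  y <- as_label_factor(train$gold_label)
  if (any(is.na(y)))
    stop("gold_label must be 'cohesion' or 'non_cohesion'", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L)
    stop("training data contain a single class; cannot fit", call. = FALSE)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "split"))
  val_idx <- unlist(lapply(levels(y), function(cl) {
    rows <- which(y == cl)
    rows[sample.int(length(rows), max(1L, round(length(rows) * val_fraction)))]
  }))
  tr_idx <- setdiff(seq_len(nrow(train)), val_idx)

  vectorizer <- fit_tfidf(train$text[tr_idx], config, lexicon)
  Xtr <- transform_tfidf(vectorizer, train$text[tr_idx])
  Xval <- transform_tfidf(vectorizer, train$text[val_idx])
  ytr <- y[tr_idx]; yval <- y[val_idx]

  classifiers <- list()
  val_f1 <- stats::setNames(numeric(length(.CLASSIFIER_NAMES)), .CLASSIFIER_NAMES)
  for (nm in .CLASSIFIER_NAMES) {
    cl <- fit_learner(nm, Xtr, ytr, seed = derive_seed(seed, "train"))
    classifiers[[nm]] <- cl
    pred <- ifelse(predict_prob(cl, Xval) >= 0.5, .POSITIVE, .NEGATIVE)
    val_f1[[nm]] <- f1_binary(pred, as.character(yval))
  }
  selected <- select_top3(val_f1)

  structure(list(vectorizer = vectorizer, classifiers = classifiers,
                 val_f1 = val_f1, selected = selected, config = config,
                 seed = as.integer(seed)),
            class = "ensemble_model")
}

#' Select the top three classifiers by F1
#'
#' Ties are broken by fixed (alphabetical) classifier name order.
#'
#' @param val_f1 Named numeric vector of per-classifier F1 values.
#' @return Character vector of the three selected names, best first.
#' @export
select_top3 <- function(val_f1) {
  stopifnot(length(val_f1) >= 3L, !is.null(names(val_f1)))
  nm <- sort(names(val_f1))
  ord <- order(-val_f1[nm])
  nm[ord][1:3]
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> features:", length(x$vectorizer$vocab),
      if (!is.null(x$vectorizer$lex_phrases)) "(+ lexicon)", "\n")
  f1 <- sprintf("%s=%.3f", names(x$val_f1), x$val_f1)
  cat("  val F1:", paste(f1, collapse = " "), "\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Combine three classifier probabilities by 2-of-3 majority vote
#'
#' Each committee member labels the post by thresholding its positive-class
#' probability; the label agreed by at least 2 of the 3 is the outcome.
#' `raw_score` is the mean probability and the confidence is the
#' F1-weighted share of the committee agreeing with the outcome:
#' `sum(F1 of agreeing) / sum(F1 of all three)`, so confidence is 1 exactly
#' when the vote is unanimous.
#'
#' @param probabilities Named numeric vector of exactly 3 probabilities in
#'   `[0, 1]` (names = selected classifiers).
#' @param val_f1 Named F1 vector covering those classifiers.
#' @param decision_threshold Probability threshold for each member's label.
#' @return List with `vote_label`, `raw_score`, `confidence`, `votes`.
#' @export
vote <- function(probabilities, val_f1, decision_threshold = 0.5) {
  if (length(probabilities) != 3L)
    stop("exactly 3 probabilities are required", call. = FALSE)
  if (any(is.na(probabilities)) || any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  nms <- names(probabilities)
  stopifnot(!is.null(nms), all(nms %in% names(val_f1)))
  labels <- ifelse(probabilities >= decision_threshold, .POSITIVE, .NEGATIVE)
  vote_label <- if (sum(labels == .POSITIVE) >= 2L) .POSITIVE else .NEGATIVE
  w <- val_f1[nms]
  denom <- sum(w)
  confidence <- if (denom > 0) sum(w[labels == vote_label]) / denom else
    mean(labels == vote_label)
  list(vote_label = vote_label,
       raw_score = mean(probabilities),
       confidence = as.numeric(confidence),
       votes = stats::setNames(as.character(labels), nms))
}

#' Score messages with a fitted ensemble
#'
#' @param model A fitted `ensemble_model`.
#' @param messages Data frame with columns `text` and (optionally)
#'   `message_id`, or a character vector of texts.
#' @param decision_threshold Per-member probability threshold.
#' @return A tibble, one row per message in input order: `message_id`,
#'   per-member probability columns `prob_<name>`, `raw_score`,
#'   `vote_label`, `confidence`.
#' @export
predict_ensemble <- function(model, messages, decision_threshold = 0.5) {
  if (!inherits(model, "ensemble_model"))
    stop("`model` must be a fitted ensemble_model", call. = FALSE)
  if (is.character(messages))
    messages <- tibble::tibble(text = messages)
  stopifnot(is.data.frame(messages), "text" %in% names(messages))
  ids <- if ("message_id" %in% names(messages)) messages$message_id else
    sprintf("M%04d", seq_len(nrow(messages)))
  n <- nrow(messages)
  if (n == 0L) {
    return(tibble::tibble(message_id = character(), raw_score = numeric(),
                          vote_label = character(), confidence = numeric()))
  }
  X <- transform_tfidf(model$vectorizer, messages$text)
  probs <- vapply(model$selected, function(nm)
    predict_prob(model$classifiers[[nm]], X), numeric(n))
  probs <- matrix(probs, nrow = n, dimnames = list(NULL, model$selected))

  vl <- character(n); rs <- numeric(n); cf <- numeric(n)
  for (i in seq_len(n)) {
    v <- vote(probs[i, ], model$val_f1, decision_threshold)
    vl[i] <- v$vote_label; rs[i] <- v$raw_score; cf[i] <- v$confidence
  }
  out <- tibble::tibble(message_id = ids)
  for (nm in model$selected) out[[paste0("prob_", nm)]] <- probs[, nm]
  out$raw_score <- rs
  out$vote_label <- vl
  out$confidence <- cf
  out
}

#' Persist / restore an ensemble model directory
#'
#' The directory holds the fitted components plus a JSON manifest
#' (selected classifiers, validation F1, feature config, seed).
#'
#' @param model A fitted `ensemble_model`.
#' @param dir Directory path (created if missing).
#' @return `save_ensemble()` returns `dir` invisibly; `load_ensemble()` the
#'   model.
#' @export
save_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "ensemble_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "ensemble.rds"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("osgcohesion")),
    selected = model$selected,
    val_f1 = as.list(model$val_f1),
    config = unclass(model$config),
    seed = model$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  path <- file.path(dir, "ensemble.rds")
  if (!file.exists(path))
    stop("no fitted model found at ", dir, call. = FALSE)
  readRDS(path)
}
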