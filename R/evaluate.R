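# Confusion-matrix metrics and the human-in-the-loop active-learning round.

#' Confusion matrix of predicted vs gold labels
#'
#' Positive class is `cohesion` throughout.
#'
#' @param pred,gold Character vectors of labels
#'   (`cohesion` / `non_cohesion`), equal length.
#' @return List of class `confusion_matrix`: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  structure(list(
    tp = sum(pred == .POSITIVE & gold == .POSITIVE),
    fp = sum(pred == .POSITIVE & gold == .NEGATIVE),
    fn = sum(pred == .NEGATIVE & gold == .POSITIVE),
    tn = sum(pred == .NEGATIVE & gold == .NEGATIVE)
  ), class = "confusion_matrix")
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Precision (recall) is `NA` when no positive prediction (gold positive)
#' exists; F1 is the harmonic mean `2pr / (p + r)`, defined as 0 when
#' `p + r = 0`. Values are kept at full precision; round only when
#' reporting.
#'
#' @param cm A [confusion_matrix()], or a list with `tp`, `fp`, `fn`, `tn`.
#' @return List with `precision`, `recall`, `f1`.
#' @export
metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  p <- if (cm$tp + cm$fp == 0L) NA_real_ else cm$tp / (cm$tp + cm$fp)
  r <- if (cm$tp + cm$fn == 0L) NA_real_ else cm$tp / (cm$tp + cm$fn)
  f1 <- if (is.na(p) || is.na(r)) NA_real_
    else if (p + r == 0) 0
    else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1)
}

#' Build an evaluation report
#'
#' @param cm A [confusion_matrix()].
#' @param round_id Identifier of the scoring round.
#' @param error_listing Optional tibble of misclassified messages
#'   (`message_id`, `kind` = fp/fn, `theme`).
#' @return List of class `eval_report`: metrics plus `counts`, `round_id`,
#'   `error_listing`.
#' @export
eval_report <- function(cm, round_id = 1L, error_listing = NULL) {
  m <- metrics(cm)
  structure(c(m, list(counts = cm, round_id = round_id,
                      error_listing = error_listing)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(format_report_table(list(x)), sep = "\n")
  invisible(x)
}

#' Render reports as a text table (2-decimal rounding)
#'
#' @param reports List of `eval_report` objects (or one).
#' @param labels Optional row labels; defaults to the round ids.
#' @return Character vector of table lines.
#' @export
format_report_table <- function(reports, labels = NULL) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  if (is.null(labels))
    labels <- vapply(reports, function(r) as.character(r$round_id), character(1))
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  header <- sprintf("%-24s %9s %9s %9s", "Scoring round", "Precision",
                    "Recall", "F1")
  rows <- vapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    sprintf("%-24s %9s %9s %9s", labels[i], fmt(r$precision), fmt(r$recall),
            fmt(r$f1))
  }, character(1))
  c(header, rows)
}

#' Stop rule for the active-learning loop
#'
#' @param report An `eval_report`.
#' @param target_f1 Deployment threshold (default 0.80).
#' @return `TRUE` when the report's F1 has reached the target.
#' @export
stop_rule <- function(report, target_f1 = 0.80) {
  stopifnot(inherits(report, "eval_report"))
  !is.na(report$f1) && report$f1 >= target_f1
}

# closed list of function words never promoted into the lexicon
.FN_STOPWORDS <- c(
  "a", "an", "the", "and", "or", "but", "of", "to", "in", "on", "at", "is",
  "are", "am", "was", "were", "be", "been", "it", "that", "this", "there",
  "i", "you", "my", "your", "me", "so", "do", "did", "have", "has", "had",
  "will", "would", "going", "'s", "'m", "'ve", "'ll", "n't"
)

# gold-label lookup: accepts a function, a named vector, or a data frame
as_oracle <- function(oracle) {
  if (is.function(oracle)) return(oracle)
  if (is.data.frame(oracle)) {
    stopifnot(all(c("message_id", "gold_label") %in% names(oracle)))
    oracle <- stats::setNames(oracle$gold_label, oracle$message_id)
  }
  stopifnot(is.character(oracle), !is.null(names(oracle)))
  function(id) {
    if (!id %in% names(oracle))
      stop("oracle has no label for message ", id, call. = FALSE)
    unname(oracle[[id]])
  }
}

#' Read a human-scoring CSV as an oracle
#'
#' @param path CSV with columns `message_id`, `gold_label`.
#' @return Named character vector usable as the `oracle` argument of
#'   [active_learning_round()].
#' @export
read_oracle_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("message_id", "gold_label") %in% names(df)))
  stats::setNames(df$gold_label, df$message_id)
}

#' One active-learning round
#'
#' Samples every `k`-th message of the unscored transcript, has the oracle
#' (human scorers, or gold labels in simulation) label the sample, and
#' scores the model against it. Terms that recur among false negatives
#' (frequency >= 2, not already in the lexicon, not function words) are
#' appended to the lexicon as `human_added`, and the ensemble is refit on
#' the training data augmented with the newly labeled sample.
#'
#' @param model A fitted `ensemble_model`.
#' @param unscored Transcript data frame (`message_id`, `text`, optionally
#'   `theme`).
#' @param oracle Function `message_id -> label`, named label vector, or data
#'   frame (`message_id`, `gold_label`).
#' @param train Training data the model was fit on (`text`, `gold_label`).
#' @param lexicon The current `cohesion_lexicon`.
#' @param k Sampling stride (default 5: every fifth message, 20%).
#' @param round_id Round number carried into the report.
#' @param seed Seed for the refit.
#' @return List with `model` (refit), `report` (`eval_report` on the
#'   sample), `lexicon` (possibly grown), `scored` (the labeled sample).
#' @export
active_learning_round <- function(model, unscored, oracle, train, lexicon,
                                  k = 5L, round_id = 1L, seed = 1L) {
  stopifnot(inherits(model, "ensemble_model"),
            is.data.frame(unscored), "text" %in% names(unscored))
  look <- as_oracle(oracle)
  sampled <- sample_every_kth(unscored, k)
  gold <- vapply(sampled$message_id, look, character(1), USE.NAMES = FALSE)

  pred <- predict_ensemble(model, sampled)$vote_label
  cm <- confusion_matrix(pred, gold)

  is_fp <- pred == .POSITIVE & gold == .NEGATIVE
  is_fn <- pred == .NEGATIVE & gold == .POSITIVE
  err_idx <- which(is_fp | is_fn)
  errs <- tibble::tibble(
    message_id = sampled$message_id[err_idx],
    kind = ifelse(is_fp[err_idx], "fp", "fn"),
    theme = if ("theme" %in% names(sampled))
      sampled$theme[err_idx] else rep(NA_character_, length(err_idx))
  )
  report <- eval_report(cm, round_id = round_id, error_listing = errs)

  fn_tokens <- unlist(lapply(sampled$text[is_fn], feature_tokens))
  fn_tokens <- fn_tokens[!(fn_tokens %in% .FN_STOPWORDS) &
                           grepl("^[a-z]", fn_tokens)]
  tab <- table(fn_tokens)
  novel <- names(tab)[tab >= 2L]
  new_lexicon <- lexicon_add_human(lexicon, novel)

  augmented <- rbind(
    train[, c("text", "gold_label")],
    tibble::tibble(text = sampled$text, gold_label = gold)
  )
  new_model <- fit_ensemble(augmented, config = model$config,
                            lexicon = new_lexicon, seed = seed)
  list(model = new_model, report = report, lexicon = new_lexicon,
       scored = tibble::tibble(message_id = sampled$message_id,
                               text = sampled$text, gold_label = gold))
}
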