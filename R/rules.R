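# Hand-coded linguistic rules adjusting the ensemble's cohesion score.
#
# Order of application is forced by the semantics: negation zeroes the score
# outright (short-circuit), the remaining rules are multiplicative (past
# tense dampens, empathy doubles, each intensity booster amplifies), and the
# result is clamped to [0, 1] before thresholding into the final label.

#' Rule-layer configuration
#'
#' @param past_tense_multiplier Applied when any past-tense verb is present
#'   (the expressed event lies in the past, so its effect is assumed to have
#'   subsided).
#' @param empathy_multiplier Applied when an empathy cue is found.
#' @param intensifier_multiplier Per-booster factor.
#' @param intensifier_cap Maximum boosters counted.
#' @param second_third_person_multiplier Applied when the message is not
#'   first-person (default 1: the flag is recorded, the score untouched).
#' @param final_threshold Adjusted-score threshold for the final label.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(past_tense_multiplier = 0.5,
                        empathy_multiplier = 2.0,
                        intensifier_multiplier = 1.25,
                        intensifier_cap = 2L,
                        second_third_person_multiplier = 1.0,
                        final_threshold = 0.5) {
  mult <- c(past_tense_multiplier, empathy_multiplier,
            intensifier_multiplier, second_third_person_multiplier)
  if (any(!is.finite(mult)) || any(mult <= 0))
    abort_field("multiplier", "all multipliers must be positive")
  if (!is.numeric(final_threshold) || final_threshold <= 0 || final_threshold >= 1)
    abort_field("final_threshold", "must lie in (0, 1)")
  structure(list(
    past_tense_multiplier = past_tense_multiplier,
    empathy_multiplier = empathy_multiplier,
    intensifier_multiplier = intensifier_multiplier,
    intensifier_cap = check_count(intensifier_cap, "intensifier_cap", min = 0L),
    second_third_person_multiplier = second_third_person_multiplier,
    final_threshold = final_threshold
  ), class = "rule_config")
}

#' Read a rule configuration from a key = value file
#'
#' Plain `key = value` lines (comments with `#`); unknown keys are an error,
#' missing keys keep their defaults.
#'
#' @param path File path.
#' @return A [rule_config()].
#' @export
read_rule_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- read_term_list(path)
  args <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed rule-config line: ", l, call. = FALSE)
    args[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  do.call(rule_config, args)
}

#' Detect an empathy statement
#'
#' Case-insensitive match of cue phrases ("I can relate", "sending hugs",
#' ...) against the message's token stream.
#'
#' @param text A single non-empty string.
#' @param empathy_lexicon Character vector of cue phrases; defaults to the
#'   shipped list.
#' @return `TRUE` if any cue matches.
#' @export
detect_empathy <- function(text, empathy_lexicon = NULL) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    abort_field("text", "must be a single non-empty string")
  if (is.null(empathy_lexicon)) empathy_lexicon <- shipped_terms("empathy_cues")
  toks <- tokenize(text)
  # normalise cue phrases through the same tokenizer so clitics line up
  cues <- vapply(empathy_lexicon,
                 function(ph) paste(tokenize(ph), collapse = " "),
                 character(1), USE.NAMES = FALSE)
  count_phrase_hits(toks, unique(cues)) > 0L
}

#' Apply the linguistic rules to one raw cohesion score
#'
#' Application order: negation (score set to 0, nothing else applies) ->
#' past tense (x `past_tense_multiplier`) -> empathy
#' (x `empathy_multiplier`) -> intensifiers (x `intensifier_multiplier` per
#' booster, capped) -> non-first-person (x
#' `second_third_person_multiplier`) -> clamp to `[0, 1]`. The final label
#' is `cohesion` when the adjusted score reaches `final_threshold`.
#'
#' @param raw_score Ensemble probability in `[0, 1]`.
#' @param flags [analyze()] output for the message.
#' @param empathy_hit Result of [detect_empathy()].
#' @param config A [rule_config()].
#' @param message_id Optional id carried through.
#' @return List of class `adjusted_score`: `message_id`, `raw_score`,
#'   `adjusted_score`, `fired_rules` (ordered), `final_label`.
#' @export
adjust <- function(raw_score, flags, empathy_hit = FALSE,
                   config = rule_config(), message_id = NA_character_) {
  if (!is.numeric(raw_score) || length(raw_score) != 1L || is.na(raw_score) ||
      raw_score < 0 || raw_score > 1)
    abort_field("raw_score", "must lie in [0, 1]")
  stopifnot(inherits(flags, "linguistic_flags"), inherits(config, "rule_config"))

  fired <- character()
  if (flags$has_negation) {
    fired <- "negation"
    s <- 0
  } else {
    s <- raw_score
    if (flags$has_past_tense) {
      s <- s * config$past_tense_multiplier
      fired <- c(fired, "past_tense")
    }
    if (isTRUE(empathy_hit)) {
      s <- s * config$empathy_multiplier
      fired <- c(fired, "empathy")
    }
    k <- min(flags$intensifier_count, config$intensifier_cap)
    if (k > 0L) {
      s <- s * config$intensifier_multiplier^k
      fired <- c(fired, "intensifier")
    }
    if (!flags$first_person) {
      s <- s * config$second_third_person_multiplier
      fired <- c(fired, "person")
    }
    s <- min(max(s, 0), 1)
  }
  structure(list(
    message_id = message_id,
    raw_score = raw_score,
    adjusted_score = s,
    fired_rules = fired,
    final_label = if (s >= config$final_threshold) .POSITIVE else .NEGATIVE
  ), class = "adjusted_score")
}

#' Score a transcript end to end (ensemble + rules)
#'
#' Runs [predict_ensemble()] and then [adjust()] on every message; the
#' rule-adjusted score, not the vote, determines the final label, so
#' negation can veto a positive classification.
#'
#' @param model A fitted `ensemble_model`.
#' @param messages Data frame with `text` (and optionally `message_id`).
#' @param rule_cfg A [rule_config()].
#' @param empathy_lexicon Optional cue-phrase override.
#' @return Tibble: ensemble columns plus `adjusted_score`, `fired_rules`
#'   (comma-joined), `final_label`.
#' @export
score_messages <- function(model, messages, rule_cfg = rule_config(),
                           empathy_lexicon = NULL) {
  scored <- predict_ensemble(model, messages)
  if (nrow(scored) == 0L) {
    scored$adjusted_score <- numeric()
    scored$fired_rules <- character()
    scored$final_label <- character()
    return(scored)
  }
  texts <- if (is.character(messages)) messages else messages$text
  adj <- numeric(nrow(scored)); rules <- character(nrow(scored))
  lab <- character(nrow(scored))
  for (i in seq_len(nrow(scored))) {
    fl <- analyze(texts[[i]])
    emp <- detect_empathy(texts[[i]], empathy_lexicon)
    a <- adjust(scored$raw_score[i], fl, emp, rule_cfg,
                message_id = scored$message_id[i])
    adj[i] <- a$adjusted_score
    rules[i] <- paste(a$fired_rules, collapse = ",")
    lab[i] <- a$final_label
  }
  scored$adjusted_score <- adj
  scored$fired_rules <- rules
  scored$final_label <- lab
  scored
}
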