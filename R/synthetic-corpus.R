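# Synthetic labeled transcripts for online support-group (OSG) sessions.
#
# Real OSG chat corpora are private clinical data, so the pipeline ships a
# generator that emulates their structure: 90-minute sessions of short chat
# posts, a minority of which express group cohesion drawn from the eight
# scoring-guide themes, plus "trap" constructs that defeat naive keyword
# matching (negated cohesion, support from outside the group, "we" used
# non-cohesively, idioms and empathy that lack "we"-language entirely).

.COHESION_THEMES <- c(
  "Reassurance among peers",
  "Expressing support/feeling supported",
  "Deepening emotional disclosure and trust",
  "Sense of belonging",
  "Gratitude for the group and peers",
  "Shared experiences",
  "Reflecting on the positive aspects of the group",
  "Anticipating future groups/chats"
)

.TRAP_THEMES <- c(
  false_we = "trap: false detection of we/us",
  outside_support = "trap: outside-group support",
  negated_cohesion = "trap: negated cohesion",
  idiom_cohesion = "trap: idiomatic cohesion",
  empathy_no_we = "trap: empathy without we-language",
  missing_we = "trap: cohesion without we-language"
)

# trap categories whose gold label is cohesion (hard positives); the rest are
# hard negatives
.TRAP_GOLD <- c(
  false_we = "non_cohesion", outside_support = "non_cohesion",
  negated_cohesion = "non_cohesion", idiom_cohesion = "cohesion",
  empathy_no_we = "cohesion", missing_we = "cohesion"
)

tpl <- function(theme, category, gold_label, text, text_past = NA_character_) {
  tibble::tibble(theme = theme, category = category, gold_label = gold_label,
                 text = text, text_past = text_past)
}

#' Template bank for the synthetic-transcript generator
#'
#' Hand-written message templates organised by theme. Cohesion templates
#' cover the eight scoring-guide themes; trap templates reproduce the
#' documented failure modes of keyword-driven cohesion detection; neutral
#' templates are ordinary session chatter. Templates may carry a
#' `{booster}` slot (filled with an intensity booster or dropped) and an
#' optional past-tense variant; [render_template()] realises one variant.
#'
#' @return A tibble with columns `theme`, `category`
#'   (`cohesion`/`trap`/`neutral`), `gold_label`, `text`, `text_past`.
#' @export
template_bank <- function() {
  th <- .COHESION_THEMES
  bank <- rbind(
    # -- cohesion themes -------------------------------------------------
    tpl(th[1], "cohesion", "cohesion",
        "Good for you, that must have been really difficult to do"),
    tpl(th[1], "cohesion", "cohesion",
        "You handled that {booster}well, keep going",
        "You handled that {booster}well, you kept going"),
    tpl(th[1], "cohesion", "cohesion",
        "Do not give up, we are all rooting for you"),
    tpl(th[2], "cohesion", "cohesion", "sending hugs"),
    tpl(th[2], "cohesion", "cohesion", "thanks everyone for your support <3"),
    tpl(th[2], "cohesion", "cohesion",
        "I feel {booster}supported by everyone here",
        "I felt {booster}supported by everyone here"),
    tpl(th[2], "cohesion", "cohesion", "thank you for your support and input"),
    tpl(th[3], "cohesion", "cohesion",
        "At my last treatment, I felt really scared, I didn't want to tell my family this. But I can tell this group"),
    tpl(th[3], "cohesion", "cohesion",
        "I trust this group {booster}deeply and can share anything here",
        "I trusted this group {booster}deeply and could share anything here"),
    tpl(th[4], "cohesion", "cohesion", "I am glad to be part of this group",
        "I was glad to be part of this group"),
    tpl(th[4], "cohesion", "cohesion",
        "I'm so glad I found this group"),
    tpl(th[4], "cohesion", "cohesion",
        "I {booster}belong here with all of you",
        "I {booster}belonged here with all of you"),
    tpl(th[5], "cohesion", "cohesion",
        "Thank you everyone, this is such a great group."),
    tpl(th[5], "cohesion", "cohesion",
        "thank you all {booster}for being here every week"),
    tpl(th[6], "cohesion", "cohesion",
        "It is amazing how much we all have in common"),
    tpl(th[6], "cohesion", "cohesion", "we are friends"),
    tpl(th[6], "cohesion", "cohesion",
        "we have been through {booster}similar things, it helps to share",
        "we went through {booster}similar things, it helped to share"),
    tpl(th[7], "cohesion", "cohesion",
        "This group has been a great resource venue for meeting and I will continue down the road with fond memories of the time spent here"),
    tpl(th[7], "cohesion", "cohesion", "A very good chat session"),
    tpl(th[7], "cohesion", "cohesion", "time went by fast!"),
    tpl(th[8], "cohesion", "cohesion", "I can't wait to chat with you all next week"),
    tpl(th[8], "cohesion", "cohesion", "thinking of you all!"),
    tpl(th[8], "cohesion", "cohesion",
        "I am going to miss this group",
        "I missed this group {booster}last week"),
    # -- traps -----------------------------------------------------------
    tpl(.TRAP_THEMES["false_we"], "trap", "non_cohesion",
        "When I mentioned that last week, when we all said what our situations were, no one even acknowledged it. I was very hurt by that"),
    tpl(.TRAP_THEMES["false_we"], "trap", "non_cohesion",
        "we waited two hours at the clinic and nobody told us anything"),
    tpl(.TRAP_THEMES["outside_support"], "trap", "non_cohesion",
        "When I put my things in order I involved my children and as challenging and emotional as it was it made it easier for me and for them - we laughed and cried but it really made me feel supported"),
    tpl(.TRAP_THEMES["outside_support"], "trap", "non_cohesion",
        "My husband has been {booster}supportive at home, my family helps me through it",
        "My husband was {booster}supportive at home, my family helped me through it"),
    tpl(.TRAP_THEMES["outside_support"], "trap", "non_cohesion",
        "my friends from work sent flowers, they support me a lot"),
    tpl(.TRAP_THEMES["negated_cohesion"], "trap", "non_cohesion",
        "I don't feel supported by this group",
        "I didn't feel supported by this group"),
    tpl(.TRAP_THEMES["negated_cohesion"], "trap", "non_cohesion",
        "honestly there is no sense of belonging here for me"),
    tpl(.TRAP_THEMES["negated_cohesion"], "trap", "non_cohesion",
        "we are not close at all, nothing in common"),
    tpl(.TRAP_THEMES["idiom_cohesion"], "trap", "cohesion",
        "been there, am there... got the t-shirt"),
    tpl(.TRAP_THEMES["idiom_cohesion"], "trap", "cohesion",
        "I hope you don't think you've been placed in a hot seat. It's just that I missed you and worried about you."),
    tpl(.TRAP_THEMES["empathy_no_we"], "trap", "cohesion",
        "I am with you, be strong please"),
    tpl(.TRAP_THEMES["empathy_no_we"], "trap", "cohesion",
        "I can relate"),
    tpl(.TRAP_THEMES["empathy_no_we"], "trap", "cohesion",
        "I feel the same way"),
    tpl(.TRAP_THEMES["empathy_no_we"], "trap", "cohesion",
        "Are you going to be alright? I want you to know how much I appreciate your presence."),
    tpl(.TRAP_THEMES["missing_we"], "trap", "cohesion",
        "I am sure there will be a sense of connection, so much sharing already"),
    tpl(.TRAP_THEMES["missing_we"], "trap", "cohesion",
        "I am sure I will think of you often"),
    tpl(.TRAP_THEMES["missing_we"], "trap", "cohesion",
        "I feel like I've suddenly inherited a whole group of sisters."),
    # -- neutral session chatter ----------------------------------------
    tpl("neutral", "neutral", "non_cohesion",
        "my scan is scheduled for thursday morning",
        "my scan was scheduled for thursday morning"),
    tpl("neutral", "neutral", "non_cohesion",
        "the new medication makes me {booster}tired in the afternoon",
        "the new medication made me {booster}tired in the afternoon"),
    tpl("neutral", "neutral", "non_cohesion",
        "has anyone tried the breathing exercise from the reading?"),
    tpl("neutral", "neutral", "non_cohesion",
        "I have a question about the homework for this week"),
    tpl("neutral", "neutral", "non_cohesion",
        "sorry I'm late, my computer froze again"),
    tpl("neutral", "neutral", "non_cohesion",
        "the nurse said the side effects should settle down"),
    tpl("neutral", "neutral", "non_cohesion",
        "my appointment got moved to next month"),
    tpl("neutral", "neutral", "non_cohesion",
        "I am reading chapter three tonight",
        "I was reading chapter three last night"),
    tpl("neutral", "neutral", "non_cohesion",
        "it snowed here all day today"),
    tpl("neutral", "neutral", "non_cohesion",
        "the parking at the hospital is {booster}expensive"),
    tpl("neutral", "neutral", "non_cohesion",
        "let me type that again, autocorrect changed it"),
    tpl("neutral", "neutral", "non_cohesion",
        "tonight's topic is managing fatigue, please open the handout"),
    tpl("neutral", "neutral", "non_cohesion",
        "please take a moment to write down one worry from this week"),
    tpl("neutral", "neutral", "non_cohesion",
        "my head is swirling with all the appointments")
  )
  tibble::as_tibble(bank)
}

.BOOSTER_FILLS <- c("very ", "really ", "so much ", "truly ", "incredibly ")

#' Render one template variant
#'
#' @param template One row of [template_bank()] (or a list with `text`,
#'   `text_past`).
#' @param booster Replacement for the `{booster}` slot (`""` drops it).
#' @param tense `"present"` or `"past"`; falls back to the base text when no
#'   past variant exists.
#' @return A single non-empty string.
#' @export
render_template <- function(template, booster = "", tense = "present") {
  txt <- if (identical(tense, "past") && !is.na(template$text_past))
    template$text_past else template$text
  out <- gsub("{booster}", booster, txt, fixed = TRUE)
  gsub("[ ]+", " ", trimws(out))
}

#' Generator configuration for synthetic transcripts
#'
#' @param n_sessions Number of 90-minute sessions.
#' @param messages_per_session Posts per session.
#' @param cohesion_rate Probability that a post's gold label is cohesion.
#' @param trap_rate Fraction of posts drawn from trap templates (hard
#'   positives/negatives); `cohesion_rate + trap_rate` must be `<= 1` so both
#'   can be realised as marginal rates.
#' @param session_duration Session length in minutes.
#' @param n_participants Group members per session (a facilitator posts in
#'   addition, 1 post in 10).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `gen_config`.
#' @export
gen_config <- function(n_sessions = 1L, messages_per_session = 100L,
                       cohesion_rate = 0.2, trap_rate = 0.1,
                       session_duration = 90, n_participants = 8L,
                       seed = 1L) {
  n_sessions <- check_count(n_sessions, "n_sessions")
  messages_per_session <- check_count(messages_per_session, "messages_per_session")
  n_participants <- check_count(n_participants, "n_participants")
  check_prob(cohesion_rate, "cohesion_rate")
  check_prob(trap_rate, "trap_rate")
  if (cohesion_rate + trap_rate > 1)
    abort_field("trap_rate", "cohesion_rate + trap_rate must be <= 1")
  if (!is.numeric(session_duration) || session_duration <= 0)
    abort_field("session_duration", "must be a positive number of minutes")
  structure(
    list(n_sessions = n_sessions, messages_per_session = messages_per_session,
         cohesion_rate = cohesion_rate, trap_rate = trap_rate,
         session_duration = session_duration, n_participants = n_participants,
         seed = as.integer(seed)),
    class = "gen_config"
  )
}

#' Generate a labeled synthetic transcript corpus
#'
#' Draws each post's gold label as Bernoulli(`cohesion_rate`) and,
#' independently, whether it comes from a trap template
#' (Bernoulli(`trap_rate`)); trap templates are then sampled on the matching
#' label side, so the marginal cohesion fraction converges to
#' `cohesion_rate` while `trap_rate` of posts remain adversarial.
#' Timestamps are uniform order statistics over the session (seconds,
#' rounded to 1 ms), participants are assigned uniformly, and every tenth
#' post comes from the therapist.
#'
#' @param config A [gen_config()].
#' @return A tibble of labeled messages: `session_id`, `message_id`,
#'   `participant_id`, `timestamp` (seconds from session start), `text`,
#'   `role`, `gold_label`, `theme`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  bank <- template_bank()
  coh_bank <- bank[bank$category == "cohesion", ]
  trap_pos <- bank[bank$category == "trap" & bank$gold_label == "cohesion", ]
  trap_neg <- bank[bank$category == "trap" & bank$gold_label == "non_cohesion", ]
  neutral <- bank[bank$category == "neutral", ]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  out <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    m <- config$messages_per_session
    session_id <- sprintf("S%03d", s)
    ts <- round(sort(stats::runif(m, 0, config$session_duration * 60)), 3)
    is_coh <- stats::runif(m) < config$cohesion_rate
    is_trap <- stats::runif(m) < config$trap_rate
    part <- sprintf("P%02d", sample.int(config$n_participants, m, replace = TRUE))
    role <- rep("participant", m)
    therapist <- (seq_len(m) - 1L) %% 10L == 0L
    role[therapist] <- "therapist"
    part[therapist] <- "T01"

    text <- character(m); theme <- character(m); gold <- character(m)
    for (i in seq_len(m)) {
      pool <- if (is_coh[i] && is_trap[i]) trap_pos
        else if (is_coh[i]) coh_bank
        else if (is_trap[i]) trap_neg
        else neutral
      row <- pool[sample.int(nrow(pool), 1L), ]
      booster <- if (stats::runif(1) < 0.3) sample(.BOOSTER_FILLS, 1L) else ""
      tense <- if (!is.na(row$text_past) && stats::runif(1) < 0.25) "past" else "present"
      text[i] <- render_template(row, booster = booster, tense = tense)
      theme[i] <- if (row$category == "neutral") NA_character_ else row$theme
      gold[i] <- row$gold_label
    }
    out[[s]] <- tibble::tibble(
      session_id = session_id,
      message_id = sprintf("%s-M%04d", session_id, seq_len(m)),
      participant_id = part,
      timestamp = ts,
      text = text,
      role = role,
      gold_label = gold,
      theme = theme
    )
  }
  do.call(rbind, out)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write / read a corpus as JSON Lines
#'
#' One message object per line, UTF-8, snake_case keys; `NA` themes are
#' serialised as `null`. The same-seed generator output round-trips
#' byte-identically.
#'
#' @param corpus Tibble as returned by [generate_corpus()].
#' @param path Output file.
#' @return `write_corpus_jsonl()` returns `path` invisibly;
#'   `read_corpus_jsonl()` returns the corpus tibble.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(is.data.frame(corpus), nrow(corpus) >= 0)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(as.list(corpus[i, ]), auto_unbox = TRUE, digits = NA,
                     na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x$theme <- if (is.null(x$theme)) NA_character_ else x$theme
    tibble::as_tibble(x)
  })
  do.call(rbind, rows)
}

#' Write the companion gold-label CSV
#'
#' @param corpus Labeled corpus tibble.
#' @param path Output CSV (`message_id`, `gold_label`, `theme`).
#' @export
write_gold_csv <- function(corpus, path) {
  utils::write.csv(corpus[, c("message_id", "gold_label", "theme")], path,
                   row.names = FALSE, na = "")
  invisible(path)
}
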