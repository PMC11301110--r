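# Tokenisation and message-level linguistic flags.
#
# The downstream rule layer needs only coarse linguistic evidence per message:
# did any verb look past-tense, is a negation cue present, which grammatical
# persons occur, how many intensity boosters. A closed-vocabulary rule
# tokenizer and tagger keeps this fully deterministic and dependency-free.

# emoticons are passed through as single tokens, never split
.EMOTICON_RE <- "<3|:-?[)(dp/]|;-?\\)|:'\\("

# irregular simple-past forms (coarse list; suffix rule handles regular verbs)
.IRREGULAR_PAST <- c(
  "was", "were", "had", "did", "said", "went", "got", "made", "knew",
  "thought", "came", "took", "saw", "found", "gave", "told", "felt",
  "became", "left", "put", "meant", "kept", "began", "brought", "wrote",
  "stood", "heard", "ran", "paid", "met", "sat", "spoke", "led", "grew",
  "lost", "fell", "sent", "built", "understood", "drew", "broke", "spent",
  "rose", "sold", "chose", "dealt", "fought", "threw", "caught", "taught",
  "wore", "shook", "held", "lay", "woke"
)

.PAST_PARTICIPLE <- c(
  "been", "done", "gone", "seen", "known", "taken", "given", "gotten",
  "written", "spoken", "broken", "chosen", "fallen", "forgotten", "hidden",
  "eaten", "driven", "risen", "worn", "drawn", "grown", "thrown", "shown",
  "flown", "beaten", "begun"
)

# words ending in -ed that are not past-tense verbs
.ED_EXCEPTIONS <- c(
  "indeed", "hundred", "sacred", "naked", "wicked", "hatred", "feed",
  "seed", "weed", "speed", "bleed", "breed", "creed", "greed", "shed",
  "shred", "embed", "proceed", "succeed", "exceed", "agreed"
)

#' Tokenize a chat message
#'
#' Lowercases, keeps emoticons (`<3`, `:)`, ...) intact, emits punctuation as
#' separate tokens, and splits clitics Penn-style (`don't` -> `do`, `n't`;
#' `we're` -> `we`, `'re`) so pronoun and negation lists match cleanly.
#'
#' @param text A single character string.
#' @return Character vector of lowercase tokens.
#' @export
#' @examples
#' tokenize("We're glad you're here! <3")
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(text)
  pat <- paste0(.EMOTICON_RE,
                "|[a-z0-9]+(?:'[a-z]+)?|'[a-z]+|[^a-z0-9[:space:]]")
  toks <- regmatches(x, gregexpr(pat, x, perl = TRUE))[[1]]
  if (length(toks) == 0L) return(character())
  split_clitics(toks)
}

split_clitics <- function(toks) {
  out <- vector("list", length(toks))
  clitics <- c("'ll", "'re", "'ve", "'m", "'d", "'s")
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (grepl("n't$", tk) && nchar(tk) > 3L) {
      out[[i]] <- c(substr(tk, 1L, nchar(tk) - 3L), "n't")
    } else {
      hit <- clitics[endsWith(tk, clitics)]
      if (length(hit) == 1L && nchar(tk) > nchar(hit)) {
        out[[i]] <- c(substr(tk, 1L, nchar(tk) - nchar(hit)), hit)
      } else {
        out[[i]] <- tk
      }
    }
  }
  unlist(out, use.names = FALSE)
}

# coarse per-token tags: PRP pronouns, VBD simple past, VBN past participle,
# EMOT emoticons, PUNCT punctuation, WORD everything else
tag_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character())
  pron <- c(
    shipped_terms("pronouns_first_singular"),
    shipped_terms("pronouns_first_plural"),
    shipped_terms("pronouns_second"),
    shipped_terms("pronouns_third")
  )
  vapply(tokens, function(tk) {
    if (grepl(paste0("^(", .EMOTICON_RE, ")$"), tk)) return("EMOT")
    if (grepl("^[^a-z0-9']", tk)) return("PUNCT")
    if (tk %in% pron) return("PRP")
    if (tk %in% .IRREGULAR_PAST) return("VBD")
    if (tk %in% .PAST_PARTICIPLE) return("VBN")
    if (endsWith(tk, "ed") && nchar(tk) > 3L && !(tk %in% .ED_EXCEPTIONS))
      return("VBD")
    "WORD"
  }, character(1), USE.NAMES = FALSE)
}

# count occurrences of (possibly multiword) phrases in a token stream
count_phrase_hits <- function(tokens, phrases) {
  if (length(tokens) == 0L || length(phrases) == 0L) return(0L)
  total <- 0L
  for (ph in phrases) {
    ptoks <- strsplit(ph, " +")[[1]]
    np <- length(ptoks)
    if (np > length(tokens)) next
    if (np == 1L) {
      total <- total + sum(tokens == ptoks)
    } else {
      for (s in seq_len(length(tokens) - np + 1L)) {
        if (all(tokens[s:(s + np - 1L)] == ptoks)) total <- total + 1L
      }
    }
  }
  total
}

#' Derive linguistic flags for one message
#'
#' Computes the evidence consumed by the rule-based score adjustment:
#' tokens with aligned coarse part-of-speech tags, a past-tense flag (any
#' simple-past or past-participle verb), a message-level negation flag,
#' grammatical-person detection from closed pronoun lists, an intensity
#' booster count, and a question flag. `first_person` is `TRUE` only when a
#' first-person pronoun occurs and no second- or third-person pronoun does.
#'
#' @param text A single non-empty character string.
#' @return An object of class `linguistic_flags`: a list with elements
#'   `tokens`, `pos_tags`, `has_past_tense`, `has_negation`, `person`,
#'   `first_person`, `intensifier_count`, `is_question`.
#' @export
#' @examples
#' analyze("I was very scared")
analyze <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    abort_field("text", "must be a single non-empty string")
  tokens <- tokenize(text)
  tags <- tag_tokens(tokens)

  person <- character()
  if (any(tokens %in% shipped_terms("pronouns_first_singular"))) person <- c(person, "first_singular")
  if (any(tokens %in% shipped_terms("pronouns_first_plural")))   person <- c(person, "first_plural")
  if (any(tokens %in% shipped_terms("pronouns_second")))         person <- c(person, "second")
  if (any(tokens %in% shipped_terms("pronouns_third")))          person <- c(person, "third")

  first_person <- any(c("first_singular", "first_plural") %in% person) &&
    !any(c("second", "third") %in% person)

  flags <- list(
    tokens = tokens,
    pos_tags = tags,
    has_past_tense = any(tags %in% c("VBD", "VBN")),
    has_negation = count_phrase_hits(tokens, shipped_terms("negation")) > 0L,
    person = person,
    first_person = first_person,
    intensifier_count = count_phrase_hits(tokens, shipped_terms("boosters")),
    is_question = any(tokens == "?")
  )
  class(flags) <- "linguistic_flags"
  flags
}

#' @export
print.linguistic_flags <- function(x, ...) {
  cat("<linguistic_flags> ", length(x$tokens), " tokens; past=",
      x$has_past_tense, " neg=", x$has_negation,
      " person={", paste(x$person, collapse = ","), "}",
      " boosters=", x$intensifier_count, "\n", sep = "")
  invisible(x)
}

#' Take every k-th element of a transcript
#'
#' Systematic sampling in transcript order: positions 1, 1+k, 1+2k, ...
#' (the first message is always included), yielding `ceiling(n / k)`
#' elements. With `k = 5` this is the "score every fifth message" protocol
#' used for human evaluation.
#'
#' @param messages A vector, list, or data frame (rows are messages).
#' @param k Positive integer stride.
#' @return Object of the same type holding the sampled elements/rows.
#' @export
sample_every_kth <- function(messages, k) {
  k <- check_count(k, "k", min = 1L)
  n <- if (is.data.frame(messages)) nrow(messages) else length(messages)
  if (n == 0L) return(messages)
  idx <- seq.int(1L, n, by = k)
  if (is.data.frame(messages)) messages[idx, , drop = FALSE] else messages[idx]
}
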