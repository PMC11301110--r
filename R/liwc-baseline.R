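# Dictionary-category baseline (closed-vocabulary, LIWC-style).
#
# The proprietary dictionary cannot be shipped, so the package bundles a
# small open stand-in in the same wildcard format and accepts user-supplied
# .dic files. A message is labeled cohesion when at least 3 of the 5
# categories {we, positive_emotion, family, friend, affiliation} register a
# match -- a deliberately keyword-bound rule that serves as the comparison
# point for the learned ensemble.

.BASELINE_CATEGORIES <- c("we", "positive_emotion", "family", "friend",
                          "affiliation")

#' Load a category dictionary file
#'
#' Format: `%CAT <name>` header lines, then one lowercase pattern per line;
#' a trailing `*` makes the pattern a prefix wildcard. All five baseline
#' categories must be present.
#'
#' @param path Dictionary file; defaults to the shipped synthetic stand-in
#'   (open word lists, not the proprietary tool's dictionary).
#' @return Named list of class `category_dictionary`: category -> character
#'   vector of patterns.
#' @export
load_dictionary <- function(path = NULL) {
  if (is.null(path)) path <- osg_extdata("dictionaries", "cohesion_standin.dic")
  if (!file.exists(path)) stop("dictionary file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  dicts <- list()
  current <- NULL
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l) || startsWith(l, "#")) next
    if (startsWith(l, "%")) {
      parts <- strsplit(l, "[[:space:]]+")[[1]]
      if (length(parts) != 2L || parts[1] != "%CAT")
        stop(sprintf("malformed category header at line %d: '%s'", i, l),
             call. = FALSE)
      current <- parts[2]
      dicts[[current]] <- character()
    } else {
      if (is.null(current))
        stop(sprintf("pattern before any %%CAT header at line %d: '%s'", i, l),
             call. = FALSE)
      if (l != tolower(l))
        stop(sprintf("pattern must be lowercase at line %d: '%s'", i, l),
             call. = FALSE)
      dicts[[current]] <- c(dicts[[current]], l)
    }
  }
  missing <- setdiff(.BASELINE_CATEGORIES, names(dicts))
  if (length(missing) > 0L)
    stop("dictionary is missing required categories: ",
         paste(missing, collapse = ", "), call. = FALSE)
  empty <- names(dicts)[vapply(dicts, length, integer(1)) == 0L]
  if (length(empty) > 0L)
    stop("dictionary categories with no entries: ",
         paste(empty, collapse = ", "), call. = FALSE)
  structure(dicts, class = "category_dictionary")
}

# does token match pattern (trailing * = prefix wildcard)?
match_pattern <- function(tokens, pattern) {
  if (endsWith(pattern, "*")) {
    startsWith(tokens, substr(pattern, 1L, nchar(pattern) - 1L))
  } else {
    tokens == pattern
  }
}

#' Classify one message with the dictionary baseline
#'
#' Computes, per category, the percentage of message tokens matching any of
#' the category's patterns; a category is met when its percentage exceeds
#' 0, and the message is labeled cohesion when at least 3 of the 5
#' categories are met.
#'
#' @param text A single non-empty string.
#' @param dictionaries A `category_dictionary` (default: shipped stand-in).
#' @return List of class `category_profile`: `percentages` (named, in
#'   `[0, 100]`), `met` (named logical), `n_met`, `label`.
#' @export
classify_baseline <- function(text, dictionaries = load_dictionary()) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    abort_field("text", "must be a single non-empty string")
  stopifnot(inherits(dictionaries, "category_dictionary"))
  toks <- tokenize(text)
  words <- toks[grepl("^[a-z0-9']", toks)]  # token count excludes punctuation
  n <- length(words)
  pct <- vapply(.BASELINE_CATEGORIES, function(cat) {
    pats <- dictionaries[[cat]]
    hit <- rep(FALSE, n)
    for (p in pats) hit <- hit | match_pattern(words, p)
    if (n == 0L) 0 else 100 * sum(hit) / n
  }, numeric(1))
  met <- pct > 0
  structure(list(
    percentages = pct,
    met = met,
    n_met = sum(met),
    label = if (sum(met) >= 3L) .POSITIVE else .NEGATIVE
  ), class = "category_profile")
}

#' Run the dictionary baseline over a transcript
#'
#' @param messages Data frame with `text` (and optionally `message_id`), or
#'   a character vector.
#' @param dictionaries A `category_dictionary`.
#' @return Tibble: `message_id`, one percentage column per category,
#'   `n_met`, `label`.
#' @export
baseline_transcript <- function(messages, dictionaries = load_dictionary()) {
  if (is.character(messages)) messages <- tibble::tibble(text = messages)
  ids <- if ("message_id" %in% names(messages)) messages$message_id else
    sprintf("M%04d", seq_len(nrow(messages)))
  rows <- lapply(seq_len(nrow(messages)), function(i) {
    pr <- classify_baseline(messages$text[[i]], dictionaries)
    c(as.list(pr$percentages), list(n_met = pr$n_met, label = pr$label))
  })
  out <- tibble::as_tibble(do.call(rbind.data.frame, rows))
  tibble::add_column(out, message_id = ids, .before = 1)
}
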