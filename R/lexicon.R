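# Word embeddings and seed-lexicon expansion.
#
# Seed cohesion keywords ("we", "us", "our group", theme phrases) are
# expanded into contextually similar expressions by querying a word
# embedding trained on the session corpus. The embedding is a positive
# pointwise-mutual-information (PPMI) co-occurrence matrix factorised by
# truncated SVD — the count-based factorisation that window-based neural
# embeddings implicitly perform — which makes training exactly reproducible.

#' Embedding configuration
#'
#' @param dimension Vector length per term.
#' @param window Symmetric co-occurrence window in tokens.
#' @param min_count Minimum corpus frequency for a term to enter the
#'   vocabulary.
#' @param epochs Accepted for interface stability; the factorisation is
#'   single-pass and deterministic, so it has no effect.
#' @param seed Integer; kept for interface stability (no stochastic step).
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(dimension = 100L, window = 10L, min_count = 2L,
                             epochs = 5L, seed = 0L) {
  structure(list(
    dimension = check_count(dimension, "dimension"),
    window = check_count(window, "window"),
    min_count = check_count(min_count, "min_count"),
    epochs = check_count(epochs, "epochs"),
    seed = as.integer(seed)
  ), class = "embedding_config")
}

#' Train word embeddings on a tokenised corpus
#'
#' Builds the symmetric within-window co-occurrence matrix over all terms
#' with frequency at least `min_count`, transforms it to PPMI, and takes the
#' top-`dimension` SVD factors (`U sqrt(S)`), zero-padded when the corpus
#' supports fewer dimensions. Deterministic: singular-vector signs are fixed
#' so repeated runs agree exactly.
#'
#' @param corpus A list of token vectors, or a character vector of raw texts
#'   (tokenised with [tokenize()]).
#' @param config An [embedding_config()].
#' @return Object of class `word_embeddings`: list with `vectors` (terms x
#'   dimension matrix), `freq`, `config`.
#' @export
train_embeddings <- function(corpus, config = embedding_config()) {
  stopifnot(inherits(config, "embedding_config"))
  if (is.character(corpus)) corpus <- lapply(corpus, tokenize)
  stopifnot(is.list(corpus))
  freq <- table(unlist(corpus, use.names = FALSE))
  vocab <- names(freq)[freq >= config$min_count]
  if (length(vocab) < 2L)
    stop("vocabulary has fewer than 2 terms after the min_count filter",
         call. = FALSE)
  vocab <- sort(vocab)
  idx <- stats::setNames(seq_along(vocab), vocab)

  acc_i <- vector("list", length(corpus))
  acc_j <- vector("list", length(corpus))
  for (k in seq_along(corpus)) {
    sent <- corpus[[k]]
    s <- idx[sent[sent %in% vocab]]
    n <- length(s)
    if (n < 2L) next
    pi <- vector("list", min(config$window, n - 1L))
    pj <- pi
    for (d in seq_len(min(config$window, n - 1L))) {
      a <- s[seq_len(n - d)]
      b <- s[seq.int(d + 1L, n)]
      pi[[d]] <- c(a, b); pj[[d]] <- c(b, a)
    }
    acc_i[[k]] <- unlist(pi, use.names = FALSE)
    acc_j[[k]] <- unlist(pj, use.names = FALSE)
  }
  ii <- unlist(acc_i, use.names = FALSE)
  jj <- unlist(acc_j, use.names = FALSE)
  if (length(ii) == 0L)
    stop("no within-window co-occurrences in the corpus", call. = FALSE)
  co <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                             dims = c(length(vocab), length(vocab)))
  co <- as.matrix(co)
  total <- sum(co)
  rs <- rowSums(co)
  pmi <- log((co * total) / outer(rs, rs))
  pmi[!is.finite(pmi) | pmi < 0] <- 0

  k <- min(config$dimension, nrow(pmi))
  sv <- svd(pmi, nu = k, nv = 0)
  d <- sv$d[seq_len(k)]
  U <- sv$u
  # fix the sign convention so decomposition is reproducible across BLAS
  for (c in seq_len(k)) {
    piv <- which.max(abs(U[, c]))
    if (U[piv, c] < 0) U[, c] <- -U[, c]
  }
  vec <- U %*% diag(sqrt(pmax(d, 0)), nrow = k)
  if (k < config$dimension)
    vec <- cbind(vec, matrix(0, nrow(vec), config$dimension - k))
  rownames(vec) <- vocab
  structure(list(vectors = vec, freq = as.integer(freq[vocab]),
                 config = config),
            class = "word_embeddings")
}

#' @export
print.word_embeddings <- function(x, ...) {
  cat("<word_embeddings> ", nrow(x$vectors), " terms x ",
      ncol(x$vectors), " dims\n", sep = "")
  invisible(x)
}

#' Embedding vector for a (possibly multiword) expression
#'
#' Multiword expressions are embedded as the mean of their in-vocabulary
#' token vectors.
#'
#' @param model A `word_embeddings` object.
#' @param expression A single string.
#' @return Numeric vector, or `NULL` when no token is in vocabulary.
#' @export
embedding_vector <- function(model, expression) {
  stopifnot(inherits(model, "word_embeddings"))
  toks <- tokenize(expression)
  toks <- toks[toks %in% rownames(model$vectors)]
  if (length(toks) == 0L) return(NULL)
  v <- model$vectors[toks, , drop = FALSE]
  colMeans(v)
}

#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`; 0 when either vector is all-zero.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# cosine of one query against every vocabulary term
.cosine_all <- function(model, v) {
  M <- model$vectors
  norms <- sqrt(rowSums(M * M))
  qn <- sqrt(sum(v * v))
  sims <- as.numeric(M %*% v) / (norms * qn)
  sims[!is.finite(sims)] <- 0
  stats::setNames(sims, rownames(M))
}

#' Default seed lexicon of cohesion expressions
#'
#' Maps the eight scoring-guide themes to seed keywords and phrases,
#' including the core "we-talk" markers `us`, `we`, `our group`.
#'
#' @return Named list: theme -> character vector of expressions.
#' @export
default_seed_lexicon <- function() {
  list(
    "Reassurance among peers" = c("good for you", "keep going", "be strong"),
    "Expressing support/feeling supported" = c("support", "supported", "sending hugs"),
    "Deepening emotional disclosure and trust" = c("trust", "tell this group", "share"),
    "Sense of belonging" = c("us", "we", "our group", "belong", "part of this group"),
    "Gratitude for the group and peers" = c("thank you", "thanks", "great group"),
    "Shared experiences" = c("in common", "we are friends", "similar"),
    "Reflecting on the positive aspects of the group" = c("good chat", "fond memories"),
    "Anticipating future groups/chats" = c("next week", "miss this group", "thinking of you")
  )
}

#' Expand seed expressions into a cohesion lexicon
#'
#' Each seed expression is embedded (multiword seeds as token-mean vectors)
#' and the vocabulary is ranked by cosine similarity; up to `top_k`
#' neighbours with similarity at least `min_similarity` are added per seed.
#' Seed tokens themselves are never returned as expansions, and expansions
#' are deduplicated across seeds keeping the most similar attribution.
#' Seeds with no in-vocabulary token are skipped with a warning; if none
#' survives, expansion fails.
#'
#' @param model A `word_embeddings` object.
#' @param seeds Named list (theme -> expressions) such as
#'   [default_seed_lexicon()], or a character vector of expressions.
#' @param top_k Maximum expansions per seed.
#' @param min_similarity Cosine threshold for keeping an expansion.
#' @return Object of class `cohesion_lexicon`: list with `seeds`, `expanded`
#'   (tibble `expression`, `nearest_seed`, `similarity`, `provenance`), and
#'   `config`.
#' @export
expand_seeds <- function(model, seeds = default_seed_lexicon(),
                         top_k = 10L, min_similarity = 0.5) {
  stopifnot(inherits(model, "word_embeddings"))
  top_k <- check_count(top_k, "top_k", min = 0L)
  if (is.character(seeds)) seeds <- list(seeds = seeds)
  seed_exprs <- unique(unlist(seeds, use.names = FALSE))
  seed_tokens <- unique(unlist(lapply(seed_exprs, tokenize)))

  rows <- list()
  n_in_vocab <- 0L
  for (expr in seed_exprs) {
    v <- embedding_vector(model, expr)
    if (is.null(v)) {
      warning(sprintf("seed '%s' has no in-vocabulary token; skipped", expr),
              call. = FALSE)
      next
    }
    n_in_vocab <- n_in_vocab + 1L
    if (top_k == 0L) next
    sims <- .cosine_all(model, v)
    sims <- sims[!(names(sims) %in% seed_tokens)]
    sims <- sort(sims, decreasing = TRUE)
    keep <- sims[sims >= min_similarity]
    keep <- utils::head(keep, top_k)
    if (length(keep) > 0L)
      rows[[expr]] <- tibble::tibble(expression = names(keep),
                                     nearest_seed = expr,
                                     similarity = as.numeric(keep))
  }
  if (n_in_vocab == 0L)
    stop("no seed expression has an in-vocabulary token", call. = FALSE)

  expanded <- if (length(rows) > 0L) do.call(rbind, rows) else
    tibble::tibble(expression = character(), nearest_seed = character(),
                   similarity = numeric())
  if (nrow(expanded) > 0L) {
    expanded <- expanded[order(-expanded$similarity), ]
    expanded <- expanded[!duplicated(expanded$expression), ]
  }
  expanded$provenance <- rep("expanded", nrow(expanded))

  structure(list(
    seeds = seeds,
    expanded = tibble::as_tibble(expanded),
    config = list(top_k = top_k, min_similarity = min_similarity)
  ), class = "cohesion_lexicon")
}

#' @export
print.cohesion_lexicon <- function(x, ...) {
  cat("<cohesion_lexicon> ", length(unlist(x$seeds)), " seed expressions, ",
      nrow(x$expanded), " expansions\n", sep = "")
  invisible(x)
}

#' All matchable expressions in a cohesion lexicon
#'
#' @param lexicon A `cohesion_lexicon`.
#' @return Character vector: seed expressions plus expansions (lowercase).
#' @export
lexicon_terms <- function(lexicon) {
  stopifnot(inherits(lexicon, "cohesion_lexicon"))
  tolower(unique(c(unlist(lexicon$seeds, use.names = FALSE),
                   lexicon$expanded$expression)))
}

#' Append human-supplied expressions to a lexicon
#'
#' Used by the active-learning loop: terms recovered from false negatives
#' are added with provenance `human_added`; duplicates are ignored.
#'
#' @param lexicon A `cohesion_lexicon`.
#' @param terms Character vector of expressions.
#' @return The updated lexicon.
#' @export
lexicon_add_human <- function(lexicon, terms) {
  stopifnot(inherits(lexicon, "cohesion_lexicon"))
  terms <- setdiff(tolower(unique(terms)), lexicon_terms(lexicon))
  if (length(terms) > 0L) {
    lexicon$expanded <- rbind(
      lexicon$expanded,
      tibble::tibble(expression = terms, nearest_seed = NA_character_,
                     similarity = NA_real_, provenance = "human_added")
    )
  }
  lexicon
}

#' Serialise / load a cohesion lexicon as JSON
#'
#' @param lexicon A `cohesion_lexicon`.
#' @param path File path.
#' @return `write_lexicon_json()` returns `path` invisibly;
#'   `read_lexicon_json()` the lexicon.
#' @export
write_lexicon_json <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "cohesion_lexicon"))
  payload <- list(seeds = lexicon$seeds,
                  expanded = lexicon$expanded,
                  config = lexicon$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_lexicon_json
#' @export
read_lexicon_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  expanded <- tibble::as_tibble(x$expanded)
  if (nrow(expanded) == 0L)
    expanded <- tibble::tibble(expression = character(),
                               nearest_seed = character(),
                               similarity = numeric(),
                               provenance = character())
  structure(list(seeds = lapply(x$seeds, as.character),
                 expanded = expanded,
                 config = x$config),
            class = "cohesion_lexicon")
}
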