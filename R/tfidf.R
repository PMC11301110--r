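# TF-IDF n-gram featurisation (unigrams + bigrams, capped vocabulary).

# feature tokens: words and emoticons; bare punctuation is dropped
feature_tokens <- function(text) {
  toks <- tokenize(text)
  toks[grepl("^[a-z0-9']|^<3|^[:;]", toks)]
}

ngram_terms <- function(toks, ngram_max = 2L) {
  out <- toks
  if (ngram_max >= 2L && length(toks) >= 2L) {
    big <- paste(toks[-length(toks)], toks[-1L])
    out <- c(out, big)
  }
  out
}

#' Feature-extraction configuration
#'
#' @param max_features Vocabulary cap over unigrams + bigrams (most frequent
#'   kept; ties broken lexicographically).
#' @param ngram_max Highest n-gram order (2 = unigrams and bigrams).
#' @param lexicon_feature Append one engineered feature counting cohesion-
#'   lexicon phrase matches in the message.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(max_features = 5000L, ngram_max = 2L,
                           lexicon_feature = TRUE) {
  structure(list(
    max_features = check_count(max_features, "max_features"),
    ngram_max = check_count(ngram_max, "ngram_max"),
    lexicon_feature = isTRUE(lexicon_feature)
  ), class = "feature_config")
}

#' Fit a TF-IDF vectorizer
#'
#' Builds the capped unigram+bigram vocabulary on the training texts and the
#' smoothed inverse document frequencies `log((1 + N) / (1 + df)) + 1`.
#' Document vectors are L2-normalised. When a cohesion lexicon is supplied
#' (and enabled in the config), one extra column holds `log(1 + phrase
#' hits)` of lexicon expressions in the message.
#'
#' @param texts Character vector of training texts.
#' @param config A [feature_config()].
#' @param lexicon Optional `cohesion_lexicon` for the engineered feature.
#' @return Object of class `tfidf_vectorizer`.
#' @export
fit_tfidf <- function(texts, config = feature_config(), lexicon = NULL) {
  stopifnot(is.character(texts), length(texts) > 0L)
  docs <- lapply(texts, function(t) ngram_terms(feature_tokens(t), config$ngram_max))
  tf_all <- table(unlist(docs, use.names = FALSE))
  ord <- order(-as.integer(tf_all), names(tf_all))
  vocab <- names(tf_all)[ord]
  vocab <- utils::head(vocab, config$max_features)
  vocab <- sort(vocab)
  vidx <- stats::setNames(seq_along(vocab), vocab)

  df <- integer(length(vocab))
  for (d in docs) {
    hit <- unique(d[d %in% vocab])
    df[vidx[hit]] <- df[vidx[hit]] + 1L
  }
  n <- length(docs)
  idf <- log((1 + n) / (1 + df)) + 1

  lex_phrases <- NULL
  if (config$lexicon_feature && !is.null(lexicon))
    lex_phrases <- lapply(lexicon_terms(lexicon), tokenize)

  structure(list(vocab = vidx, idf = idf, config = config,
                 lex_phrases = lex_phrases),
            class = "tfidf_vectorizer")
}

#' Transform texts into the fitted TF-IDF feature space
#'
#' @param vectorizer A fitted `tfidf_vectorizer`.
#' @param texts Character vector.
#' @return A sparse `dgCMatrix`, one row per text; columns are the vocabulary
#'   (plus `.lexicon` when the engineered feature is enabled).
#' @export
transform_tfidf <- function(vectorizer, texts) {
  stopifnot(inherits(vectorizer, "tfidf_vectorizer"))
  vidx <- vectorizer$vocab
  n <- length(texts)
  ii <- list(); jj <- list(); xx <- list()
  lexcol <- numeric(n)
  for (i in seq_len(n)) {
    toks <- feature_tokens(texts[[i]])
    terms <- ngram_terms(toks, vectorizer$config$ngram_max)
    terms <- terms[terms %in% names(vidx)]
    if (length(terms) > 0L) {
      cnt <- table(terms)
      j <- vidx[names(cnt)]
      ii[[i]] <- rep.int(i, length(j)); jj[[i]] <- as.integer(j)
      xx[[i]] <- as.numeric(cnt) * vectorizer$idf[j]
    }
    if (!is.null(vectorizer$lex_phrases)) {
      hits <- 0L
      for (ph in vectorizer$lex_phrases)
        hits <- hits + count_phrase_hits(toks, paste(ph, collapse = " "))
      lexcol[i] <- log1p(hits)
    }
  }
  iv <- unlist(ii); jv <- unlist(jj); xv <- unlist(xx)
  X <- Matrix::sparseMatrix(
    i = if (is.null(iv)) integer(0) else iv,
    j = if (is.null(jv)) integer(0) else jv,
    x = if (is.null(xv)) numeric(0) else xv,
    dims = c(n, length(vidx)),
    dimnames = list(NULL, names(vidx))
  )
  norms <- sqrt(Matrix::rowSums(X^2))
  norms[norms == 0] <- 1
  X <- Matrix::Diagonal(x = 1 / norms) %*% X
  if (!is.null(vectorizer$lex_phrases))
    X <- cbind(X, Matrix::Matrix(lexcol, ncol = 1, dimnames = list(NULL, ".lexicon")))
  methods::as(X, "CsparseMatrix")
}
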