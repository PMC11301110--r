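# small deterministic corpus builder: "group" and "support" always share a
# window; "zzyzx" occurs rarely and far from "group"
co_occurring_corpus <- function(n = 200L) {
  base <- rep(c("the group gives support every week",
                "our group offers support and care",
                "group support helps members cope"), length.out = n)
  extra <- c("zzyzx appeared once more", "zzyzx again", "zzyzx here")
  lapply(c(base, extra), function(t) strsplit(t, " ")[[1]])
}

test_that("co-occurring terms sit closer in embedding space", {
  emb <- train_embeddings(co_occurring_corpus())
  vg <- embedding_vector(emb, "group")
  vs <- embedding_vector(emb, "support")
  vr <- embedding_vector(emb, "zzyzx")
  expect_gt(cosine_similarity(vg, vs), cosine_similarity(vg, vr))
})

test_that("embedding respects min_count, dimension and determinism", {
  corpus <- co_occurring_corpus(50L)
  emb <- train_embeddings(corpus, embedding_config(dimension = 100L))
  expect_equal(ncol(emb$vectors), 100L)
  # "once" appears a single time -> filtered at min_count = 2
  expect_false("once" %in% rownames(emb$vectors))
  expect_true("group" %in% rownames(emb$vectors))
  emb2 <- train_embeddings(corpus, embedding_config(dimension = 100L))
  expect_identical(emb$vectors, emb2$vectors)
  # self-similarity and range of cosines
  v <- emb$vectors[c("group", "support", "members"), ]
  for (i in 1:3) expect_equal(cosine_similarity(v[i, ], v[i, ]), 1,
                              tolerance = 1e-6)
  sims <- apply(v, 1, function(a) cosine_similarity(a, v[1, ]))
  expect_true(all(sims >= -1 - 1e-9 & sims <= 1 + 1e-9))
  expect_error(train_embeddings(list(c("solo"))), "vocabulary")
})

test_that("seed expansion finds planted synonyms and respects limits", {
  # plant "grp" as a distributional synonym of "group"
  sents <- c(rep("the group gives support every week", 60),
             rep("the grp gives support every week", 60),
             rep("my scan was on thursday morning", 30))
  emb <- train_embeddings(lapply(sents, function(t) strsplit(t, " ")[[1]]))
  lex <- expand_seeds(emb, list(seeds = c("group")), top_k = 10L,
                      min_similarity = 0.5)
  expect_true("grp" %in% lex$expanded$expression)
  # oracle: exhaustive cosine ranking over the vocabulary
  v <- embedding_vector(emb, "group")
  sims <- apply(emb$vectors, 1, function(r) cosine_similarity(r, v))
  sims <- sort(sims[names(sims) != "group"], decreasing = TRUE)
  top <- names(sims)[sims >= 0.5][1:nrow(lex$expanded)]
  expect_setequal(lex$expanded$expression, top)
  expect_true(all(lex$expanded$similarity >= 0.5))
  expect_false(is.unsorted(rev(lex$expanded$similarity)))

  # top_k = 0 keeps only the seeds
  lex0 <- expand_seeds(emb, list(seeds = c("group")), top_k = 0L)
  expect_equal(nrow(lex0$expanded), 0L)
  expect_equal(lex0$seeds$seeds, "group")

  # an impossible threshold also yields only seeds
  lex1 <- expand_seeds(emb, list(seeds = c("group")), min_similarity = 1.01)
  expect_equal(nrow(lex1$expanded), 0L)

  # expansions unique across seeds
  lex2 <- expand_seeds(emb, list(a = "group", b = "grp"), top_k = 10L,
                       min_similarity = 0.3)
  expect_false(any(duplicated(lex2$expanded$expression)))

  # out-of-vocabulary seeds: skipped with warning, all-missing rejected
  expect_warning(expand_seeds(emb, list(s = c("group", "qqqq"))), "qqqq")
  expect_error(suppressWarnings(expand_seeds(emb, list(s = "qqqq"))),
               "no seed")
})

test_that("default seed lexicon covers the eight themes and we-talk markers", {
  seeds <- default_seed_lexicon()
  expect_length(seeds, 8L)
  all_terms <- unlist(seeds)
  expect_true(all(c("us", "we", "our group") %in% all_terms))
})

test_that("lexicon JSON round-trips losslessly", {
  emb <- train_embeddings(co_occurring_corpus(30L))
  lex <- expand_seeds(emb, list(core = c("group", "support")),
                      top_k = 5L, min_similarity = 0.2)
  lex <- lexicon_add_human(lex, c("hot seat", "been there"))
  path <- withr::local_tempfile(fileext = ".json")
  write_lexicon_json(lex, path)
  back <- read_lexicon_json(path)
  expect_equal(back$seeds, lex$seeds)
  expect_equal(as.data.frame(back$expanded), as.data.frame(lex$expanded))
  expect_setequal(lexicon_terms(back), lexicon_terms(lex))
})
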