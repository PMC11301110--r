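test_that("template bank carries the documented theme and trap examples", {
  bank <- template_bank()
  expect_true("Thank you everyone, this is such a great group." %in%
                bank$text[bank$theme == "Gratitude for the group and peers"])
  expect_true("sending hugs" %in% bank$text)
  expect_true("thanks everyone for your support <3" %in% bank$text)
  expect_true("I am glad to be part of this group" %in% bank$text)
  expect_true("we are friends" %in% bank$text)

  # outside-group support trap: about family/friends, gold non_cohesion
  outs <- bank[grepl("outside-group", bank$theme), ]
  expect_gt(nrow(outs), 0)
  expect_true(all(outs$gold_label == "non_cohesion"))
  expect_true(any(grepl("famil|husband|children|friends", outs$text)))

  # the bank defeats bare keyword matching on "we": a trap template contains
  # "we" yet is non-cohesion, and a cohesion template has no we/us/our
  has_we <- vapply(bank$text, function(t)
    any(tokenize(t) %in% c("we", "us", "our")), logical(1))
  expect_true(any(has_we & bank$gold_label == "non_cohesion"))
  expect_true(any(!has_we & bank$gold_label == "cohesion"))
})

test_that("every template renders non-empty text under all slot fillings", {
  bank <- template_bank()
  for (i in seq_len(nrow(bank))) {
    for (b in c("", "very ", "so much ")) {
      for (tense in c("present", "past")) {
        out <- render_template(bank[i, ], booster = b, tense = tense)
        expect_true(nzchar(out))
        expect_false(grepl("{", out, fixed = TRUE))
      }
    }
  }
})

test_that("generator respects rates, bounds and determinism", {
  cfg <- gen_config(n_sessions = 1L, messages_per_session = 100L,
                    cohesion_rate = 0.3, trap_rate = 0.1, seed = 1L)
  co <- generate_corpus(cfg)
  expect_equal(nrow(co), 100L)
  frac <- mean(co$gold_label == "cohesion")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 100))

  # boundary: zero cohesion rate
  co0 <- generate_corpus(gen_config(messages_per_session = 200L,
                                    cohesion_rate = 0, trap_rate = 0.2,
                                    seed = 3L))
  expect_false(any(co0$gold_label == "cohesion"))

  # determinism: same seed twice is byte-identical on disk
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(generate_corpus(cfg), f1)
  write_corpus_jsonl(generate_corpus(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  # timestamps sorted within the session and inside [0, duration]
  expect_true(all(diff(co$timestamp) >= 0))
  expect_true(all(co$timestamp >= 0 & co$timestamp <= 90 * 60))
  expect_true(all(nzchar(co$text)))
  expect_true(all(co$role %in% c("participant", "therapist")))
})

test_that("generator rejects invalid rates naming the offending field", {
  expect_error(gen_config(cohesion_rate = 1.2), "cohesion_rate")
  expect_error(gen_config(trap_rate = -0.1), "trap_rate")
  expect_error(gen_config(cohesion_rate = 0.7, trap_rate = 0.5), "trap_rate")
  expect_error(gen_config(n_sessions = 0), "n_sessions")
})

test_that("large corpora cover all themes and at least four trap kinds", {
  co <- generate_corpus(gen_config(n_sessions = 5L,
                                   messages_per_session = 120L,
                                   cohesion_rate = 0.3, trap_rate = 0.15,
                                   seed = 5L))
  themes <- unique(stats::na.omit(co$theme))
  expect_length(setdiff(unique(template_bank()$theme[
    template_bank()$category == "cohesion"]), themes), 0)
  expect_gte(length(grep("^trap:", themes)), 4)

  # trap gold labels honour trap semantics
  expect_true(all(co$gold_label[grepl("negated cohesion|outside-group|false detection",
                                      co$theme)] == "non_cohesion"))
  expect_true(all(co$gold_label[grepl("without we-language", co$theme)] == "cohesion"))
})

test_that("corpus round-trips through JSONL field by field", {
  co <- generate_corpus(gen_config(messages_per_session = 40L, seed = 9L))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(co, path)
  back <- read_corpus_jsonl(path)
  expect_equal(as.data.frame(back), as.data.frame(co))
})
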