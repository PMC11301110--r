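# End-to-end pipeline: simulate -> lexicon -> train -> score -> aggregate
# -> baseline -> evaluate -> active-learn, with per-stage artifacts,
# JSON-lines logging, and one root seed feeding every stochastic stage.

#' Pipeline run configuration
#'
#' @param out_dir Directory for all artifacts (created if missing).
#' @param seed Root seed; every stage derives its own seed from it.
#' @param gen [gen_config()] for the training corpus; the held-out test
#'   transcript reuses it with a derived seed.
#' @param test_sessions Number of test sessions to simulate (ignored when
#'   `transcript` is given).
#' @param transcript Optional path to an existing JSONL transcript to score
#'   instead of simulating test data.
#' @param feature [feature_config()] for the ensemble.
#' @param rules [rule_config()] for the adjustment layer.
#' @param top_k,min_similarity Lexicon-expansion parameters.
#' @param interval_minutes Aggregation interval T.
#' @param al_rounds Active-learning rounds to run (0 disables).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = "osg_run", seed = 1L,
                       gen = gen_config(n_sessions = 20L,
                                        messages_per_session = 100L,
                                        cohesion_rate = 0.2, trap_rate = 0.1,
                                        seed = seed),
                       test_sessions = 5L, transcript = NULL,
                       feature = feature_config(), rules = rule_config(),
                       top_k = 10L, min_similarity = 0.5,
                       interval_minutes = 30, al_rounds = 2L) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), gen = gen,
                 test_sessions = check_count(test_sessions, "test_sessions"),
                 transcript = transcript, feature = feature, rules = rules,
                 top_k = top_k, min_similarity = min_similarity,
                 interval_minutes = interval_minutes,
                 al_rounds = check_count(al_rounds, "al_rounds", min = 0L)),
            class = "run_config")
}

log_line <- function(con, stage, event, ...) {
  rec <- c(list(stage = stage, event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"),
             con)
}

missing_input <- function(path) {
  stop(structure(class = c("osg_missing_input", "error", "condition"),
                 list(message = paste0("required input does not exist: ", path),
                      call = NULL)))
}

#' Run the full cohesion-monitoring pipeline
#'
#' Executes the stages in order, writing `train.jsonl`, `transcript.jsonl`,
#' `gold.csv`, `lexicon.json`, `model/`, `scores.jsonl`, `beta.csv`,
#' `baseline.csv`, `eval.json`, a JSON-lines `log.jsonl` (stage boundaries,
#' rule-firing counts, interval scores) and a `manifest.json` carrying the
#' config hash, seed and package version.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with artifact `paths` and the evaluation
#'   `reports`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    train = file.path(config$out_dir, "train.jsonl"),
    transcript = file.path(config$out_dir, "transcript.jsonl"),
    gold = file.path(config$out_dir, "gold.csv"),
    lexicon = file.path(config$out_dir, "lexicon.json"),
    model = file.path(config$out_dir, "model"),
    scores = file.path(config$out_dir, "scores.jsonl"),
    beta = file.path(config$out_dir, "beta.csv"),
    baseline = file.path(config$out_dir, "baseline.csv"),
    eval = file.path(config$out_dir, "eval.json"),
    log = file.path(config$out_dir, "log.jsonl"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  con <- file(paths$log, open = "wt")
  on.exit(close(con), add = TRUE)

  # -- simulate ------------------------------------------------------------
  log_line(con, "simulate", "start")
  train <- generate_corpus(config$gen)
  write_corpus_jsonl(train, paths$train)
  if (is.null(config$transcript)) {
    test_cfg <- config$gen
    test_cfg$n_sessions <- config$test_sessions
    test_cfg$seed <- derive_seed(config$seed, "simulate")
    test <- generate_corpus(test_cfg)
    write_corpus_jsonl(test, paths$transcript)
  } else {
    if (!file.exists(config$transcript)) missing_input(config$transcript)
    test <- read_corpus_jsonl(config$transcript)
  }
  write_gold_csv(test, paths$gold)
  log_line(con, "simulate", "done", n_train = nrow(train), n_test = nrow(test))

  # -- lexicon -------------------------------------------------------------
  log_line(con, "lexicon", "start")
  emb <- train_embeddings(train$text,
                          embedding_config(seed = derive_seed(config$seed, "lexicon")))
  lexicon <- expand_seeds(emb, default_seed_lexicon(),
                          top_k = config$top_k,
                          min_similarity = config$min_similarity)
  write_lexicon_json(lexicon, paths$lexicon)
  log_line(con, "lexicon", "done", n_expanded = nrow(lexicon$expanded))

  # -- train ---------------------------------------------------------------
  log_line(con, "train", "start")
  model <- fit_ensemble(train, config$feature, lexicon,
                        seed = derive_seed(config$seed, "train"))
  save_ensemble(model, paths$model)
  log_line(con, "train", "done", selected = model$selected,
           val_f1 = as.list(round(model$val_f1, 4)))

  # -- score (classify + rules) --------------------------------------------
  log_line(con, "score", "start")
  scored <- score_messages(model, test, config$rules)
  scored$session_id <- test$session_id
  scored$timestamp <- test$timestamp
  scored$participant_id <- test$participant_id
  lines <- vapply(seq_len(nrow(scored)), function(i)
    as.character(jsonlite::toJSON(as.list(scored[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null")), character(1))
  writeLines(lines, paths$scores, useBytes = TRUE)
  fired <- table(unlist(strsplit(scored$fired_rules[nzchar(scored$fired_rules)], ",")))
  log_line(con, "score", "done", n = nrow(scored),
           rule_firing_counts = as.list(fired))

  # -- aggregate -----------------------------------------------------------
  log_line(con, "aggregate", "start")
  beta_all <- do.call(rbind, lapply(split(scored, scored$session_id), function(df) {
    b <- beta_series(df, config$interval_minutes, config$gen$session_duration)
    cbind(session_id = df$session_id[1], b)
  }))
  utils::write.csv(beta_all, paths$beta, row.names = FALSE, na = "")
  log_line(con, "aggregate", "done",
           beta = stats::setNames(as.list(beta_all$beta),
                                  paste(beta_all$session_id, beta_all$t_start)))

  # -- baseline ------------------------------------------------------------
  log_line(con, "baseline", "start")
  base <- baseline_transcript(test)
  utils::write.csv(base, paths$baseline, row.names = FALSE)
  log_line(con, "baseline", "done", n = nrow(base))

  # -- evaluate ------------------------------------------------------------
  log_line(con, "evaluate", "start")
  reports <- list(
    pipeline = eval_report(confusion_matrix(scored$final_label, test$gold_label),
                           round_id = "pipeline"),
    baseline = eval_report(confusion_matrix(base$label, test$gold_label),
                           round_id = "baseline")
  )
  log_line(con, "evaluate", "done",
           pipeline_f1 = reports$pipeline$f1, baseline_f1 = reports$baseline$f1)

  # -- active learning -----------------------------------------------------
  al_train <- train
  al_model <- model
  al_lex <- lexicon
  if (config$al_rounds > 0L) {
    oracle <- stats::setNames(test$gold_label, test$message_id)
    for (r in seq_len(config$al_rounds)) {
      log_line(con, "active_learn", "round_start", round = r)
      res <- active_learning_round(al_model, test, oracle,
                                   train = al_train, lexicon = al_lex,
                                   round_id = r,
                                   seed = derive_seed(config$seed + r, "active_learn"))
      al_model <- res$model; al_lex <- res$lexicon
      al_train <- rbind(al_train[, c("text", "gold_label")],
                        res$scored[, c("text", "gold_label")])
      reports[[paste0("round_", r)]] <- res$report
      log_line(con, "active_learn", "round_done", round = r,
               recall = res$report$recall, f1 = res$report$f1,
               stop = stop_rule(res$report))
      if (stop_rule(res$report)) break
    }
  }

  to_json <- function(r) list(round_id = r$round_id, precision = r$precision,
                              recall = r$recall, f1 = r$f1,
                              counts = unclass(r$counts))
  jsonlite::write_json(lapply(reports, to_json), paths$eval,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("osgcohesion")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(paths = paths, reports = reports, model = al_model,
                 lexicon = al_lex))
}
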