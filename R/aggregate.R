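# Interval-level group-cohesion score over a session timeline.
#
# beta = |C(t, t+T)| / |A(t, t+T)|, where A is the set of all posts in the
# half-open interval [t, t+T) and C the subset whose final label is
# cohesion; T defaults to 30 minutes on a 90-minute session, giving three
# dashboard updates per session.

#' Interval cohesion score series
#'
#' Intervals are half-open `[t, t+T)` anchored at 0 and cover the session
#' (`ceiling(duration / T)` of them); a post exactly at the session end is
#' counted in the last interval so every post lands in exactly one. An
#' interval with no posts has an undefined score (`NA`, serialised as an
#' empty CSV cell), never 0: "no one posted" must not read as "no
#' cohesion".
#'
#' @param scored Data frame with columns `timestamp` (seconds from session
#'   start), `final_label`, and `participant_id` (needed for
#'   `scope = "participant"`).
#' @param interval_minutes Interval length T in minutes.
#' @param session_minutes Session duration in minutes.
#' @param scope `"group"` for one series, `"participant"` for one series
#'   per participant.
#' @return Tibble of class `interval_scores`: `scope`, `t_start` (minutes),
#'   `interval_minutes`, `n_posts`, `n_cohesion`, `beta`.
#' @export
beta_series <- function(scored, interval_minutes = 30, session_minutes = 90,
                        scope = c("group", "participant")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(scored),
            all(c("timestamp", "final_label") %in% names(scored)))
  if (!is.numeric(interval_minutes) || interval_minutes <= 0)
    abort_field("interval_minutes", "must be a positive number of minutes")
  ts_min <- scored$timestamp / 60
  if (nrow(scored) > 0 && (min(ts_min) < 0 || max(ts_min) > session_minutes))
    abort_field("timestamp", "must lie within [0, session_duration]")

  n_int <- ceiling(session_minutes / interval_minutes)
  starts <- (seq_len(n_int) - 1L) * interval_minutes

  one_scope <- function(df, label) {
    idx <- pmin(floor(df$timestamp / 60 / interval_minutes) + 1L, n_int)
    n_posts <- tabulate(idx, nbins = n_int)
    n_coh <- tabulate(idx[df$final_label == .POSITIVE], nbins = n_int)
    tibble::tibble(
      scope = label, t_start = starts, interval_minutes = interval_minutes,
      n_posts = n_posts, n_cohesion = n_coh,
      beta = ifelse(n_posts > 0, n_coh / n_posts, NA_real_)
    )
  }

  out <- if (scope == "group") {
    one_scope(scored, "group")
  } else {
    stopifnot("participant_id" %in% names(scored))
    parts <- sort(unique(scored$participant_id))
    do.call(rbind, lapply(parts, function(p)
      one_scope(scored[scored$participant_id == p, , drop = FALSE],
                paste0("participant:", p))))
  }
  class(out) <- c("interval_scores", class(out))
  out
}

#' Write an interval score series as CSV
#'
#' Undefined scores become empty cells.
#'
#' @param scores [beta_series()] output.
#' @param path Output CSV.
#' @param session_id Optional id written in the first column.
#' @export
write_beta_csv <- function(scores, path, session_id = NA_character_) {
  df <- as.data.frame(scores)
  df <- cbind(session_id = session_id, df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
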