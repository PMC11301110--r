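#' @keywords internal
"_PACKAGE"

# package-local cache for shipped word lists
.osg_cache <- new.env(parent = emptyenv())

#' Path to a word list or dictionary shipped with the package
#'
#' @param ... path components under `inst/extdata`.
#' @return Absolute file path.
#' @keywords internal
osg_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "osgcohesion", mustWork = TRUE)
  p
}

#' Read a plain-text term list (one term per line, `#` comments allowed)
#'
#' @param path file path.
#' @return Character vector of lowercase terms, comments and blanks dropped.
#' @export
read_term_list <- function(path) {
  stopifnot(file.exists(path))
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  tolower(x)
}

# cached accessor for a shipped lexicon file
shipped_terms <- function(name) {
  key <- paste0("terms_", name)
  if (!is.null(.osg_cache[[key]])) return(.osg_cache[[key]])
  out <- read_term_list(osg_extdata("lexicons", paste0(name, ".txt")))
  assign(key, out, envir = .osg_cache)
  out
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort_field(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    abort_field(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

# deterministic per-stage seed derived from a root seed; stays below 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, lexicon = 211L, train = 307L, score = 401L,
    aggregate = 503L, baseline = 601L, evaluate = 701L, active_learn = 809L,
    split = 907L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483629)
}
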