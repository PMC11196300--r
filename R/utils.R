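# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Timestamps are POSIXct in UTC throughout; serialised as ISO-8601 with an
# explicit +00:00 offset so the on-disk form is unambiguous.
TIME_FMT <- "%Y-%m-%dT%H:%M:%S"

format_time <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- paste0(format(x[ok], TIME_FMT, tz = "UTC"), "+00:00")
  out
}

parse_time <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    stripped <- sub("(Z|[+-][0-9]{2}:?[0-9]{2})$", "", x[ok])
    parsed <- as.POSIXct(stripped, format = TIME_FMT, tz = "UTC")
    if (anyNA(parsed)) {
      stop("malformed timestamp: ", paste(x[ok][is.na(parsed)], collapse = ", "),
           call. = FALSE)
    }
    out[ok] <- parsed
  }
  out
}

# Multi-valued cells (interaction partner ids, activity labels) are
# semicolon-joined strings both in memory and on disk.
join_ids <- function(x) vapply(x, function(v) paste(v, collapse = ";"), character(1))

split_ids <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ";", fixed = TRUE)[[1]]
  })
}

#' Normalise a display name for matching: case-folded, trimmed,
#' internal whitespace collapsed. No fuzzy matching by design.
#' @noRd
normalise_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Canonical undirected edge representation: from < to lexicographically.
canonical_ties <- function(ties) {
  if (nrow(ties) == 0) {
    return(tibble::tibble(from = character(0), to = character(0)))
  }
  a <- pmin(ties$from, ties$to)
  b <- pmax(ties$from, ties$to)
  out <- tibble::tibble(from = a, to = b)
  out <- out[order(out$from, out$to), , drop = FALSE]
  tibble::as_tibble(out)
}
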