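# Descriptive statistics behind the feedback report: composition, counts,
# quality summaries with confidence intervals, timelines, perception vs
# behaviour, network structure, and term frequencies.

#' Role composition of a network wave
#'
#' Counts network members per social role; roles with zero members are
#' included so pre/post compositions are directly comparable (e.g. a
#' break-up shows as romantic_partner dropping from 1 to 0).
#'
#' @param wave A [network_wave()].
#' @return Tibble `role`, `n` covering every role level.
#' @export
role_composition <- function(wave) {
  stopifnot(inherits(wave, "network_wave"))
  tab <- table(factor(wave$alters$role, levels = ROLE_LEVELS))
  tibble::tibble(role = ROLE_LEVELS, n = as.integer(tab))
}

# One row per (event, partner), with the partner's role attached.
expand_partners <- function(events, roster) {
  if (nrow(events) == 0) {
    return(cbind(events[0, , drop = FALSE],
                 tibble::tibble(partner_id = character(0), role = character(0))))
  }
  partners <- split_ids(events$partner_ids)
  idx <- rep(seq_len(nrow(events)), lengths(partners))
  out <- events[idx, , drop = FALSE]
  out$partner_id <- unlist(partners, use.names = FALSE)
  out$role <- roster$role[match(out$partner_id, roster$alter_id)]
  tibble::as_tibble(out)
}

#' Interaction counts per role or per partner
#'
#' A group interaction increments every listed partner, and each partner's
#' role once per event (so the sum of per-partner counts exceeds the
#' number of events whenever group events exist — the only source of
#' excess). Roster members (or roles) with zero interactions are included
#' with count 0.
#'
#' @param events Interaction-event tibble.
#' @param roster Roster tibble the partner ids resolve against.
#' @param by `"role"` or `"partner"`.
#' @return Tibble `group`, `n`, ordered by descending `n` then group id.
#' @export
interaction_counts <- function(events, roster, by = c("role", "partner")) {
  by <- match.arg(by)
  ex <- expand_partners(events, roster)
  if (by == "partner") {
    keys <- roster$alter_id
    got <- table(ex$partner_id)
  } else {
    keys <- ROLE_LEVELS
    # each event counts once per distinct partner role
    per_event_roles <- unique(ex[, c("event_id", "role")])
    got <- table(per_event_roles$role)
  }
  n <- as.integer(got[keys])
  n[is.na(n)] <- 0L
  out <- tibble::tibble(group = keys, n = n)
  out[order(-out$n, out$group), ]
}

t_interval <- function(points, level = 0.95, method = c("t", "normal")) {
  method <- match.arg(method)
  n <- length(points)
  m <- mean(points)
  if (n < 2) return(c(mean = m, ci_low = NA_real_, ci_high = NA_real_))
  se <- sd(points) / sqrt(n)
  crit <- if (method == "t") qt(1 - (1 - level) / 2, df = n - 1) else
    stats::qnorm(1 - (1 - level) / 2)
  c(mean = m, ci_low = m - crit * se, ci_high = m + crit * se)
}

#' Per-group quality summaries with confidence intervals
#'
#' For each role or interaction partner, collects all scores of one
#' quality indicator (a group event contributes its score once per listed
#' partner and once per distinct partner role), and reports the raw
#' points, the mean, and a two-sided 95% confidence interval for the mean
#' (t-interval `mean +/- t_{0.975, n-1} * s / sqrt(n)` by default; a
#' normal-approximation interval is available by config). Groups with
#' fewer than 2 scores get no interval rather than a degenerate one.
#'
#' @param events Interaction-event tibble.
#' @param roster Roster the partner ids resolve against.
#' @param by `"role"` or `"partner"`.
#' @param indicator Quality indicator name, e.g. `"meaningfulness"`; must
#'   exist as a `quality_<indicator>` column.
#' @param level Confidence level (default 0.95).
#' @param ci_method `"t"` (default) or `"normal"`.
#' @return Tibble `group_key`, `indicator`, `n`, `mean`, `ci_low`,
#'   `ci_high`, `points` (list column of raw scores), ordered by
#'   descending `n` then group id. Groups with no scored interactions are
#'   omitted.
#' @export
quality_summary <- function(events, roster, by = c("role", "partner"),
                            indicator, level = 0.95,
                            ci_method = c("t", "normal")) {
  by <- match.arg(by)
  ci_method <- match.arg(ci_method)
  col <- paste0("quality_", indicator)
  if (nrow(events) > 0 && !(col %in% names(events))) {
    stop("unknown quality indicator: ", indicator, call. = FALSE)
  }
  ex <- expand_partners(events, roster)
  if (nrow(ex) == 0) {
    return(tibble::tibble(group_key = character(0), indicator = character(0),
                          n = integer(0), mean = numeric(0),
                          ci_low = numeric(0), ci_high = numeric(0),
                          points = list()))
  }
  if (by == "role") {
    ex <- unique(ex[, c("event_id", "role", col)])
    ex$group_key <- ex$role
  } else {
    ex$group_key <- ex$partner_id
  }
  ex <- ex[!is.na(ex[[col]]), , drop = FALSE]
  groups <- split(ex[[col]], ex$group_key)
  rows <- lapply(names(groups), function(g) {
    pts <- as.numeric(groups[[g]])
    ci <- t_interval(pts, level, ci_method)
    tibble::tibble(group_key = g, indicator = indicator, n = length(pts),
                   mean = ci[["mean"]], ci_low = ci[["ci_low"]],
                   ci_high = ci[["ci_high"]], points = list(pts))
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$n, out$group_key), ]
}

#' Merged affect and interaction timeline
#'
#' Builds the payload for the study-period timeline: an affect series
#' merging prompt-level responses and event-level momentary affect (each
#' point tagged with its source; no deduplication), and one point per
#' interaction event carrying the selected quality indicator, the role of
#' the event's primary (first-listed) partner, the group flag, and the
#' partner ids for detail lookup. An optional partner filter restricts the
#' event points to events involving at least one filtered partner; the
#' affect series is never filtered.
#'
#' @param responses Momentary-response tibble.
#' @param events Interaction-event tibble.
#' @param roster Roster for partner role lookup.
#' @param affect_item Affect item name (an `affect_<item>` column).
#' @param indicator Quality indicator name (a `quality_<indicator>` column).
#' @param partner_filter Optional character vector of alter ids.
#' @return A `timeline_payload`: list of `affect_series` (tibble `time`,
#'   `value`, `source`) and `event_points` (tibble `time`, `value`, `role`,
#'   `is_group`, `partner_ids`, `event_id`), both time-sorted.
#' @export
affect_timeline <- function(responses, events, roster, affect_item, indicator,
                            partner_filter = NULL) {
  acol <- paste0("affect_", affect_item)
  qcol <- paste0("quality_", indicator)
  if (nrow(responses) > 0 && !(acol %in% names(responses))) {
    stop("unknown affect item: ", affect_item, call. = FALSE)
  }
  if (nrow(events) > 0 && !(qcol %in% names(events))) {
    stop("unknown quality indicator: ", indicator, call. = FALSE)
  }

  prompt_pts <- if (nrow(responses) > 0) {
    keep <- !is.na(responses$response_time) & !is.na(responses[[acol]])
    tibble::tibble(time = responses$response_time[keep],
                   value = as.numeric(responses[[acol]][keep]),
                   source = "prompt")
  } else tibble::tibble(time = parse_time(character(0)), value = numeric(0),
                        source = character(0))
  # event-level affect is optional: events without the item contribute no
  # mood points, only interaction points
  event_pts_affect <- if (nrow(events) > 0 && acol %in% names(events)) {
    keep <- !is.na(events$start_time) & !is.na(events[[acol]])
    tibble::tibble(time = events$start_time[keep],
                   value = as.numeric(events[[acol]][keep]),
                   source = "event")
  } else prompt_pts[0, ]
  affect_series <- rbind(prompt_pts, event_pts_affect)
  affect_series <- affect_series[order(affect_series$time), ]

  ev <- events
  if (!is.null(partner_filter) && nrow(ev) > 0) {
    hit <- vapply(split_ids(ev$partner_ids),
                  function(p) any(p %in% partner_filter), logical(1))
    ev <- ev[hit, , drop = FALSE]
  }
  event_points <- if (nrow(ev) > 0) {
    primary <- vapply(split_ids(ev$partner_ids), function(p) p[1], character(1))
    tibble::tibble(time = ev$start_time,
                   value = as.numeric(ev[[qcol]]),
                   role = roster$role[match(primary, roster$alter_id)],
                   is_group = ev$is_group,
                   partner_ids = ev$partner_ids,
                   event_id = ev$event_id)
  } else {
    tibble::tibble(time = parse_time(character(0)), value = numeric(0),
                   role = character(0), is_group = logical(0),
                   partner_ids = character(0), event_id = character(0))
  }
  event_points <- event_points[order(event_points$time), ]

  structure(list(affect_series = tibble::as_tibble(affect_series),
                 event_points = tibble::as_tibble(event_points)),
            class = "timeline_payload")
}

#' Full detail of one logged interaction
#'
#' The click-through record behind a timeline point: timing, mode,
#' duration, location, category, free-text content, all quality and affect
#' scores, and the partners. Partner names honour the dataset's
#' anonymisation mode (they are whatever the roster currently displays).
#'
#' @param dataset A [participant_dataset()].
#' @param event_id Id of a logged event.
#' @return Named list of event fields, with `partner_names` resolved from
#'   the roster.
#' @export
interaction_detail <- function(dataset, event_id) {
  ev <- dataset$events
  i <- match(event_id, ev$event_id)
  if (is.na(i)) stop("unknown event id: ", event_id, call. = FALSE)
  row <- ev[i, , drop = FALSE]
  partners <- split_ids(row$partner_ids)[[1]]
  qcols <- score_cols(ev, "quality")
  acols <- score_cols(ev, "affect")
  list(
    event_id = row$event_id,
    start_time = row$start_time,
    mode = row$mode,
    duration_min = row$duration_min,
    location = row$location,
    is_group = row$is_group,
    category = row$category,
    content_text = row$content_text,
    quality = setNames(as.numeric(row[1, qcols]), sub("^quality_", "", qcols)),
    affect = setNames(as.numeric(row[1, acols]), sub("^affect_", "", acols)),
    partner_ids = partners,
    partner_names = dataset$roster$display_name[
      match(partners, dataset$roster$alter_id)]
  )
}

#' Relationship perception versus daily-life behaviour
#'
#' Confronts each network member's rated relationship (closeness, support
#' flags) with what actually happened during the ESM period (number of
#' interactions, mean interaction quality). The discrepancy flag marks the
#' "good relationship, never reaches out" pattern: closeness in the top
#' tercile of the wave's ratings but zero logged interactions. The tercile
#' threshold is a package default, configurable via `closeness_quantile`;
#' all inputs are echoed so users can apply their own judgement.
#'
#' @param wave A [network_wave()] supplying the ratings.
#' @param events Interaction-event tibble.
#' @param indicator Quality indicator used for the mean quality column;
#'   `NULL` (default) averages across all quality indicators per event.
#' @param closeness_quantile Quantile defining "high closeness"
#'   (default 2/3 = top tercile).
#' @return Tibble per alter: `alter_id`, `display_name`, `role`,
#'   `closeness`, the four support/disclosure flags, `n_interactions`,
#'   `mean_quality`, `discrepancy`.
#' @export
perception_behavior_table <- function(wave, events, indicator = NULL,
                                      closeness_quantile = 2 / 3) {
  stopifnot(inherits(wave, "network_wave"))
  counts <- interaction_counts(events, wave$alters, by = "partner")
  ex <- expand_partners(events, wave$alters)
  qcols <- if (is.null(indicator)) score_cols(events, "quality") else
    paste0("quality_", indicator)
  mean_q <- if (nrow(ex) > 0 && length(qcols) > 0) {
    per_row <- rowMeans(as.data.frame(ex[, qcols, drop = FALSE]), na.rm = TRUE)
    tapply(per_row, ex$partner_id, function(v) mean(v, na.rm = TRUE))
  } else numeric(0)

  a <- wave$alters
  n_int <- counts$n[match(a$alter_id, counts$group)]
  thr <- if (all(is.na(a$closeness))) NA_real_ else
    quantile(a$closeness, probs = closeness_quantile, na.rm = TRUE, names = FALSE)
  out <- tibble::tibble(
    alter_id = a$alter_id, display_name = a$display_name, role = a$role,
    closeness = a$closeness,
    gives_emotional_support = a$gives_emotional_support,
    gives_practical_support = a$gives_practical_support,
    can_be_myself = a$can_be_myself,
    discuss_personal_issues = a$discuss_personal_issues,
    n_interactions = n_int,
    mean_quality = as.numeric(mean_q[a$alter_id]),
    discrepancy = !is.na(a$closeness) & !is.na(thr) & a$closeness >= thr &
      n_int == 0
  )
  out[order(-ifelse(is.na(out$closeness), -1L, out$closeness), out$alter_id), ]
}

#' Structure of the alter-alter tie graph
#'
#' Connected components and isolates of a wave's undirected tie graph —
#' e.g. a tightly knit family cluster versus a member who knows nobody
#' else in the network.
#'
#' @param wave A [network_wave()].
#' @return List with `isolates` (ids with degree 0, sorted) and
#'   `components` (list of sorted id vectors, largest first, ties broken
#'   by smallest member id).
#' @export
network_structure <- function(wave) {
  stopifnot(inherits(wave, "network_wave"))
  ids <- wave$alters$alter_id
  if (length(ids) == 0) return(list(isolates = character(0), components = list()))
  g <- igraph::graph_from_data_frame(wave$ties, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(m) sort(m))
  ord <- order(-lengths(members), vapply(members, `[`, character(1), 1))
  deg <- igraph::degree(g)
  list(isolates = sort(names(deg)[deg == 0]),
       components = unname(members[ord]))
}

#' English stop words shipped with the package
#'
#' A compact list of common English function words used as the default
#' exclusion list for [word_frequencies()]. A Dutch list is available via
#' `stopword_list("nl")` since the assessments may run in Dutch.
#'
#' @param language `"en"` or `"nl"`.
#' @return Character vector of lowercase stop words.
#' @export
stopword_list <- function(language = c("en", "nl")) {
  language <- match.arg(language)
  if (language == "en") {
    c("a", "about", "above", "after", "again", "all", "also", "am", "an",
      "and", "any", "are", "as", "at", "be", "because", "been", "before",
      "being", "between", "both", "but", "by", "can", "could", "did", "do",
      "does", "doing", "down", "during", "each", "few", "for", "from",
      "further", "had", "has", "have", "having", "he", "her", "here", "hers",
      "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
      "just", "me", "more", "most", "my", "no", "nor", "not", "now", "of",
      "off", "on", "once", "only", "or", "other", "our", "ours", "out",
      "over", "own", "same", "she", "should", "so", "some", "such", "than",
      "that", "the", "their", "theirs", "them", "then", "there", "these",
      "they", "this", "those", "through", "to", "too", "under", "until",
      "up", "very", "was", "we", "were", "what", "when", "where", "which",
      "while", "who", "whom", "why", "will", "with", "would", "you", "your",
      "yours")
  } else {
    c("aan", "al", "alles", "als", "altijd", "andere", "ben", "bij", "daar",
      "dan", "dat", "de", "der", "deze", "die", "dit", "doch", "doen",
      "door", "dus", "een", "eens", "en", "er", "ge", "geen", "geweest",
      "haar", "had", "heb", "hebben", "heeft", "hem", "het", "hier", "hij",
      "hoe", "hun", "iemand", "iets", "ik", "in", "is", "ja", "je", "kan",
      "kon", "kunnen", "maar", "me", "meer", "men", "met", "mij", "mijn",
      "moet", "na", "naar", "niet", "niets", "nog", "nu", "of", "om",
      "omdat", "ook", "op", "over", "reeds", "te", "tegen", "toch", "toen",
      "tot", "u", "uit", "uw", "van", "veel", "voor", "want", "waren",
      "was", "wat", "we", "wel", "werd", "wezen", "wie", "wil", "worden",
      "zal", "ze", "zei", "zelf", "zich", "zij", "zijn", "zo", "zonder",
      "zou")
  }
}

#' Verbs of talking excluded from the word cloud
#'
#' Interaction descriptions are dominated by verbs that merely restate
#' that a conversation happened; these are removed so the cloud shows
#' topics instead.
#'
#' @param language `"en"` or `"nl"`.
#' @return Character vector of lowercase exclusions.
#' @export
talking_verbs <- function(language = c("en", "nl")) {
  language <- match.arg(language)
  if (language == "en") {
    c("talk", "talks", "talked", "talking", "speak", "speaks", "spoke",
      "spoken", "speaking", "chat", "chats", "chatted", "chatting", "say",
      "says", "said", "saying", "tell", "tells", "told", "telling",
      "discuss", "discusses", "discussed", "discussing", "conversation",
      "conversations")
  } else {
    c("praten", "praatte", "gepraat", "praat", "spreken", "sprak",
      "gesproken", "spreekt", "zeggen", "zei", "gezegd", "zegt", "vertellen",
      "vertelde", "verteld", "vertelt", "kletsen", "geklets", "gesprek",
      "gesprekken")
  }
}

tokenise <- function(text) {
  text <- tolower(text[!is.na(text)])
  m <- gregexpr("[\\p{L}\\p{N}]+(?:'[\\p{L}]+)?", text, perl = TRUE)
  unlist(regmatches(text, m), use.names = FALSE)
}

#' Term frequencies of interaction descriptions
#'
#' Lowercases and tokenises the free-text content of all events on
#' unicode-aware word boundaries (no stemming), removes stop words and the
#' 'talking'-verb exclusions, and counts the remaining terms — the data
#' behind the word cloud.
#'
#' @param events Interaction-event tibble (uses `content_text`).
#' @param stopwords Character vector; default [stopword_list()] English.
#' @param extra_exclusions Character vector; default [talking_verbs()]
#'   English.
#' @return Tibble `term`, `count`, sorted by descending count then term.
#' @export
word_frequencies <- function(events, stopwords = stopword_list("en"),
                             extra_exclusions = talking_verbs("en")) {
  tokens <- if (nrow(events) > 0) tokenise(events$content_text) else character(0)
  tokens <- tokens[!(tokens %in% c(stopwords, extra_exclusions))]
  if (length(tokens) == 0) {
    return(tibble::tibble(term = character(0), count = integer(0)))
  }
  tab <- table(tokens)
  out <- tibble::tibble(term = names(tab), count = as.integer(tab))
  out[order(-out$count, out$term), ]
}
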