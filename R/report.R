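# Feedback report assembly: payload, clinical-question coverage, and the
# self-contained interactive HTML renderer.

#' The clinical questions the feedback is designed to answer
#'
#' Twelve questions about a person's social context, grouped by data
#' source (network assessment, experience sampling, or their combination),
#' each mapped to the report sections that answer it. The mapping is the
#' report's requirements list: [coverage_check()] verifies every question
#' is answered by at least one populated section.
#'
#' @return Tibble `id`, `group`, `text`, `sections` (list column of
#'   section keys).
#' @export
clinical_questions <- function() {
  q <- function(id, group, text, sections) {
    tibble::tibble(id = id, group = group, text = text, sections = list(sections))
  }
  dplyr::bind_rows(
    q("q01", "PSN", "How many network members does the participant have?",
      c("network_composition", "alter_table")),
    q("q02", "PSN", "Does the network change over the course of the assessment period or intervention?",
      c("sociograms", "membership_change")),
    q("q03", "PSN", "Does the participant have (emotional/practical) support resources?",
      "alter_table"),
    q("q04", "PSN", "How does the participant perceive social relationships?",
      "alter_table"),
    q("q05", "ESM", "How socially active is the participant in daily life?",
      "counts_quality"),
    q("q06", "ESM", "Of what quality are the social interactions of the participant?",
      c("counts_quality", "wordcloud")),
    q("q07", "ESM", "To what extent are social interactions related to mood or other symptoms?",
      "timeline"),
    q("q08", "ESM", "Are there particularly impactful social interactions? If so, what happened during these?",
      "timeline"),
    q("q09", "PSN+ESM", "Does the participant use available social resources in daily life?",
      "counts_quality"),
    q("q10", "PSN+ESM", "With which network members does the participant interact?",
      "counts_quality"),
    q("q11", "PSN+ESM", "Social interactions with which network members are perceived particularly positively or negatively?",
      c("counts_quality", "timeline")),
    q("q12", "PSN+ESM", "Does the participant's overall perception of a relationship match what is happening in daily life?",
      "alter_table")
  )
}

SECTION_KEYS <- c("network_composition", "sociograms", "membership_change",
                  "alter_table", "counts_quality", "timeline", "wordcloud")

section <- function(available, data = NULL, questions = character(0),
                    reason = NULL) {
  list(available = available, data = data, questions = questions,
       reason = reason)
}

# Deterministic force-directed layout on the union graph of both waves so
# the pre/post sociogram panels are directly comparable.
sociogram_layout <- function(waves) {
  ids <- sort(unique(unlist(lapply(waves, function(w) w$alters$alter_id))))
  ties <- unique(dplyr::bind_rows(lapply(waves, function(w) w$ties)))
  g <- igraph::graph_from_data_frame(ties, directed = FALSE,
                                     vertices = data.frame(name = ids))
  xy <- with_seed(42L, igraph::layout_with_fr(g))
  rng <- apply(xy, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  xy <- sweep(sweep(xy, 2, apply(xy, 2, min)), 2, rng, "/")
  tibble::tibble(alter_id = ids, x = round(xy[, 1], 4), y = round(xy[, 2], 4))
}

wave_nodes <- function(wave, roster, layout) {
  idx <- match(wave$alters$alter_id, layout$alter_id)
  tibble::tibble(alter_id = wave$alters$alter_id,
                 label = wave$alters$display_name,
                 role = wave$alters$role,
                 x = layout$x[idx], y = layout$y[idx])
}

#' Assemble the feedback report payload
#'
#' Computes every section of the two-tab feedback report from a validated
#' dataset, using only the metric and reconciliation operations: role
#' composition per wave, comparable sociograms, membership change,
#' the alter table with perception-versus-behaviour columns, interaction
#' counts and per-group quality summaries (for every quality indicator
#' present, so the rendered report can switch indicator client-side), the
#' affect/interaction timeline (per affect item), interaction details for
#' click-through, and word frequencies. With a single wave, the
#' change-dependent content degrades gracefully: the membership-change
#' section is marked unavailable and the sociogram section stops claiming
#' the network-change question.
#'
#' @param dataset A valid [participant_dataset()].
#' @param options List: `indicator` (default first available), `affect_item`
#'   (default first available), `partner_filter` (optional id vector),
#'   `simple_mode` (start the timeline as a bare mood line), `language`
#'   (stop-word language for the word cloud).
#' @return A `report_payload` list: `participant_id`, `options`, `sections`
#'   (all seven keys, each with `available`, `data`, `questions`,
#'   `reason`), plus the `questions` table.
#' @export
build_payload <- function(dataset, options = list()) {
  stopifnot(inherits(dataset, "participant_dataset"))
  ev <- dataset$events
  indicators <- sub("^quality_", "", score_cols(ev, "quality"))
  affect_items <- unique(c(sub("^affect_", "", score_cols(dataset$responses, "affect")),
                           sub("^affect_", "", score_cols(ev, "affect"))))
  opt <- list(
    indicator = options$indicator %||% (if (length(indicators)) indicators[1] else NULL),
    affect_item = options$affect_item %||%
      (if (length(affect_items)) affect_items[1] else NULL),
    partner_filter = options$partner_filter,
    simple_mode = isTRUE(options$simple_mode),
    language = options$language %||% "en",
    anonymisation_mode = dataset$anonymisation_mode)
  if (!is.null(opt$indicator) && length(indicators) &&
      !(opt$indicator %in% indicators)) {
    stop("unknown quality indicator: ", opt$indicator, call. = FALSE)
  }
  if (!is.null(opt$affect_item) && length(affect_items) &&
      !(opt$affect_item %in% affect_items)) {
    stop("unknown affect item: ", opt$affect_item, call. = FALSE)
  }

  waves <- dataset$waves
  two_waves <- all(c("pre", "post") %in% names(waves))
  layout <- sociogram_layout(waves)

  sections <- list()

  sections$network_composition <- section(
    TRUE,
    data = lapply(waves, function(w) role_composition(w)),
    questions = "q01")

  sections$sociograms <- section(
    TRUE,
    data = lapply(waves, function(w) {
      list(nodes = wave_nodes(w, dataset$roster, layout), ties = w$ties)
    }),
    questions = if (two_waves) "q02" else character(0))

  recon <- NULL
  if (two_waves) {
    recon <- suppressWarnings(
      reconcile(waves$pre, waves$post, dataset$roster))
    sections$membership_change <- section(
      TRUE,
      data = list(status = recon$status, role_changes = recon$role_changes,
                  rating_deltas = recon$rating_deltas,
                  flag_flips = recon$flag_flips),
      questions = "q02")
  } else {
    sections$membership_change <- section(
      FALSE, questions = "q02",
      reason = "requires both a pre- and a post-ESM network assessment")
  }

  latest <- if (two_waves) waves$post else waves[[1]]
  sections$alter_table <- section(
    TRUE,
    data = perception_behavior_table(latest, ev,
                                     indicator = opt$indicator),
    questions = c("q01", "q03", "q04", "q12"))

  qual <- list()
  for (ind in indicators) {
    qual[[ind]] <- list(
      by_role = quality_summary(ev, dataset$roster, "role", ind),
      by_partner = quality_summary(ev, dataset$roster, "partner", ind))
  }
  sections$counts_quality <- section(
    TRUE,
    data = list(counts_by_role = interaction_counts(ev, dataset$roster, "role"),
                counts_by_partner = interaction_counts(ev, dataset$roster,
                                                       "partner"),
                quality = qual, indicators = indicators),
    questions = c("q05", "q06", "q09", "q10", "q11"))

  timelines <- list()
  if (length(affect_items) && length(indicators)) {
    for (item in affect_items) {
      timelines[[item]] <- affect_timeline(dataset$responses, ev,
                                           dataset$roster, item,
                                           opt$indicator,
                                           partner_filter = opt$partner_filter)
    }
  }
  details <- lapply(ev$event_id, function(id) {
    d <- interaction_detail(dataset, id)
    d$start_time <- format_time(d$start_time)
    d
  })
  names(details) <- ev$event_id
  sections$timeline <- section(
    length(timelines) > 0,
    data = if (length(timelines)) list(series = timelines, details = details,
                                       affect_items = affect_items) else NULL,
    questions = if (length(timelines)) c("q07", "q08", "q11") else character(0),
    reason = if (!length(timelines)) "no affect or quality items assessed" else NULL)

  wf <- word_frequencies(ev, stopwords = stopword_list(opt$language),
                         extra_exclusions = talking_verbs(opt$language))
  sections$wordcloud <- section(
    TRUE, data = head(wf, 60), questions = "q06")

  structure(list(participant_id = dataset$participant_id,
                 options = opt,
                 two_waves = two_waves,
                 sections = sections[SECTION_KEYS],
                 questions = clinical_questions()),
            class = "report_payload")
}

#' Check clinical-question coverage of a payload
#'
#' Returns the ids of the clinical questions not answered by any
#' available section of the payload — empty iff every question maps to at
#' least one populated section. With a single network wave, exactly the
#' network-change question is reported missing.
#'
#' @param payload A [build_payload()] result.
#' @return Character vector of unanswered question ids (sorted).
#' @export
coverage_check <- function(payload) {
  stopifnot(inherits(payload, "report_payload"))
  claimed <- unlist(lapply(payload$sections, function(s) {
    if (isTRUE(s$available)) s$questions else character(0)
  }))
  sort(setdiff(clinical_questions()$id, claimed))
}

#' @export
print.report_payload <- function(x, ...) {
  avail <- vapply(x$sections, function(s) isTRUE(s$available), logical(1))
  missing_q <- coverage_check(x)
  cat(sprintf("<report_payload '%s': %d/%d sections populated; %s>\n",
              x$participant_id, sum(avail), length(avail),
              if (length(missing_q) == 0) "all clinical questions covered"
              else paste("unanswered:", paste(missing_q, collapse = ", "))))
  invisible(x)
}

payload_to_json <- function(payload) {
  prep <- unclass(payload)
  prep$sections <- lapply(prep$sections, function(s) {
    s$data <- prepare_json(s$data)
    s
  })
  prep$questions <- prepare_json(prep$questions)
  jsonlite::toJSON(prep, dataframe = "rows", auto_unbox = TRUE, na = "null",
                   digits = NA, POSIXt = "ISO8601", null = "null",
                   pretty = FALSE)
}

prepare_json <- function(x) {
  if (inherits(x, "timeline_payload")) x <- unclass(x)
  if (inherits(x, "POSIXct")) return(format_time(x))
  if (is.data.frame(x)) {
    for (col in names(x)) {
      if (inherits(x[[col]], "POSIXct")) x[[col]] <- format_time(x[[col]])
    }
    return(x)
  }
  if (is.list(x)) return(lapply(x, prepare_json))
  x
}

#' Render the interactive HTML feedback report
#'
#' Writes a single self-contained HTML document with two tabs ("Network &
#' Relationships", "Daily Interactions"), all seven report sections,
#' client-side dropdowns for the quality indicator and affect item, a
#' partner filter, click-through interaction details under the timeline,
#' and a simple mode that starts the timeline as a bare mood line with the
#' detail encodings toggleable. The full payload is embedded as JSON and
#' every displayed number is read from it — the template computes nothing.
#' Rendering is a pure view: the same payload always produces identical
#' bytes and the payload is never modified.
#'
#' @param payload A [build_payload()] result.
#' @param destination Path of the HTML file to write.
#' @return Invisibly, `destination`.
#' @export
render_report <- function(payload, destination) {
  stopifnot(inherits(payload, "report_payload"))
  json <- payload_to_json(payload)
  html <- sub("__PAYLOAD__", gsub("</", "<\\\\/", json, fixed = TRUE),
              report_template(), fixed = TRUE)
  html <- sub("__TITLE__", paste0("Social context feedback - ",
                                  payload$participant_id), html, fixed = TRUE)
  con <- file(destination, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(html), con)
  invisible(destination)
}
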