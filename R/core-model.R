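# Domain model: alters, network waves, participant datasets, validation.

ROSTER_COLS <- c("alter_id", "display_name", "role", "gender", "age_bracket",
                 "closeness", "contact_freq_in_person", "contact_freq_online",
                 FLAG_ITEMS, "origin")

#' Construct an alter (network member) record
#'
#' One row per network member: role, demographics, ordinal relationship
#' ratings (closeness 0-10, contact frequencies 0-6), dichotomous support
#' flags, and the wave of first appearance (`origin`). Ordinal ratings may
#' be `NA` (explicitly missing, e.g. an interaction partner first seen
#' during the ESM period and not yet rated).
#'
#' @param alter_id Opaque stable identifier, unique within a dataset.
#' @param display_name Free-text name shown in feedback (real or pseudonym).
#' @param role One of `family`, `friend`, `romantic_partner`,
#'   `fellow_student_or_colleague`, `acquaintance`, `other`.
#' @param gender One of `female`, `male`, `other`, `unknown`.
#' @param age_bracket Decade band such as `"<20"` or `"20-29"`.
#' @param closeness Ordinal 0-10 or `NA`.
#' @param contact_freq_in_person,contact_freq_online Ordinal 0-6 or `NA`.
#' @param gives_emotional_support,gives_practical_support,can_be_myself,discuss_personal_issues
#'   Dichotomous relationship ratings (`TRUE`/`FALSE`/`NA`).
#' @param origin Wave of first appearance: `wave1`, `esm` or `wave2`.
#' @return A one-row tibble in roster column order.
#' @export
#' @examples
#' alter("a1", "Sam", role = "friend", closeness = 8)
alter <- function(alter_id, display_name, role = "other", gender = "unknown",
                  age_bracket = NA_character_, closeness = NA_integer_,
                  contact_freq_in_person = NA_integer_,
                  contact_freq_online = NA_integer_,
                  gives_emotional_support = NA, gives_practical_support = NA,
                  can_be_myself = NA, discuss_personal_issues = NA,
                  origin = "wave1") {
  tibble::tibble(
    alter_id = as.character(alter_id),
    display_name = as.character(display_name),
    role = as.character(role),
    gender = as.character(gender),
    age_bracket = as.character(age_bracket),
    closeness = as.integer(closeness),
    contact_freq_in_person = as.integer(contact_freq_in_person),
    contact_freq_online = as.integer(contact_freq_online),
    gives_emotional_support = as.logical(gives_emotional_support),
    gives_practical_support = as.logical(gives_practical_support),
    can_be_myself = as.logical(can_be_myself),
    discuss_personal_issues = as.logical(discuss_personal_issues),
    origin = as.character(origin)
  )
}

empty_roster <- function() alter(character(0), character(0))[0, ]

#' Construct a personal-network wave
#'
#' A snapshot of the ego network at one assessment: the alters elicited by
#' the name generators plus the undirected alter-alter ties ("any form of
#' contact" between two network members). Ties are stored canonically
#' (lexicographically ordered endpoint pairs, no duplicates kept apart).
#'
#' @param label `"pre"` or `"post"` (before/after the ESM period).
#' @param date Assessment date (`Date`).
#' @param alters Tibble of alter rows (see [alter()]).
#' @param ties Tibble with columns `from`, `to` holding alter ids.
#' @return An object of class `network_wave`.
#' @export
network_wave <- function(label, date, alters, ties = NULL) {
  stopifnot(label %in% c("pre", "post"))
  if (is.null(ties)) ties <- tibble::tibble(from = character(0), to = character(0))
  structure(
    list(label = label, date = as.Date(date),
         alters = tibble::as_tibble(alters),
         ties = canonical_ties(tibble::as_tibble(ties))),
    class = "network_wave"
  )
}

#' @export
print.network_wave <- function(x, ...) {
  cat(sprintf("<network_wave '%s' (%s): %d alters, %d ties>\n",
              x$label, format(x$date), nrow(x$alters), nrow(x$ties)))
  invisible(x)
}

#' Assemble a participant dataset
#'
#' The bundle of everything assessed for one participant: one or two
#' network waves, the prompt schedule, signal-contingent momentary
#' responses, event-contingent interaction records, and the evolving
#' roster (union of all alters ever elicited or encountered, tagged with
#' their origin).
#'
#' @param participant_id Identifier string.
#' @param waves Named list of [network_wave()] objects (`pre` and/or `post`).
#' @param schedule Prompt tibble as produced by [generate_schedule()].
#' @param responses Momentary-response tibble: `prompt_id`, `response_time`
#'   (`NA` = non-compliance; missing responses are rows, not absences, so the
#'   compliance denominator stays explicit), `alone`, `company_perception`,
#'   `activities`, and `affect_*` item columns.
#' @param events Interaction-event tibble: `event_id`, `start_time`, `mode`,
#'   `duration_min` (>= 5, the logging rule), `location`, `is_group`,
#'   `category`, `content_text`, `partner_ids` (semicolon-joined alter ids),
#'   plus `quality_*` and `affect_*` score columns.
#' @param roster Tibble of alter rows; if `NULL`, derived from the waves.
#' @param anonymisation_mode `"real_names"` or `"pseudonyms"`.
#' @return An object of class `participant_dataset`.
#' @export
participant_dataset <- function(participant_id, waves, schedule = NULL,
                                responses = NULL, events = NULL, roster = NULL,
                                anonymisation_mode = "real_names") {
  if (inherits(waves, "network_wave")) waves <- list(waves)
  names(waves) <- vapply(waves, function(w) w$label, character(1))
  if (is.null(roster)) {
    roster <- do.call(rbind, lapply(waves, function(w) w$alters))
    roster <- roster[!duplicated(roster$alter_id), , drop = FALSE]
    rownames(roster) <- NULL
  }
  structure(
    list(participant_id = as.character(participant_id),
         waves = waves,
         schedule = schedule %||% empty_schedule(),
         responses = responses %||% empty_responses(),
         events = events %||% empty_events(),
         roster = tibble::as_tibble(roster),
         anonymisation_mode = anonymisation_mode),
    class = "participant_dataset"
  )
}

empty_schedule <- function() {
  tibble::tibble(prompt_id = character(0), day_index = integer(0),
                 kind = character(0),
                 scheduled_time = parse_time(character(0)),
                 window_start = parse_time(character(0)),
                 window_end = parse_time(character(0)))
}

empty_responses <- function() {
  tibble::tibble(prompt_id = character(0),
                 response_time = parse_time(character(0)),
                 alone = logical(0), company_perception = integer(0),
                 activities = character(0))
}

empty_events <- function() {
  tibble::tibble(event_id = character(0),
                 start_time = parse_time(character(0)),
                 mode = character(0), duration_min = numeric(0),
                 location = character(0), is_group = logical(0),
                 category = character(0), content_text = character(0),
                 partner_ids = character(0))
}

#' @export
print.participant_dataset <- function(x, ...) {
  cat(sprintf(
    "<participant_dataset '%s': waves [%s], %d alters, %d prompts, %d responses, %d events, %s>\n",
    x$participant_id, paste(names(x$waves), collapse = ", "),
    nrow(x$roster), nrow(x$schedule), nrow(x$responses), nrow(x$events),
    x$anonymisation_mode))
  invisible(x)
}

score_cols <- function(df, prefix) {
  grep(paste0("^", prefix, "_"), names(df), value = TRUE)
}

violation <- function(severity, code, message, subject_id = NA_character_) {
  tibble::tibble(severity = severity, code = code,
                 message = message, subject_id = as.character(subject_id))
}

empty_report <- function() violation(character(0), character(0), character(0))[0, ]

check_range <- function(values, ids, item, range, subject_prefix) {
  bad <- which(!is.na(values) & (values < range[1] | values > range[2]))
  if (length(bad) == 0) return(empty_report())
  violation("error", "out_of_range",
            sprintf("%s value %s outside [%d, %d]", item,
                    values[bad], range[1], range[2]),
            paste0(subject_prefix, ids[bad]))
}

validate_wave <- function(wave, label) {
  rep <- list(empty_report())
  ids <- wave$alters$alter_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    rep[[length(rep) + 1]] <- violation(
      "error", "duplicate_alter_id",
      sprintf("alter id '%s' duplicated in wave %s", dup, label), dup)
  }
  bad_role <- is.na(wave$alters$role) | !(wave$alters$role %in% ROLE_LEVELS)
  if (any(bad_role)) {
    rep[[length(rep) + 1]] <- violation(
      "error", "missing_role",
      sprintf("alter '%s' has missing or unknown role in wave %s",
              ids[bad_role], label), ids[bad_role])
  }
  ties <- wave$ties
  loops <- ties$from == ties$to
  if (any(loops)) {
    rep[[length(rep) + 1]] <- violation(
      "error", "self_loop_tie",
      sprintf("self-loop tie on '%s' in wave %s", ties$from[loops], label),
      ties$from[loops])
  }
  endpoints <- unique(c(ties$from, ties$to))
  dangling <- setdiff(endpoints, ids)
  if (length(dangling) > 0) {
    rep[[length(rep) + 1]] <- violation(
      "error", "dangling_tie",
      sprintf("tie endpoint '%s' not an alter of wave %s", dangling, label),
      dangling)
  }
  key <- paste(pmin(ties$from, ties$to), pmax(ties$from, ties$to))
  dup_tie <- duplicated(key)
  if (any(dup_tie)) {
    rep[[length(rep) + 1]] <- violation(
      "error", "duplicate_tie",
      sprintf("tie %s duplicated in wave %s", key[dup_tie], label),
      ties$from[dup_tie])
  }
  rep[[length(rep) + 1]] <- check_range(wave$alters$closeness, ids, "closeness",
                                        scale_range("closeness"), "")
  rep[[length(rep) + 1]] <- check_range(wave$alters$contact_freq_in_person, ids,
                                        "contact_freq_in_person",
                                        scale_range("contact_freq"), "")
  rep[[length(rep) + 1]] <- check_range(wave$alters$contact_freq_online, ids,
                                        "contact_freq_online",
                                        scale_range("contact_freq"), "")
  do.call(rbind, rep)
}

#' Validate a participant dataset
#'
#' Pure consistency check over every domain invariant: unique alter ids,
#' roles set, no self-loop or dangling or duplicate ties, ordinal and
#' score ranges per [scale_registry()], event partners resolvable against
#' the roster, the 5-minute event logging rule, responses referencing
#' scheduled prompts, and (as warnings) event/response timestamps outside
#' the schedule span. Violations are reported, never thrown; the dataset
#' is unchanged. An empty report means the dataset is internally
#' consistent.
#'
#' @param dataset A [participant_dataset()].
#' @return Tibble with columns `severity` (`error`/`warning`), `code`,
#'   `message`, `subject_id`; zero rows iff the dataset is valid.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "participant_dataset"))
  rep <- list(empty_report())

  roster_ids <- dataset$roster$alter_id
  dup <- unique(roster_ids[duplicated(roster_ids)])
  if (length(dup) > 0) {
    rep[[length(rep) + 1]] <- violation(
      "error", "duplicate_alter_id",
      sprintf("alter id '%s' duplicated in roster", dup), dup)
  }
  bad_origin <- !is.na(dataset$roster$origin) &
    !(dataset$roster$origin %in% ORIGIN_LEVELS)
  if (any(bad_origin)) {
    rep[[length(rep) + 1]] <- violation(
      "error", "bad_origin",
      sprintf("alter '%s' has unknown origin tag", roster_ids[bad_origin]),
      roster_ids[bad_origin])
  }

  labels <- names(dataset$waves)
  if (anyDuplicated(labels)) {
    rep[[length(rep) + 1]] <- violation(
      "error", "duplicate_wave_label",
      sprintf("more than one wave labelled '%s'",
              unique(labels[duplicated(labels)])),
      unique(labels[duplicated(labels)]))
  }
  for (w in dataset$waves) {
    rep[[length(rep) + 1]] <- validate_wave(w, w$label)
    missing_from_roster <- setdiff(w$alters$alter_id, roster_ids)
    if (length(missing_from_roster) > 0) {
      rep[[length(rep) + 1]] <- violation(
        "error", "alter_not_in_roster",
        sprintf("wave %s alter '%s' missing from roster", w$label,
                missing_from_roster), missing_from_roster)
    }
  }

  ev <- dataset$events
  if (nrow(ev) > 0) {
    partners <- split_ids(ev$partner_ids)
    empty <- lengths(partners) == 0
    if (any(empty)) {
      rep[[length(rep) + 1]] <- violation(
        "error", "empty_partner_list",
        sprintf("event '%s' has no interaction partners", ev$event_id[empty]),
        ev$event_id[empty])
    }
    for (i in which(!empty)) {
      miss <- setdiff(partners[[i]], roster_ids)
      if (length(miss) > 0) {
        rep[[length(rep) + 1]] <- violation(
          "error", "dangling_partner",
          sprintf("event '%s' references unknown partner '%s'",
                  ev$event_id[i], miss), ev$event_id[i])
      }
    }
    short <- !is.na(ev$duration_min) & ev$duration_min < 5
    if (any(short)) {
      rep[[length(rep) + 1]] <- violation(
        "error", "short_duration",
        sprintf("event '%s' duration %.1f min below the 5-min logging rule",
                ev$event_id[short], ev$duration_min[short]), ev$event_id[short])
    }
    for (col in c(score_cols(ev, "quality"), score_cols(ev, "affect"))) {
      rep[[length(rep) + 1]] <- check_range(ev[[col]], ev$event_id, col,
                                            scale_range("quality"), "")
    }
  }

  rs <- dataset$responses
  if (nrow(rs) > 0) {
    unknown <- setdiff(rs$prompt_id, dataset$schedule$prompt_id)
    if (length(unknown) > 0) {
      rep[[length(rep) + 1]] <- violation(
        "error", "dangling_prompt",
        sprintf("response references unknown prompt '%s'", unknown), unknown)
    }
    answered <- !is.na(rs$response_time)
    bad_cp <- (!answered & !is.na(rs$company_perception)) |
      (answered & is.na(rs$company_perception))
    if (any(bad_cp)) {
      rep[[length(rep) + 1]] <- violation(
        "error", "company_perception_mismatch",
        sprintf("prompt '%s': company_perception must be present iff answered",
                rs$prompt_id[bad_cp]), rs$prompt_id[bad_cp])
    }
    for (col in score_cols(rs, "affect")) {
      rep[[length(rep) + 1]] <- check_range(rs[[col]], rs$prompt_id, col,
                                            scale_range("affect"), "")
    }
    rep[[length(rep) + 1]] <- check_range(rs$company_perception, rs$prompt_id,
                                          "company_perception",
                                          scale_range("company_perception"), "")
  }

  # Timestamps outside the schedule span are suspicious but tolerated.
  if (nrow(dataset$schedule) > 0) {
    span <- range(c(dataset$schedule$window_start, dataset$schedule$window_end))
    span <- c(as.POSIXct(format(span[1], "%Y-%m-%d", tz = "UTC"), tz = "UTC"),
              as.POSIXct(format(span[2], "%Y-%m-%d", tz = "UTC"), tz = "UTC") + 86400)
    if (nrow(ev) > 0) {
      out <- !is.na(ev$start_time) & (ev$start_time < span[1] | ev$start_time > span[2])
      if (any(out)) {
        rep[[length(rep) + 1]] <- violation(
          "warning", "timestamp_out_of_span",
          sprintf("event '%s' outside the schedule period", ev$event_id[out]),
          ev$event_id[out])
      }
    }
    if (nrow(rs) > 0) {
      out <- !is.na(rs$response_time) &
        (rs$response_time < span[1] | rs$response_time > span[2])
      if (any(out)) {
        rep[[length(rep) + 1]] <- violation(
          "warning", "timestamp_out_of_span",
          sprintf("response to '%s' outside the schedule period",
                  rs$prompt_id[out]), rs$prompt_id[out])
      }
    }
  }

  tibble::as_tibble(do.call(rbind, rep))
}

#' Register an interaction partner on the roster
#'
#' When a participant logs an interaction with someone not yet on their
#' roster, the name is added once and saved for future assessments. Name
#' matching is case-insensitive and whitespace-collapsed, with no fuzzy
#' matching: a silent merge of two distinct people is worse than a
#' duplicate the user can merge by hand. Re-registering a known name is a
#' no-op that returns the existing id.
#'
#' @param dataset A [participant_dataset()].
#' @param name Free-text partner name (non-empty).
#' @param at Timestamp of first encounter (recorded for provenance).
#' @return List with elements `dataset` (roster possibly extended by one
#'   alter with `origin = "esm"`, `role = "other"`) and `alter_id`.
#' @export
register_partner <- function(dataset, name, at = Sys.time()) {
  stopifnot(inherits(dataset, "participant_dataset"))
  if (is.na(name) || !nzchar(trimws(name))) {
    stop("partner name must be non-empty", call. = FALSE)
  }
  norm <- normalise_name(name)
  hit <- which(normalise_name(dataset$roster$display_name) == norm)
  if (length(hit) > 0) {
    return(list(dataset = dataset, alter_id = dataset$roster$alter_id[hit[1]]))
  }
  new_id <- next_alter_id(dataset$roster$alter_id)
  dataset$roster <- rbind(
    dataset$roster,
    alter(new_id, trimws(name), role = "other", origin = "esm"))
  list(dataset = dataset, alter_id = new_id)
}

next_alter_id <- function(existing) {
  n <- length(existing) + 1L
  repeat {
    cand <- paste0("a", n)
    if (!(cand %in% existing)) return(cand)
    n <- n + 1L
  }
}
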