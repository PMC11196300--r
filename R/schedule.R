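# Signal-contingent prompt schedules and compliance summaries.

#' Configure a signal-contingent sampling schedule
#'
#' The study design combines 2 semi-fixed assessment moments per day (a
#' morning and an evening questionnaire, each drawn uniformly within its
#' daily window) with `n_random` semi-random prompts. "Semi-random" is
#' operationalised as block randomisation: the random window is split into
#' `n_random` equal blocks and one time is drawn uniformly per block, then
#' adjusted so that consecutive same-day prompts are at least
#' `min_gap_minutes` apart.
#'
#' @param n_days Length of the assessment period in days (default 28).
#' @param n_random Semi-random prompts per day (default 4; a 5-prompt-total
#'   variant is obtained with `n_random = 3`).
#' @param morning_window,evening_window,random_window Daily windows as
#'   `c("HH:MM", "HH:MM")` local wall-clock times. The exact study windows
#'   are not fixed by the design; the defaults are configuration.
#' @param min_gap_minutes Minimum spacing between consecutive same-day
#'   prompts (default 30).
#' @param start_date First study day (`Date`).
#' @param seed Integer seed; schedules are fully seed-deterministic.
#' @return A `schedule_config` list, checked for feasibility
#'   (`n_random * min_gap` must fit in the random window).
#' @export
schedule_config <- function(n_days = 28, n_random = 4,
                            morning_window = c("08:00", "10:00"),
                            evening_window = c("20:00", "22:00"),
                            random_window = c("10:00", "20:00"),
                            min_gap_minutes = 30,
                            start_date = as.Date("2026-01-05"),
                            seed = 1L) {
  cfg <- list(n_days = as.integer(n_days), n_random = as.integer(n_random),
              morning_window = morning_window, evening_window = evening_window,
              random_window = random_window,
              min_gap_minutes = as.numeric(min_gap_minutes),
              start_date = as.Date(start_date), seed = as.integer(seed))
  rw <- window_minutes(random_window)
  if (cfg$n_random > 0 && cfg$n_random * cfg$min_gap_minutes > diff(rw)) {
    stop("infeasible schedule config: ", cfg$n_random, " prompts with a ",
         cfg$min_gap_minutes, "-min gap exceed the random window", call. = FALSE)
  }
  if (cfg$n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  structure(cfg, class = "schedule_config")
}

window_minutes <- function(w) {
  vapply(w, function(t) {
    p <- as.numeric(strsplit(t, ":", fixed = TRUE)[[1]])
    p[1] * 60 + p[2]
  }, numeric(1), USE.NAMES = FALSE)
}

day_time <- function(start_date, day_index, minutes) {
  as.POSIXct(start_date, tz = "UTC") + (day_index - 1) * 86400 +
    round(minutes) * 60
}

# Draw one time in [lo, hi] (minutes of day) at least `gap` after `prev`:
# rejection sampling keeps the uniform-within-window marginal approximately
# intact; after `tries` failures fall back to a deterministic push-apart.
draw_with_gap <- function(lo, hi, prev, gap, tries = 100) {
  for (i in seq_len(tries)) {
    cand <- runif(1, lo, hi)
    if (is.na(prev) || cand - prev >= gap) return(cand)
  }
  min(max(lo, prev + gap), hi)
}

#' Generate a prompt schedule
#'
#' Produces exactly `2 + n_random` prompts per day for `n_days` days:
#' morning and evening prompts uniform within their windows, random
#' prompts block-randomised within the random window, all spaced at least
#' `min_gap_minutes` apart within a day. Deterministic for a fixed seed.
#' Scheduled times are rounded to whole minutes.
#'
#' @param config A [schedule_config()].
#' @return Tibble of prompts: `prompt_id`, `day_index`, `kind`
#'   (`morning`/`random`/`evening`), `scheduled_time`, and the prompt's own
#'   containment window `window_start`/`window_end` (for random prompts,
#'   its block).
#' @export
generate_schedule <- function(config) {
  stopifnot(inherits(config, "schedule_config"))
  mw <- window_minutes(config$morning_window)
  ew <- window_minutes(config$evening_window)
  rw <- window_minutes(config$random_window)
  gap <- config$min_gap_minutes
  nr <- config$n_random
  block_len <- if (nr > 0) diff(rw) / nr else 0

  with_seed(config$seed, {
    rows <- vector("list", config$n_days)
    for (d in seq_len(config$n_days)) {
      mins <- numeric(0); kinds <- character(0)
      ws <- numeric(0); we <- numeric(0)
      t_morning <- round(runif(1, mw[1], mw[2]))
      mins <- t_morning; kinds <- "morning"; ws <- mw[1]; we <- mw[2]
      prev <- t_morning
      for (b in seq_len(nr)) {
        lo <- rw[1] + (b - 1) * block_len
        hi <- rw[1] + b * block_len
        t <- round(draw_with_gap(lo, hi, prev, gap))
        mins <- c(mins, t); kinds <- c(kinds, "random")
        ws <- c(ws, lo); we <- c(we, hi)
        prev <- t
      }
      t_evening <- round(draw_with_gap(ew[1], ew[2], prev, gap))
      mins <- c(mins, t_evening); kinds <- c(kinds, "evening")
      ws <- c(ws, ew[1]); we <- c(we, ew[2])
      rows[[d]] <- tibble::tibble(
        prompt_id = sprintf("d%03dp%d", d, seq_along(mins)),
        day_index = d, kind = kinds,
        scheduled_time = day_time(config$start_date, d, mins),
        window_start = day_time(config$start_date, d, ws),
        window_end = day_time(config$start_date, d, we))
    }
    dplyr::bind_rows(rows)
  })
}

#' Weekly compliance and logging summary
#'
#' Computes, per study week (days 1-7, 8-14, ... aligned to study day 1),
#' the number of scheduled prompts, the number answered (a response with a
#' `response_time`; non-compliance rows count in the denominator only),
#' the compliance rate, and the number of event-contingent interaction
#' logs. Interaction logs are participant-initiated and therefore excluded
#' from the compliance denominator — their count is reported separately,
#' as in the weekly participant emails.
#'
#' @param schedule Prompt tibble from [generate_schedule()].
#' @param responses Momentary-response tibble; every `prompt_id` must be in
#'   the schedule.
#' @param events Interaction-event tibble (may be empty).
#' @return Tibble: `week`, `n_scheduled`, `n_answered`, `compliance_rate`,
#'   `n_events_logged`.
#' @export
compliance <- function(schedule, responses, events = NULL) {
  if (is.null(events)) events <- empty_events()
  unknown <- setdiff(responses$prompt_id, schedule$prompt_id)
  if (length(unknown) > 0) {
    stop("response references unknown prompt: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_weeks <- max(1L, ceiling(max(schedule$day_index) / 7))
  start <- as.POSIXct(min(as.Date(schedule$scheduled_time) -
                            (schedule$day_index - 1)), tz = "UTC")
  sched_week <- ceiling(schedule$day_index / 7)
  answered_ids <- responses$prompt_id[!is.na(responses$response_time)]
  ev_week <- if (nrow(events) > 0) {
    pmin(n_weeks, pmax(1L, ceiling((as.numeric(events$start_time - start,
                                               units = "days") + 1e-9) / 7)))
  } else integer(0)
  tibble::tibble(
    week = seq_len(n_weeks),
    n_scheduled = vapply(seq_len(n_weeks),
                         function(w) sum(sched_week == w), integer(1)),
    n_answered = vapply(seq_len(n_weeks), function(w) {
      sum(schedule$prompt_id[sched_week == w] %in% answered_ids)
    }, integer(1)),
    n_events_logged = vapply(seq_len(n_weeks),
                             function(w) sum(ev_week == w), integer(1))
  ) |>
    dplyr::mutate(compliance_rate = ifelse(.data$n_scheduled > 0,
                                           .data$n_answered / .data$n_scheduled,
                                           NA_real_)) |>
    dplyr::select("week", "n_scheduled", "n_answered", "compliance_rate",
                  "n_events_logged")
}
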