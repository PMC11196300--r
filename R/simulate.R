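# Synthetic cohort simulator: role-structured personal networks, prompt
# schedules, event-contingent interaction logs with per-partner latent
# quality, and affect series coupled to interaction quality.

FIRST_NAMES <- c("Alex", "Bram", "Carmen", "Daan", "Emma", "Femke", "Gio",
                 "Hanna", "Iris", "Jesse", "Kato", "Lena", "Milan", "Noor",
                 "Omar", "Pia", "Quinn", "Rosa", "Sam", "Tess", "Umut",
                 "Vera", "Wout", "Xena", "Yara", "Zoe", "Anouk", "Boris",
                 "Chris", "Dana", "Elif", "Finn", "Greta", "Hugo", "Ines",
                 "Jan", "Kim", "Lars", "Mila", "Nina", "Otto", "Paula",
                 "Rik", "Sofia", "Tom", "Una", "Victor", "Willem", "Yusuf",
                 "Zara")

# Topic vocabulary for interaction descriptions, weighted so that food,
# plans and going(-somewhere) dominate, with a long tail of other topics.
TOPIC_WORDS <- c(food = 0.16, plans = 0.13, going = 0.11, music = 0.07,
                 study = 0.07, coffee = 0.06, dinner = 0.06, movie = 0.05,
                 walk = 0.05, work = 0.05, weekend = 0.04, travel = 0.04,
                 game = 0.03, party = 0.03, thesis = 0.03, gym = 0.02)

ACTIVITY_POOL <- c("studying", "working", "relaxing", "sports", "commuting",
                   "chores", "eating", "social_media")
LOCATION_POOL <- c("home", "university", "cafe", "outdoors", "work", "other")
CATEGORY_POOL <- c("casual", "deep_talk", "practical", "leisure")

#' Configure the synthetic-cohort simulator
#'
#' Defaults encode the study conditions the feedback design assumes: a
#' 42-member network (the observed median; observed range 10-80), a
#' 28-day schedule of 2 semi-fixed + 4 semi-random daily prompts, roughly
#' four >5-minute interactions logged per day, per-partner latent quality
#' means on the 0-10 scale, partner selection weighted towards closer
#' alters (weight proportional to `exp(closeness / partner_tau)`), and a
#' first-order autoregressive affect series lifted by the mean quality of
#' interactions since the previous prompt.
#'
#' @param seed Integer master seed; simulation is fully deterministic.
#' @param n_alters Pre-wave network size (10-80 plausible; default 42).
#' @param role_distribution Named probabilities over the six roles.
#' @param within_role_density Named per-role probability of a tie between
#'   two same-role alters (family tightly knit by default).
#' @param between_role_density Tie probability across roles.
#' @param quality_mu Optional named vector of per-alter latent quality
#'   means (0-10); if `NULL`, drawn uniformly in \[3, 8\].
#' @param quality_sigma Latent quality SD (scores are drawn
#'   `Normal(mu_i, sigma)`, clamped to \[0, 10\], rounded to integers —
#'   the granularity of the rating sliders).
#' @param interactions_per_day Poisson mean of logged interactions per day.
#' @param partner_tau Softmax temperature of closeness-weighted partner
#'   selection; smaller values concentrate interactions on close alters
#'   (the heavy-tailed per-partner profile).
#' @param group_prob Probability an event is a group interaction with 2-4
#'   partners drawn from one tie-graph component.
#' @param affect_baseline,affect_phi,affect_gamma,affect_noise_sd Affect
#'   model `A_t = b + phi * (A_prev - b) + gamma * Qbar_t + noise`, where
#'   `Qbar_t` is the mean quality of interactions since the last prompt
#'   (0 if none); clamped to 0-10 and rounded.
#' @param response_prob Per-prompt compliance probability.
#' @param breakup If `TRUE`, the romantic partner is re-categorised as a
#'   friend at the post assessment (the captured break-up scenario).
#' @param growth Number of new network members first encountered as ESM
#'   interaction partners and kept at the post assessment.
#' @param removals Number of pre-wave members dropped at the post
#'   assessment.
#' @param n_days,n_random,start_date Passed to [schedule_config()].
#' @param affect_items,quality_indicators Item batteries (open maps; the
#'   first affect item carries the autoregressive model, the others are
#'   derived or noise).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_alters = 42,
                              role_distribution = c(
                                family = 0.20, friend = 0.40,
                                romantic_partner = 0.03,
                                fellow_student_or_colleague = 0.17,
                                acquaintance = 0.15, other = 0.05),
                              within_role_density = c(
                                family = 0.8, friend = 0.3,
                                romantic_partner = 0.3,
                                fellow_student_or_colleague = 0.35,
                                acquaintance = 0.1, other = 0.05),
                              between_role_density = 0.04,
                              quality_mu = NULL, quality_sigma = 1.5,
                              interactions_per_day = 4, partner_tau = 2,
                              group_prob = 0.15,
                              affect_baseline = 6, affect_phi = 0.4,
                              affect_gamma = 0.3, affect_noise_sd = 1.5,
                              response_prob = 0.85,
                              breakup = FALSE, growth = 0L, removals = 0L,
                              n_days = 28, n_random = 4,
                              start_date = as.Date("2026-01-05"),
                              affect_items = c("happy", "stressed"),
                              quality_indicators = c("meaningfulness",
                                                     "enjoyment")) {
  stopifnot(n_alters >= 2, abs(sum(role_distribution) - 1) < 1e-8,
            all(within_role_density >= 0 & within_role_density <= 1),
            between_role_density >= 0, between_role_density <= 1,
            affect_phi >= 0, affect_phi < 1,
            is.null(quality_mu) || all(quality_mu >= 0 & quality_mu <= 10),
            quality_sigma >= 0, growth >= 0, removals >= 0,
            removals < n_alters)
  structure(as.list(environment()), class = "simulation_config")
}

sample_weighted <- function(x, n = 1, w = NULL, replace = FALSE) {
  # sample() with a length-1 x treats it as 1:x; avoid that trap
  if (length(x) == 1) return(rep(x, n))
  sample(x, n, prob = w, replace = replace)
}

simulate_pre_wave <- function(cfg) {
  n <- cfg$n_alters
  roles <- sample(names(cfg$role_distribution), n, replace = TRUE,
                  prob = cfg$role_distribution)
  # at most one romantic partner; force one if the breakup scenario is on
  rp <- which(roles == "romantic_partner")
  if (length(rp) > 1) roles[rp[-1]] <- "friend"
  if (cfg$breakup && !any(roles == "romantic_partner")) {
    roles[sample_weighted(which(roles == "friend"), 1)] <- "romantic_partner"
  }

  base_close <- c(family = 7, friend = 6, romantic_partner = 9,
                  fellow_student_or_colleague = 4, acquaintance = 2, other = 3)
  closeness <- as.integer(clamp(round(base_close[roles] + rnorm(n, 0, 1.5)), 0, 10))
  p_flag <- clamp(closeness / 10, 0.05, 0.95)

  nm <- paste(sample(FIRST_NAMES, n, replace = TRUE),
              sample(LETTERS, n, replace = TRUE))
  nm <- make.unique(nm, sep = " ")

  alters <- tibble::tibble(
    alter_id = paste0("a", seq_len(n)),
    display_name = nm,
    role = unname(roles),
    gender = sample(GENDER_LEVELS, n, replace = TRUE,
                    prob = c(0.45, 0.45, 0.05, 0.05)),
    age_bracket = sample(AGE_BRACKETS, n, replace = TRUE,
                         prob = c(0.15, 0.5, 0.12, 0.1, 0.08, 0.05)),
    closeness = closeness,
    contact_freq_in_person = as.integer(clamp(round(closeness * 0.5 +
                                                      rnorm(n, 1, 1)), 0, 6)),
    contact_freq_online = as.integer(clamp(round(closeness * 0.4 +
                                                   rnorm(n, 1.5, 1)), 0, 6)),
    gives_emotional_support = runif(n) < p_flag,
    gives_practical_support = runif(n) < p_flag,
    can_be_myself = runif(n) < p_flag,
    discuss_personal_issues = runif(n) < p_flag,
    origin = "wave1")

  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  same <- roles[pairs[, 1]] == roles[pairs[, 2]]
  p <- ifelse(same, cfg$within_role_density[roles[pairs[, 1]]],
              cfg$between_role_density)
  keep <- runif(nrow(pairs)) < p
  ties <- tibble::tibble(from = alters$alter_id[pairs[keep, 1]],
                         to = alters$alter_id[pairs[keep, 2]])
  network_wave("pre", cfg$start_date - 2, alters, ties)
}

simulate_events <- function(cfg, pre, esm_alters, mu, components) {
  avail_day1 <- pre$alters$alter_id
  arrival <- if (nrow(esm_alters) > 0) {
    setNames(sort(sample(2:max(2, cfg$n_days %/% 2), nrow(esm_alters),
                         replace = TRUE)), esm_alters$alter_id)
  } else integer(0)
  closeness <- setNames(pre$alters$closeness, pre$alters$alter_id)
  closeness[esm_alters$alter_id] <- 5L  # unrated yet; neutral weight
  comp_of <- setNames(rep(seq_along(components), lengths(components)),
                      unlist(components))

  day <- integer(0); minute <- numeric(0)
  primary <- character(0); partner_ids <- character(0); is_group <- logical(0)
  for (d in seq_len(cfg$n_days)) {
    ids <- c(avail_day1, names(arrival)[arrival <= d])
    n_ev <- rpois(1, cfg$interactions_per_day)
    if (n_ev == 0) next
    minutes <- sort(round(runif(n_ev, 9 * 60, 22 * 60)))
    w <- exp(closeness[ids] / cfg$partner_tau)
    for (j in seq_len(n_ev)) {
      prim <- sample_weighted(ids, 1, w = w)
      partners <- prim
      grp <- runif(1) < cfg$group_prob
      if (grp) {
        mates <- setdiff(names(comp_of)[comp_of == comp_of[prim]], prim)
        mates <- mates[mates %in% ids]
        if (length(mates) == 0) mates <- setdiff(ids, prim)
        extra <- sample_weighted(mates, min(length(mates), sample(1:3, 1)))
        partners <- c(prim, extra)
      }
      day <- c(day, d); minute <- c(minute, minutes[j])
      primary <- c(primary, prim)
      partner_ids <- c(partner_ids, paste(partners, collapse = ";"))
      is_group <- c(is_group, grp && length(partners) > 1)
    }
  }
  k <- length(day)
  if (k == 0) return(list(events = empty_events(), arrival = arrival))

  topics <- vapply(seq_len(k), function(i) {
    paste(sample(names(TOPIC_WORDS), sample(1:3, 1), prob = TOPIC_WORDS),
          collapse = " and ")
  }, character(1))
  events <- tibble::tibble(
    event_id = sprintf("e%04d", seq_len(k)),
    start_time = day_time(cfg$start_date, day, minute),
    mode = sample(MODE_LEVELS, k, replace = TRUE, prob = c(0.7, 0.1, 0.2)),
    duration_min = 5 + round(rexp(k, 1 / 25)),
    location = sample(LOCATION_POOL, k, replace = TRUE),
    is_group = is_group,
    category = sample(CATEGORY_POOL, k, replace = TRUE),
    content_text = paste("we talked about", topics),
    partner_ids = partner_ids)
  q1 <- NULL
  for (ind in cfg$quality_indicators) {
    q <- clamp(round(rnorm(k, mu[primary], cfg$quality_sigma)), 0, 10)
    if (is.null(q1)) q1 <- q
    events[[paste0("quality_", ind)]] <- as.numeric(q)
  }
  for (item in cfg$affect_items) {
    events[[paste0("affect_", item)]] <- as.numeric(
      clamp(round(cfg$affect_baseline + cfg$affect_gamma * (q1 - 5) +
                    rnorm(k, 0, cfg$affect_noise_sd)), 0, 10))
  }
  list(events = events, arrival = arrival)
}

simulate_responses <- function(cfg, schedule, events) {
  n <- nrow(schedule)
  n_items <- length(cfg$affect_items)
  a_prev <- cfg$affect_baseline
  t_prev <- min(schedule$scheduled_time) - 86400
  qmain <- paste0("quality_", cfg$quality_indicators[1])

  response_time <- rep(parse_time(NA_character_), n)
  alone <- rep(NA, n)
  company <- rep(NA_integer_, n)
  activities <- rep(NA_character_, n)
  scores <- matrix(NA_integer_, nrow = n, ncol = n_items)

  for (i in seq_len(n)) {
    t <- schedule$scheduled_time[i]
    in_win <- if (nrow(events) > 0) {
      events$start_time > t_prev & events$start_time <= t
    } else logical(0)
    qbar <- if (any(in_win)) mean(events[[qmain]][in_win]) else 0
    a_latent <- cfg$affect_baseline +
      cfg$affect_phi * (a_prev - cfg$affect_baseline) +
      cfg$affect_gamma * qbar + rnorm(1, 0, cfg$affect_noise_sd)
    a_prev <- a_latent
    if (runif(1) < cfg$response_prob) {
      response_time[i] <- t + round(runif(1, 0, 15)) * 60
      alone[i] <- runif(1) < 0.4
      company[i] <- as.integer(clamp(round(rnorm(1, 7, 2)), 0, 10))
      activities[i] <- paste(sample(ACTIVITY_POOL, sample(1:3, 1)),
                             collapse = ";")
      scores[i, 1] <- as.integer(clamp(round(a_latent), 0, 10))
      if (n_items > 1) {
        scores[i, -1] <- as.integer(clamp(round(10 - a_latent +
                                                  rnorm(n_items - 1, 0, 1)),
                                          0, 10))
      }
    }
    t_prev <- t
  }
  out <- tibble::tibble(prompt_id = schedule$prompt_id,
                        response_time = response_time, alone = alone,
                        company_perception = company, activities = activities)
  for (j in seq_len(n_items)) {
    out[[paste0("affect_", cfg$affect_items[j])]] <- scores[, j]
  }
  out
}

simulate_post_wave <- function(cfg, pre, esm_alters) {
  draft <- seed_post_wave(pre, esm_alters, date = cfg$start_date + cfg$n_days + 2)
  a <- draft$alters

  if (cfg$removals > 0) {
    keep_safe <- a$role == "romantic_partner" | a$origin == "esm"
    cand <- a$alter_id[!keep_safe]
    cand <- cand[order(a$closeness[match(cand, a$alter_id)])]
    drop <- head(cand, cfg$removals)
    a <- a[!(a$alter_id %in% drop), , drop = FALSE]
  }
  if (cfg$breakup) {
    a$role[a$role == "romantic_partner"] <- "friend"
  }
  # participant rates the newly added members at the post assessment
  new <- which(a$origin == "esm")
  if (length(new) > 0) {
    a$role[new] <- sample(c("friend", "acquaintance", "other"), length(new),
                          replace = TRUE, prob = c(0.5, 0.4, 0.1))
    a$closeness[new] <- as.integer(sample(2:7, length(new), replace = TRUE))
    a$contact_freq_in_person[new] <- as.integer(sample(0:4, length(new),
                                                       replace = TRUE))
    a$contact_freq_online[new] <- as.integer(sample(0:5, length(new),
                                                    replace = TRUE))
    for (f in FLAG_ITEMS) a[[f]][new] <- runif(length(new)) < 0.3
    a$age_bracket[new] <- sample(AGE_BRACKETS, length(new), replace = TRUE,
                                 prob = c(0.15, 0.5, 0.12, 0.1, 0.08, 0.05))
  }
  # a few reconsidered closeness ratings among carried-over members
  old <- which(a$origin == "wave1")
  touch <- old[runif(length(old)) < 0.15]
  a$closeness[touch] <- as.integer(clamp(a$closeness[touch] +
                                           sample(c(-2L, -1L, 1L, 2L),
                                                  length(touch), replace = TRUE),
                                         0, 10))

  ties <- draft$ties
  ties <- ties[ties$from %in% a$alter_id & ties$to %in% a$alter_id, ]
  if (length(new) > 0) {
    olds <- a$alter_id[a$origin == "wave1"]
    extra <- lapply(a$alter_id[new], function(id) {
      n_new <- min(length(olds), rpois(1, 1.5))
      if (n_new == 0) return(NULL)
      tibble::tibble(from = id, to = sample_weighted(olds, n_new))
    })
    ties <- unique(rbind(ties, dplyr::bind_rows(extra)))
  }
  network_wave("post", cfg$start_date + cfg$n_days + 2, a, ties)
}

#' Simulate a full participant dataset
#'
#' Generates a pre-ESM network wave (role-clustered ties), a prompt
#' schedule, event-contingent interaction logs with per-partner latent
#' quality, momentary responses whose lead affect item follows the
#' autoregressive quality-coupled model, and a post-ESM wave reflecting
#' the scenario flags (break-up, growth, removals). The result passes
#' [validate_dataset()] with zero errors and is fully seed-deterministic.
#' The drawn latent quality means are attached as
#' `attr(dataset, "latents")` for recovery checks.
#'
#' @param config A [simulation_config()].
#' @return A [participant_dataset()] with both waves.
#' @export
simulate_participant <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  schedule <- generate_schedule(schedule_config(
    n_days = config$n_days, n_random = config$n_random,
    start_date = config$start_date, seed = config$seed))

  with_seed(config$seed + 1L, {
    pre <- simulate_pre_wave(config)

    esm_alters <- if (config$growth > 0) {
      nm <- paste(sample(FIRST_NAMES, config$growth, replace = TRUE),
                  sample(LETTERS, config$growth, replace = TRUE))
      nm <- make.unique(paste(nm, "(new)"), sep = " ")
      alter(paste0("a", config$n_alters + seq_len(config$growth)),
            nm, role = "other", origin = "esm")
    } else empty_roster()

    all_ids <- c(pre$alters$alter_id, esm_alters$alter_id)
    mu <- config$quality_mu
    if (is.null(mu)) mu <- setNames(runif(length(all_ids), 3, 8), all_ids)
    if (is.null(names(mu))) mu <- setNames(rep_len(mu, length(all_ids)), all_ids)

    comps <- network_structure(pre)$components
    sim_ev <- simulate_events(config, pre, esm_alters, mu, comps)
    responses <- simulate_responses(config, schedule, sim_ev$events)
    post <- simulate_post_wave(config, pre, esm_alters)

    roster <- rbind(pre$alters, esm_alters)
    dropped <- setdiff(roster$alter_id, post$alters$alter_id)

    ds <- participant_dataset(
      participant_id = paste0("sim-", config$seed),
      waves = list(pre, post),
      schedule = schedule, responses = responses, events = sim_ev$events,
      roster = roster)
    attr(ds, "latents") <- list(quality_mu = mu, arrival_day = sim_ev$arrival,
                                removed_ids = dropped)
    ds
  })
}

#' Latent-parameter recovery report
#'
#' Compares the per-partner quality summaries computed from a simulated
#' dataset against the latent quality means that generated it: for every
#' alter with at least one scored interaction, the latent `mu`, the
#' estimated mean, the 95% CI, and whether the CI covers `mu` (NA when
#' n < 2). Used to check simulator/estimator calibration.
#'
#' @param dataset A dataset from [simulate_participant()].
#' @param config The [simulation_config()] that produced it (supplies the
#'   latent means when they were given explicitly; otherwise the latents
#'   recorded on the dataset are used).
#' @param indicator Quality indicator to check (default: the first).
#' @return Tibble `alter_id`, `mu`, `n`, `est_mean`, `ci_low`, `ci_high`,
#'   `covered`.
#' @export
recovery_report <- function(dataset, config,
                            indicator = config$quality_indicators[1]) {
  mu <- config$quality_mu %||% attr(dataset, "latents")$quality_mu
  if (is.null(mu)) stop("no latent quality means available", call. = FALSE)
  qs <- quality_summary(dataset$events, dataset$roster, by = "partner",
                        indicator = indicator)
  if (is.null(names(mu))) {
    mu <- setNames(rep_len(mu, nrow(dataset$roster)), dataset$roster$alter_id)
  }
  mu_i <- as.numeric(mu[qs$group_key])
  tibble::tibble(
    alter_id = qs$group_key,
    mu = mu_i,
    n = qs$n,
    est_mean = qs$mean,
    ci_low = qs$ci_low,
    ci_high = qs$ci_high,
    covered = ifelse(is.na(qs$ci_low), NA,
                     qs$ci_low <= mu_i & mu_i <= qs$ci_high))
}
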