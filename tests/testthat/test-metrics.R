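test_that("role composition counts every role, including empty ones", {
  expect_equal(role_composition(make_wave("pre", character(0)))$n, rep(0L, 6))

  wave <- make_wave("pre", paste0("a", 1:10),
                    roles = c(rep("friend", 5), rep("family", 3),
                              rep("acquaintance", 2)))
  comp <- role_composition(wave)
  expect_equal(comp$n[comp$role == "friend"], 5L)
  expect_equal(comp$n[comp$role == "family"], 3L)
  expect_equal(comp$n[comp$role == "acquaintance"], 2L)
  expect_equal(sum(comp$n), 10L)
})

test_that("pre/post composition difference exposes a break-up", {
  pre <- make_wave("pre", c("a1", "a2"), roles = c("romantic_partner", "friend"))
  post <- make_wave("post", c("a1", "a2"), roles = c("friend", "friend"))
  n_rp <- function(w) role_composition(w)$n[
    role_composition(w)$role == "romantic_partner"]
  expect_equal(n_rp(pre), 1L)
  expect_equal(n_rp(post), 0L)
})

test_that("interaction counts include zero-count members and honour groups", {
  roster <- make_alters(c("a1", "a2", "a3"),
                        roles = c("friend", "friend", "family"))
  none <- interaction_counts(empty_events(), roster, "partner")
  expect_equal(none$n, rep(0L, 3))

  ev <- make_events(c("a1", "a1;a2;a3", "a2"), quality = c(7, 8, 9))
  per_partner <- interaction_counts(ev, roster, "partner")
  expect_equal(per_partner$n[match(c("a1", "a2", "a3"), per_partner$group)],
               c(2L, 2L, 1L))
  # the multi-partner convention: partner sum exceeds the event count
  expect_gt(sum(per_partner$n), nrow(ev))

  per_role <- interaction_counts(ev, roster, "role")
  # the group event counts once per distinct partner role
  expect_equal(per_role$n[per_role$group == "friend"], 3L)
  expect_equal(per_role$n[per_role$group == "family"], 1L)
  expect_equal(per_role$n[per_role$group == "other"], 0L)
})

test_that("per-role counts of one-on-one events sum to the event count", {
  ds <- simulate_participant(simulation_config(seed = 31, n_alters = 14,
                                               n_days = 14, group_prob = 0))
  counts <- interaction_counts(ds$events, ds$roster, "role")
  expect_equal(sum(counts$n), nrow(ds$events))
})

test_that("per-partner counts expose within-role differences", {
  roster <- make_alters(c("a1", "a2"), roles = "friend")
  ev <- make_events(c(rep("a1", 20), rep("a2", 2)), quality = 7)
  counts <- interaction_counts(ev, roster, "partner")
  expect_equal(counts$group[1], "a1")
  expect_equal(counts$n, c(20L, 2L))
})

test_that("a single-score group gets a mean but no interval", {
  qs <- quality_summary(make_events("a1", quality = 7),
                        make_alters("a1"), "partner", "meaningfulness")
  expect_equal(qs$mean, 7)
  expect_equal(qs$n, 1L)
  expect_true(is.na(qs$ci_low) && is.na(qs$ci_high))
})

test_that("the t-interval matches the hand-derived value on {6..10}", {
  qs <- quality_summary(make_events(rep("a1", 5), quality = 6:10),
                        make_alters("a1"), "partner", "meaningfulness")
  # s = 1.5811388, t_{0.975,4} = 2.7764451, half-width = 1.9632432
  expect_equal(qs$mean, 8.0, tolerance = 1e-12)
  expect_equal(qs$ci_low, 8 - 1.963243161478, tolerance = 1e-9)
  expect_equal(qs$ci_high, 8 + 1.963243161478, tolerance = 1e-9)
  expect_equal(qs$points[[1]], as.numeric(6:10))

  nr <- quality_summary(make_events(rep("a1", 5), quality = 6:10),
                        make_alters("a1"), "partner", "meaningfulness",
                        ci_method = "normal")
  expect_equal(nr$ci_high - nr$ci_low,
               2 * 1.959964 * 1.5811388 / sqrt(5), tolerance = 1e-6)
})

test_that("a consistently lower-rated friend has the lowest friend mean", {
  roster <- make_alters(paste0("a", 1:4), roles = "friend")
  ev <- make_events(c(rep("a1", 6), rep("a2", 6), rep("a3", 6), rep("a4", 6)),
                    quality = c(rep(8, 6), rep(9, 6), rep(3, 6), rep(7, 6)))
  qs <- quality_summary(ev, roster, "partner", "meaningfulness")
  expect_equal(qs$group_key[which.min(qs$mean)], "a3")
  expect_true(all(qs$mean[qs$group_key != "a3"] >= 7))
})

test_that("group ordering is stable: descending n, then id", {
  roster <- make_alters(c("b", "a", "c"))
  ev <- make_events(c("a", "a", "b", "b", "c"), quality = c(5, 6, 5, 6, 5))
  qs <- quality_summary(ev, roster, "partner", "meaningfulness")
  expect_equal(qs$group_key, c("a", "b", "c"))
  expect_error(quality_summary(ev, roster, "partner", "bogus"),
               "unknown quality indicator")
})

test_that("quality means are invariant under event order permutation", {
  ds <- simulate_participant(simulation_config(seed = 41, n_alters = 10,
                                               n_days = 14))
  base <- quality_summary(ds$events, ds$roster, "partner", "meaningfulness")
  set.seed(1)
  for (i in 1:3) {
    perm <- ds$events[sample.int(nrow(ds$events)), ]
    shuffled <- quality_summary(perm, ds$roster, "partner", "meaningfulness")
    expect_equal(shuffled[c("group_key", "n", "mean", "ci_low", "ci_high")],
                 base[c("group_key", "n", "mean", "ci_low", "ci_high")])
  }
})

test_that("CI width shrinks with n on fixed-variance scores", {
  set.seed(7)
  widths <- vapply(c(5, 50, 500), function(n) {
    ev <- make_events(rep("a1", n),
                      quality = pmin(10, pmax(0, round(rnorm(n, 6, 1.5)))))
    qs <- quality_summary(ev, make_alters("a1"), "partner", "meaningfulness")
    qs$ci_high - qs$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the timeline merges prompt and event affect without deduplication", {
  t0 <- as.POSIXct("2026-01-05 09:00:00", tz = "UTC")
  responses <- tibble::tibble(
    prompt_id = paste0("p", 1:4),
    response_time = c(t0, t0 + 3600, NA, t0 + 7200),
    alone = c(TRUE, FALSE, NA, TRUE),
    company_perception = c(5L, 6L, NA, 7L),
    activities = "studying",
    affect_happy = c(6L, 7L, NA, 5L))
  ev <- make_events(c("a1", "a1;a2"), quality = c(8, 9), affect = c(7, 6),
                    times = c(t0 + 1800, t0 + 5400))
  roster <- make_alters(c("a1", "a2"), roles = c("friend", "family"))

  tl <- affect_timeline(responses, ev, roster, "happy", "meaningfulness")
  # 3 answered prompts with affect + 2 events with affect
  expect_equal(nrow(tl$affect_series), 5)
  expect_equal(sum(tl$affect_series$source == "prompt"), 3)
  expect_equal(sum(tl$affect_series$source == "event"), 2)
  expect_false(is.unsorted(tl$affect_series$time))
  expect_equal(nrow(tl$event_points), 2)
  expect_equal(tl$event_points$role, c("friend", "friend"))
  expect_equal(tl$event_points$is_group, c(FALSE, TRUE))
})

test_that("the partner filter restricts event points but not the mood line", {
  t0 <- as.POSIXct("2026-01-05 09:00:00", tz = "UTC")
  responses <- tibble::tibble(prompt_id = "p1", response_time = t0,
                              alone = FALSE, company_perception = 5L,
                              activities = NA_character_, affect_happy = 6L)
  ev <- make_events(c("a1", "a2", "a1;a2"), quality = c(8, 9, 7),
                    times = t0 + c(1, 2, 3) * 3600)
  roster <- make_alters(c("a1", "a2"))
  tl <- affect_timeline(responses, ev, roster, "happy", "meaningfulness",
                        partner_filter = "a2")
  expect_equal(nrow(tl$event_points), 2)
  expect_true(all(grepl("a2", tl$event_points$partner_ids)))
  expect_equal(nrow(tl$affect_series), 1)

  none <- affect_timeline(responses, empty_events(), roster, "happy",
                          "meaningfulness")
  expect_equal(nrow(none$event_points), 0)
  expect_equal(nrow(none$affect_series), 1)
  expect_error(affect_timeline(responses, ev, roster, "bogus", "meaningfulness"),
               "unknown")
})

test_that("interaction detail returns the stored event, or a clear error", {
  ds <- simulate_participant(simulation_config(seed = 12, n_alters = 10,
                                               n_days = 7))
  id <- ds$events$event_id[3]
  d <- interaction_detail(ds, id)
  expect_equal(d$start_time, ds$events$start_time[3])
  expect_equal(d$duration_min, ds$events$duration_min[3])
  expect_equal(d$content_text, ds$events$content_text[3])
  expect_equal(d$quality[["meaningfulness"]],
               ds$events$quality_meaningfulness[3])
  expect_setequal(d$partner_ids, split_partner_ids(ds$events$partner_ids[3]))
  expect_error(interaction_detail(ds, "e9999"), "unknown event id")
})

test_that("interaction detail shows pseudonyms on an anonymised dataset", {
  ds <- simulate_participant(simulation_config(seed = 12, n_alters = 10,
                                               n_days = 7))
  res <- anonymise(ds, "pseudonyms", seed = 2)
  id <- ds$events$event_id[1]
  d <- interaction_detail(res$dataset, id)
  expect_true(all(grepl("^Contact ", d$partner_names)))
  expect_equal(d$partner_names,
               res$map$pseudonym[match(d$partner_ids, res$map$alter_id)])
})

test_that("high closeness with zero interactions raises the discrepancy flag", {
  wave <- make_wave("pre", paste0("a", 1:3), closeness = c(9L, 9L, 2L))
  ev <- make_events(rep("a2", 30), quality = 7)
  tab <- perception_behavior_table(wave, ev)
  expect_true(tab$discrepancy[tab$alter_id == "a1"])
  expect_false(tab$discrepancy[tab$alter_id == "a2"])
  expect_false(tab$discrepancy[tab$alter_id == "a3"])
  expect_equal(tab$n_interactions[tab$alter_id == "a2"], 30L)
})

test_that("discrepancy flags on a 10-alter fixture match a hand evaluation", {
  closeness <- c(10L, 9L, 8L, 8L, 7L, 5L, 4L, 3L, 2L, 1L)
  wave <- make_wave("pre", paste0("a", 1:10), closeness = closeness)
  # interactions for a1, a3, a6 only
  ev <- make_events(c("a1", "a3", "a6"), quality = 7)
  tab <- perception_behavior_table(wave, ev)
  # top tercile: closeness >= quantile(c, 2/3) = 8 -> {a1, a2, a3, a4}
  # of these, a2 and a4 have zero interactions
  expect_equal(sort(tab$alter_id[tab$discrepancy]), c("a2", "a4"))
  expect_equal(sum(tab$discrepancy), 2)
})

test_that("a tieless wave is all isolates and singleton components", {
  wave <- make_wave("pre", paste0("a", 1:4))
  ns <- network_structure(wave)
  expect_setequal(ns$isolates, paste0("a", 1:4))
  expect_equal(lengths(ns$components), rep(1L, 4))
})

test_that("a family clique plus an isolate is recovered exactly", {
  ids <- c("f1", "f2", "f3", "f4", "x41")
  ties <- expand.grid(from = c("f1", "f2", "f3", "f4"),
                      to = c("f1", "f2", "f3", "f4"),
                      stringsAsFactors = FALSE)
  ties <- ties[ties$from < ties$to, ]
  wave <- make_wave("pre", ids, roles = c(rep("family", 4), "acquaintance"),
                    ties = ties)
  ns <- network_structure(wave)
  expect_equal(ns$isolates, "x41")
  expect_equal(ns$components[[1]], c("f1", "f2", "f3", "f4"))
  expect_equal(ns$components[[2]], "x41")
})

test_that("components agree with a brute-force reachability oracle", {
  # exhaustive over all graphs on <= 4 nodes, then random larger graphs
  for (n in 2:4) {
    ids <- paste0("a", seq_len(n))
    pairs <- t(combn(ids, 2))
    for (mask in 0:(2^nrow(pairs) - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0)
      ties <- tibble::tibble(from = pairs[sel, 1], to = pairs[sel, 2])
      wave <- make_wave("pre", ids, ties = ties)
      got <- canon_components(network_structure(wave)$components)
      want <- canon_components(oracle_components(ids, ties))
      expect_identical(got, want)
    }
  }
  set.seed(99)
  for (i in 1:50) {
    n <- sample(13:40, 1)
    ids <- paste0("a", seq_len(n))
    pairs <- t(combn(ids, 2))
    sel <- runif(nrow(pairs)) < 0.08
    ties <- tibble::tibble(from = pairs[sel, 1], to = pairs[sel, 2])
    wave <- make_wave("pre", ids, ties = ties)
    expect_identical(canon_components(network_structure(wave)$components),
                     canon_components(oracle_components(ids, ties)))
  }
})

test_that("word frequencies match a hand tokenisation", {
  expect_equal(nrow(word_frequencies(empty_events())), 0)

  ev <- make_events(rep("a1", 1),
                    content = "talked about food. made plans for going out. food again")
  wf <- word_frequencies(ev, stopwords = c("about", "for", "out", "again"),
                         extra_exclusions = "talked")
  expect_equal(wf$term[1], "food")
  expect_equal(wf$count[1], 2L)
  expect_setequal(wf$term, c("food", "made", "plans", "going"))
  expect_equal(wf$count[match(c("made", "plans", "going"), wf$term)],
               c(1L, 1L, 1L))
})

test_that("excluded terms never appear and counts aggregate over events", {
  ev <- make_events(c("a1", "a1", "a1"),
                    content = c("We talked about food and music",
                                "said we made plans, plans for FOOD",
                                "going to talk about the food place"))
  wf <- word_frequencies(ev)
  expect_false(any(wf$term %in% stopword_list("en")))
  expect_false(any(wf$term %in% talking_verbs("en")))
  expect_equal(wf$count[wf$term == "food"], 3L)
  expect_equal(wf$count[wf$term == "plans"], 2L)
  expect_true(all(wf$count >= 1))
  # case folding and punctuation stripping
  expect_false(any(grepl("[[:punct:]]", wf$term)))
  expect_equal(wf$term, tolower(wf$term))
})

test_that("simulated interaction content is dominated by food/plans/going", {
  ds <- simulate_participant(simulation_config(seed = 2, n_alters = 20,
                                               n_days = 28,
                                               interactions_per_day = 8))
  wf <- word_frequencies(ds$events)
  expect_true(all(c("food", "plans", "going") %in% head(wf$term, 6)))
})
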