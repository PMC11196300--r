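# Fixture builders and independent oracles used across the suite.

# A minimal event row; extra quality/affect columns via ...
make_events <- function(partner_ids, quality = NULL, times = NULL,
                        is_group = NULL, affect = NULL,
                        content = NA_character_, indicator = "meaningfulness",
                        affect_item = "happy") {
  n <- length(partner_ids)
  ev <- tibble::tibble(
    event_id = sprintf("e%03d", seq_len(n)),
    start_time = if (is.null(times))
      as.POSIXct("2026-01-05 12:00:00", tz = "UTC") + (seq_len(n) - 1) * 3600
    else times,
    mode = "face_to_face",
    duration_min = 30,
    location = "home",
    is_group = if (is.null(is_group)) grepl(";", partner_ids) else is_group,
    category = "casual",
    content_text = rep_len(content, n),
    partner_ids = partner_ids)
  if (!is.null(quality)) ev[[paste0("quality_", indicator)]] <- as.numeric(quality)
  if (!is.null(affect)) ev[[paste0("affect_", affect_item)]] <- as.numeric(affect)
  ev
}

make_alters <- function(ids, roles = "friend", closeness = 5L,
                        origin = "wave1", names = NULL) {
  n <- length(ids)
  alter(ids, names %||% paste("Person", toupper(ids)),
        role = rep_len(roles, n), gender = "unknown",
        closeness = rep_len(closeness, n), origin = rep_len(origin, n))
}

make_wave <- function(label, ids, roles = "friend", ties = NULL,
                      closeness = 5L, origin = "wave1", date = "2026-01-03",
                      names = NULL) {
  network_wave(label, as.Date(date),
               make_alters(ids, roles, closeness, origin, names), ties)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent membership oracle: plain set algebra, no per-id logic shared
# with reconcile().
oracle_partition <- function(pre_ids, post_ids, esm_ids) {
  list(
    stable = sort(intersect(pre_ids, post_ids)),
    removed = sort(union(setdiff(pre_ids, post_ids),
                         setdiff(esm_ids, union(pre_ids, post_ids)))),
    added_during_esm = sort(intersect(setdiff(post_ids, pre_ids), esm_ids)),
    added_post = sort(setdiff(setdiff(post_ids, pre_ids), esm_ids)))
}

recon_partition <- function(result) {
  st <- split(result$status$alter_id, result$status$status)
  lapply(list(stable = "stable", removed = "removed",
              added_during_esm = "added_during_esm", added_post = "added_post"),
         function(k) sort(unname(st[[k]] %||% character(0))))
}

# Brute-force reachability oracle for connected components: repeated
# boolean matrix closure, independent of igraph.
oracle_components <- function(ids, ties) {
  n <- length(ids)
  adj <- diag(TRUE, n)
  rownames(adj) <- colnames(adj) <- ids
  if (nrow(ties) > 0) {
    for (i in seq_len(nrow(ties))) {
      adj[ties$from[i], ties$to[i]] <- TRUE
      adj[ties$to[i], ties$from[i]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- unname(apply(adj, 1, function(r) paste(sort(ids[r]), collapse = ",")))
  unname(lapply(unique(comp), function(s) strsplit(s, ",", fixed = TRUE)[[1]]))
}

# Component lists as canonical sets for comparison.
canon_components <- function(comps) {
  sorted <- lapply(comps, sort)
  sorted[order(vapply(sorted, `[`, character(1), 1))]
}

split_partner_ids <- function(x) strsplit(x, ";", fixed = TRUE)[[1]]

# Mean quality of logged interactions in the window (previous prompt, prompt],
# recomputed from the data alone; NA when the window holds no events.
prompt_window_quality <- function(ds, indicator = "meaningfulness") {
  qcol <- paste0("quality_", indicator)
  sched <- ds$schedule[order(ds$schedule$scheduled_time), ]
  t_prev <- min(sched$scheduled_time) - 86400
  vapply(seq_len(nrow(sched)), function(i) {
    t <- sched$scheduled_time[i]
    sel <- ds$events$start_time > t_prev & ds$events$start_time <= t
    t_prev <<- t
    if (any(sel)) mean(ds$events[[qcol]][sel]) else NA_real_
  }, numeric(1))
}

affect_quality_correlation <- function(ds, affect_item = "happy") {
  q <- prompt_window_quality(ds)
  sched <- ds$schedule[order(ds$schedule$scheduled_time), ]
  a <- ds$responses[[paste0("affect_", affect_item)]][
    match(sched$prompt_id, ds$responses$prompt_id)]
  keep <- !is.na(q) & !is.na(a)
  cor(q[keep], a[keep])
}

affect_by_preceding_quality <- function(ds, affect_item = "happy",
                                        high = 7) {
  q <- prompt_window_quality(ds)
  sched <- ds$schedule[order(ds$schedule$scheduled_time), ]
  a <- ds$responses[[paste0("affect_", affect_item)]][
    match(sched$prompt_id, ds$responses$prompt_id)]
  list(after_high = mean(a[!is.na(a) & !is.na(q) & q >= high]),
       after_none = mean(a[!is.na(a) & is.na(q)]))
}

# Dataset equality on content (ignores attributes such as simulator latents).
expect_dataset_equal <- function(a, b) {
  expect_equal(a$participant_id, b$participant_id)
  expect_equal(names(a$waves), names(b$waves))
  for (w in names(a$waves)) {
    expect_equal(a$waves[[w]]$label, b$waves[[w]]$label)
    expect_equal(a$waves[[w]]$date, b$waves[[w]]$date)
    expect_equal(a$waves[[w]]$alters, b$waves[[w]]$alters)
    expect_equal(a$waves[[w]]$ties, b$waves[[w]]$ties)
  }
  expect_equal(a$schedule, b$schedule)
  expect_equal(a$responses, b$responses)
  expect_equal(a$events, b$events)
  expect_equal(a$roster, b$roster)
  expect_equal(a$anonymisation_mode, b$anonymisation_mode)
}
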