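test_that("seeding with an empty ESM roster reproduces the pre wave", {
  pre <- make_wave("pre", paste0("a", 1:5),
                   ties = data.frame(from = "a1", to = "a2"))
  draft <- seed_post_wave(pre, empty_roster())
  expect_equal(draft$alters, pre$alters)
  expect_equal(draft$ties, pre$ties)
  expect_equal(draft$label, "post")
})

test_that("26 pre-wave alters plus 16 ESM partners seed a 42-member draft", {
  pre <- make_wave("pre", paste0("a", 1:26), closeness = 7L)
  esm <- make_alters(paste0("a", 27:42), origin = "esm")
  draft <- seed_post_wave(pre, esm)
  expect_equal(nrow(draft$alters), 42)
  new <- draft$alters[draft$alters$origin == "esm", ]
  expect_equal(nrow(new), 16)
  expect_true(all(is.na(new$closeness)))
  expect_true(all(is.na(new$gives_emotional_support)))
})

test_that("carried ratings equal the pre-wave ratings field by field", {
  pre <- simulate_participant(simulation_config(seed = 9, n_alters = 15,
                                                n_days = 7))$waves$pre
  draft <- seed_post_wave(pre, make_alters("x1", origin = "esm"))
  carried <- draft$alters[match(pre$alters$alter_id, draft$alters$alter_id), ]
  expect_equal(carried, pre$alters)
})

test_that("id collisions between pre wave and ESM roster are refused", {
  pre <- make_wave("pre", c("a1", "a2"))
  expect_error(seed_post_wave(pre, make_alters("a2", origin = "esm")),
               "collision")
})

test_that("the captured-breakup participant reconciles to the narrative", {
  # post contains everyone from pre plus 16 novel members; the romantic
  # partner is re-categorised as a friend
  pre_roles <- c(rep("friend", 15), rep("family", 6), "romantic_partner",
                 rep("acquaintance", 4))
  pre <- make_wave("pre", paste0("a", 1:26), roles = pre_roles)
  post_roles <- replace(pre_roles, 22, "friend")
  post <- make_wave("post", paste0("a", 1:42),
                    roles = c(post_roles, rep("friend", 16)))
  esm <- make_alters(paste0("a", 27:42), origin = "esm")
  r <- reconcile(pre, post, esm)
  tab <- table(r$status$status)
  expect_equal(unname(tab["added_during_esm"]), 16)
  expect_false("removed" %in% names(tab))
  expect_equal(unname(tab["stable"]), 26)
  expect_equal(r$role_changes,
               tibble::tibble(alter_id = "a22", role_pre = "romantic_partner",
                              role_post = "friend"))
})

test_that("identical waves reconcile to all-stable with no changes", {
  w <- simulate_participant(simulation_config(seed = 3, n_alters = 12,
                                              n_days = 7))$waves$pre
  post <- network_wave("post", w$date, w$alters, w$ties)
  r <- reconcile(w, post, NULL)
  expect_true(all(r$status$status == "stable"))
  expect_equal(nrow(r$role_changes), 0)
  expect_true(all(r$rating_deltas$delta == 0))
  expect_equal(nrow(r$flag_flips), 0)
})

test_that("an ESM partner absent from the post wave is removed, with warning", {
  pre <- make_wave("pre", c("a1", "a2"))
  post <- make_wave("post", c("a1", "a2"))
  esm <- make_alters("x9", origin = "esm")
  expect_warning(r <- reconcile(pre, post, esm), "absent from the post wave")
  expect_equal(r$status$status[r$status$alter_id == "x9"], "removed")
})

test_that("reconcile matches the set-operation oracle on exhaustive fixtures", {
  # every alter is independently in any non-empty subset of
  # {pre, post, esm-roster}: exhaust all 7^n assignments for n <= 4
  combos <- list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                 c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                 c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
                 c(TRUE, TRUE, TRUE))
  for (n in 1:3) {
    grid <- do.call(expand.grid, rep(list(1:7), n))
    for (g in seq_len(nrow(grid))) {
      ids <- paste0("a", seq_len(n))
      member <- vapply(unlist(grid[g, ]), function(k) combos[[k]], logical(3))
      pre_ids <- ids[member[1, ]]
      post_ids <- ids[member[2, ]]
      esm_ids <- ids[member[3, ]]
      pre <- make_wave("pre", pre_ids)
      post <- make_wave("post", post_ids)
      r <- suppressWarnings(reconcile(pre, post, esm_ids))
      expect_identical(recon_partition(r),
                       oracle_partition(pre_ids, post_ids, esm_ids))
      # partition property
      expect_setequal(r$status$alter_id, union(union(pre_ids, post_ids), esm_ids))
      expect_equal(anyDuplicated(r$status$alter_id), 0)
    }
  }
})

test_that("reconcile matches the oracle on random larger fixtures", {
  set.seed(404)
  for (i in 1:50) {
    pool <- paste0("a", 1:60)
    pre_ids <- sample(pool, sample(13:50, 1))
    post_ids <- sample(pool, sample(13:50, 1))
    esm_ids <- sample(pool, sample(0:20, 1))
    r <- suppressWarnings(reconcile(make_wave("pre", pre_ids),
                                    make_wave("post", post_ids), esm_ids))
    expect_identical(recon_partition(r),
                     oracle_partition(pre_ids, post_ids, esm_ids))
    sizes <- table(factor(r$status$status,
                          c("stable", "removed", "added_during_esm",
                            "added_post")))
    expect_equal(sum(sizes), length(union(union(pre_ids, post_ids), esm_ids)))
  }
})

test_that("swapping pre and post maps removed onto the added statuses", {
  set.seed(77)
  for (i in 1:25) {
    pool <- paste0("a", 1:30)
    pre_ids <- sample(pool, sample(5:25, 1))
    post_ids <- sample(pool, sample(5:25, 1))
    esm_ids <- sample(post_ids, min(length(post_ids), sample(0:10, 1)))
    fw <- reconcile(make_wave("pre", pre_ids), make_wave("post", post_ids),
                    esm_ids)
    bw <- reconcile(make_wave("pre", post_ids), make_wave("post", pre_ids),
                    character(0))
    fw_removed <- fw$status$alter_id[fw$status$status == "removed"]
    bw_added <- bw$status$alter_id[bw$status$status %in%
                                     c("added_during_esm", "added_post")]
    expect_setequal(fw_removed, bw_added)
  }
})

test_that("rating deltas cover exactly the items rated in both waves", {
  pre <- make_wave("pre", c("a1", "a2"), closeness = 5L)
  post_alters <- make_alters(c("a1", "a2"), closeness = c(8L, 5L))
  post_alters$closeness[2] <- NA_integer_
  post <- network_wave("post", as.Date("2026-02-01"), post_alters)
  r <- reconcile(pre, post, NULL)
  d <- r$rating_deltas[r$rating_deltas$item == "closeness", ]
  expect_equal(d$alter_id, "a1")
  expect_equal(d$delta, 3L)
})
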