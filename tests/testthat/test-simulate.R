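test_that("the same seed reproduces the dataset byte for byte on disk", {
  cfg <- simulation_config(seed = 19, n_alters = 14, n_days = 7, growth = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_participant(cfg), d1)
  write_dataset(simulate_participant(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("every simulated dataset validates cleanly", {
  for (seed in c(1, 23, 57)) {
    ds <- simulate_participant(simulation_config(
      seed = seed, n_alters = 10 + 3 * seed %% 20, n_days = 10,
      breakup = seed %% 2 == 0, growth = seed %% 5, removals = seed %% 3))
    rep <- validate_dataset(ds)
    expect_equal(nrow(rep[rep$severity == "error", ]), 0)
    expect_true(all(ds$events$duration_min >= 5))
  }
})

test_that("the breakup flag yields exactly one partner-to-friend role change", {
  ds <- simulate_participant(simulation_config(seed = 8, n_alters = 30,
                                               n_days = 7, breakup = TRUE))
  r <- reconcile(ds$waves$pre, ds$waves$post, ds$roster)
  expect_equal(r$role_changes,
               tibble::tibble(alter_id = r$role_changes$alter_id,
                              role_pre = "romantic_partner",
                              role_post = "friend"))
  expect_equal(nrow(r$role_changes), 1)
})

test_that("growth 16 with no removals reconciles to 16 added, 0 removed", {
  ds <- simulate_participant(simulation_config(seed = 8, n_alters = 26,
                                               growth = 16, removals = 0))
  r <- reconcile(ds$waves$pre, ds$waves$post, ds$roster)
  tab <- table(r$status$status)
  expect_equal(unname(tab[["added_during_esm"]]), 16)
  expect_false("removed" %in% names(tab))
  expect_equal(nrow(ds$waves$post$alters), 26 + 16)
})

test_that("requested removals are reflected in the reconciliation", {
  ds <- simulate_participant(simulation_config(seed = 14, n_alters = 20,
                                               n_days = 7, removals = 3))
  r <- reconcile(ds$waves$pre, ds$waves$post, ds$roster)
  expect_equal(sum(r$status$status == "removed"), 3)
})

test_that("with zero noise the estimated partner means equal the latent means", {
  ids <- paste0("a", 1:8)
  mu <- setNames(rep(c(3, 5, 7, 9), 2), ids)
  cfg <- simulation_config(seed = 5, n_alters = 8, n_days = 14,
                           quality_mu = mu, quality_sigma = 0,
                           group_prob = 0, interactions_per_day = 6)
  ds <- simulate_participant(cfg)
  rec <- recovery_report(ds, cfg)
  expect_gt(nrow(rec), 0)
  expect_equal(rec$est_mean, rec$mu, tolerance = 1e-12)
})

test_that("with no coupling, affect is uncorrelated with interaction quality", {
  cfg <- simulation_config(seed = 33, n_alters = 12, n_days = 334,
                           affect_gamma = 0, affect_phi = 0.4)
  ds <- simulate_participant(cfg)
  expect_gte(nrow(ds$schedule), 2000)
  r <- affect_quality_correlation(ds)
  expect_lt(abs(r), 0.1)
})

test_that("with positive coupling, affect is higher after good interactions", {
  cfg <- simulation_config(seed = 34, n_alters = 12, n_days = 28,
                           affect_gamma = 0.4)
  ds <- simulate_participant(cfg)
  m <- affect_by_preceding_quality(ds)
  expect_gt(m$after_high, m$after_none)
})

test_that("with phi = 0 and gamma = 0, affect is white noise around baseline", {
  cfg <- simulation_config(seed = 35, n_alters = 10, n_days = 84,
                           affect_phi = 0, affect_gamma = 0,
                           affect_baseline = 6, affect_noise_sd = 1.5,
                           response_prob = 1)
  ds <- simulate_participant(cfg)
  a <- ds$responses$affect_happy
  a <- a[!is.na(a)]
  n <- length(a)
  expect_lt(abs(mean(a) - 6), 3 * sd(a) / sqrt(n))
  # lag-1 autocorrelation of white noise is near zero
  expect_lt(abs(cor(a[-1], a[-n])), 3 / sqrt(n))
})

test_that("doubling the interaction rate increases every count", {
  base <- simulate_participant(simulation_config(seed = 40, n_alters = 10,
                                                 interactions_per_day = 4))
  dbl <- simulate_participant(simulation_config(seed = 40, n_alters = 10,
                                                interactions_per_day = 8))
  expect_gt(nrow(dbl$events), nrow(base$events))
  c1 <- interaction_counts(base$events, base$roster, "role")
  c2 <- interaction_counts(dbl$events, dbl$roster, "role")
  expect_gte(sum(c2$n), sum(c1$n))
})

test_that("group events draw co-present partners who know each other", {
  ds <- simulate_participant(simulation_config(seed = 44, n_alters = 20,
                                               n_days = 28, group_prob = 0.5))
  grp <- ds$events[ds$events$is_group, ]
  expect_gt(nrow(grp), 0)
  sizes <- lengths(strsplit(grp$partner_ids, ";", fixed = TRUE))
  expect_true(all(sizes >= 2 & sizes <= 4))
})

test_that("95% CIs cover the latent means at the nominal rate", {
  covered <- c(); n_alters_pooled <- 0
  for (seed in 1:24) {
    cfg <- simulation_config(seed = seed, n_alters = 20, n_days = 28,
                             interactions_per_day = 30, partner_tau = 50,
                             group_prob = 0)
    ds <- simulate_participant(cfg)
    rec <- recovery_report(ds, cfg)
    rec <- rec[!is.na(rec$covered) & rec$n >= 30, ]
    covered <- c(covered, rec$covered)
    n_alters_pooled <- n_alters_pooled + nrow(rec)
  }
  expect_gte(n_alters_pooled, 400)
  rate <- mean(covered)
  expect_gte(rate, 0.91)
  expect_lte(rate, 0.99)
})
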