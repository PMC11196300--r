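# Two-wave network reconciliation: post-wave seeding, membership turnover,
# role changes and rating deltas.

#' Seed a post-ESM network wave from the pre wave and the ESM roster
#'
#' Reproduces the re-elicitation flow: all pre-wave members with their
#' ratings carried over, plus every interaction partner first encountered
#' during the ESM period (origin `esm`) with ratings left empty for the
#' participant to fill in. Ties are carried from the pre wave. Identity is
#' by `alter_id` throughout, so later renames are rating changes, never
#' membership turnover.
#'
#' @param pre The pre-ESM [network_wave()].
#' @param esm_roster Tibble of alters with `origin == "esm"` (others are
#'   ignored); ids must not collide with pre-wave ids.
#' @param date Draft assessment date.
#' @return A `post`-labelled [network_wave()] draft.
#' @export
seed_post_wave <- function(pre, esm_roster, date = pre$date) {
  stopifnot(inherits(pre, "network_wave"))
  esm_roster <- esm_roster[esm_roster$origin == "esm", , drop = FALSE]
  clash <- intersect(esm_roster$alter_id, pre$alters$alter_id)
  if (length(clash) > 0) {
    stop("id collision between pre wave and ESM roster: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  blank <- esm_roster
  for (item in ORDINAL_ITEMS) blank[[item]] <- NA_integer_
  for (item in FLAG_ITEMS) blank[[item]] <- NA
  blank$age_bracket <- NA_character_
  network_wave("post", date, rbind(pre$alters, blank), pre$ties)
}

#' Reconcile two network waves against the ESM roster
#'
#' Partitions the union of all alter ids into membership statuses:
#' `stable` (in both waves), `removed` (in the pre wave but dropped at the
#' post assessment), `added_during_esm` (new in the post wave and first
#' seen as an ESM interaction partner) and `added_post` (new in the post
#' wave, first named at the post assessment). An ESM-roster member absent
#' from the post wave is classed `removed` with a warning — the
#' participant declined to keep them. Also reports role changes among
#' stable alters, post-minus-pre deltas for every ordinal rating both
#' waves scored, and flips of the dichotomous relationship flags.
#'
#' @param pre,post [network_wave()] objects with stable ids.
#' @param esm_roster Tibble of alters (only `origin == "esm"` rows are
#'   used) or a character vector of ESM-first alter ids.
#' @return A `reconciliation_result`: list with `status` (tibble
#'   `alter_id`, `status`), `role_changes` (tibble `alter_id`, `role_pre`,
#'   `role_post`), `rating_deltas` (tibble `alter_id`, `item`, `pre`,
#'   `post`, `delta`), `flag_flips` (tibble `alter_id`, `flag`, `pre`,
#'   `post`).
#' @export
reconcile <- function(pre, post, esm_roster = NULL) {
  stopifnot(inherits(pre, "network_wave"), inherits(post, "network_wave"))
  if (anyDuplicated(pre$alters$alter_id) || anyDuplicated(post$alters$alter_id)) {
    stop("duplicate alter ids within a wave", call. = FALSE)
  }
  esm_ids <- if (is.null(esm_roster)) {
    character(0)
  } else if (is.character(esm_roster)) {
    esm_roster
  } else {
    esm_roster$alter_id[esm_roster$origin == "esm"]
  }

  all_ids <- sort(unique(c(pre$alters$alter_id, post$alters$alter_id, esm_ids)))
  # Deliberately a per-id classification (not set algebra) so the
  # set-operation oracle used in tests stays independent.
  status <- vapply(all_ids, function(id) {
    in_pre <- id %in% pre$alters$alter_id
    in_post <- id %in% post$alters$alter_id
    in_esm <- id %in% esm_ids
    if (in_pre && in_post) "stable"
    else if (in_pre) "removed"
    else if (in_post && in_esm) "added_during_esm"
    else if (in_post) "added_post"
    else "removed"  # encountered during ESM, not kept at post assessment
  }, character(1))
  orphans <- all_ids[!(all_ids %in% pre$alters$alter_id) &
                       !(all_ids %in% post$alters$alter_id)]
  if (length(orphans) > 0) {
    warning("ESM partner(s) absent from the post wave, classed removed: ",
            paste(orphans, collapse = ", "), call. = FALSE)
  }

  stable_ids <- all_ids[status == "stable"]
  pre_a <- pre$alters[match(stable_ids, pre$alters$alter_id), , drop = FALSE]
  post_a <- post$alters[match(stable_ids, post$alters$alter_id), , drop = FALSE]

  changed <- which(pre_a$role != post_a$role)
  role_changes <- tibble::tibble(alter_id = stable_ids[changed],
                                 role_pre = pre_a$role[changed],
                                 role_post = post_a$role[changed])

  deltas <- lapply(ORDINAL_ITEMS, function(it) {
    both <- which(!is.na(pre_a[[it]]) & !is.na(post_a[[it]]))
    tibble::tibble(alter_id = stable_ids[both], item = it,
                   pre = as.integer(pre_a[[it]][both]),
                   post = as.integer(post_a[[it]][both]),
                   delta = as.integer(post_a[[it]][both] - pre_a[[it]][both]))
  })
  rating_deltas <- dplyr::bind_rows(deltas)

  flips <- lapply(FLAG_ITEMS, function(fl) {
    both <- which(!is.na(pre_a[[fl]]) & !is.na(post_a[[fl]]) &
                    pre_a[[fl]] != post_a[[fl]])
    tibble::tibble(alter_id = stable_ids[both], flag = fl,
                   pre = pre_a[[fl]][both], post = post_a[[fl]][both])
  })
  flag_flips <- dplyr::bind_rows(flips)

  structure(
    list(status = tibble::tibble(alter_id = all_ids, status = unname(status)),
         role_changes = role_changes,
         rating_deltas = rating_deltas,
         flag_flips = flag_flips),
    class = "reconciliation_result")
}

#' @export
print.reconciliation_result <- function(x, ...) {
  tab <- table(factor(x$status$status,
                      levels = c("stable", "removed", "added_during_esm",
                                 "added_post")))
  cat(sprintf(
    "<reconciliation: %d stable, %d removed, %d added during ESM, %d added post; %d role change(s)>\n",
    tab["stable"], tab["removed"], tab["added_during_esm"], tab["added_post"],
    nrow(x$role_changes)))
  invisible(x)
}
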