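# Dyadic encounter analysis: event streams -> conflicts -> dominance calls,
# behaviour ordination and cage use.

#' Behaviour classification map
#'
#' Maps each coded behaviour to one of three agonistic classes. Offensive
#' and defensive behaviours are "agonistic" and can form conflicts; neutral
#' behaviours never open a conflict. The default map covers the usual
#' male-male encounter vocabulary; site-specific vocabularies can be loaded
#' from a JSON file with the same three top-level keys.
#'
#' @param path Optional path to a JSON file with keys `offensive`,
#'   `defensive`, `neutral`.
#' @return Named list of three character vectors.
#' @export
behavior_classes <- function(path = NULL) {
  if (is.null(path)) {
    return(list(
      offensive = c("attack", "chase", "fight", "bite", "box", "tail_rattle"),
      defensive = c("flight", "escape_to_water", "submissive_posture"),
      neutral   = c("cleaning", "sniffing", "vocalization")
    ))
  }
  classes <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("offensive", "defensive", "neutral") %in% names(classes))) {
    abort("behaviour class file must define offensive, defensive and neutral")
  }
  lapply(classes[c("offensive", "defensive", "neutral")], as.character)
}

behavior_class_of <- function(behavior, classes) {
  cls <- rep(NA_character_, length(behavior))
  for (nm in names(classes)) cls[behavior %in% classes[[nm]]] <- nm
  if (anyNA(cls)) {
    warn(sprintf("unclassified behaviours treated as neutral: %s",
                 paste(unique(behavior[is.na(cls)]), collapse = ", ")))
    cls[is.na(cls)] <- "neutral"
  }
  cls
}

check_event_cols <- function(events) {
  need <- c("dyad_id", "day", "time_s", "actor_id", "behavior")
  miss <- setdiff(need, names(events))
  if (length(miss)) abort(paste("events is missing columns:", paste(miss, collapse = ", ")))
}

#' Segment an encounter event stream into conflicts
#'
#' A conflict (bout) is a maximal run of agonistic-class events within one
#' dyad and session day whose inter-event gaps do not exceed `gap_s`.
#' Neutral events neither open nor extend a conflict. A bout is "decided"
#' when exactly one of the dyad's two members shows at least one
#' defensive-class event; the other member is the bout's winner. Bouts with
#' no defensive event, or in which both members act defensively, are
#' "undecided".
#'
#' @param events Tibble with columns `dyad_id`, `day`, `time_s`, `actor_id`,
#'   `behavior`.
#' @param gap_s Maximal within-bout gap in seconds (default 15, one location
#'   scan interval).
#' @param classes Behaviour class map, see [behavior_classes()].
#' @return Tibble of conflicts: `dyad_id`, `day`, `conflict_id`, `start_s`,
#'   `end_s`, `n_events`, `status` (`"decided"`/`"undecided"`), `winner_id`,
#'   `loser_id`.
#' @export
segment_conflicts <- function(events, gap_s = 15, classes = behavior_classes()) {
  if (gap_s <= 0) abort("gap_s must be positive")
  if (nrow(events) == 0L) {
    return(tibble::tibble(dyad_id = character(), day = integer(),
                          conflict_id = character(), start_s = numeric(),
                          end_s = numeric(), n_events = integer(),
                          status = character(), winner_id = character(),
                          loser_id = character()))
  }
  check_event_cols(events)
  events <- dplyr::mutate(events,
                          behavior_class = behavior_class_of(.data$behavior, classes))
  members <- events |>
    dplyr::distinct(.data$dyad_id, .data$actor_id) |>
    dplyr::group_by(.data$dyad_id) |>
    dplyr::summarise(members = list(sort(unique(.data$actor_id))), .groups = "drop")

  agon <- events |>
    dplyr::filter(.data$behavior_class %in% c("offensive", "defensive")) |>
    dplyr::arrange(.data$dyad_id, .data$day, .data$time_s)
  if (nrow(agon) == 0L) return(segment_conflicts(events[0, ], gap_s, classes))

  agon |>
    dplyr::group_by(.data$dyad_id, .data$day) |>
    dplyr::mutate(bout = cumsum(c(TRUE, diff(.data$time_s) > gap_s))) |>
    dplyr::group_by(.data$dyad_id, .data$day, .data$bout) |>
    dplyr::summarise(
      start_s = min(.data$time_s), end_s = max(.data$time_s),
      n_events = dplyr::n(),
      defensive_actors = list(unique(.data$actor_id[.data$behavior_class == "defensive"])),
      .groups = "drop"
    ) |>
    dplyr::left_join(members, by = "dyad_id") |>
    dplyr::mutate(
      conflict_id = sprintf("%s_d%s_c%03d", .data$dyad_id, .data$day, .data$bout),
      loser_id = purrr::map_chr(.data$defensive_actors,
                                ~ if (length(.x) == 1L) .x else NA_character_),
      winner_id = purrr::map2_chr(.data$members, .data$loser_id, function(mem, los) {
        if (is.na(los)) return(NA_character_)
        other <- setdiff(mem, los)
        if (length(other) == 1L) other else NA_character_
      }),
      status = ifelse(!is.na(.data$winner_id), "decided", "undecided")
    ) |>
    dplyr::select("dyad_id", "day", "conflict_id", "start_s", "end_s",
                  "n_events", "status", "winner_id", "loser_id")
}

#' Score conflicts into per-dyad dominance summaries
#'
#' Pools decided conflicts across session days, tallies wins per dyad
#' member, and attaches an exact two-sided binomial test of an even win
#' split. A member is declared dominant when it won more than half of the
#' decided conflicts and the binomial p-value falls below `alpha`. Dyads
#' without any decided conflict get status `"no_hierarchy"`.
#'
#' @param conflicts Output of [segment_conflicts()] (a single study's dyads).
#' @param dyad_info Optional tibble `individual_id`, `population`,
#'   `weight_g`, `age_d` merged into the summary.
#' @param alpha Dominance significance threshold (default 0.05).
#' @return Tibble with one row per dyad: member ids and win counts, totals,
#'   binomial `statistic`/`p_value`, `dominant_id`, `dominant_population`
#'   (if `dyad_info` given) and `status`.
#' @export
score_dyads <- function(conflicts, dyad_info = NULL, alpha = 0.05) {
  if (nrow(conflicts) == 0L) {
    return(tibble::tibble(dyad_id = character(), id_a = character(),
                          id_b = character(), wins_a = integer(),
                          wins_b = integer(), n_conflicts = integer(),
                          n_decided = integer(), statistic = numeric(),
                          p_value = numeric(), dominant_id = character(),
                          dominant_population = character(), status = character()))
  }
  skipped <- sum(conflicts$status == "decided" & is.na(conflicts$winner_id))
  if (skipped > 0) warn(sprintf("%d conflicts without identifiable participants skipped", skipped))

  summaries <- conflicts |>
    dplyr::group_by(.data$dyad_id) |>
    dplyr::summarise(
      n_conflicts = dplyr::n(),
      n_decided = sum(.data$status == "decided"),
      winners = list(.data$winner_id[.data$status == "decided"]),
      members = list(sort(unique(stats::na.omit(c(.data$winner_id, .data$loser_id))))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      id_a = purrr::map_chr(.data$members, ~ .x[1] %||% NA_character_),
      id_b = purrr::map_chr(.data$members, ~ if (length(.x) > 1) .x[2] else NA_character_),
      wins_a = purrr::map2_int(.data$winners, .data$id_a, ~ sum(.x == .y)),
      wins_b = purrr::map2_int(.data$winners, .data$id_b, ~ sum(.x == .y))
    )
  scored <- summaries |>
    dplyr::mutate(
      test = purrr::map2(.data$wins_a, .data$wins_b, function(wa, wb) {
        if (wa + wb == 0) return(NULL)
        binom_exact(max(wa, wb), wa + wb, 0.5, "two_sided")
      }),
      statistic = purrr::map_dbl(.data$test, ~ if (is.null(.x)) NA_real_ else .x$statistic),
      p_value = purrr::map_dbl(.data$test, ~ if (is.null(.x)) NA_real_ else .x$p_value),
      dominant_id = dplyr::case_when(
        .data$n_decided == 0 ~ NA_character_,
        !is.na(.data$p_value) & .data$p_value < alpha & .data$wins_a > .data$n_decided / 2 ~ .data$id_a,
        !is.na(.data$p_value) & .data$p_value < alpha & .data$wins_b > .data$n_decided / 2 ~ .data$id_b,
        TRUE ~ NA_character_
      ),
      status = dplyr::case_when(
        .data$n_decided == 0 ~ "no_hierarchy",
        !is.na(.data$dominant_id) ~ "hierarchy",
        TRUE ~ "undetermined"
      )
    ) |>
    dplyr::select("dyad_id", "id_a", "id_b", "wins_a", "wins_b",
                  "n_conflicts", "n_decided", "statistic", "p_value",
                  "dominant_id", "status")
  if (!is.null(dyad_info)) {
    pops <- dplyr::select(dyad_info, individual_id = "individual_id",
                          dominant_population = "population")
    scored <- dplyr::left_join(scored, pops,
                               by = c(dominant_id = "individual_id"))
  }
  scored
}

#' Population-level dominance bias tests
#'
#' Given per-dyad summaries and each individual's population, tests (i)
#' whether dyads form hierarchies more often than chance (one-sided
#' continuity-corrected proportion test on the number of dyads with decided
#' conflicts) and (ii) whether one population's members win more dyads than
#' an even split predicts (one-sided toward the majority population).
#'
#' @param summaries Output of [score_dyads()].
#' @param pop_of Named character vector or tibble
#'   (`individual_id`, `population`) mapping individuals to populations.
#' @return A list with `counts` (tibble) and `tests` (tidy tibble); when no
#'   dyad has decided conflicts the tests are skipped with a message.
#' @export
population_bias <- function(summaries, pop_of) {
  if (is.data.frame(pop_of)) {
    pop_of <- setNames(as.character(pop_of$population), pop_of$individual_id)
  }
  n_dyads <- nrow(summaries)
  k_hier <- sum(summaries$n_decided > 0)
  dominant <- summaries$dominant_id[!is.na(summaries$dominant_id)]
  if (k_hier == 0L) {
    inform("no dyad shows decided conflicts; population bias tests skipped")
    return(list(counts = tibble::tibble(n_dyads = n_dyads, n_hierarchy = 0L),
                tests = tibble::tibble()))
  }
  dom_pop <- pop_of[dominant]
  tab <- sort(table(dom_pop), decreasing = TRUE)
  majority <- names(tab)[1]
  k_major <- as.integer(tab[1])
  n_dom <- length(dominant)
  tests <- list(
    hierarchy_prevalence = prop_test_cc(k_hier, n_dyads, 0.5, "greater"),
    population_dominance = prop_test_cc(k_major, n_dom, 0.5, "greater")
  )
  list(
    counts = tibble::tibble(
      n_dyads = n_dyads, n_hierarchy = k_hier, n_dominated = n_dom,
      majority_population = majority, n_won_majority = k_major
    ),
    tests = tidy_tests(tests)
  )
}

#' Individual-by-behaviour count matrix
#'
#' Tallies events per individual over the behaviours that account for more
#' than `min_total_fraction` of all recorded events (the frequency filter is
#' global, computed before tallying).
#'
#' @inheritParams segment_conflicts
#' @param min_total_fraction Keep behaviours above this overall frequency
#'   (default 0.05).
#' @return Count matrix, individuals in rows; ready for [pca_counts()] and
#'   [bray_curtis()].
#' @export
behavior_matrix <- function(events, min_total_fraction = 0.05) {
  check_event_cols(events)
  frac <- table(events$behavior) / nrow(events)
  keep <- names(frac)[frac > min_total_fraction]
  ev <- events[events$behavior %in% keep, ]
  tab <- table(ev$actor_id, ev$behavior)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m[, keep[keep %in% colnames(m)], drop = FALSE]
}

#' Cage-use analysis of the 15-second location scans
#'
#' Computes each individual's visit proportions over the compartments
#' (home, neutral and foreign cage, connecting tubes, water bath / escape
#' cage combined), then asks whether the three main cages are visited
#' equally often (Friedman test over individuals, overall and per
#' population), follows up with pairwise signed-rank tests between cages
#' (Bonferroni, m = 3), and compares foreign-cage use between the two
#' populations (paired within dyads when possible).
#'
#' @param scans Tibble `dyad_id`, `day`, `time_s`, `individual_id`,
#'   `compartment` with compartments in `home`, `neutral`, `foreign`,
#'   `tube`, `water`, `escape`.
#' @param pop_of Optional mapping of individuals to populations (named
#'   vector or tibble as in [population_bias()]).
#' @return List of class `cage_use`: `proportions` (tibble, one row per
#'   individual, proportions summing to 1) and `tests` (tidy tibble with
#'   columns `test`, `group` and Bonferroni-adjusted p-values where
#'   applicable).
#' @export
cage_use <- function(scans, pop_of = NULL) {
  need <- c("dyad_id", "day", "time_s", "individual_id", "compartment")
  miss <- setdiff(need, names(scans))
  if (length(miss)) abort(paste("scans is missing columns:", paste(miss, collapse = ", ")))
  lvl <- c("home", "neutral", "foreign", "tube", "water_escape")
  scans <- dplyr::mutate(scans, compartment = ifelse(
    .data$compartment %in% c("water", "escape"), "water_escape", .data$compartment))
  bad <- setdiff(unique(scans$compartment), lvl)
  if (length(bad)) abort(paste("unknown compartments:", paste(bad, collapse = ", ")))

  props <- scans |>
    dplyr::count(.data$dyad_id, .data$individual_id, .data$compartment) |>
    dplyr::group_by(.data$dyad_id, .data$individual_id) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "prop",
                       values_fill = 0)
  for (cc in setdiff(lvl, names(props))) props[[cc]] <- 0
  props <- props[, c("dyad_id", "individual_id", lvl)]

  if (is.data.frame(pop_of)) {
    pop_of <- setNames(as.character(pop_of$population), pop_of$individual_id)
  }
  props$population <- if (!is.null(pop_of)) unname(pop_of[props$individual_id]) else NA_character_

  main <- as.matrix(props[, c("home", "neutral", "foreign")])
  rownames(main) <- props$individual_id
  tests <- list()
  tests[["friedman_all"]] <- friedman_rank(main)
  if (!is.null(pop_of)) {
    for (p in sort(unique(stats::na.omit(props$population)))) {
      sub <- main[props$population == p, , drop = FALSE]
      if (nrow(sub) >= 2) tests[[paste0("friedman_", p)]] <- friedman_rank(sub)
    }
  }
  pairs <- list(c("home", "neutral"), c("home", "foreign"), c("neutral", "foreign"))
  for (pr in pairs) {
    tests[[paste0("wilcoxon_", pr[1], "_vs_", pr[2])]] <-
      wilcoxon_signed_rank(main[, pr[1]], main[, pr[2]])
  }
  out <- tidy_tests(tests)
  pairwise <- grepl("^wilcoxon_", out$test)
  out$p.adjusted <- NA_real_
  out$p.adjusted[pairwise] <- bonferroni_adjust(out$p.value[pairwise], m = 3)

  if (!is.null(pop_of) && length(unique(stats::na.omit(props$population))) == 2) {
    pops <- sort(unique(stats::na.omit(props$population)))
    wide <- props |>
      dplyr::filter(!is.na(.data$population)) |>
      dplyr::select("dyad_id", "population", "foreign") |>
      tidyr::pivot_wider(names_from = "population", values_from = "foreign")
    paired <- !anyNA(wide[[pops[1]]]) && !anyNA(wide[[pops[2]]]) &&
      all(lengths(wide[[pops[1]]]) == 1)
    ft <- if (paired) {
      wilcoxon_signed_rank(unlist(wide[[pops[1]]]), unlist(wide[[pops[2]]]))
    } else {
      mann_whitney(props$foreign[props$population == pops[1]],
                   props$foreign[props$population == pops[2]])
    }
    ftd <- tidy(ft); ftd$test <- "foreign_use_between_populations"
    ftd$p.adjusted <- NA_real_
    out <- dplyr::bind_rows(out, ftd[, names(out)])
  }
  structure(list(proportions = props, tests = out), class = "cage_use")
}

#' @export
print.cage_use <- function(x, ...) {
  cat(sprintf("Cage use of %d individuals\n", nrow(x$proportions)))
  print(x$tests, ...)
  invisible(x)
}
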