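# Bundled example data: published summary tables from an encounter and
# enclosure study of two wild-derived western house-mouse populations --
# MC (Massif Central, France) and CB (Cologne/Bonn, Germany). These are the
# printed per-dyad and per-room summaries, not raw observation streams, and
# serve as worked-example inputs for the aggregate analyses.

#' Example per-dyad encounter outcomes (15 MC x CB male dyads)
#'
#' One row per individual (two per dyad): population of origin, body weight,
#' age at testing, and the number of decided conflicts the individual won,
#' pooled over both 10-minute session days.
#'
#' @return Tibble with columns `dyad`, `population`, `weight_g`, `age_d`,
#'   `wins`.
#' @examples
#' encounter_summary(example_dyads())
#' @export
example_dyads <- function() {
  cb <- tibble::tibble(
    dyad = 1:15, population = "CB",
    weight_g = c(33.64, 34.02, 34.75, 36.56, 36.77, 23.91, 25.06, 25.38,
                 26.60, 27.00, 24.53, 28.21, 28.62, 28.70, 28.71),
    age_d = c(288, 306, 318, 326, 315, 326, 293, 326, 319, 344, 319, 293,
              316, 288, 290),
    wins = c(28L, 0L, 0L, 27L, 39L, 0L, 12L, 25L, 0L, 22L, 0L, 8L, 6L, 11L, 11L)
  )
  mc <- tibble::tibble(
    dyad = 1:15, population = "MC",
    weight_g = c(19.89, 20.57, 21.64, 21.84, 24.08, 27.94, 28.43, 31.17,
                 33.36, 35.83, 24.27, 24.73, 25.62, 26.65, 26.89),
    age_d = c(313, 301, 313, 401, 331, 309, 311, 309, 309, 383, 382, 383,
              331, 343, 401),
    wins = c(2L, 0L, 24L, 0L, 0L, 28L, 1L, 1L, 24L, 2L, 0L, 0L, 0L, 0L, 0L)
  )
  dplyr::arrange(dplyr::bind_rows(cb, mc), .data$dyad, .data$population)
}

#' Example offspring sire counts per enclosure room
#'
#' Mixed-background offspring attributed to a sire population by the
#' top-two-parent consensus rule, per duplicate enclosure room.
#'
#' @return Tibble with columns `room`, `cb_sired`, `mc_sired`,
#'   `undetermined`.
#' @examples
#' sire_population_test(example_sire_counts())
#' @export
example_sire_counts <- function() {
  tibble::tibble(
    room = c("113", "114"),
    cb_sired = c(11L, 33L),
    mc_sired = c(5L, 3L),
    undetermined = c(3L, 10L)
  )
}

#' Summarise a per-dyad win table
#'
#' Entry point for dominance analysis when the per-dyad decided-conflict
#' counts are already known (e.g. scored live). Attaches the exact binomial
#' test per dyad, population totals, the aggregate hierarchy-prevalence and
#' population-dominance proportion tests, and the between/within-dyad weight
#' comparisons (rank-sum between populations; signed-rank within dyads,
#' reported for both difference directions since V depends on it).
#'
#' @param dyads Tibble as returned by [example_dyads()]: one row per
#'   individual with `dyad`, `population`, `weight_g`, `age_d`, `wins`.
#' @param alpha Dominance significance threshold (default 0.05).
#' @return List with `dyads` (wide per-dyad table), `totals` (per
#'   population), `counts` and `tests` (tidy tibble).
#' @export
encounter_summary <- function(dyads, alpha = 0.05) {
  need <- c("dyad", "population", "weight_g", "age_d", "wins")
  miss <- setdiff(need, names(dyads))
  if (length(miss)) abort(paste("dyads is missing columns:", paste(miss, collapse = ", ")))
  pops <- sort(unique(dyads$population))
  if (length(pops) != 2L) abort("exactly two populations expected")

  wide <- dyads |>
    tidyr::pivot_wider(id_cols = "dyad", names_from = "population",
                       values_from = c("weight_g", "age_d", "wins")) |>
    dplyr::mutate(
      n_decided = .data[[paste0("wins_", pops[1])]] + .data[[paste0("wins_", pops[2])]],
      p_value = purrr::map2_dbl(
        pmax(.data[[paste0("wins_", pops[1])]], .data[[paste0("wins_", pops[2])]]),
        .data$n_decided,
        function(k, n) if (n == 0) NA_real_ else binom_exact(k, n)$p_value),
      dominant_population = dplyr::case_when(
        .data$n_decided == 0 ~ NA_character_,
        .data$p_value < alpha &
          .data[[paste0("wins_", pops[1])]] > .data$n_decided / 2 ~ pops[1],
        .data$p_value < alpha &
          .data[[paste0("wins_", pops[2])]] > .data$n_decided / 2 ~ pops[2],
        TRUE ~ NA_character_
      )
    )

  totals <- dyads |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_weight_g = mean(.data$weight_g),
                     mean_age_d = mean(.data$age_d),
                     decided_won = sum(.data$wins), .groups = "drop")

  n_dyads <- nrow(wide)
  k_hier <- sum(wide$n_decided > 0)
  dom <- wide$dominant_population[!is.na(wide$dominant_population)]
  tab <- sort(table(dom), decreasing = TRUE)
  majority <- names(tab)[1]
  w1 <- dyads$weight_g[dyads$population == pops[1]][order(dyads$dyad[dyads$population == pops[1]])]
  w2 <- dyads$weight_g[dyads$population == pops[2]][order(dyads$dyad[dyads$population == pops[2]])]
  tests <- list(
    hierarchy_prevalence = prop_test_cc(k_hier, n_dyads, 0.5, "greater"),
    population_dominance = prop_test_cc(as.integer(tab[1]), length(dom), 0.5, "greater"),
    weight_between_populations = mann_whitney(w1, w2),
    weight_within_dyads = wilcoxon_signed_rank(w1, w2),
    weight_within_dyads_reversed = wilcoxon_signed_rank(w2, w1)
  )
  list(
    dyads = wide,
    totals = totals,
    counts = tibble::tibble(
      n_dyads = n_dyads, n_hierarchy = k_hier,
      total_decided = sum(wide$n_decided),
      majority_population = majority,
      n_won_majority = as.integer(tab[1]), n_dominated = length(dom)
    ),
    tests = tidy_tests(tests)
  )
}
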