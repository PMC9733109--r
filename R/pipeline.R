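# End-to-end stage runners. Each is a pure function of (inputs, config);
# the effective configuration travels with the result so any run can be
# reproduced exactly.

#' Run the complete encounter-experiment analysis
#'
#' Segments the event stream into conflicts, scores dominance per dyad,
#' tests the population-level bias, ordains the individual behaviour
#' profiles (PCA, Bray-Curtis + ANOSIM on population background, Mantel
#' tests of weight and age distance against behavioural distance), and
#' summarises cage use from the location scans when available.
#'
#' @param events Behaviour event tibble (`dyad_id`, `day`, `time_s`,
#'   `actor_id`, `behavior`).
#' @param scans Optional location-scan tibble; when `NULL` the cage-use
#'   stage is skipped with a notice.
#' @param dyad_info Tibble `individual_id`, `population`, `weight_g`,
#'   `age_d`.
#' @param gap_s Conflict segmentation gap (default 15 s).
#' @param classes Behaviour class map.
#' @param min_total_fraction Behaviour frequency filter (default 0.05).
#' @param alpha Dominance threshold (default 0.05).
#' @param n_perm_anosim,n_perm_mantel Permutation counts (999 and 9999).
#' @param seed RNG seed for all permutation tests.
#' @return List with `conflicts`, `dyads`, `bias`, `pca`, `anosim`,
#'   `mantel_weight`, `mantel_age`, `cage_use`, `config`.
#' @export
run_encounter <- function(events, scans = NULL, dyad_info,
                          gap_s = 15, classes = behavior_classes(),
                          min_total_fraction = 0.05, alpha = 0.05,
                          n_perm_anosim = 999, n_perm_mantel = 9999,
                          seed = 1234) {
  conflicts <- segment_conflicts(events, gap_s = gap_s, classes = classes)
  dyads <- score_dyads(conflicts, dyad_info = dyad_info, alpha = alpha)
  bias <- if (nrow(dyads) > 0) population_bias(dyads, dyad_info) else NULL

  pca <- anosim <- mantel_weight <- mantel_age <- NULL
  if (nrow(events) > 0) {
    bm <- behavior_matrix(events, min_total_fraction = min_total_fraction)
    if (nrow(bm) >= 3 && ncol(bm) >= 2) {
      pca <- pca_counts(bm, min_total_fraction = 0) # already filtered
      pop_of <- setNames(dyad_info$population, dyad_info$individual_id)
      groups <- pop_of[rownames(bm)]
      if (length(unique(groups)) == 2 && all(table(groups) >= 2)) {
        anosim <- anosim_test(bray_curtis(bm), groups,
                              n_perm = n_perm_anosim, seed = seed)
      }
      props <- sweep(bm, 1, rowSums(bm), "/")
      dm_beh <- as.matrix(stats::dist(props))
      info <- dyad_info[match(rownames(bm), dyad_info$individual_id), ]
      if (!anyNA(info$weight_g)) {
        dm_w <- as.matrix(stats::dist(info$weight_g))
        dimnames(dm_w) <- dimnames(dm_beh)
        mantel_weight <- mantel_test(dm_beh, dm_w, n_perm = n_perm_mantel,
                                     seed = seed)
      }
      if (!anyNA(info$age_d)) {
        dm_a <- as.matrix(stats::dist(info$age_d))
        dimnames(dm_a) <- dimnames(dm_beh)
        mantel_age <- mantel_test(dm_beh, dm_a, n_perm = n_perm_mantel,
                                  seed = seed)
      }
    }
  }
  cage <- NULL
  if (!is.null(scans) && nrow(scans) > 0) {
    cage <- cage_use(scans, pop_of = dyad_info)
  } else {
    inform("no location scans supplied; cage-use analysis skipped")
  }
  list(conflicts = conflicts, dyads = dyads, bias = bias, pca = pca,
       anosim = anosim, mantel_weight = mantel_weight,
       mantel_age = mantel_age, cage_use = cage,
       config = list(gap_s = gap_s, min_total_fraction = min_total_fraction,
                     alpha = alpha, n_perm_anosim = n_perm_anosim,
                     n_perm_mantel = n_perm_mantel, seed = seed))
}

#' Run the complete enclosure-tracking analysis
#'
#' Infers arena occupancy from the antenna reads, derives the per-mouse
#' movement metrics, and compares the two populations.
#'
#' @param reads Antenna read tibble (`time_s`, `tube`, `side`, `tag_id`).
#' @param manifest Tibble `tag_id`, `population`, `sex`, `weight_g`,
#'   `home_arena`.
#' @param t_open,t_end Experiment window in seconds.
#' @param session_gap_s Session definition gap (default 10 s).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param seed RNG seed.
#' @return List with `occupancy`, `metrics`, `comparison`, `config`.
#' @export
run_enclosure <- function(reads, manifest, t_open, t_end,
                          session_gap_s = 10, n_perm = 999, seed = 1234) {
  if (nrow(reads) == 0 || !any(reads$tag_id %in% manifest$tag_id)) {
    abort("no manifest tag was ever read; nothing to analyse")
  }
  occupancy <- infer_occupancy(reads, setNames(manifest$home_arena, manifest$tag_id),
                               t_open, t_end)
  metrics <- rfid_metrics(reads, manifest, t_open, t_end,
                          session_gap_s = session_gap_s)
  comparison <- cohort_compare(metrics, n_perm = n_perm, seed = seed)
  list(occupancy = occupancy, metrics = metrics, comparison = comparison,
       config = list(t_open = t_open, t_end = t_end,
                     session_gap_s = session_gap_s, n_perm = n_perm,
                     seed = seed))
}

#' Run the complete population-assignment and parentage analysis
#'
#' Estimates founder allele-frequency panels, assigns every non-founder an
#' admixture proportion and origin class, runs the top-two-parent consensus
#' parentage for the mixed-background offspring, and tests the per-room and
#' pooled sire-population proportions.
#'
#' @param genotypes Long genotype tibble.
#' @param manifest Tibble `individual_id`, `sex`, `cohort`, `room`,
#'   `population` (population filled for founders).
#' @param error_rate Genotyping error rate (default 0.01).
#' @param pseudocount Allele-frequency smoothing (default 0.5).
#' @param thresholds Pure-class cutoffs (default 0.9 / 0.1).
#' @param min_loci Minimal typed loci for assignment (default 6).
#' @param min_founders Minimal founders per population (default 5).
#' @return List with `panel`, `assignments`, `class_counts`, `parentage`,
#'   `sire_counts`, `sire_tests`, `config`.
#' @export
run_popgen <- function(genotypes, manifest, error_rate = 0.01,
                       pseudocount = 0.5, thresholds = c(0.9, 0.1),
                       min_loci = 6, min_founders = 5) {
  founders <- manifest[manifest$cohort == "founder" & !is.na(manifest$population), ]
  pops <- sort(unique(founders$population))
  if (length(pops) != 2L) abort("need founders of exactly two populations")
  if (any(table(founders$population) < min_founders)) {
    abort(sprintf("fewer than %d founders in a population; panel too small",
                  min_founders))
  }
  panel <- estimate_freqs(
    genotypes[genotypes$individual_id %in% founders$individual_id, ],
    founders, pseudocount = pseudocount)
  others <- setdiff(unique(genotypes$individual_id), founders$individual_id)
  assignments <- assign_origin(genotypes[genotypes$individual_id %in% others, ],
                               panel, thresholds = thresholds,
                               min_loci = min_loci)
  assignments <- dplyr::left_join(
    assignments,
    manifest[, c("individual_id", "cohort", "room")], by = "individual_id")
  class_counts <- dplyr::count(assignments, .data$cohort, .data$class)

  mixed_ids <- assignments$individual_id[assignments$class == "mixed" &
                                           !isTRUE(assignments$uninformative)]
  parentage <- if (length(mixed_ids) > 0) {
    assign_parent_population(mixed_ids, genotypes, manifest,
                             error_rate = error_rate,
                             pseudocount = pseudocount)
  } else tibble::tibble()
  if (nrow(parentage) > 0) {
    sires <- parentage[parentage$parent_sex == "M", ]
    rooms <- setNames(manifest$room, manifest$individual_id)
    sires$room <- rooms[sires$offspring_id]
    sire_counts <- sires |>
      dplyr::group_by(room = .data$room) |>
      dplyr::summarise(
        !!paste0(tolower(pops[1]), "_sired") :=
          sum(.data$consensus_population == pops[1]),
        !!paste0(tolower(pops[2]), "_sired") :=
          sum(.data$consensus_population == pops[2]),
        undetermined = sum(.data$consensus_population == "undetermined"),
        .groups = "drop")
    sire_tests <- sire_population_test(sire_counts, populations = pops)
  } else {
    sire_counts <- tibble::tibble()
    sire_tests <- tibble::tibble()
  }
  list(panel = panel, assignments = assignments, class_counts = class_counts,
       parentage = parentage, sire_counts = sire_counts,
       sire_tests = sire_tests,
       config = list(error_rate = error_rate, pseudocount = pseudocount,
                     thresholds = thresholds, min_loci = min_loci))
}
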