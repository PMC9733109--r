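# Agent-based generators for the three data streams the analysis consumes:
# dyadic encounter ethograms, two-arena enclosure RFID logs, and two-
# population microsatellite pedigrees. Every generator attaches the ground
# truth needed to score the downstream inference, and a single root seed
# fans out to one RNG stream per simulated unit (dyad / mouse / section),
# so enlarging a simulation never perturbs the draws of earlier units.

stream_seed <- function(seed, component, i) {
  as.integer((as.numeric(seed) + component * 7919 + as.numeric(i) * 1000003) %% 2147483647)
}

draw_multinom <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Simulate dyadic encounter experiments
#'
#' Each dyad pairs one individual per population and is observed for
#' `sessions_per_dyad` sessions of `session_length_s` seconds. Conflicts
#' arrive Poisson per session (capped so that inter-bout gaps stay above
#' `gap_s`, keeping the stream segmentable), are decided with probability
#' `decided_prob`, and a decided conflict is won by the dyad's dominant
#' member with probability `dominant_win_prob`. Decided bouts emit
#' offensive events by the winner and at least one defensive event by the
#' loser; undecided bouts are offensive-only on both sides. Neutral
#' behaviours (sniffing, cleaning, vocalization -- the latter biased toward
#' subordinates) are sprinkled independently. Location scans are emitted
#' every `scan_interval_s` seconds from a per-role compartment Markov
#' chain in which subordinates avoid the foreign cage.
#'
#' Defaults mirror the encounter-study conditions: 15 dyads, two 10-minute
#' sessions, about 21 conflicts per session of which ~42% are decided, a
#' near-deterministic dominant (d = 0.95) and a 10:3 bias of dominance
#' toward the first population.
#'
#' @param n_dyads Number of dyads (default 15).
#' @param sessions_per_dyad Sessions per dyad (default 2).
#' @param session_length_s Session length in seconds (default 600).
#' @param conflict_rate Mean conflicts per session (default 21.3).
#' @param decided_prob Probability a conflict is decided (default 0.42).
#' @param dominant_win_prob Probability the dominant wins a decided
#'   conflict (default 0.95).
#' @param p_dominant_a Probability the population-A member is the dyad's
#'   dominant (default 10/13).
#' @param populations Two population labels (default `c("CB", "MC")`).
#' @param gap_s Minimal between-bout gap the generator respects
#'   (default 15).
#' @param scan_interval_s Location-scan interval (default 15).
#' @param neutral_rate Mean neutral events per individual per session
#'   (default 20).
#' @param seed Root RNG seed (default 1234).
#' @return List `events`, `scans`, `truth` (per-dyad member ids,
#'   populations and the true dominant) and `config`.
#' @export
simulate_dyads <- function(n_dyads = 15, sessions_per_dyad = 2,
                           session_length_s = 600, conflict_rate = 21.3,
                           decided_prob = 0.42, dominant_win_prob = 0.95,
                           p_dominant_a = 10 / 13,
                           populations = c("CB", "MC"), gap_s = 15,
                           scan_interval_s = 15, neutral_rate = 20,
                           seed = 1234) {
  stopifnot(conflict_rate >= 0, decided_prob >= 0, decided_prob <= 1,
            dominant_win_prob >= 0, dominant_win_prob <= 1)
  offensive <- c(attack = 0.35, chase = 0.25, tail_rattle = 0.15, box = 0.1,
                 fight = 0.1, bite = 0.05)
  defensive <- c(flight = 0.6, submissive_posture = 0.25, escape_to_water = 0.15)
  neutral_dom <- c(sniffing = 0.5, cleaning = 0.4, vocalization = 0.1)
  neutral_sub <- c(sniffing = 0.4, cleaning = 0.2, vocalization = 0.4)
  comps <- c("home", "neutral", "foreign", "tube", "water", "escape")
  pref_dom <- c(home = 0.30, neutral = 0.25, foreign = 0.25, tube = 0.10,
                water = 0.05, escape = 0.05)
  pref_sub <- c(home = 0.50, neutral = 0.30, foreign = 0.05, tube = 0.08,
                water = 0.03, escape = 0.04)

  events <- list(); scans <- list(); truth <- list()
  bout_span_max <- 6 # events within a bout stay inside this span
  capacity <- floor(session_length_s / (gap_s + bout_span_max + 2))
  for (d in seq_len(n_dyads)) {
    withr::with_seed(stream_seed(seed, 1L, d), {
      dyad <- sprintf("d%02d", d)
      ids <- setNames(paste(dyad, populations, sep = "_"), populations)
      dominant_pop <- if (runif(1) < p_dominant_a) populations[1] else populations[2]
      dominant <- ids[[dominant_pop]]
      subordinate <- setdiff(unname(ids), dominant)
      any_decided <- FALSE
      for (s in seq_len(sessions_per_dyad)) {
        n_conf <- min(rpois(1, conflict_rate), capacity)
        ev <- list()
        if (n_conf > 0) {
          # lay out bouts left to right with gaps strictly above gap_s
          slack <- session_length_s - n_conf * (gap_s + bout_span_max + 1)
          starts <- cumsum(c(runif(1, 0, max(slack / (n_conf + 1), 1)),
                             rep(gap_s + bout_span_max + 1, max(n_conf - 1, 0)))) +
            (seq_len(n_conf) - 1) * 0
          for (b in seq_len(n_conf)) {
            decided <- runif(1) < decided_prob
            winner <- if (runif(1) < dominant_win_prob) dominant else subordinate
            loser <- setdiff(c(dominant, subordinate), winner)
            if (decided) {
              beh_w <- draw_multinom(sample(1:3, 1), offensive)
              beh_l <- draw_multinom(sample(1:2, 1), defensive)
              actors <- c(rep(winner, length(beh_w)), rep(loser, length(beh_l)))
              beh <- c(beh_w, beh_l)
            } else {
              b1 <- draw_multinom(sample(1:2, 1), offensive)
              b2 <- draw_multinom(sample(1:2, 1), offensive)
              actors <- c(rep(dominant, length(b1)), rep(subordinate, length(b2)))
              beh <- c(b1, b2)
            }
            ord <- sample(length(beh))
            times <- starts[b] + cumsum(runif(length(beh), 0.3, 1.2))
            ev[[length(ev) + 1L]] <- tibble::tibble(
              dyad_id = dyad, day = s, time_s = times,
              actor_id = actors[ord], behavior = beh[ord])
            if (decided) any_decided <- TRUE
          }
        }
        # neutral chatter, role-dependent
        for (who in c(dominant, subordinate)) {
          nv <- rpois(1, neutral_rate)
          if (nv > 0) {
            probs <- if (who == dominant) neutral_dom else neutral_sub
            ev[[length(ev) + 1L]] <- tibble::tibble(
              dyad_id = dyad, day = s,
              time_s = sort(runif(nv, 0, session_length_s)),
              actor_id = who, behavior = draw_multinom(nv, probs))
          }
        }
        events[[length(events) + 1L]] <-
          dplyr::arrange(dplyr::bind_rows(ev), .data$time_s)
        # location scans from a lazy Markov chain over compartments
        for (who in c(dominant, subordinate)) {
          pref <- if (who == dominant) pref_dom else pref_sub
          ticks <- seq(0, session_length_s - scan_interval_s, by = scan_interval_s)
          state <- "home"
          path <- character(length(ticks))
          for (k in seq_along(ticks)) {
            if (runif(1) < 0.5) state <- draw_multinom(1, pref)
            path[k] <- state
          }
          scans[[length(scans) + 1L]] <- tibble::tibble(
            dyad_id = dyad, day = s, time_s = ticks,
            individual_id = who, compartment = path)
        }
      }
      truth[[d]] <- tibble::tibble(
        dyad_id = dyad, id_a = ids[[populations[1]]], id_b = ids[[populations[2]]],
        population_a = populations[1], population_b = populations[2],
        dominant_id = dominant, dominant_population = dominant_pop,
        any_decided = any_decided)
    })
  }
  list(events = dplyr::bind_rows(events), scans = dplyr::bind_rows(scans),
       truth = dplyr::bind_rows(truth),
       config = list(n_dyads = n_dyads, sessions_per_dyad = sessions_per_dyad,
                     session_length_s = session_length_s,
                     conflict_rate = conflict_rate, decided_prob = decided_prob,
                     dominant_win_prob = dominant_win_prob,
                     p_dominant_a = p_dominant_a, gap_s = gap_s,
                     scan_interval_s = scan_interval_s, seed = seed))
}

#' Simulate a two-arena enclosure with RFID antennae
#'
#' Each mouse performs a memoryless (continuous-time Markov) movement
#' process: after a first-exploration waiting time it visits the three
#' connecting tubes at a population-specific rate, dwells briefly, and
#' either crosses to the other arena or retreats. Every true antenna pass
#' (one at tube entry, one at exit, on the side where the mouse enters or
#' leaves) is detected independently with probability `p_detect`. The
#' two parameter sets encode the observed ordering between the
#' populations -- the first population explores sooner, crosses more and
#' stays longer in the foreign arena -- without claiming magnitudes.
#'
#' @param n_mice Two mice counts, named by population (default
#'   `c(CB = 35, MC = 35)`).
#' @param duration_h Experiment length in hours after opening
#'   (default 2016, i.e. 12 weeks).
#' @param params Per-population movement rates; see the function body for
#'   the structure (`explore_hazard_h`, `tube_entry_h`, `p_cross`,
#'   `dwell_s`, `foreign_return_h`, `p_return`).
#' @param p_detect Detection probability per antenna pass (default 0.95).
#' @param n_tubes Number of connecting tubes (default 3).
#' @param seed Root RNG seed.
#' @return List `reads` (antenna log), `manifest` (tag, population, sex,
#'   weight, home arena), `truth` (per-mouse true first touch, crossing
#'   count and times, tube and foreign-arena occupancy) and `config`.
#' @export
simulate_enclosure <- function(n_mice = c(CB = 35, MC = 35),
                               duration_h = 2016,
                               params = NULL, p_detect = 0.95,
                               n_tubes = 3, seed = 1234) {
  if (p_detect <= 0 || p_detect > 1) abort("p_detect must be in (0, 1]")
  pops <- names(n_mice)
  if (length(pops) != 2L) abort("n_mice must name exactly two populations")
  if (is.null(params)) {
    params <- list(
      list(explore_hazard_h = 40, tube_entry_h = 1.2, p_cross = 0.25,
           dwell_s = 8, foreign_return_h = 4, p_return = 0.6),
      list(explore_hazard_h = 15, tube_entry_h = 0.6, p_cross = 0.10,
           dwell_s = 10, foreign_return_h = 12, p_return = 0.6))
    names(params) <- pops
  }
  t_end <- duration_h * 3600
  sides <- setNames(c("A", "B"), pops) # home arena per population
  reads <- list(); manifest <- list(); truth <- list()
  idx <- 0L
  for (p in pops) {
    pp <- params[[p]]
    for (m in seq_len(n_mice[[p]])) {
      idx <- idx + 1L
      withr::with_seed(stream_seed(seed, 2L, idx), {
        tag <- sprintf("%s%03d", p, m)
        home <- sides[[p]]
        sex <- sample(c("M", "F"), 1)
        weight <- max(10, rnorm(1, 20, 4))
        cur <- home
        t <- rexp(1, pp$explore_hazard_h / 3600)
        first_touch <- if (t < t_end) t else NA_real_
        cross_times <- numeric(0)
        tube_s <- 0; foreign_s <- 0
        rr <- list()
        last_arena_enter <- 0
        in_tube_at_end <- FALSE
        while (t < t_end) {
          tube <- sample.int(n_tubes, 1)
          dwell <- rexp(1, 1 / pp$dwell_s)
          t_exit <- min(t + dwell, t_end)
          if (cur != home) foreign_s <- foreign_s + (t - last_arena_enter)
          if (runif(1) < p_detect) {
            rr[[length(rr) + 1L]] <- tibble::tibble(
              time_s = t, tube = tube, side = cur, tag_id = tag)
          }
          p_go <- if (cur == home) pp$p_cross else pp$p_return
          crossed <- runif(1) < p_go && t + dwell < t_end
          exit_side <- if (crossed) setdiff(c("A", "B"), cur) else cur
          if (t_exit > t) tube_s <- tube_s + (t_exit - t)
          if (t_exit >= t_end) { in_tube_at_end <- TRUE; break }
          if (runif(1) < p_detect) {
            rr[[length(rr) + 1L]] <- tibble::tibble(
              time_s = t_exit, tube = tube, side = exit_side, tag_id = tag)
          }
          if (crossed) {
            cross_times <- c(cross_times, t_exit)
            cur <- exit_side
          }
          last_arena_enter <- t_exit
          rate_h <- if (cur == home) pp$tube_entry_h else pp$foreign_return_h
          t <- t_exit + rexp(1, rate_h / 3600)
        }
        if (!in_tube_at_end && cur != home) {
          foreign_s <- foreign_s + (t_end - last_arena_enter)
        }
        reads[[idx]] <- dplyr::bind_rows(rr)
        manifest[[idx]] <- tibble::tibble(
          tag_id = tag, population = p, sex = sex, weight_g = weight,
          home_arena = home)
        truth[[idx]] <- tibble::tibble(
          tag_id = tag, first_touch_s = first_touch,
          n_crossings = length(cross_times),
          crossing_times = list(cross_times),
          tube_time_s = tube_s, foreign_time_s = foreign_s)
      })
    }
  }
  list(reads = dplyr::arrange(dplyr::bind_rows(reads), .data$tag_id, .data$time_s),
       manifest = dplyr::bind_rows(manifest),
       truth = dplyr::bind_rows(truth),
       config = list(n_mice = as.list(n_mice), duration_h = duration_h,
                     params = params, p_detect = p_detect,
                     n_tubes = n_tubes, seed = seed))
}

#' Simulate a two-population microsatellite pedigree
#'
#' Per-locus ancestral allele frequencies are drawn from a flat Dirichlet;
#' the two population panels are then drawn from
#' `Dirichlet(p_ancestral * (1 - fst) / fst)`, which targets the requested
#' divergence in expectation. Founders are drawn in Hardy-Weinberg
#' proportions; offspring arise by Mendelian transmission from named
#' parents (pure matings within a population, mixed matings across);
#' genotyping error and missingness are applied last. The truth table
#' lists each offspring's parents, class and sire population.
#'
#' @param n_loci Number of microsatellite loci (default 13).
#' @param n_alleles Alleles per locus (default 8).
#' @param fst Target divergence between the populations (default 0.15).
#' @param founders_per_pop Founders per population (default 25, half of
#'   each sex).
#' @param n_pure_matings,n_mixed_matings Numbers of within- and
#'   cross-population matings (defaults 10 and 10; mixed matings alternate
#'   the sire population).
#' @param offspring_per_mating Offspring per mating (default 3).
#' @param error_rate Per-allele genotyping error (default 0).
#' @param missing_rate Per-locus missing probability (default 0).
#' @param populations Population labels (default `c("CB", "MC")`).
#' @param room Room label written to the manifest (default `"113"`).
#' @param seed Root RNG seed.
#' @return List `genotypes` (long tibble), `manifest`, `truth`, `freqs`
#'   (the true panels) and `config`.
#' @export
simulate_pedigree <- function(n_loci = 13, n_alleles = 8, fst = 0.15,
                              founders_per_pop = 25, n_pure_matings = 10,
                              n_mixed_matings = 10, offspring_per_mating = 3,
                              error_rate = 0, missing_rate = 0,
                              populations = c("CB", "MC"), room = "113",
                              seed = 1234) {
  stopifnot(n_loci >= 1, fst >= 0)
  loci <- sprintf("L%02d", seq_len(n_loci))
  rdirichlet1 <- function(alpha) {
    x <- rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(x) == 0) x <- rep(1, length(alpha))
    x / sum(x)
  }
  freqs <- withr::with_seed(stream_seed(seed, 3L, 0L), {
    out <- list()
    for (l in loci) {
      anc <- rdirichlet1(rep(1, n_alleles))
      for (p in populations) {
        f <- if (fst > 0) rdirichlet1(anc * (1 - fst) / fst) else anc
        out[[length(out) + 1L]] <- tibble::tibble(
          population = p, locus = l, allele = seq_len(n_alleles), freq = f)
      }
    }
    dplyr::bind_rows(out)
  })
  draw_geno <- function(pop) {
    f <- freqs[freqs$population == pop, ]
    purrr::map_dfr(loci, function(l) {
      fr <- f[f$locus == l, ]
      al <- sample(fr$allele, 2, replace = TRUE, prob = fr$freq)
      tibble::tibble(locus = l, a1 = al[1], a2 = al[2])
    })
  }
  founders <- list(); geno <- list(); k <- 0L
  for (p in populations) {
    for (i in seq_len(founders_per_pop)) {
      k <- k + 1L
      withr::with_seed(stream_seed(seed, 4L, k), {
        id <- sprintf("F_%s_%02d", p, i)
        g <- draw_geno(p)
        geno[[length(geno) + 1L]] <- dplyr::mutate(g, individual_id = id)
        founders[[length(founders) + 1L]] <- tibble::tibble(
          individual_id = id, sex = if (i <= founders_per_pop / 2) "M" else "F",
          cohort = "founder", room = room, population = p)
      })
    }
  }
  founders <- dplyr::bind_rows(founders)
  pick_parent <- function(pop, sex) {
    pool <- founders$individual_id[founders$population == pop & founders$sex == sex]
    sample(pool, 1)
  }
  geno_by_id <- function(id) {
    gg <- dplyr::bind_rows(geno)
    gg[gg$individual_id == id, c("locus", "a1", "a2")]
  }
  matings <- withr::with_seed(stream_seed(seed, 5L, 0L), {
    rows <- list()
    for (i in seq_len(n_pure_matings)) {
      p <- populations[(i %% 2) + 1L]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        father = pick_parent(p, "M"), mother = pick_parent(p, "F"),
        class = paste0("pure_", p), sire_population = p)
    }
    for (i in seq_len(n_mixed_matings)) {
      sire_pop <- populations[(i %% 2) + 1L]
      dam_pop <- setdiff(populations, sire_pop)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        father = pick_parent(sire_pop, "M"), mother = pick_parent(dam_pop, "F"),
        class = "mixed", sire_population = sire_pop)
    }
    dplyr::bind_rows(rows)
  })
  all_geno <- dplyr::bind_rows(geno)
  gsplit <- split(all_geno[, c("locus", "a1", "a2")], all_geno$individual_id)
  truth <- list(); off_manifest <- list(); off_id <- 0L
  union_alleles <- seq_len(n_alleles)
  for (i in seq_len(nrow(matings))) {
    fg <- gsplit[[matings$father[i]]]
    mg <- gsplit[[matings$mother[i]]]
    for (j in seq_len(offspring_per_mating)) {
      off_id <- off_id + 1L
      withr::with_seed(stream_seed(seed, 6L, off_id), {
        id <- sprintf("O_%03d", off_id)
        a_f <- ifelse(runif(n_loci) < 0.5, fg$a1, fg$a2)
        a_m <- ifelse(runif(n_loci) < 0.5, mg$a1, mg$a2)
        err <- runif(2 * n_loci) < error_rate
        if (any(err)) {
          repl <- sample(union_alleles, sum(err), replace = TRUE)
          av <- c(a_f, a_m); av[err] <- repl
          a_f <- av[seq_len(n_loci)]; a_m <- av[n_loci + seq_len(n_loci)]
        }
        miss <- runif(n_loci) < missing_rate
        g <- tibble::tibble(individual_id = id, locus = loci,
                            a1 = ifelse(miss, NA_integer_, as.integer(a_f)),
                            a2 = ifelse(miss, NA_integer_, as.integer(a_m)))
        geno[[length(geno) + 1L]] <- g
        off_manifest[[off_id]] <- tibble::tibble(
          individual_id = id, sex = sample(c("M", "F"), 1), cohort = "final",
          room = room, population = NA_character_)
        truth[[off_id]] <- tibble::tibble(
          offspring_id = id, mother_id = matings$mother[i],
          father_id = matings$father[i], class = matings$class[i],
          sire_population = matings$sire_population[i])
      })
    }
  }
  genotypes <- dplyr::bind_rows(geno)[, c("individual_id", "locus", "a1", "a2")]
  list(genotypes = genotypes,
       manifest = dplyr::bind_rows(founders, dplyr::bind_rows(off_manifest)),
       truth = dplyr::bind_rows(truth),
       freqs = freqs,
       config = list(n_loci = n_loci, n_alleles = n_alleles, fst = fst,
                     founders_per_pop = founders_per_pop,
                     n_pure_matings = n_pure_matings,
                     n_mixed_matings = n_mixed_matings,
                     offspring_per_mating = offspring_per_mating,
                     error_rate = error_rate, missing_rate = missing_rate,
                     seed = seed))
}
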