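# Microsatellite population assignment and parentage.
#
# Genotypes travel as a long tibble: one row per individual x locus with
# integer allele columns `a1`, `a2` (both NA when the locus failed).
# Population assignment uses a supervised two-panel admixture MLE: founder
# allele-frequency panels are estimated per population and each individual's
# admixture proportion q toward the first panel is fitted by maximising the
# independent-allele log-likelihood. Parentage uses a single-parent
# likelihood-ratio (LOD) with an explicit genotyping-error model.

ALLELE_FLOOR <- 1e-4 # frequency floor for alleles absent from a panel

#' Read a GenePop genotype file
#'
#' Supports the common dialect: a title line, one locus name per line (or a
#' single comma-separated line), and `Pop`-delimited blocks of lines
#' `id ,  aabb aabb ...` with 2- or 3-digit allele coding (`0000`/`000000`
#' missing). The block index is recorded in `pop_block`; what a block means
#' (population, cohort) is up to a sidecar manifest.
#'
#' @param path Path to the GenePop file.
#' @return Long tibble `individual_id`, `pop_block`, `locus`, `a1`, `a2`.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) abort("GenePop file too short")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("no 'Pop' line found")
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- if (length(locus_lines) == 1L && grepl(",", locus_lines)) {
    trimws(strsplit(locus_lines, ",")[[1]])
  } else {
    trimws(locus_lines)
  }
  n_loci <- length(loci)
  rows <- list()
  block <- 0L
  for (i in seq(first_pop, length(lines))) {
    if (is_pop[i]) { block <- block + 1L; next }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2L) abort(sprintf("line %d: expected 'id , genotypes'", i))
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(toks) != n_loci) {
      abort(sprintf("line %d (%s): %d genotype fields, expected %d",
                    i, id, length(toks), n_loci))
    }
    w <- nchar(toks)
    if (!all(w %in% c(4L, 6L))) abort(sprintf("line %d: allele coding must be 4 or 6 digits", i))
    half <- w / 2
    a1 <- as.integer(substr(toks, 1, half))
    a2 <- as.integer(substr(toks, half + 1, w))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      individual_id = id, pop_block = block, locus = loci, a1 = a1, a2 = a2)
  }
  dplyr::bind_rows(rows)
}

#' Write genotypes to a GenePop file
#'
#' Inverse of [read_genepop()]: individuals are grouped by `pop_block`
#' (single block if absent) and alleles written with 3-digit coding
#' (`000000` for missing), which round-trips losslessly for repeat-length
#' labels below 1000.
#'
#' @param genotypes Long genotype tibble as from [read_genepop()].
#' @param path Output path.
#' @param title Title line (first line of the file).
#' @export
write_genepop <- function(genotypes, path, title = "mousecomp genotypes") {
  if (!"pop_block" %in% names(genotypes)) genotypes$pop_block <- 1L
  loci <- unique(genotypes$locus)
  enc <- function(a) sprintf("%03d", ifelse(is.na(a), 0L, a))
  out <- c(title, loci)
  for (b in sort(unique(genotypes$pop_block))) {
    out <- c(out, "Pop")
    sub <- genotypes[genotypes$pop_block == b, ]
    for (id in unique(sub$individual_id)) {
      g <- sub[sub$individual_id == id, ]
      g <- g[match(loci, g$locus), ]
      out <- c(out, paste0(id, " ,  ",
                           paste0(enc(g$a1), enc(g$a2), collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

genotype_split <- function(genotypes) {
  split(genotypes[, c("locus", "a1", "a2")], genotypes$individual_id)
}

#' Estimate per-population allele-frequency panels
#'
#' Counting estimator with an additive pseudocount over the union allele
#' set of each locus (union across all supplied founders), so every allele
#' observed anywhere retains positive frequency in both panels. A locus
#' with no typed founder in one population falls back to uniform over the
#' union set, with a warning.
#'
#' @param genotypes Long genotype tibble of the founders.
#' @param pop_of Named character vector or tibble (`individual_id`,
#'   `population`) labelling each founder's population.
#' @param pseudocount Additive smoothing count per allele (default 0.5).
#' @return Tibble `population`, `locus`, `allele`, `freq`; frequencies sum
#'   to 1 within population x locus.
#' @export
estimate_freqs <- function(genotypes, pop_of, pseudocount = 0.5) {
  if (is.data.frame(pop_of)) {
    pop_of <- setNames(as.character(pop_of$population), pop_of$individual_id)
  }
  g <- genotypes[genotypes$individual_id %in% names(pop_of), ]
  long <- tidyr::pivot_longer(g, c("a1", "a2"), values_to = "allele")
  long <- long[!is.na(long$allele), ]
  long$population <- unname(pop_of[long$individual_id])
  union_set <- long |>
    dplyr::distinct(.data$locus, .data$allele)
  pops <- sort(unique(pop_of))
  grid <- tidyr::expand_grid(population = pops, union_set)
  counts <- long |>
    dplyr::count(.data$population, .data$locus, .data$allele)
  panel <- grid |>
    dplyr::left_join(counts, by = c("population", "locus", "allele")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(total = sum(.data$n),
                  freq = if (sum(.data$n) + pseudocount * dplyr::n() > 0) {
                    (.data$n + pseudocount) / (sum(.data$n) + pseudocount * dplyr::n())
                  } else rep(1 / dplyr::n(), dplyr::n())) |>
    dplyr::ungroup()
  empty <- panel |>
    dplyr::distinct(.data$population, .data$locus, .data$total) |>
    dplyr::filter(.data$total == 0)
  if (nrow(empty) > 0) {
    warn(sprintf("%d population x locus panels without typed founders set to uniform",
                 nrow(empty)))
  }
  dplyr::select(panel, "population", "locus", "allele", "freq")
}

panel_lookup <- function(panel, population) {
  sub <- panel[panel$population == population, ]
  setNames(sub$freq, paste(sub$locus, sub$allele, sep = "\r"))
}

freq_of <- function(lookup, locus, allele) {
  f <- unname(lookup[paste(locus, allele, sep = "\r")])
  ifelse(is.na(f), ALLELE_FLOOR, f)
}

#' Assign population of origin by admixture-proportion MLE
#'
#' For each individual, maximises over `q` in `[0, 1]` the log-likelihood
#' `sum over allele copies of log(q f_A + (1 - q) f_B)` where `f_A`, `f_B`
#' are the two panel frequencies; loci and allele copies are treated as
#' independent. `q` is fitted by a 0.001-step grid search followed by local
#' refinement. Individuals are classed pure toward panel A when
#' `q >= thresholds[1]`, pure toward panel B when `q <= thresholds[2]`, and
#' mixed otherwise; individuals typed at fewer than `min_loci` loci are
#' `unassigned`. When the two panels are identical the likelihood is flat:
#' `q` is tie-broken to 0.5, the class is mixed and the result is flagged
#' uninformative.
#'
#' @param genotypes Long genotype tibble of the individuals to assign.
#' @param panel Output of [estimate_freqs()] with exactly two populations;
#'   panel A is the alphabetically first.
#' @param thresholds Pure-class cutoffs `c(high, low)` (default 0.9, 0.1).
#' @param min_loci Minimal number of typed loci (default 6).
#' @return Tibble `individual_id`, `n_loci`, `q_hat`, `loglik`, `class`,
#'   `uninformative`. Classes are `pure_<A>`, `pure_<B>`, `mixed`,
#'   `unassigned`.
#' @export
assign_origin <- function(genotypes, panel, thresholds = c(0.9, 0.1),
                          min_loci = 6) {
  pops <- sort(unique(panel$population))
  if (length(pops) != 2L) abort("panel must contain exactly two populations")
  lkA <- panel_lookup(panel, pops[1])
  lkB <- panel_lookup(panel, pops[2])
  qgrid <- seq(0, 1, by = 0.001)
  per_ind <- genotype_split(genotypes)
  rows <- purrr::imap(per_ind, function(g, id) {
    ok <- !is.na(g$a1) & !is.na(g$a2)
    n_loci <- sum(ok)
    if (n_loci < min_loci) {
      return(tibble::tibble(individual_id = id, n_loci = n_loci,
                            q_hat = NA_real_, loglik = NA_real_,
                            class = "unassigned", uninformative = NA))
    }
    loci <- rep(g$locus[ok], 2L)
    alleles <- c(g$a1[ok], g$a2[ok])
    fA <- freq_of(lkA, loci, alleles)
    fB <- freq_of(lkB, loci, alleles)
    ll <- function(q) sum(log(q * fA + (1 - q) * fB))
    llg <- vapply(qgrid, ll, numeric(1))
    if (max(llg) - min(llg) < 1e-8) {
      return(tibble::tibble(individual_id = id, n_loci = n_loci, q_hat = 0.5,
                            loglik = ll(0.5), class = "mixed",
                            uninformative = TRUE))
    }
    qi <- qgrid[which.max(llg)]
    lo <- max(0, qi - 0.001); hi <- min(1, qi + 0.001)
    opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-9)
    q_hat <- if (opt$objective >= max(llg)) opt$maximum else qi
    cls <- if (q_hat >= thresholds[1]) paste0("pure_", pops[1])
           else if (q_hat <= thresholds[2]) paste0("pure_", pops[2])
           else "mixed"
    tibble::tibble(individual_id = id, n_loci = n_loci, q_hat = q_hat,
                   loglik = ll(q_hat), class = cls, uninformative = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Single-parent parentage LOD score
#'
#' log10 likelihood ratio that `candidate` is a parent of `offspring`
#' against the null that the offspring's alleles are random draws from the
#' background frequencies (Hardy-Weinberg). At each locus one offspring
#' allele comes from the candidate -- transmitted correctly with probability
#' `1 - error_rate`, otherwise drawn from the background -- and the other
#' from the background. Mendelian-incompatible loci therefore contribute a
#' large negative term instead of a hard exclusion, becoming `-Inf` only
#' when `error_rate = 0`. Loci missing in either individual are skipped.
#'
#' @param offspring,candidate Genotype tibbles (`locus`, `a1`, `a2`) for one
#'   individual each.
#' @param freqs Background allele frequencies: tibble `locus`, `allele`,
#'   `freq` (e.g. one population of [estimate_freqs()], or room-pooled).
#' @param error_rate Per-allele genotyping error rate (default 0.01).
#' @return LOD score (log10), with the number of loci compared as attribute
#'   `n_loci`.
#' @export
parent_lod <- function(offspring, candidate, freqs, error_rate = 0.01) {
  lk <- setNames(freqs$freq, paste(freqs$locus, freqs$allele, sep = "\r"))
  cand <- candidate[match(offspring$locus, candidate$locus), ]
  ok <- !is.na(offspring$a1) & !is.na(offspring$a2) &
    !is.na(cand$a1) & !is.na(cand$a2)
  o1 <- offspring$a1[ok]; o2 <- offspring$a2[ok]
  c1 <- cand$a1[ok]; c2 <- cand$a2[ok]
  loci <- offspring$locus[ok]
  p1 <- freq_of(lk, loci, o1)
  p2 <- freq_of(lk, loci, o2)
  m <- function(x) ((c1 == x) + (c2 == x)) / 2
  tr <- function(x, px) (1 - error_rate) * m(x) + error_rate * px
  het <- o1 != o2
  num <- ifelse(het, tr(o1, p1) * p2 + tr(o2, p2) * p1, tr(o1, p1) * p1)
  den <- ifelse(het, 2 * p1 * p2, p1 * p2)
  lod <- sum(log10(num) - log10(den))
  attr(lod, "n_loci") <- sum(ok)
  lod
}

#' Parental population assignment by top-two-candidate consensus
#'
#' For each offspring and each parental sex, ranks all sex-appropriate
#' adult candidates in the same room by LOD (ties broken by candidate id
#' for determinism) and accepts a parental population only when the two
#' top-ranked candidates come from the same population; otherwise the
#' assignment is `undetermined` (as it is when fewer than two candidates
#' exist). Background frequencies are room-pooled over the candidate
#' adults.
#'
#' @param offspring_ids Character vector of offspring to assign.
#' @param genotypes Long genotype tibble covering offspring and candidates.
#' @param manifest Tibble `individual_id`, `sex` (`"M"`/`"F"`), `cohort`,
#'   `room`, `population`; candidates are rows with `cohort` in
#'   `candidate_cohorts`.
#' @param error_rate Genotyping error rate passed to [parent_lod()].
#' @param pseudocount Smoothing for the room-pooled background frequencies.
#' @param candidate_cohorts Cohorts eligible as parents (default founder
#'   and health-check adults).
#' @return Tibble `offspring_id`, `parent_sex`, `parent1_id`, `lod1`,
#'   `parent2_id`, `lod2`, `consensus_population`.
#' @export
assign_parent_population <- function(offspring_ids, genotypes, manifest,
                                     error_rate = 0.01, pseudocount = 0.5,
                                     candidate_cohorts = c("founder", "healthcheck")) {
  gsplit <- genotype_split(genotypes)
  rooms <- setNames(manifest$room, manifest$individual_id)
  rows <- list()
  for (room in unique(manifest$room[manifest$individual_id %in% offspring_ids])) {
    adults <- manifest[manifest$room == room &
                         manifest$cohort %in% candidate_cohorts &
                         manifest$individual_id %in% names(gsplit), ]
    # room-pooled background over all candidate adults, both populations
    bg <- estimate_freqs(genotypes[genotypes$individual_id %in% adults$individual_id, ],
                         setNames(rep("pooled", nrow(adults)), adults$individual_id),
                         pseudocount = pseudocount)
    bg <- bg[, c("locus", "allele", "freq")]
    offs <- intersect(offspring_ids[rooms[offspring_ids] == room], names(gsplit))
    for (off in offs) {
      for (sx in c("M", "F")) {
        cand <- adults[adults$sex == sx & adults$individual_id != off, ]
        if (nrow(cand) < 2L) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            offspring_id = off, parent_sex = sx,
            parent1_id = NA_character_, lod1 = NA_real_,
            parent2_id = NA_character_, lod2 = NA_real_,
            consensus_population = "undetermined")
          next
        }
        lods <- vapply(cand$individual_id, function(cid) {
          as.numeric(parent_lod(gsplit[[off]], gsplit[[cid]], bg, error_rate))
        }, numeric(1))
        ord <- order(-lods, cand$individual_id)
        top <- cand[ord[1:2], ]
        consensus <- if (top$population[1] == top$population[2]) {
          top$population[1]
        } else "undetermined"
        rows[[length(rows) + 1L]] <- tibble::tibble(
          offspring_id = off, parent_sex = sx,
          parent1_id = top$individual_id[1], lod1 = lods[ord[1]],
          parent2_id = top$individual_id[2], lod2 = lods[ord[2]],
          consensus_population = consensus)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Equal-proportions tests on sire counts
#'
#' For each room and pooled over rooms, tests whether mixed-background
#' offspring are sired equally often by males of the two populations:
#' the continuity-corrected proportion test, with the exact binomial
#' alongside. Undetermined offspring are excluded; a room with zero
#' determined offspring is skipped.
#'
#' @param counts Tibble with a `room` column and one `<population>_sired`
#'   count column per population (see [example_sire_counts()]).
#' @param populations The two sire populations; `k` counts the first
#'   (default `c("CB", "MC")`).
#' @param alternative Test direction (default two-sided).
#' @return Tidy tibble with one row per room (and `pooled`) and method.
#' @export
sire_population_test <- function(counts, populations = c("CB", "MC"),
                                 alternative = "two_sided") {
  cols <- paste0(tolower(populations), "_sired")
  need <- c("room", cols)
  miss <- setdiff(need, names(counts))
  if (length(miss)) abort(paste("counts is missing columns:", paste(miss, collapse = ", ")))
  pooled <- tibble::as_tibble(c(list(room = "pooled"),
                                setNames(list(sum(counts[[cols[1]]]),
                                              sum(counts[[cols[2]]])), cols)))
  all_rows <- dplyr::bind_rows(counts[, need], pooled)
  out <- list()
  for (i in seq_len(nrow(all_rows))) {
    k <- all_rows[[cols[1]]][i]; n <- k + all_rows[[cols[2]]][i]
    if (n == 0L) {
      inform(sprintf("room %s has no determined offspring; skipped", all_rows$room[i]))
      next
    }
    for (tst in list(prop_test_cc(k, n, 0.5, alternative),
                     binom_exact(k, n, 0.5, alternative))) {
      td <- tidy(tst)
      td$room <- all_rows$room[i]
      td$k <- k; td$n <- n
      out[[length(out) + 1L]] <- td
    }
  }
  dplyr::bind_rows(out)
}
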