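# Two-arena enclosure tracking: raw dual-antenna RFID reads -> occupancy
# intervals -> per-mouse movement metrics -> population comparisons.
#
# Geometry: two round arenas (A and B) joined by three tubes; each tube
# carries one antenna at each end, and the side-A antenna sits at the
# arena-A entrance. A read therefore places the mouse at that arena's end
# of a tube.

#' Read an antenna log file
#'
#' Expects a CSV with columns `timestamp` (ISO-8601 or epoch seconds),
#' `antenna_tube`, `antenna_side`, `tag_id`. Rows with an unknown antenna
#' (tube outside 1..3 or side outside A/B) are rejected, counted and
#' reported; exact duplicate detections are collapsed; output is sorted by
#' tag and time.
#'
#' @param path Path to the CSV file.
#' @return Tibble `time_s`, `tube`, `side`, `tag_id` with attribute
#'   `n_rejected`.
#' @export
read_antenna <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("timestamp", "antenna_tube", "antenna_side", "tag_id")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste("antenna log is missing columns:", paste(miss, collapse = ", ")))
  ts <- raw$timestamp
  time_s <- if (is.numeric(ts)) as.numeric(ts) else {
    as.numeric(as.POSIXct(as.character(ts), tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")))
  }
  out <- tibble::tibble(time_s = time_s,
                        tube = suppressWarnings(as.integer(raw$antenna_tube)),
                        side = toupper(as.character(raw$antenna_side)),
                        tag_id = as.character(raw$tag_id))
  ok <- !is.na(out$time_s) & !is.na(out$tube) & out$tube %in% 1:3 & out$side %in% c("A", "B")
  n_rejected <- sum(!ok)
  if (n_rejected > 0) warn(sprintf("%d rows with unknown antenna rejected", n_rejected))
  out <- out[ok, ]
  out <- dplyr::distinct(out)
  out <- dplyr::arrange(out, .data$tag_id, .data$time_s)
  attr(out, "n_rejected") <- n_rejected
  out
}

check_read_cols <- function(reads) {
  need <- c("time_s", "tube", "side", "tag_id")
  miss <- setdiff(need, names(reads))
  if (length(miss)) abort(paste("reads is missing columns:", paste(miss, collapse = ", ")))
}

#' Infer arena occupancy intervals from antenna reads
#'
#' Deterministic single pass per tag: the stretch from the opening of the
#' connections to the first read is assigned to the mouse's home arena
#' (mice were born and raised there); the interval between two consecutive
#' reads on the same side -- any tube -- is assigned to that side's arena;
#' the interval between opposite-side reads is left unassigned (the mouse
#' crossed at some unknown moment, possibly missing intermediate antenna
#' detections) and counts as exactly one passage; the tail after the last
#' read is assigned to that read's side. Tags without any read are excluded
#' and reported. The returned intervals tile `[t_open, t_end]` exactly.
#'
#' @param reads Tibble `time_s`, `tube`, `side`, `tag_id`.
#' @param home_arena Named character vector (`"A"`/`"B"` per tag) or a
#'   single value recycled to all tags.
#' @param t_open,t_end Start and end of the experiment window (seconds,
#'   `t_open < t_end`). Reads outside the window are clipped with a warning.
#' @return Tibble `tag_id`, `start_s`, `end_s`, `location`
#'   (`arena_A`/`arena_B`/`unassigned`), with attribute `excluded` listing
#'   read-free tags (from `names(home_arena)`).
#' @export
infer_occupancy <- function(reads, home_arena, t_open, t_end) {
  check_read_cols(reads)
  if (t_open >= t_end) abort("t_open must precede t_end")
  tags <- unique(reads$tag_id)
  if (length(home_arena) == 1L && is.null(names(home_arena))) {
    home_arena <- setNames(rep(home_arena, length(tags)), tags)
  }
  outside <- reads$time_s < t_open | reads$time_s > t_end
  if (any(outside)) {
    warn(sprintf("%d reads outside [t_open, t_end] clipped", sum(outside)))
    reads <- reads[!outside, ]
  }
  arena_of <- function(side) paste0("arena_", side)
  pieces <- reads |>
    dplyr::arrange(.data$tag_id, .data$time_s) |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::group_map(function(df, key) {
      tag <- key$tag_id[[1]]
      home <- home_arena[[tag]]
      if (is.null(home) || is.na(home)) abort(sprintf("no home arena for tag %s", tag))
      times <- df$time_s; sides <- df$side
      k <- length(times)
      starts <- c(t_open, times)
      ends <- c(times, t_end)
      loc <- c(arena_of(home),
               ifelse(sides[-k] == sides[-1], arena_of(sides[-1]), "unassigned")[seq_len(max(k - 1, 0))],
               arena_of(sides[k]))
      tibble::tibble(tag_id = tag, start_s = starts, end_s = ends, location = loc)
    })
  out <- dplyr::bind_rows(pieces)
  out <- out[out$end_s > out$start_s, ] # drop zero-length pieces
  excluded <- setdiff(names(home_arena), tags)
  attr(out, "excluded") <- excluded
  out
}

#' Per-mouse movement and latency metrics
#'
#' From the raw reads and inferred occupancy of each tagged mouse:
#' * `touch_latency_s` -- time from the opening of the connections to the
#'   first antenna registration anywhere;
#' * `cross_latency_s` -- time from that first registration to the first
#'   registration on the foreign arena's side (missing if the mouse never
#'   reached it);
#' * `n_passages` -- number of opposite-side transitions in the read
#'   sequence (each counted once, the minimum number of crossings the
#'   evidence implies);
#' * `n_sessions` -- number of maximal runs of reads at one antenna with
#'   internal gaps of at most `session_gap_s` seconds;
#' * `time_home_h` / `time_foreign_h` -- assigned occupancy time, in hours;
#' * `fraction_assigned` -- assigned share of the experiment window.
#'
#' Tags never registered at any antenna are excluded (listed in attribute
#' `excluded`).
#'
#' @inheritParams infer_occupancy
#' @param manifest Tibble `tag_id`, `population`, `sex`, `weight_g`,
#'   `home_arena`.
#' @param session_gap_s Maximal within-session read gap (default 10 s).
#' @return Tibble of per-mouse metrics joined with the manifest.
#' @export
rfid_metrics <- function(reads, manifest, t_open, t_end, session_gap_s = 10) {
  check_read_cols(reads)
  need <- c("tag_id", "population", "sex", "weight_g", "home_arena")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) abort(paste("manifest is missing columns:", paste(miss, collapse = ", ")))
  home_arena <- setNames(manifest$home_arena, manifest$tag_id)
  occ <- infer_occupancy(reads, home_arena, t_open, t_end)
  reads <- reads |>
    dplyr::filter(.data$time_s >= t_open, .data$time_s <= t_end) |>
    dplyr::arrange(.data$tag_id, .data$time_s)

  per_tag <- reads |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::group_map(function(df, key) {
      tag <- key$tag_id[[1]]
      home <- home_arena[[tag]]
      foreign <- setdiff(c("A", "B"), home)
      first_t <- df$time_s[1]
      first_foreign <- df$time_s[df$side == foreign][1]
      antenna <- paste0(df$tube, df$side)
      new_sess <- c(TRUE, antenna[-1] != antenna[-nrow(df)] |
                      diff(df$time_s) > session_gap_s)
      tibble::tibble(
        tag_id = tag,
        touch_latency_s = first_t - t_open,
        cross_latency_s = if (is.na(first_foreign)) NA_real_ else first_foreign - first_t,
        n_passages = sum(df$side[-1] != df$side[-nrow(df)]),
        n_sessions = sum(new_sess)
      )
    }) |>
    dplyr::bind_rows()

  occ_sum <- occ |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(
      assigned_s = sum((.data$end_s - .data$start_s)[.data$location != "unassigned"]),
      .groups = "drop"
    )
  home_time <- occ |>
    dplyr::mutate(home = paste0("arena_", home_arena[.data$tag_id]) == .data$location) |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(
      time_home_h = sum((.data$end_s - .data$start_s)[.data$home]) / 3600,
      time_foreign_h = sum((.data$end_s - .data$start_s)[!.data$home &
                                                           .data$location != "unassigned"]) / 3600,
      .groups = "drop"
    )
  out <- per_tag |>
    dplyr::left_join(occ_sum, by = "tag_id") |>
    dplyr::left_join(home_time, by = "tag_id") |>
    dplyr::mutate(fraction_assigned = .data$assigned_s / (t_end - t_open)) |>
    dplyr::select(-"assigned_s")
  out <- dplyr::inner_join(manifest, out, by = "tag_id")
  excluded <- setdiff(manifest$tag_id, out$tag_id)
  if (length(excluded)) {
    inform(sprintf("%d tags never registered at any antenna excluded", length(excluded)))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Compare movement metrics between the two populations
#'
#' Runs the per-metric rank-sum comparisons (touch and cross latency,
#' passages, sessions, foreign-arena time, body weight), the two latency /
#' space-use correlations, and a PERMANOVA of the four behavioural metrics
#' on population, sex and weight (sequential terms, log(x+1)-standardised
#' Euclidean response). Mice with a missing metric are excluded pairwise
#' from that comparison; the PERMANOVA uses complete cases.
#'
#' @param metrics Output of [rfid_metrics()].
#' @param n_perm Permutations for the PERMANOVA (default 999).
#' @param seed RNG seed for the PERMANOVA permutations.
#' @return List of class `cohort_compare`: `summary` (per-population
#'   mean/sd/median/min/max for each metric), `tests` (tidy tibble) and
#'   `permanova`.
#' @export
cohort_compare <- function(metrics, n_perm = 999, seed = 1234) {
  pops <- sort(unique(metrics$population))
  if (length(pops) != 2L) abort("exactly two populations expected")
  if (any(table(metrics$population) < 2L)) abort("need >= 2 mice per population")
  vars <- c("weight_g", "n_sessions", "touch_latency_s", "cross_latency_s",
            "time_foreign_h", "n_passages")
  summary <- metrics |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "metric") |>
    dplyr::group_by(.data$population, .data$metric) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      median = median(.data$value, na.rm = TRUE),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      .groups = "drop"
    )
  tests <- list()
  for (v in vars) {
    x <- metrics[[v]][metrics$population == pops[1]]
    y <- metrics[[v]][metrics$population == pops[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L) {
      inform(sprintf("metric %s entirely missing in one population; skipped", v))
      next
    }
    tests[[v]] <- mann_whitney(x, y)
  }
  ok_lat <- complete.cases(metrics$touch_latency_s, metrics$cross_latency_s)
  if (sum(ok_lat) >= 3) {
    tests[["cor_touch_cross"]] <- pearson_cor(metrics$touch_latency_s[ok_lat],
                                              metrics$cross_latency_s[ok_lat])
  }
  tests[["cor_foreign_passages"]] <- pearson_cor(metrics$time_foreign_h,
                                                 metrics$n_passages)
  resp_vars <- c("touch_latency_s", "cross_latency_s", "n_sessions", "time_foreign_h")
  cc <- complete.cases(metrics[, c(resp_vars, "population", "sex", "weight_g")])
  pmv <- permanova_test(
    metrics[cc, resp_vars],
    data.frame(population = factor(metrics$population[cc]),
               sex = factor(metrics$sex[cc]),
               weight = metrics$weight_g[cc]),
    n_perm = n_perm, seed = seed
  )
  structure(list(summary = summary, tests = tidy_tests(tests), permanova = pmv),
            class = "cohort_compare")
}

#' @export
print.cohort_compare <- function(x, ...) {
  cat("Between-population comparison of enclosure metrics\n")
  print(x$tests, ...)
  cat("\nPERMANOVA:\n")
  print(x$permanova, ...)
  invisible(x)
}
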